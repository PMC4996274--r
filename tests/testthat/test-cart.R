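test_that("node deviance matches its closed forms", {
  expect_equal(node_deviance(5, 0), 0)
  expect_equal(node_deviance(0, 7), 0)
  expect_equal(node_deviance(5, 5), 20 * log(2))
  expect_equal(node_deviance(10, 20),
               -2 * (10 * log(1 / 3) + 20 * log(2 / 3)))
  expect_equal(node_deviance(10, 20), 38.1908, tolerance = 1e-3)
  expect_error(node_deviance(0, 0), "empty")
})

test_that("any split is deviance-reducing (additivity)", {
  set.seed(61)
  for (i in 1:100) {
    n <- sample(4:30, 1)                      # parent: ne / (n - ne)
    ne <- sample(1:(n - 1), 1)
    nl <- sample(1:(n - 1), 1)                # left child size
    lo <- max(0, nl - (n - ne))
    hi <- min(ne, nl)
    nle <- if (lo == hi) lo else sample(lo:hi, 1)  # expressing going left
    d_parent <- node_deviance(ne, n - ne)
    d_kids <- node_deviance(nle, nl - nle) +
      node_deviance(ne - nle, (n - ne) - (nl - nle))
    expect_lte(d_kids, d_parent + 1e-9)
  }
})

test_that("best split separates a perfectly informative site", {
  x <- cbind(noise = c(0.5, 0.4, 0.6, 0.5, 0.45, 0.55),
             inf = c(0.1, 0.2, 0.15, 0.8, 0.9, 0.85))
  y <- c(1, 1, 1, 0, 0, 0)
  sp <- best_split(x, y)
  expect_equal(sp$site, "inf")
  expect_equal(sp$child_deviance, 0)
  expect_gt(sp$threshold, 0.2)
  expect_lt(sp$threshold, 0.8)

  # constant frequencies: no candidate thresholds
  expect_null(best_split(cbind(f = rep(0.4, 6)), y))
  # pure node: nothing to split
  expect_null(best_split(x, rep(0, 6)))
  # equal-deviance tie broken toward the earlier column
  x2 <- cbind(a = c(0.1, 0.9), b = c(0.1, 0.9))
  sp2 <- best_split(x2, c(1, 0))
  expect_equal(sp2$site, "a")
})

test_that("best split agrees with exhaustive enumeration", {
  set.seed(62)
  for (i in 1:40) {
    n <- sample(4:8, 1)
    x <- matrix(round(runif(n * 3), 2), n, 3,
                dimnames = list(NULL, c("s1", "s2", "s3")))
    y <- sample(0:1, n, replace = TRUE)
    if (sum(y) == 0 || sum(y) == n) next
    got <- best_split(x, y)
    want <- oracle_best_split(x, y)
    parent <- node_deviance(sum(y), n - sum(y))
    if (is.null(got)) {
      expect_gte(want$child_deviance, parent - 1e-9)
    } else {
      expect_equal(got$child_deviance, want$child_deviance)
      expect_equal(got$site, want$site)
    }
  }
})

test_that("growth stopping rules produce the expected trees", {
  # all one class: single leaf, zero deviance
  d_pure <- tibble::tibble(expression = rep(0L, 30),
                           f1 = runif(30))
  fit <- grow_tree(d_pure)
  expect_equal(fit$size, 1L)
  expect_equal(fit$deviance, 0)

  # perfectly separable single site: two leaves, zero deviance
  d_sep <- tibble::tibble(expression = rep(c(1L, 0L), c(10, 20)),
                          f1 = c(runif(10, 0, 0.3), runif(20, 0.6, 1)))
  fit2 <- grow_tree(d_sep)
  expect_equal(fit2$size, 2L)
  expect_equal(fit2$deviance, 0)
  expect_equal(misclassification(fit2)$count, 0)

  # 9 mixed cases: terminal despite impurity (n < 10 stop)
  d_nine <- tibble::tibble(expression = rep(c(1L, 0L), c(4, 5)),
                           f1 = seq(0.1, 0.9, length.out = 9))
  fit3 <- grow_tree(d_nine)
  expect_equal(fit3$size, 1L)
  expect_gt(fit3$deviance, 0)
})

test_that("pruning minimizes deviance plus 2 per leaf", {
  # gain of the only useful split chain < 2 per added leaf: collapse
  d <- tibble::tibble(expression = c(0L, 1L, 0L), f1 = c(1, 2, 3))
  full <- grow_tree(d, min_node = 1, min_dev_frac = 0)
  expect_equal(full$size, 3L)
  expect_equal(full$deviance, 0)
  pruned <- prune_tree(full, k = 2)
  expect_equal(pruned$size, 1L)
  expect_equal(pruned$deviance, node_deviance(1, 2))
  # k = 0 keeps the deviance-optimal full tree
  expect_equal(prune_tree(full, k = 0)$size, 3L)
  # single-leaf tree unchanged
  single <- grow_tree(tibble::tibble(expression = rep(1L, 5), f1 = 1:5))
  expect_equal(prune_tree(single, 2)$size, 1L)
})

test_that("pruned trees attain the exhaustive cost-complexity minimum", {
  set.seed(63)
  for (i in 1:30) {
    n <- sample(5:8, 1)
    d <- tibble::tibble(expression = sample(0:1, n, replace = TRUE))
    for (s in 1:3) d[[paste0("f", s)]] <- round(runif(n), 2)
    if (length(unique(d$expression)) < 2) next
    full <- grow_tree(d, min_node = 1, min_dev_frac = 0)
    pruned <- prune_tree(full, k = 2)
    expect_equal(pruned$deviance + 2 * pruned$size,
                 oracle_min_cost_complexity(full, k = 2))
  }
})

test_that("prediction descends thresholds and flags missing sites", {
  d <- tibble::tibble(expression = rep(c(1L, 0L), c(10, 20)),
                      `f1.-765` = c(runif(10, 0, 0.3), runif(20, 0.6, 1)))
  fit <- meth_cart(d)
  expect_equal(fit$size, 2L)
  pred <- predict(fit, tibble::tibble(`f1.-765` = c(0.1, 0.9)))
  expect_equal(as.character(pred), c("P", "A"))
  # resubstitution on separable training data is perfect
  expect_equal(as.character(predict(fit, d)),
               ifelse(d$expression == 1, "P", "A"))
  expect_error(predict(fit, tibble::tibble(other = 1)), "f1.-765")

  single <- grow_tree(tibble::tibble(expression = rep(0L, 12), f1 = 1:12))
  expect_equal(as.character(predict(single, tibble::tibble(f1 = 5))), "A")
})

test_that("misclassification ratios follow the minority-count rule", {
  d <- tibble::tibble(expression = rep(c(1L, 0L), c(2, 8)),
                      f1 = runif(10))
  fit <- grow_tree(d)      # n = 10 but likely no useful split; force leaf
  nodes <- tidy(fit)
  root <- nodes[1, ]
  expect_equal(root$label, "A")
  expect_equal(root$misclass_ratio, 2 / 10)
  mis <- misclassification(fit, d, d$expression)
  expect_equal(mis$count, sum(predict(fit, d) !=
                                ifelse(d$expression == 1, "P", "A")))
})

test_that("tree JSON serialization round-trips byte-identically", {
  d <- simulate_frequency_cohort(10, 20, planted_site = -765, seed = 71)
  fit <- meth_cart(d)
  js <- cart_to_json(fit)
  fit2 <- cart_from_json(js)
  js2 <- cart_to_json(fit2)
  expect_identical(as.character(js), as.character(js2))
  # leaf count in the document equals size(T)
  doc <- jsonlite::fromJSON(js, simplifyVector = FALSE)
  count_leaves <- function(nd) {
    if (is.null(nd$site)) 1L
    else count_leaves(nd$left) + count_leaves(nd$right)
  }
  expect_equal(count_leaves(doc$root), fit$size)
  # thresholds at full precision
  expect_identical(tidy(fit2)$threshold, tidy(fit)$threshold)
  # file round trip
  f <- withr::local_tempfile(fileext = ".json")
  cart_to_json(fit, f)
  expect_identical(cart_to_json(cart_from_json(f)), js)
})

test_that("planted informative site is recovered by the root split", {
  set.seed(72)
  hits <- 0
  for (i in 1:20) {
    d <- simulate_frequency_cohort(10, 20, planted_site = -765)
    fit <- meth_cart(d)
    if (!is.null(fit$root$split) && fit$root$split$site == "f1.-765") {
      hits <- hits + 1
    }
  }
  expect_gte(hits, 19)
})
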