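#' Node deviance of a two-class classification tree node
#'
#' The multinomial -2 log-likelihood of the class counts at a node,
#' `D = -2 * sum_k n_k * ln(n_k / n)` with `0 * ln(0) = 0`: zero for a
#' pure node, maximal (per case) at a 50/50 split. On this scale the
#' cost-complexity penalty `k = 2` per terminal node is exactly AIC.
#'
#' @param n_exp,n_nonexp Class counts (vectorized).
#' @return Deviance value(s).
#' @export
#' @examples
#' node_deviance(5, 0)    # 0
#' node_deviance(5, 5)    # 20 * log(2)
node_deviance <- function(n_exp, n_nonexp) {
  n <- n_exp + n_nonexp
  if (any(n < 1)) abort("empty node")
  xlogy <- function(a, p) ifelse(a == 0, 0, a * log(p))
  d <- -2 * (xlogy(n_exp, n_exp / n) + xlogy(n_nonexp, n_nonexp / n))
  ifelse(d == 0, 0, d)    # normalize -0
}

.as_cart_xy <- function(data, label_col = "expression", sites = NULL,
                        id_col = "clone_id") {
  data <- as_tibble(data)
  if (!label_col %in% names(data)) {
    abort(sprintf("no label column '%s'", label_col))
  }
  y <- data[[label_col]]
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  if (any(!y %in% c(0L, 1L))) abort("labels must be binary 0/1")
  if (is.null(sites)) {
    sites <- setdiff(names(data)[vapply(data, is.numeric, TRUE)],
                     c(label_col, id_col))
  }
  x <- as.matrix(data[sites])
  rownames(x) <- if (id_col %in% names(data)) data[[id_col]] else NULL
  list(x = x, y = y, sites = sites)
}

#' Exhaustive best deviance split of a node
#'
#' Evaluates every candidate site and every midpoint between consecutive
#' sorted unique frequency values, and returns the split minimizing the
#' sum of the two child deviances. Cases with value strictly below the
#' threshold go left. Ties are broken toward the earlier site (ascending
#' column order) and then the smaller threshold. Returns `NULL` when no
#' split reduces the deviance (including pure or constant nodes).
#'
#' @param data Wide tibble (or matrix) of per-clone site frequencies.
#' @param labels Binary labels (1 = expressing); taken from
#'   `data[[label_col]]` if missing.
#' @param sites Candidate site columns (default: all numeric columns
#'   except the label and `clone_id`).
#' @param label_col,id_col Column names used when `labels` is missing.
#' @return `NULL`, or a list with `site`, `threshold`, `child_deviance`.
#' @export
best_split <- function(data, labels = NULL, sites = NULL,
                       label_col = "expression", id_col = "clone_id") {
  if (is.null(labels)) {
    xy <- .as_cart_xy(data, label_col, sites, id_col)
    x <- xy$x; y <- xy$y
  } else {
    x <- as.matrix(data)
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
    y <- as.integer(labels)
  }
  .best_split_xy(x, y)
}

.best_split_xy <- function(x, y) {
  n <- length(y)
  n_exp <- sum(y)
  n_non <- n - n_exp
  if (n < 2 || n_exp == 0 || n_non == 0) return(NULL)
  parent_dev <- node_deviance(n_exp, n_non)
  best <- NULL
  best_dev <- Inf
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    ord <- order(v)
    vs <- v[ord]
    ys <- y[ord]
    last <- which(diff(vs) > 0)            # last index of each unique value
    if (length(last) == 0) next
    ce <- cumsum(ys)[last]
    cn <- cumsum(1L - ys)[last]
    nl <- last
    dev <- .child_dev_sum(ce, cn, n_exp - ce, n_non - cn)
    jmin <- which.min(dev)
    if (dev[jmin] < best_dev) {
      best_dev <- dev[jmin]
      thr <- unname((vs[last[jmin]] + vs[last[jmin] + 1L]) / 2)
      best <- list(site = colnames(x)[j], threshold = thr,
                   child_deviance = dev[jmin])
    }
  }
  if (is.null(best) || best$child_deviance >= parent_dev - 1e-9) {
    return(NULL)
  }
  best
}

.child_dev_sum <- function(le, ln, re, rn) {
  xlogy <- function(a, p) ifelse(a == 0, 0, a * log(p))
  d1 <- -2 * (xlogy(le, le / (le + ln)) + xlogy(ln, ln / (le + ln)))
  d2 <- -2 * (xlogy(re, re / (re + rn)) + xlogy(rn, rn / (re + rn)))
  d1 + d2
}

.grow_node <- function(x, y, min_node, min_dev, depth = 0) {
  n_exp <- sum(y)
  n_non <- length(y) - n_exp
  node <- list(n_exp = n_exp, n_nonexp = n_non,
               deviance = node_deviance(n_exp, n_non),
               label = if (n_exp > n_non) "P" else "A",
               split = NULL, left = NULL, right = NULL)
  if (length(y) < min_node || node$deviance < min_dev) return(node)
  sp <- .best_split_xy(x, y)
  if (is.null(sp)) return(node)
  lidx <- x[, sp$site] < sp$threshold
  node$split <- list(site = sp$site, threshold = sp$threshold)
  node$left <- .grow_node(x[lidx, , drop = FALSE], y[lidx],
                          min_node, min_dev, depth + 1)
  node$right <- .grow_node(x[!lidx, , drop = FALSE], y[!lidx],
                           min_node, min_dev, depth + 1)
  node
}

.tree_stats <- function(node) {
  if (is.null(node$split)) {
    return(list(size = 1L, deviance = node$deviance))
  }
  l <- .tree_stats(node$left)
  r <- .tree_stats(node$right)
  list(size = l$size + r$size, deviance = l$deviance + r$deviance)
}

.new_cart <- function(root, sites, params, pruned) {
  st <- .tree_stats(root)
  structure(list(root = root, sites = sites,
                 size = st$size, deviance = st$deviance,
                 root_deviance = root$deviance,
                 params = params, pruned = pruned),
            class = "meth_cart")
}

#' Grow a classification tree over CpG methylation frequencies
#'
#' Recursive partitioning of expressing (P) vs non-expressing (A) clones
#' on per-site methylation frequencies, splitting by exhaustive deviance
#' minimization ([best_split()]). A node becomes terminal when it holds
#' fewer than `min_node` cases, when its deviance falls below
#' `min_dev_frac` of the root deviance, or when no split reduces the
#' deviance.
#'
#' @inheritParams best_split
#' @param min_node Minimum cases for a node to be split (strictly-less
#'   stopping: a node with `n < min_node` is terminal). Default 10.
#' @param min_dev_frac Homogeneity stop as a fraction of root deviance.
#'   Default 0.01.
#' @return An unpruned `meth_cart` tree.
#' @seealso [prune_tree()], [meth_cart()]
#' @export
grow_tree <- function(data, labels = NULL, sites = NULL, min_node = 10,
                      min_dev_frac = 0.01, label_col = "expression",
                      id_col = "clone_id") {
  if (is.null(labels)) {
    xy <- .as_cart_xy(data, label_col, sites, id_col)
  } else {
    x <- as.matrix(data)
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
    xy <- list(x = x, y = as.integer(labels), sites = colnames(x))
  }
  if (length(xy$y) < 1) abort("no cases")
  root_dev <- node_deviance(sum(xy$y), length(xy$y) - sum(xy$y))
  root <- .grow_node(xy$x, xy$y, min_node, min_dev_frac * root_dev)
  .new_cart(root, xy$sites,
            params = list(min_node = min_node, min_dev_frac = min_dev_frac),
            pruned = FALSE)
}

#' Cost-complexity (AIC) pruning
#'
#' Selects, among all pruned subtrees of the grown tree, the one
#' minimizing the cost-complexity `D(T) + k * size(T)` where `D(T)` is the
#' sum of leaf deviances and `size(T)` the number of terminal nodes; with
#' `k = 2` (the default) this is AIC on the deviance scale. The optimum is
#' found exactly by bottom-up dynamic programming; ties are broken toward
#' the smaller tree.
#'
#' @param tree A `meth_cart` from [grow_tree()].
#' @param k Cost-complexity parameter (penalty per terminal node).
#' @return The pruned `meth_cart`.
#' @export
prune_tree <- function(tree, k = 2) {
  stopifnot(inherits(tree, "meth_cart"))
  prune_node <- function(node) {
    leaf_cost <- node$deviance + k
    if (is.null(node$split)) return(list(node = node, cost = leaf_cost))
    l <- prune_node(node$left)
    r <- prune_node(node$right)
    split_cost <- l$cost + r$cost
    if (leaf_cost <= split_cost) {       # tie -> collapse (smaller tree)
      node$split <- NULL
      node$left <- NULL
      node$right <- NULL
      return(list(node = node, cost = leaf_cost))
    }
    node$left <- l$node
    node$right <- r$node
    list(node = node, cost = split_cost)
  }
  pruned <- prune_node(tree$root)$node
  out <- .new_cart(pruned, tree$sites, tree$params, pruned = TRUE)
  out$params$k <- k
  out
}

#' Fit a pruned classification tree in one call
#'
#' Convenience wrapper: [grow_tree()] followed by [prune_tree()].
#'
#' @inheritParams grow_tree
#' @inheritParams prune_tree
#' @param prune Prune after growing (default `TRUE`).
#' @return A `meth_cart`.
#' @export
#' @examples
#' d <- simulate_frequency_cohort(10, 20, planted_site = -765, seed = 1)
#' fit <- meth_cart(d)
#' glance(fit)
meth_cart <- function(data, labels = NULL, sites = NULL, min_node = 10,
                      min_dev_frac = 0.01, k = 2, prune = TRUE,
                      label_col = "expression", id_col = "clone_id") {
  fit <- grow_tree(data, labels, sites, min_node, min_dev_frac,
                   label_col, id_col)
  if (prune) fit <- prune_tree(fit, k) else fit$params$k <- k
  fit
}

#' Predict expression class from a fitted tree
#'
#' Descends the tree by the stored threshold inequalities (strictly below
#' the threshold goes left) and returns the leaf majority label: `"P"`
#' (expressing) or `"A"` (non-expressing; also the label of tied leaves).
#'
#' @param object A `meth_cart`.
#' @param newdata Tibble or matrix with the site columns the tree uses.
#' @param ... Unused.
#' @return Factor with levels `c("A", "P")`, one value per row.
#' @export
predict.meth_cart <- function(object, newdata, ...) {
  newdata <- as_tibble(as.data.frame(newdata))
  descend <- function(node, row) {
    if (is.null(node$split)) return(node$label)
    v <- row[[node$split$site]]
    if (is.null(v) || is.na(v)) {
      abort(sprintf("missing value for site '%s'", node$split$site))
    }
    if (v < node$split$threshold) descend(node$left, row)
    else descend(node$right, row)
  }
  out <- vapply(seq_len(nrow(newdata)),
                function(i) descend(object$root, newdata[i, ]), "")
  factor(out, levels = c("A", "P"))
}

#' Resubstitution misclassification of a tree
#'
#' With no new data, reads the training counts stored in the nodes: each
#' leaf misclassifies its minority class. With `newdata` and `labels`,
#' compares predictions against the labels. Per-node ratios
#' (minority / node size) mirror the annotation convention of the assay's
#' published tree figures.
#'
#' @param tree A `meth_cart`.
#' @param newdata Optional data to classify.
#' @param labels Labels for `newdata` (1/0 or `"P"`/`"A"`).
#' @return List with `count`, `rate`, `success` (1 - rate) and `nodes`
#'   (per-node tibble with `misclass_ratio`).
#' @export
misclassification <- function(tree, newdata = NULL, labels = NULL) {
  stopifnot(inherits(tree, "meth_cart"))
  nodes <- tidy(tree)
  if (is.null(newdata)) {
    leaves <- filter(nodes, .data$leaf)
    count <- sum(pmin(leaves$n_exp, leaves$n_nonexp))
    n <- tree$root$n_exp + tree$root$n_nonexp
  } else {
    if (is.null(labels)) abort("labels required with newdata")
    pred <- predict(tree, newdata)
    truth <- if (is.numeric(labels)) {
      factor(ifelse(labels == 1, "P", "A"), levels = c("A", "P"))
    } else {
      factor(as.character(labels), levels = c("A", "P"))
    }
    count <- sum(pred != truth)
    n <- length(truth)
  }
  list(count = count, rate = count / n, success = 1 - count / n,
       nodes = nodes)
}

#' @describeIn meth_cart Tidy per-node summary: one row per node in
#'   preorder with counts, deviance, majority label, split and
#'   misclassification ratio.
#' @param x A `meth_cart`.
#' @exportS3Method generics::tidy
tidy.meth_cart <- function(x, ...) {
  rows <- list()
  walk <- function(node, id, parent, depth) {
    is_leaf <- is.null(node$split)
    row <- tibble(
      node = id, parent = parent, depth = depth, leaf = is_leaf,
      site = NA_character_, threshold = NA_real_,
      n_exp = 0L, n_nonexp = 0L, deviance = 0, label = "",
      misclass_ratio = 0)
    row$site <- if (is_leaf) NA_character_ else node$split$site
    row$threshold <- if (is_leaf) NA_real_ else node$split$threshold
    row$n_exp <- node$n_exp
    row$n_nonexp <- node$n_nonexp
    row$deviance <- node$deviance
    row$label <- node$label
    row$misclass_ratio <- min(node$n_exp, node$n_nonexp) /
      (node$n_exp + node$n_nonexp)
    rows[[length(rows) + 1]] <<- row
    next_id <- id + 1L
    if (!is.null(node$split)) {
      next_id <- walk(node$left, next_id, id, depth + 1L)
      next_id <- walk(node$right, next_id, id, depth + 1L)
    }
    next_id
  }
  walk(x$root, 1L, NA_integer_, 0L)
  bind_rows(rows)
}

#' @describeIn meth_cart One-row model summary: tree size, leaf deviance,
#'   cost-complexity, resubstitution misclassification.
#' @exportS3Method generics::glance
glance.meth_cart <- function(x, ...) {
  k <- x$params$k %||% 2
  mis <- misclassification(x)
  tibble(size = x$size, deviance = x$deviance,
         root_deviance = x$root_deviance,
         k = k, cost_complexity = x$deviance + k * x$size,
         misclassified = mis$count, misclass_rate = mis$rate,
         pruned = x$pruned)
}

#' @export
format.meth_cart <- function(x, ...) {
  lines <- character(0)
  walk <- function(node, prefix, cond) {
    tag <- sprintf("%s(%s n=%d D=%.3f mis=%d/%d)",
                   node$label,
                   if (is.null(node$split)) "leaf" else "branch",
                   node$n_exp + node$n_nonexp, node$deviance,
                   min(node$n_exp, node$n_nonexp),
                   node$n_exp + node$n_nonexp)
    lines <<- c(lines, paste0(prefix, cond, tag))
    if (!is.null(node$split)) {
      walk(node$left, paste0(prefix, "  "),
           sprintf("%s < %g: ", node$split$site, node$split$threshold))
      walk(node$right, paste0(prefix, "  "),
           sprintf("%s >= %g: ", node$split$site, node$split$threshold))
    }
  }
  walk(x$root, "", "")
  lines
}

#' @export
print.meth_cart <- function(x, ...) {
  cat(sprintf("<meth_cart> size %d, deviance %.3f%s\n", x$size,
              x$deviance, if (x$pruned) sprintf(" (pruned, k = %g)",
                                                x$params$k) else ""))
  cat(format(x), sep = "\n")
  invisible(x)
}

.node_to_list <- function(node) {
  out <- list(n_exp = node$n_exp, n_nonexp = node$n_nonexp,
              deviance = node$deviance, label = node$label,
              misclass_ratio = min(node$n_exp, node$n_nonexp) /
                (node$n_exp + node$n_nonexp))
  if (!is.null(node$split)) {
    out$site <- node$split$site
    out$inequality <- "<"
    out$threshold <- node$split$threshold
    out$left <- .node_to_list(node$left)
    out$right <- .node_to_list(node$right)
  }
  out
}

.node_from_list <- function(lst) {
  node <- list(n_exp = as.integer(lst$n_exp),
               n_nonexp = as.integer(lst$n_nonexp),
               deviance = lst$deviance, label = lst$label,
               split = NULL, left = NULL, right = NULL)
  if (!is.null(lst$site)) {
    node$split <- list(site = lst$site, threshold = lst$threshold)
    node$left <- .node_from_list(lst$left)
    node$right <- .node_from_list(lst$right)
  }
  node
}

#' Serialize a tree to JSON (and back)
#'
#' Nodes carry split site, inequality and threshold, class counts,
#' deviance, majority label and misclassification ratio; the round trip
#' is lossless (thresholds at full double precision).
#'
#' @param tree A `meth_cart`.
#' @param path Optional file to write.
#' @return `cart_to_json()`: JSON text (invisibly if written to `path`);
#'   `cart_from_json()`: the reconstructed `meth_cart`.
#' @export
cart_to_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "meth_cart"))
  doc <- list(sites = as.list(tree$sites),
              params = tree$params,
              pruned = tree$pruned,
              root = .node_to_list(tree$root))
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname cart_to_json
#' @param json JSON text or a file path.
#' @export
cart_from_json <- function(json) {
  if (length(json) == 1 && !grepl("^\\s*\\{", json) && file.exists(json)) {
    json <- paste(readLines(json), collapse = "\n")
  }
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  root <- .node_from_list(doc$root)
  fit <- .new_cart(root, unlist(doc$sites), doc$params,
                   pruned = isTRUE(doc$pruned))
  fit
}
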