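make_scored <- function(frames, theo = tiny_theo()) {
  score_reads(tibble::tibble(read_id = sprintf("r%d", seq_along(frames)),
                             clone_id = "C1",
                             ref_frame = frames,
                             identity = 1), theo)
}

test_that("per-read scoring maps CG to 1, CA to 0, gaps to NA", {
  theo <- tiny_theo()
  ref <- tiny_ref()
  meth <- bisulfite_convert_minus(ref, "tiny", "all_methylated")
  unmeth <- bisulfite_convert_minus(ref, "tiny", "all_unmethylated")
  s <- make_scored(c(meth, unmeth))
  calls <- as.matrix(s[grep("^site_", names(s))])
  expect_equal(unname(calls[1, ]), c(1L, 1L, 1L))
  expect_equal(unname(calls[2, ]), c(0L, 0L, 0L))
  expect_equal(s$n_unconverted, c(0L, 0L))
  expect_equal(s$n_converted, c(10L, 10L))

  # gap spanning the middle CpG: NA there, other sites still called
  g <- theo$site_g_cols[["-40"]]
  gapped <- meth
  substr(gapped, g - 1, g) <- "--"
  s2 <- make_scored(gapped)
  calls2 <- as.matrix(s2[grep("^site_", names(s2))])
  expect_equal(unname(calls2[1, ]), c(1L, NA, 1L))
})

test_that("conversion efficiency pools tallies and handles edge cases", {
  theo <- tiny_theo()
  ref <- tiny_ref()
  meth <- bisulfite_convert_minus(ref, "tiny", "all_methylated")
  s <- make_scored(rep(meth, 5))
  expect_equal(conversion_efficiency(s), 1.0)
  # pathological: every conversion site unconverted (reads = raw genomic)
  raw <- substr(ref$sequence, 1, 60)
  s2 <- make_scored(raw)
  expect_equal(conversion_efficiency(s2), 0.0)
  empty <- s[0, ]
  expect_true(is.na(conversion_efficiency(empty)))
})

test_that("molecule classification rules differ on sparse methylation", {
  theo <- tiny_theo()
  ref <- tiny_ref()
  one_meth <- bisulfite_convert_minus(ref, "tiny", c(1L, 0L, 0L))
  all_meth <- bisulfite_convert_minus(ref, "tiny", "all_methylated")
  all_un <- bisulfite_convert_minus(ref, "tiny", "all_unmethylated")
  s <- make_scored(c(all_meth, all_un, one_meth))
  any_rule <- classify_molecules(s, "any")
  expect_equal(any_rule$molecule_call,
               c("methylated", "unmethylated", "methylated"))
  maj_rule <- classify_molecules(s, "majority")
  expect_equal(maj_rule$molecule_call,
               c("methylated", "unmethylated", "unmethylated"))
})

test_that("methylation ratio reproduces published clone summaries", {
  expect_equal(round(methylation_ratio(315, 2175), 3), 0.145)
  expect_equal(round(methylation_ratio(3883, 3968), 3), 0.979)
  expect_equal(methylation_ratio(0, 100), 0)
  expect_error(methylation_ratio(5, 0), class = "methcart_infinite_ratio")
  expect_identical(methylation_ratio(5, 0, allow_infinite = TRUE), Inf)
})

test_that("matrix aggregation counts, labels and ratios are consistent", {
  ref <- tiny_ref()
  theo <- tiny_theo()
  meth <- bisulfite_convert_minus(ref, "tiny", "all_methylated")
  un <- bisulfite_convert_minus(ref, "tiny", "all_unmethylated")
  scored <- score_reads(
    tibble::tibble(read_id = sprintf("r%d", 1:15),
                   clone_id = rep(c("A", "B"), c(10, 5)),
                   ref_frame = c(rep(meth, 10), rep(un, 2), rep(meth, 3)),
                   identity = 1), theo)
  sheet <- tibble::tibble(clone_id = c("A", "B", "C"),
                          barcode = c("AAAAAAAAA", "CCCCCCCCC", "GGGGGGGGG"),
                          expression = c(1L, 0L, 0L))
  expect_warning(mat <- build_matrix(scored, sheet), "no scored reads")
  expect_s3_class(mat, "meth_matrix")
  a <- dplyr::filter(mat$sites, clone_id == "A")
  expect_true(all(a$frequency == 1))
  expect_true(all(a$expression == 1))
  b <- dplyr::filter(mat$sites, clone_id == "B")
  expect_true(all(b$frequency == 3 / 5))
  clone_b <- dplyr::filter(mat$clones, clone_id == "B")
  expect_equal(clone_b$molecules_methylated, 3)
  expect_equal(clone_b$molecules_unmethylated, 2)
  expect_equal(clone_b$ratio, 1.5)
  # counts never exceed read counts
  expect_true(all(mat$sites$n_meth + mat$sites$n_unmeth <=
                    rep(c(10, 5), each = 3)))
})

test_that("per-site frequencies track pattern-mode probabilities", {
  ref <- tiny_ref()
  n <- 5000
  pr <- clone_profile("C1", "ACGTACGTA", 1, c(0.3, 0.3, 0.3), n)
  cfg <- sim_config(conversion_failure_rate = 0, seq_error_rate = 0,
                    indel_rate = 0)
  rs <- simulate_clone_reads(ref, "tiny", pr, cfg, seed = 17)
  theo <- tiny_theo()
  scored <- rs |>
    trim_reads(ref$fragments$tiny) |>
    align_to_reference(theo) |>
    identity_filter() |>
    score_reads(theo)
  sheet <- tibble::tibble(clone_id = "C1", barcode = "ACGTACGTA",
                          expression = 1L)
  mat <- build_matrix(scored, sheet)
  se <- sqrt(0.3 * 0.7 / n)
  expect_true(all(abs(mat$sites$frequency - 0.3) < 3 * se))
  # frequency equals the per-cell count ratio exactly
  expect_equal(mat$sites$frequency,
               mat$sites$n_meth / (mat$sites$n_meth + mat$sites$n_unmeth))
})

test_that("wide pivot names columns by fragment prefix and site", {
  ref <- tiny_ref()
  theo <- tiny_theo()
  meth <- bisulfite_convert_minus(ref, "tiny", "all_methylated")
  scored <- score_reads(
    tibble::tibble(read_id = c("r1", "r2"), clone_id = c("A", "B"),
                   ref_frame = meth, identity = 1), theo)
  sheet <- tibble::tibble(clone_id = c("A", "B"),
                          expression = c(1L, 0L))
  mat <- build_matrix(scored, sheet)
  w <- freq_wide(mat)
  expect_setequal(setdiff(names(w), c("clone_id", "expression")),
                  c("tiny.-50", "tiny.-40", "tiny.-30"))
  expect_equal(nrow(w), 2)
})
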