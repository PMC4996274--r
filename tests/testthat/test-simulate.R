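no_noise <- function(...) sim_config(conversion_failure_rate = 0,
                                     seq_error_rate = 0, indel_rate = 0, ...)

score_readset <- function(rs, ref, fragment) {
  theo <- build_theoretical_reference(ref, fragment)
  rs |>
    trim_reads(.resolve_fragment_test(ref, fragment)) |>
    align_to_reference(theo) |>
    identity_filter() |>
    score_reads(theo)
}

.resolve_fragment_test <- function(ref, fragment) {
  if (inherits(fragment, "fragment_def")) fragment
  else ref$fragments[[fragment]]
}

site_freqs <- function(scored) {
  m <- as.matrix(scored[grep("^site_", names(scored))])
  colMeans(m == 1, na.rm = TRUE)
}

test_that("simulation is deterministic under a fixed seed", {
  ref <- tiny_ref()
  pr <- clone_profile("C1", "ACGTACGTA", 1, c(0.2, 0.5, 0.8), 50)
  a <- simulate_clone_reads(ref, "tiny", pr, sim_config(), seed = 99)
  b <- simulate_clone_reads(ref, "tiny", pr, sim_config(), seed = 99)
  expect_identical(a, b)
})

test_that("degenerate probabilities give all-methylated reads", {
  ref <- tiny_ref()
  pr <- clone_profile("C1", "ACGTACGTA", 1, c(1, 1, 1), 100)
  rs <- simulate_clone_reads(ref, "tiny", pr, no_noise(), seed = 1)
  fr <- site_freqs(score_readset(rs, ref, "tiny"))
  expect_equal(unname(fr), c(1, 1, 1))
})

test_that("pattern mode matches binomial sampling", {
  ref <- tiny_ref()
  n <- 10000
  pr <- clone_profile("C1", "ACGTACGTA", 1, c(0.5, 0.5, 0.5), n)
  rs <- simulate_clone_reads(ref, "tiny", pr, no_noise(), seed = 2)
  fr <- site_freqs(score_readset(rs, ref, "tiny"))
  se <- sqrt(0.25 / n)
  expect_true(all(abs(fr - 0.5) < 3 * se))
})

test_that("two-template mode reproduces the hyperbolic expectation", {
  ref <- tiny_ref()
  n <- 50000
  cfg <- no_noise(bias_b = 2, mixture_mode = "two_template")
  pr <- clone_profile("C1", "ACGTACGTA", 1, rep(0.5, 3), n)
  rs <- simulate_clone_reads(ref, "tiny", pr, cfg, seed = 3)
  fr <- site_freqs(score_readset(rs, ref, "tiny"))
  o <- 1 / 3
  se <- sqrt(o * (1 - o) / n)
  expect_true(all(abs(fr - o) < 3 * se))
  # non-constant site_probs is a config error in this mode
  bad <- clone_profile("C1", "ACGTACGTA", 1, c(0.2, 0.5, 0.5), 10)
  expect_error(simulate_clone_reads(ref, "tiny", bad, cfg),
               "constant site_probs")
})

test_that("control mixtures land at the biased expectations", {
  ref <- tiny_ref()
  n <- 20000
  for (b in c(1, 2, 0.5)) {
    ctrl <- simulate_controls(ref, "tiny", bias_b = b, n = n,
                              cfg = no_noise(), seed = 7)
    obs <- vapply(ctrl, function(rs) {
      mean(site_freqs(score_readset(rs, ref, "tiny")))
    }, 0)
    expected <- c("1:0" = 1, "1:1" = 1 / (1 + b), "0:1" = 0)
    expect_equal(obs[["1:0"]], 1)
    expect_equal(obs[["0:1"]], 0)
    se <- sqrt(expected[["1:1"]] * (1 - expected[["1:1"]]) / n)
    expect_lt(abs(obs[["1:1"]] - expected[["1:1"]]), 3 * se)
  }
})

test_that("cohorts have the requested composition and are demuxable", {
  ref <- tiny_ref()
  sim <- simulate_cohort(ref, 10, 20, cfg = no_noise(),
                         depth = c(5, 5), seed = 11)
  expect_equal(nrow(sim$sample_sheet), 30)
  expect_equal(sum(sim$sample_sheet$expression == 1), 10)
  expect_equal(sum(sim$sample_sheet$expression == 0), 20)
  expect_equal(nrow(sim$reads), 30 * 5)

  # (1, 1) with depth 5: exactly 10 reads, losslessly demultiplexable
  sim2 <- simulate_cohort(ref, 1, 1, cfg = no_noise(), depth = 5,
                          seed = 12)
  expect_equal(nrow(sim2$reads), 10)
  dm <- demultiplex(sim2$reads, sim2$sample_sheet)
  expect_true(all(!is.na(dm$clone_id)))
  expect_identical(dm$clone_id, dm$true_clone)

  expect_error(simulate_cohort(ref, 1, 1, barcodes = rep("ACGTACGTA", 2)),
               "duplicate")
})

test_that("cohort FASTQ output is byte-identical under a fixed seed", {
  ref <- tiny_ref()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_cohort(ref, 2, 2, cfg = sim_config(), depth = 10,
                  out_dir = d1, seed = 5)
  simulate_cohort(ref, 2, 2, cfg = sim_config(), depth = 10,
                  out_dir = d2, seed = 5)
  expect_identical(readLines(file.path(d1, "reads.fastq")),
                   readLines(file.path(d2, "reads.fastq")))
  expect_identical(readLines(file.path(d1, "sample_sheet.tsv")),
                   readLines(file.path(d2, "sample_sheet.tsv")))
})

test_that("conversion failures are recovered by the efficiency estimator", {
  ref <- tiny_ref()
  f <- 0.01
  n <- 2000
  pr <- clone_profile("C1", "ACGTACGTA", 1, c(0.5, 0.5, 0.5), n)
  cfg <- sim_config(conversion_failure_rate = f, seq_error_rate = 0,
                    indel_rate = 0)
  rs <- simulate_clone_reads(ref, "tiny", pr, cfg, seed = 21)
  scored <- score_readset(rs, ref, "tiny")
  eff <- conversion_efficiency(scored)
  n_tallies <- sum(scored$n_converted + scored$n_unconverted)
  se <- sqrt(f * (1 - f) / n_tallies)
  expect_lt(abs(eff - (1 - f)), 3 * se)
})

test_that("frequency cohorts respect the planted site", {
  d <- simulate_frequency_cohort(10, 20, planted_site = -765, seed = 4)
  expect_equal(nrow(d), 30)
  expect_equal(sum(d$expression), 10)
  planted <- d[["f1.-765"]]
  expect_true(all(planted[d$expression == 1] < 0.5))
  expect_true(all(planted[d$expression == 0] > 0.5))
  expect_error(simulate_frequency_cohort(2, 2, planted_site = 999),
               "planted_site")
})
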