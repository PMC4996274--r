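#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run. `simulate` holds the
#' cohort-generation settings (used when no FASTQ input is given);
#' `reads_path`/`sample_sheet_path` point at an existing multiplexed
#' FASTQ and sheet instead.
#'
#' @param out_dir Output directory.
#' @param seed Integer seed governing every stochastic stage.
#' @param reads_path,sample_sheet_path Optional existing inputs.
#' @param simulate List of arguments for [simulate_cohort()] (e.g.
#'   `n_expressing`, `n_nonexpressing`, `depth`).
#' @param controls List: `bias_b` and `n` for [simulate_controls()]; set
#'   `bias_b` to the condition you want to calibrate away.
#' @param identity_threshold Identity filter threshold.
#' @param molecule_rule `"any"` or `"majority"` molecule classification.
#' @param alpha Significance level for the per-site screen.
#' @param cart List: `min_node`, `min_dev_frac`, `k`.
#' @param sim List of [sim_config()] arguments.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("methcart_run_"),
                            seed = 1L,
                            reads_path = NULL, sample_sheet_path = NULL,
                            simulate = list(), controls = list(),
                            identity_threshold = 0.70,
                            molecule_rule = "any",
                            alpha = 0.05,
                            cart = list(), sim = list()) {
  simulate <- modifyList(list(n_expressing = 10, n_nonexpressing = 20,
                              depth = c(600, 1500)), simulate)
  controls <- modifyList(list(bias_b = 1.5, n = 5000), controls)
  cart <- modifyList(list(min_node = 10, min_dev_frac = 0.01, k = 2), cart)
  if (identity_threshold <= 0 || identity_threshold >= 1) {
    abort("identity_threshold must be in (0, 1)")
  }
  if (!molecule_rule %in% c("any", "majority")) {
    abort("molecule_rule must be 'any' or 'majority'")
  }
  for (p in c(reads_path, sample_sheet_path)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(sprintf("input file does not exist: %s", p))
    }
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 reads_path = reads_path,
                 sample_sheet_path = sample_sheet_path,
                 simulate = simulate, controls = controls,
                 identity_threshold = identity_threshold,
                 molecule_rule = molecule_rule, alpha = alpha,
                 cart = cart, sim = sim),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

.stage_msg <- function(...) message(sprintf(...))

#' Run the full analysis pipeline
#'
#' Demultiplexes (simulated or supplied) multiplexed reads, trims and
#' aligns them per fragment, filters at the identity threshold, scores
#' CpG methylation and conversion efficiency, builds the clone-by-site
#' matrix, calibrates and applies the hyperbolic bias correction from
#' control mixtures, compares expressing vs non-expressing clones, fits
#' the pruned classification tree, and writes every artifact (TSV/JSON
#' plus a Markdown report) under `config$out_dir`. Deterministic for a
#' fixed seed.
#'
#' @param config A [pipeline_config()].
#' @param ref A `promoter_reference`; default [mlh1_promoter()].
#' @return Invisibly, a list with all intermediate and final objects
#'   (`sample_sheet`, `matrix`, `corrected`, `bias`, `site_tests`,
#'   `aggregate`, `tree`, `conversion_efficiency`, `counters`, paths).
#' @export
run_pipeline <- function(config, ref = mlh1_promoter()) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- do.call(sim_config, config$sim)

  if (is.null(config$reads_path)) {
    .stage_msg("simulating cohort (%d + %d clones)",
               config$simulate$n_expressing,
               config$simulate$n_nonexpressing)
    sim <- do.call(simulate_cohort,
                   c(list(ref = ref, cfg = cfg), config$simulate))
    sheet <- sim$sample_sheet
    reads <- sim$reads
  } else {
    .stage_msg("reading %s", config$reads_path)
    reads <- read_reads(config$reads_path)
    sheet <- readr::read_tsv(config$sample_sheet_path,
                             show_col_types = FALSE)
  }

  .stage_msg("demultiplexing %d reads", nrow(reads))
  demuxed <- demultiplex(reads, sheet)

  scored_list <- list()
  counters <- list()
  for (fr in ref$fragments) {
    theo <- build_theoretical_reference(ref, fr)
    trimmed <- trim_reads(filter(demuxed, !is.na(.data$clone_id)), fr)
    aligned <- align_to_reference(trimmed, theo)
    passed <- identity_filter(aligned, config$identity_threshold)
    scored <- score_reads(passed, theo)
    scored_list[[fr$name]] <- scored
    counters[[fr$name]] <- tibble(
      fragment = fr$name,
      input = nrow(reads),
      matched = sum(!is.na(demuxed$clone_id)),
      trimmed = nrow(trimmed),
      aligned = nrow(aligned),
      passed = nrow(passed))
    .stage_msg("%s: %d aligned, %d passed filter", fr$name,
               nrow(aligned), nrow(passed))
  }
  counters <- bind_rows(counters)
  conv_eff <- conversion_efficiency(scored_list)

  mat <- build_matrix(scored_list, sheet, rule = config$molecule_rule)

  .stage_msg("calibrating bias (b = %g controls)", config$controls$bias_b)
  bias_models <- list()
  corrected <- mat
  for (fr in ref$fragments) {
    controls <- simulate_controls(ref, fr, bias_b = config$controls$bias_b,
                                  n = config$controls$n, cfg = cfg)
    bm <- fit_bias_from_controls(controls, ref, fr,
                                 threshold = config$identity_threshold)
    bias_models[[fr$name]] <- bm
    idx <- corrected$sites$fragment == fr$name
    corrected$sites$frequency[idx] <-
      correct_frequency(corrected$sites$frequency[idx], bm)
  }
  corrected$corrected <- TRUE

  site_tests <- compare_sites(corrected, alpha = config$alpha)
  aggregate <- aggregate_ttest(corrected)

  wide <- freq_wide(corrected)
  tree <- meth_cart(wide, min_node = config$cart$min_node,
                    min_dev_frac = config$cart$min_dev_frac,
                    k = config$cart$k)

  paths <- list(
    matrix = file.path(config$out_dir, "methylation_matrix.tsv"),
    corrected = file.path(config$out_dir,
                          "methylation_matrix_corrected.tsv"),
    clones = file.path(config$out_dir, "clone_summary.tsv"),
    site_tests = file.path(config$out_dir, "site_tests.tsv"),
    tree = file.path(config$out_dir, "tree.json"),
    counters = file.path(config$out_dir, "demux_counters.tsv"),
    report = file.path(config$out_dir, "report.md"))
  readr::write_tsv(mat$sites, paths$matrix)
  readr::write_tsv(corrected$sites, paths$corrected)
  readr::write_tsv(mat$clones, paths$clones)
  readr::write_tsv(site_tests, paths$site_tests)
  readr::write_tsv(counters, paths$counters)
  cart_to_json(tree, paths$tree)

  results <- list(sample_sheet = sheet, matrix = mat,
                  corrected = corrected, bias = bias_models,
                  site_tests = site_tests, aggregate = aggregate,
                  tree = tree, conversion_efficiency = conv_eff,
                  counters = counters, paths = paths,
                  config = config)
  writeLines(make_report(results), paths$report)
  invisible(results)
}

#' Render a human-readable run report
#'
#' @param results The list returned by [run_pipeline()].
#' @return Character vector of Markdown lines.
#' @export
make_report <- function(results) {
  sheet <- results$sample_sheet
  agg <- results$aggregate
  mis <- misclassification(results$tree)
  sig <- results$site_tests %>%
    group_by(.data$fragment) %>%
    summarise(frac = significant_fraction(.data$p_value), .groups = "drop")
  c(sprintf("# Methylation pipeline report"),
    "",
    sprintf("- clones: %d (%d expressing, %d non-expressing)",
            nrow(sheet), sum(sheet$expression == 1),
            sum(sheet$expression == 0)),
    sprintf("- conversion efficiency: %.4f%%",
            100 * results$conversion_efficiency),
    sprintf("- bias parameter b: %s",
            paste(sprintf("%s %.3f", names(results$bias),
                          vapply(results$bias, function(b) unname(b$b), 0)),
                  collapse = ", ")),
    "",
    "## Group comparison (per-site means)",
    sprintf("- %s: expressing %.3f vs non-expressing %.3f (p = %.3g)",
            agg$fragment, agg$mean_expressing, agg$mean_nonexpressing,
            agg$p_value),
    sprintf("- fraction of significant sites: %s",
            paste(sprintf("%s %.2f", sig$fragment, sig$frac),
                  collapse = ", ")),
    "",
    "## Classification tree",
    sprintf("- size %d, deviance %.3f, misclassification %d/%d (%.0f%%)",
            results$tree$size, results$tree$deviance, mis$count,
            results$tree$root$n_exp + results$tree$root$n_nonexp,
            100 * mis$rate),
    "",
    "```",
    format(results$tree),
    "```")
}
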