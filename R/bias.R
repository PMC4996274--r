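#' Forward hyperbolic amplification-bias map
#'
#' Under competing amplification of methylated and unmethylated template,
#' a true methylated fraction `m` is observed as
#' `o = m / (m + b * (1 - m))`, where `b` is the amplification-efficiency
#' ratio of unmethylated to methylated template (`b > 1`: unmethylated
#' template favoured, observed frequency pulled down).
#'
#' @param m True methylated fraction(s) in `[0, 1]`.
#' @param b Bias parameter (> 0).
#' @return Observed frequency/frequencies.
#' @export
forward_bias <- function(m, b) {
  stopifnot(all(m >= 0 & m <= 1), all(b > 0))
  ifelse(m == 0, 0, m / (m + b * (1 - m)))
}

#' Fit the hyperbolic bias model from control mixtures
#'
#' Given the observed methylated frequencies of fully methylated (true 1),
#' 1:1 mixed (true 0.5) and fully unmethylated (true 0) control template,
#' solves the hyperbola at the midpoint: `o_half = 1 / (1 + b)`, so
#' `b = (1 - o_half) / o_half`. The endpoint controls are diagnostics:
#' values farther than 0.05 from their ideals trigger a warning, since
#' the hyperbola pins them at 0 and 1 by construction.
#'
#' @param o_zero,o_half,o_one Observed frequencies of the 0:1, 1:1 and
#'   1:0 controls.
#' @param site Optional site coordinate(s) for per-site calibration; when
#'   supplied (same length as the observations) a per-site model is
#'   returned.
#' @return An object of class `bias_model` with fields `b` (scalar, or
#'   named vector for per-site scope), `scope` and `controls`.
#' @export
#' @examples
#' fit_hyperbolic(0, 1/3, 1)$b   # 2
fit_hyperbolic <- function(o_zero, o_half, o_one, site = NULL) {
  if (any(o_half <= 0 | o_half >= 1)) {
    abort("o_half must lie strictly inside (0, 1); the model is unfittable")
  }
  if (any(o_zero > 0.05) || any(o_one < 0.95)) {
    warn("endpoint controls deviate by more than 0.05 from 0/1")
  }
  b <- (1 - o_half) / o_half
  scope <- if (is.null(site)) "per_fragment" else "per_site"
  if (scope == "per_site") {
    if (length(site) != length(b)) abort("site must match observations")
    b <- setNames(b, as.character(site))
  } else if (length(b) != 1) {
    abort("per-fragment fit expects scalar controls")
  }
  structure(list(b = b, scope = scope,
                 controls = tibble(site = site %||% NA_integer_,
                                   o_zero = o_zero, o_half = o_half,
                                   o_one = o_one)),
            class = "bias_model")
}

#' @export
print.bias_model <- function(x, ...) {
  if (x$scope == "per_fragment") {
    cat(sprintf("<bias_model> b = %.4g (per fragment)\n", x$b))
  } else {
    cat(sprintf("<bias_model> per-site, %d sites, median b = %.4g\n",
                length(x$b), stats::median(x$b)))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bias_model <- function(x, ...) {
  if (x$scope == "per_fragment") {
    tibble(site = NA_integer_, b = unname(x$b))
  } else {
    tibble(site = as.integer(names(x$b)), b = unname(x$b))
  }
}

#' Correct an observed methylation frequency for amplification bias
#'
#' Analytic inverse of [forward_bias()]:
#' `m = o * b / (1 - o + o * b)`, clamped to `[0, 1]` (the normalization
#' step). `correct_frequency(forward_bias(m, b), b)` recovers `m` exactly.
#'
#' @param o Observed frequency/frequencies in `[0, 1]`.
#' @param model A `bias_model`, or a bare numeric `b`.
#' @return Corrected frequency/frequencies in `[0, 1]`.
#' @export
correct_frequency <- function(o, model) {
  b <- if (inherits(model, "bias_model")) model$b else model
  stopifnot(all(o >= 0 & o <= 1, na.rm = TRUE))
  m <- o * b / (1 - o + o * b)
  pmin(pmax(m, 0), 1)
}

#' Apply a bias model to a methylation matrix
#'
#' Replaces every per-site frequency by its bias-corrected value; the raw
#' counts are retained unmodified for audit. With a per-site model every
#' site in the matrix must have a calibrated `b`.
#'
#' @param mat A `meth_matrix`.
#' @param model A `bias_model`.
#' @return The corrected `meth_matrix` (flagged `corrected = TRUE`).
#' @export
correct_matrix <- function(mat, model) {
  stopifnot(inherits(mat, "meth_matrix"), inherits(model, "bias_model"))
  if (model$scope == "per_site") {
    missing <- setdiff(unique(mat$sites$site), as.integer(names(model$b)))
    if (length(missing) > 0) {
      abort(sprintf("no bias parameter for site(s): %s",
                    paste(missing, collapse = ", ")))
    }
    b <- unname(model$b[as.character(mat$sites$site)])
  } else {
    b <- model$b
  }
  mat$sites$frequency <- correct_frequency(mat$sites$frequency, b)
  mat$corrected <- TRUE
  mat
}

#' Fit the bias model from control read sets
#'
#' Convenience wrapper: runs the three control read sets of
#' [simulate_controls()] (or real control FASTQ reads trimmed the same
#' way) through trim, align, filter and score, computes each observed
#' methylated frequency over all site calls, and fits the hyperbola.
#'
#' @param controls Named list of read tibbles `"1:0"`, `"1:1"`, `"0:1"`.
#' @param ref A `promoter_reference`.
#' @param fragment A `fragment_def` or name.
#' @param threshold Identity filter threshold.
#' @return A `bias_model` (per-fragment scope).
#' @export
fit_bias_from_controls <- function(controls, ref, fragment,
                                   threshold = 0.70) {
  fragment <- .resolve_fragment(ref, fragment)
  theo <- build_theoretical_reference(ref, fragment)
  obs <- vapply(controls, function(rs) {
    scored <- rs %>%
      trim_reads(fragment) %>%
      align_to_reference(theo) %>%
      identity_filter(threshold) %>%
      score_reads(theo)
    m <- as.matrix(scored[.call_cols(scored)])
    sum(m == 1L, na.rm = TRUE) / sum(!is.na(m))
  }, 0)
  fit_hyperbolic(o_zero = obs[["0:1"]], o_half = obs[["1:1"]],
                 o_one = obs[["1:0"]])
}
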