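#' Two-sample unpaired t-test between clone groups at one site
#'
#' Student (pooled-variance) two-tailed t-test by default, matching the
#' classical analysis of expressing vs non-expressing clones; Welch's
#' unequal-variance form is available with `welch = TRUE`. Degenerate
#' inputs are handled explicitly: fewer than two observations in either
#' group gives an `NA` result, and zero pooled variance gives `t = 0, p =
#' 1` when the means are equal (`t = +/-Inf, p = 0` otherwise).
#'
#' @param x,y Numeric vectors of per-clone frequencies (group 1, group 2).
#' @param welch Use Welch's test instead of the pooled-variance Student
#'   test.
#' @return One-row tibble: `mean_x`, `mean_y`, `t_statistic`, `p_value`,
#'   `df`.
#' @export
#' @examples
#' site_ttest(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6))
site_ttest <- function(x, y, welch = FALSE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    return(tibble(mean_x = mean(x), mean_y = mean(y),
                  t_statistic = NA_real_, p_value = NA_real_,
                  df = NA_real_))
  }
  if (var(x) == 0 && var(y) == 0) {
    df <- length(x) + length(y) - 2
    if (mean(x) == mean(y)) {
      return(tibble(mean_x = mean(x), mean_y = mean(y), t_statistic = 0,
                    p_value = 1, df = df))
    }
    return(tibble(mean_x = mean(x), mean_y = mean(y),
                  t_statistic = sign(mean(x) - mean(y)) * Inf,
                  p_value = 0, df = df))
  }
  tt <- t.test(x, y, var.equal = !welch)
  tibble(mean_x = mean(x), mean_y = mean(y),
         t_statistic = unname(tt$statistic),
         p_value = tt$p.value,
         df = unname(tt$parameter))
}

#' Per-site comparison of expressing and non-expressing clones
#'
#' Runs [site_ttest()] at every CpG site of a methylation matrix,
#' expressing group first. The headline p-values are unadjusted (a
#' per-site screen at `alpha`); Benjamini-Hochberg q-values are emitted
#' alongside for users who want multiplicity control.
#'
#' @param mat A `meth_matrix` (usually bias-corrected).
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @param welch Use Welch's test.
#' @return Tibble: `fragment`, `site`, `mean_expressing`,
#'   `mean_nonexpressing`, `t_statistic`, `p_value`, `q_value`,
#'   `significant`.
#' @export
compare_sites <- function(mat, alpha = 0.05, welch = FALSE) {
  tbl <- if (inherits(mat, "meth_matrix")) mat$sites else as_tibble(mat)
  res <- tbl %>%
    group_by(.data$fragment, .data$site) %>%
    summarise(res = list(site_ttest(
      .data$frequency[.data$expression == 1],
      .data$frequency[.data$expression == 0],
      welch = welch)), .groups = "drop") %>%
    tidyr::unnest("res") %>%
    rename(mean_expressing = "mean_x", mean_nonexpressing = "mean_y")
  res %>%
    group_by(.data$fragment) %>%
    mutate(q_value = p.adjust(.data$p_value, "BH")) %>%
    ungroup() %>%
    mutate(significant = !is.na(.data$p_value) & .data$p_value < alpha)
}

#' Aggregate comparison of mean per-site methylation between groups
#'
#' Collapses each site to its group mean frequency (one value per site
#' per group) and compares the two sets of per-site means with the same
#' unpaired two-tailed t-test, per fragment.
#'
#' @inheritParams compare_sites
#' @return Tibble with one row per fragment: `fragment`,
#'   `mean_expressing`, `mean_nonexpressing`, `t_statistic`, `p_value`,
#'   `df`.
#' @export
aggregate_ttest <- function(mat, welch = FALSE) {
  tbl <- if (inherits(mat, "meth_matrix")) mat$sites else as_tibble(mat)
  tbl %>%
    group_by(.data$fragment, .data$site) %>%
    summarise(
      m_exp = mean(.data$frequency[.data$expression == 1], na.rm = TRUE),
      m_non = mean(.data$frequency[.data$expression == 0], na.rm = TRUE),
      .groups = "drop_last") %>%
    summarise(res = list(site_ttest(.data$m_exp, .data$m_non,
                                    welch = welch)),
              .groups = "drop") %>%
    tidyr::unnest("res") %>%
    rename(mean_expressing = "mean_x", mean_nonexpressing = "mean_y")
}

#' Univariate logistic regression of expression on site methylation
#'
#' Maximum-likelihood logistic fit of the binary expression label on one
#' site's per-clone methylation frequency, with a Wald p-value for the
#' slope. Non-convergence and complete separation are reported as flags
#' rather than silent estimates.
#'
#' @param freq Per-clone methylation frequency.
#' @param labels Binary expression labels (0/1), same length.
#' @return One-row tibble: `intercept`, `slope`, `slope_p`, `converged`,
#'   `separation`.
#' @export
logistic_fit <- function(freq, labels) {
  ok <- !is.na(freq) & !is.na(labels)
  freq <- freq[ok]; labels <- as.integer(labels[ok])
  if (length(unique(labels)) < 2) {
    abort("both expression classes must be present")
  }
  if (length(unique(freq)) == 1) {
    return(tibble(intercept = stats::qlogis(mean(labels)), slope = 0,
                  slope_p = NA_real_, converged = TRUE, separation = FALSE))
  }
  fit <- suppressWarnings(glm(labels ~ freq, family = binomial()))
  co <- summary(fit)$coefficients
  eps <- 1e-8
  separation <- any(fit$fitted.values < eps | fit$fitted.values > 1 - eps)
  tibble(intercept = co[1, 1], slope = co[2, 1],
         slope_p = co[2, 4],
         converged = fit$converged,
         separation = separation)
}

#' Per-site logistic regression over a methylation matrix
#'
#' @inheritParams compare_sites
#' @return Tibble: `fragment`, `site`, plus the [logistic_fit()] columns.
#' @export
logistic_sites <- function(mat) {
  tbl <- if (inherits(mat, "meth_matrix")) mat$sites else as_tibble(mat)
  tbl %>%
    group_by(.data$fragment, .data$site) %>%
    summarise(res = list(logistic_fit(.data$frequency, .data$expression)),
              .groups = "drop") %>%
    tidyr::unnest("res")
}

#' Fraction of sites reaching significance
#'
#' @param p_values Numeric vector of per-site p-values (or a
#'   [compare_sites()] result, whose `p_value` column is used).
#' @param alpha Significance level (default 0.05).
#' @return Fraction of sites with `p < alpha` (unadjusted).
#' @export
significant_fraction <- function(p_values, alpha = 0.05) {
  if (is.data.frame(p_values)) p_values <- p_values$p_value
  if (length(p_values) == 0) abort("need at least one site")
  mean(p_values < alpha, na.rm = TRUE)
}
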