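#' Score CpG methylation per read
#'
#' At each CpG site the informative plus-sense dinucleotide is read off
#' the reference-frame projection: `CG` scores 1 (methylated), `CA`
#' scores 0 (unmethylated), anything else -- a non-C at the C position, a
#' gap, or an unexpected base at the G position -- is unscorable (`NA`).
#' Non-CpG conversion positions are tallied per read: an `A` counts as
#' converted, a `G` as unconverted (a bisulfite conversion failure);
#' other bases are ignored.
#'
#' @param aligned Tibble from [align_to_reference()] (normally after
#'   [identity_filter()]) with a `ref_frame` column.
#' @param theo The `theoretical_reference` the reads were aligned to.
#' @return Tibble with `read_id` (and `clone_id` if present),
#'   `n_converted`, `n_unconverted`, and one integer call column per CpG
#'   site named `site_<coordinate>` (1, 0 or `NA`). The site coordinates
#'   are attached as attribute `"sites"`, the fragment name as
#'   `"fragment"`.
#' @export
score_reads <- function(aligned, theo) {
  aligned <- as_tibble(aligned)
  n <- nrow(aligned)
  rf <- aligned$ref_frame
  sites <- as.integer(names(theo$site_g_cols))
  k <- length(sites)
  calls <- matrix(NA_integer_, n, k)
  for (j in seq_len(k)) {
    cbase <- substring(rf, theo$site_c_cols[j], theo$site_c_cols[j])
    gbase <- substring(rf, theo$site_g_cols[j], theo$site_g_cols[j])
    calls[, j] <- ifelse(cbase == "C" & gbase == "G", 1L,
                         ifelse(cbase == "C" & gbase == "A", 0L,
                                NA_integer_))
  }
  colnames(calls) <- paste0("site_", sites)
  conv_cols <- which(theo$classes == "conversion")
  n_conv <- integer(n)
  n_unconv <- integer(n)
  for (cc in conv_cols) {
    b <- substring(rf, cc, cc)
    n_conv <- n_conv + (b == "A")
    n_unconv <- n_unconv + (b == "G")
  }
  out <- dplyr::bind_cols(
    aligned[intersect(c("read_id", "clone_id"), names(aligned))],
    tibble(n_converted = n_conv, n_unconverted = n_unconv),
    as_tibble(calls))
  attr(out, "sites") <- sites
  attr(out, "fragment") <- theo$fragment
  out
}

.call_cols <- function(scored) grep("^site_", names(scored), value = TRUE)

#' Estimate bisulfite conversion efficiency
#'
#' The fraction of non-CpG minus-strand cytosines observed converted,
#' pooled over all reads: `sum(n_converted) / sum(n_converted +
#' n_unconverted)`. This bounds the false-positive methylation call rate
#' of the run.
#'
#' @param scored One scored read tibble from [score_reads()], or a list of
#'   them.
#' @return Rate in `[0, 1]`, or `NA` if no conversion positions were
#'   observed.
#' @export
conversion_efficiency <- function(scored) {
  if (!is.data.frame(scored)) scored <- bind_rows(lapply(scored, function(s)
    s[c("n_converted", "n_unconverted")]))
  tot <- sum(scored$n_converted) + sum(scored$n_unconverted)
  if (tot == 0) return(NA_real_)
  sum(scored$n_converted) / tot
}

#' Classify each molecule as methylated or unmethylated
#'
#' The default rule calls a molecule methylated if at least one CpG call
#' is 1; the alternative `"majority"` rule requires more than half of the
#' non-`NA` calls to be 1 (exactly half counts as methylated). Molecules
#' with no scorable site are `NA`.
#'
#' @param scored Tibble from [score_reads()].
#' @param rule `"any"` (default) or `"majority"`.
#' @return `scored` with an added `molecule_call` column
#'   (`"methylated"`, `"unmethylated"` or `NA`).
#' @export
classify_molecules <- function(scored, rule = c("any", "majority")) {
  rule <- match.arg(rule)
  cols <- .call_cols(scored)
  m <- as.matrix(scored[cols])
  n_one <- rowSums(m == 1L, na.rm = TRUE)
  n_obs <- rowSums(!is.na(m))
  call <- rep(NA_character_, nrow(scored))
  scorable <- n_obs > 0
  if (rule == "any") {
    call[scorable] <- ifelse(n_one[scorable] >= 1, "methylated",
                             "unmethylated")
  } else {
    call[scorable] <- ifelse(n_one[scorable] >= n_obs[scorable] / 2,
                             "methylated", "unmethylated")
  }
  mutate(scored, molecule_call = call)
}

#' Clone-level methylation ratio
#'
#' The ratio of methylated to unmethylated molecules,
#' `n_meth / n_unmeth`.
#'
#' @param n_meth,n_unmeth Molecule counts (vectorized).
#' @param allow_infinite If `FALSE` (default) a zero denominator is an
#'   error (condition class `methcart_infinite_ratio`); if `TRUE`, `Inf`
#'   is returned for those entries.
#' @return Numeric ratio(s).
#' @export
#' @examples
#' methylation_ratio(315, 2175)   # 0.1448...
methylation_ratio <- function(n_meth, n_unmeth, allow_infinite = FALSE) {
  if (any(n_unmeth == 0)) {
    if (!allow_infinite) {
      abort("methylation ratio undefined: zero unmethylated molecules",
            class = "methcart_infinite_ratio")
    }
  }
  n_meth / n_unmeth
}

#' Build the clone-by-site methylation matrix
#'
#' Aggregates per-read CpG calls into per-clone per-site methylated /
#' unmethylated counts and frequencies, and per-clone molecule-level
#' summaries (Table-style: molecules methylated, unmethylated, and their
#' ratio). Unscorable (`NA`) calls are excluded from both numerator and
#' denominator. Clones with no scored reads are excluded with a warning.
#'
#' @param scored Tibble from [score_reads()] with a `clone_id` column, or
#'   a list of such tibbles (e.g. one per fragment).
#' @param sheet Sample sheet with `clone_id` and `expression` columns used
#'   to label the rows.
#' @param rule Molecule classification rule, see [classify_molecules()].
#' @return An object of class `meth_matrix`: a list with
#'   `sites` (long tibble: `clone_id`, `fragment`, `site`, `n_meth`,
#'   `n_unmeth`, `frequency`, `expression`), `clones` (tibble:
#'   `clone_id`, `fragment`, `n_reads`, `molecules_methylated`,
#'   `molecules_unmethylated`, `ratio`, `expression`) and `corrected`
#'   (logical flag).
#' @export
build_matrix <- function(scored, sheet, rule = c("any", "majority")) {
  rule <- match.arg(rule)
  if (is.data.frame(scored)) scored <- list(scored)
  site_tbls <- list()
  clone_tbls <- list()
  for (s in scored) {
    frag <- attr(s, "fragment") %||% "fragment"
    sites <- attr(s, "sites")
    if (!"clone_id" %in% names(s)) abort("scored reads need clone_id")
    s <- filter(s, !is.na(.data$clone_id))
    cols <- .call_cols(s)
    cl <- classify_molecules(s, rule)
    per_clone <- cl %>%
      group_by(.data$clone_id) %>%
      summarise(
        n_reads = dplyr::n(),
        molecules_methylated = sum(.data$molecule_call == "methylated",
                                   na.rm = TRUE),
        molecules_unmethylated = sum(.data$molecule_call == "unmethylated",
                                     na.rm = TRUE),
        .groups = "drop") %>%
      mutate(fragment = frag,
             ratio = methylation_ratio(.data$molecules_methylated,
                                       .data$molecules_unmethylated,
                                       allow_infinite = TRUE))
    long <- s %>%
      select("clone_id", dplyr::all_of(cols)) %>%
      tidyr::pivot_longer(dplyr::all_of(cols), names_to = "site_col",
                          values_to = "call") %>%
      mutate(site = as.integer(sub("^site_", "", .data$site_col))) %>%
      group_by(.data$clone_id, .data$site) %>%
      summarise(n_meth = sum(.data$call == 1L, na.rm = TRUE),
                n_unmeth = sum(.data$call == 0L, na.rm = TRUE),
                .groups = "drop") %>%
      mutate(fragment = frag,
             frequency = ifelse(.data$n_meth + .data$n_unmeth > 0,
                                .data$n_meth /
                                  (.data$n_meth + .data$n_unmeth),
                                NA_real_))
    site_tbls[[frag]] <- long
    clone_tbls[[frag]] <- per_clone
  }
  sites_tbl <- bind_rows(site_tbls)
  clones_tbl <- bind_rows(clone_tbls)
  missing <- setdiff(sheet$clone_id, clones_tbl$clone_id)
  if (length(missing) > 0) {
    warn(sprintf("clone(s) with no scored reads excluded: %s",
                 paste(missing, collapse = ", ")))
  }
  lab <- select(as_tibble(sheet), "clone_id", "expression")
  sites_tbl <- left_join(sites_tbl, lab, by = "clone_id") %>%
    select("clone_id", "fragment", "site", "n_meth", "n_unmeth",
           "frequency", "expression") %>%
    arrange(.data$fragment, .data$clone_id, .data$site)
  clones_tbl <- left_join(clones_tbl, lab, by = "clone_id") %>%
    select("clone_id", "fragment", "n_reads", "molecules_methylated",
           "molecules_unmethylated", "ratio", "expression") %>%
    arrange(.data$fragment, .data$clone_id)
  structure(list(sites = sites_tbl, clones = clones_tbl,
                 corrected = FALSE),
            class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("<meth_matrix>%s %d clones x %d sites (%s)\n",
              if (x$corrected) " bias-corrected," else "",
              dplyr::n_distinct(x$sites$clone_id),
              dplyr::n_distinct(paste(x$sites$fragment, x$sites$site)),
              paste(unique(x$sites$fragment), collapse = ", ")))
  print(head(x$sites, 5))
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.meth_matrix <- function(x, ...) x$sites

#' Pivot a methylation matrix to the wide clone-by-site layout
#'
#' One row per clone, one frequency column per site named
#' `f1.<site>` / `f2.<site>` (fragment prefix + promoter coordinate), the
#' layout the statistical and tree-learning stages consume.
#'
#' @param mat A `meth_matrix`.
#' @param fragments Optional character vector restricting to given
#'   fragment names.
#' @return Wide tibble: `clone_id`, `expression`, frequency columns.
#' @export
freq_wide <- function(mat, fragments = NULL) {
  tbl <- mat$sites
  if (!is.null(fragments)) tbl <- filter(tbl, .data$fragment %in% fragments)
  tbl %>%
    mutate(col = paste0(.frag_prefix(.data$fragment), ".", .data$site)) %>%
    select("clone_id", "expression", "col", "frequency") %>%
    tidyr::pivot_wider(names_from = "col", values_from = "frequency")
}

.frag_prefix <- function(fragment) {
  pre <- sub("^[Ff]ragment", "f", fragment)
  ifelse(grepl("^f[0-9]+$", pre), pre, fragment)
}
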