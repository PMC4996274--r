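#' The 30-clone CFC cohort table
#'
#' Per-clone metadata and sequencing tallies for the 30 hematopoietic
#' colony-forming-cell (CFC) clones of the MLH1 promoter methylation study
#' design: sample and clone identifiers, donor age, the 9-bp demultiplexing
#' barcode, the binary MLH1 expression label (1 = expressing, 0 =
#' non-expressing), and for each amplicon fragment the number of molecules
#' classified methylated and unmethylated together with their published
#' methylation ratio.
#'
#' @return A tibble with 30 rows and columns `sample_id`, `clone_id`,
#'   `donor_age`, `barcode`, `expression`, `frag1_meth`, `frag1_unmeth`,
#'   `frag1_ratio`, `frag2_meth`, `frag2_unmeth`, `frag2_ratio`.
#' @export
#' @examples
#' cohort <- mlh1_cohort()
#' table(cohort$expression)
mlh1_cohort <- function() {
  path <- system.file("extdata", "mlh1_cfc_cohort.tsv", package = "methcart")
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sample_id = "c", clone_id = "c", donor_age = "i",
                    barcode = "c", expression = "i",
                    .default = readr::col_double()))
}

#' Extract the sample sheet from a cohort table
#'
#' A sample sheet is the minimal table the demultiplexer needs: one row per
#' clone with its barcode and expression label.
#'
#' @param cohort A tibble with at least `clone_id`, `barcode`, `expression`
#'   columns (e.g. from [mlh1_cohort()]).
#' @return Tibble with columns `clone_id`, `donor_age` (if present),
#'   `barcode`, `expression`.
#' @export
sample_sheet <- function(cohort) {
  keep <- intersect(c("clone_id", "donor_age", "barcode", "expression"),
                    names(cohort))
  if (!all(c("clone_id", "barcode", "expression") %in% keep)) {
    abort("cohort must have clone_id, barcode and expression columns")
  }
  sheet <- dplyr::select(as_tibble(cohort), dplyr::all_of(keep))
  if (anyDuplicated(sheet$barcode)) {
    abort("duplicate barcodes in sample sheet")
  }
  sheet
}
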