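#' Define an amplicon fragment of the promoter window
#'
#' A fragment is one bisulfite PCR amplicon: a window of the promoter in
#' promoter coordinates (transcription start site at 0, upstream negative),
#' the bisulfite-space primer pair used to amplify it, and the CpG sites it
#' covers.
#'
#' @param name Fragment name, e.g. `"Fragment1"`.
#' @param window Length-2 integer vector `c(start, end)` in promoter
#'   coordinates, `start < end` (both typically negative).
#' @param forward_primer,reverse_primer Primer sequences (5' to 3', bisulfite
#'   space) as character scalars.
#' @param cpg_sites Integer vector of CpG site positions (position of the
#'   plus-strand C) inside the window, sorted ascending.
#' @return An object of class `fragment_def`.
#' @export
#' @examples
#' fragment_def("toy", c(-60, -1), "ACGT", "TTAA", cpg_sites = c(-50, -20))
fragment_def <- function(name, window, forward_primer, reverse_primer,
                         cpg_sites) {
  stopifnot(is.character(name), length(name) == 1,
            length(window) == 2, window[1] < window[2],
            is.character(forward_primer), is.character(reverse_primer))
  cpg_sites <- sort(as.integer(cpg_sites))
  if (any(cpg_sites < window[1] | cpg_sites + 1L > window[2])) {
    abort(sprintf("fragment '%s': CpG site outside window [%d, %d]",
                  name, window[1], window[2]))
  }
  structure(
    list(name = name,
         window = as.integer(window),
         forward_primer = toupper(forward_primer),
         reverse_primer = toupper(reverse_primer),
         cpg_sites = cpg_sites),
    class = "fragment_def")
}

#' @export
print.fragment_def <- function(x, ...) {
  cat(sprintf("<fragment_def> %s  window %d..%d  (%d CpG sites)\n",
              x$name, x$window[1], x$window[2], length(x$cpg_sites)))
  invisible(x)
}

.idx <- function(start_coord, p) as.integer(p) - start_coord + 1L

#' Construct and validate a promoter reference
#'
#' Represents the genomic plus-strand sequence of the assayed promoter
#' window together with its CpG site map and amplicon fragment definitions.
#' Coordinates follow the assay convention: the transcription start site is
#' position 0 and upstream positions are negative; a CpG site is identified
#' by the position of its plus-strand C.
#'
#' @param sequence Plus-strand DNA sequence (character scalar, A/C/G/T).
#' @param start_coord Promoter coordinate of the first base of `sequence`.
#' @param cpg_sites Integer vector of CpG site positions; every site `p`
#'   must satisfy `sequence[p] == "C"` and `sequence[p + 1] == "G"`.
#' @param fragments List of [fragment_def()] objects whose windows lie
#'   within the sequence and whose sites are a subset of `cpg_sites`.
#' @return An object of class `promoter_reference`.
#' @seealso [load_promoter_reference()], [mlh1_promoter()]
#' @export
promoter_reference <- function(sequence, start_coord, cpg_sites,
                               fragments = list()) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  sequence <- toupper(sequence)
  if (grepl("[^ACGT]", sequence)) {
    abort("reference sequence may contain only A, C, G, T")
  }
  start_coord <- as.integer(start_coord)
  cpg_sites <- sort(as.integer(cpg_sites))
  if (length(cpg_sites) == 0) abort("cpg_sites must be non-empty")
  L <- nchar(sequence)
  i <- .idx(start_coord, cpg_sites)
  if (any(i < 1 | i + 1L > L)) {
    abort(sprintf("CpG site %d outside the reference sequence",
                  cpg_sites[which(i < 1 | i + 1L > L)[1]]))
  }
  dinuc <- substring(sequence, i, i + 1L)
  bad <- dinuc != "CG"
  if (any(bad)) {
    abort(sprintf("position %d is '%s', not a CpG dinucleotide",
                  cpg_sites[which(bad)[1]], dinuc[which(bad)[1]]))
  }
  fragments <- lapply(fragments, function(fr) {
    if (!inherits(fr, "fragment_def")) abort("fragments must be fragment_def")
    w <- .idx(start_coord, fr$window)
    if (w[1] < 1 || w[2] > L) {
      abort(sprintf("fragment '%s' window %d..%d outside the sequence",
                    fr$name, fr$window[1], fr$window[2]))
    }
    if (!all(fr$cpg_sites %in% cpg_sites)) {
      abort(sprintf("fragment '%s' lists sites missing from the reference",
                    fr$name))
    }
    fr
  })
  names(fragments) <- vapply(fragments, `[[`, "", "name")
  structure(
    list(sequence = sequence, start_coord = start_coord,
         cpg_sites = cpg_sites, fragments = fragments),
    class = "promoter_reference")
}

#' @export
print.promoter_reference <- function(x, ...) {
  cat(sprintf("<promoter_reference> %d bp, coords %d..%d, %d CpG sites\n",
              nchar(x$sequence), x$start_coord,
              x$start_coord + nchar(x$sequence) - 1L, length(x$cpg_sites)))
  for (fr in x$fragments) print(fr)
  invisible(x)
}

#' Load a promoter reference from a FASTA file
#'
#' Reads a single-record FASTA and validates the declared CpG sites and
#' fragment windows against it.
#'
#' @param fasta_path Path to a FASTA file with exactly one record.
#' @param start_coord Promoter coordinate of the first base.
#' @inheritParams promoter_reference
#' @return A `promoter_reference`.
#' @export
#' @examples
#' fa <- system.file("extdata", "mlh1_promoter_synthetic.fa",
#'                   package = "methcart")
#' ref <- load_promoter_reference(fa, -938, mlh1_cpg_sites(),
#'                                fragments = mlh1_fragments())
load_promoter_reference <- function(fasta_path, start_coord, cpg_sites,
                                    fragments = list()) {
  dss <- Biostrings::readDNAStringSet(fasta_path)
  if (length(dss) != 1) {
    abort(sprintf("expected exactly one FASTA record, found %d", length(dss)))
  }
  promoter_reference(as.character(dss[[1]]), start_coord, cpg_sites,
                     fragments)
}

# CpG coordinates and bisulfite-space primers of the two MLH1 promoter
# amplicons (coordinates relative to the transcription start site).
.mlh1_f1_sites <- c(-896L, -884L, -872L, -809L, -807L, -786L, -776L, -765L,
                    -731L, -722L, -714L, -708L, -694L, -692L, -690L, -686L,
                    -683L, -679L, -669L, -665L, -656L, -644L, -636L, -629L,
                    -626L, -624L, -620L, -618L, -608L, -600L, -597L, -572L,
                    -565L, -543L, -530L, -525L, -509L, -506L)
.mlh1_f2_sites <- c(-572L, -565L, -543L, -530L, -525L, -509L, -506L, -481L,
                    -465L, -449L, -428L, -400L, -384L, -377L, -345L, -339L)

#' CpG site coordinates of the MLH1 promoter assay
#'
#' The per-fragment CpG site lists of the two MLH1 promoter amplicons
#' (38 sites in Fragment 1, 16 in Fragment 2; 7 sites shared by both),
#' in promoter coordinates.
#'
#' @param fragment `"union"` (default), `"Fragment1"` or `"Fragment2"`.
#' @return Sorted integer vector of site positions.
#' @export
mlh1_cpg_sites <- function(fragment = c("union", "Fragment1", "Fragment2")) {
  switch(match.arg(fragment),
         union = sort(union(.mlh1_f1_sites, .mlh1_f2_sites)),
         Fragment1 = .mlh1_f1_sites,
         Fragment2 = .mlh1_f2_sites)
}

#' Fragment definitions of the MLH1 promoter assay
#'
#' The two amplicons of the assay: Fragment 1 spans -938..-483 and carries
#' 38 CpG sites; Fragment 2 spans -596..-337 and carries 16. Primer
#' sequences are the published bisulfite-space primers.
#'
#' @return Named list of two [fragment_def()] objects.
#' @export
mlh1_fragments <- function() {
  list(
    Fragment1 = fragment_def(
      "Fragment1", c(-938L, -483L),
      forward_primer = "ACTCAAAATCCTCTACCTTATAATATC",
      reverse_primer = "TTAAAAGAAGTAAGATGGAAG",
      cpg_sites = .mlh1_f1_sites),
    Fragment2 = fragment_def(
      "Fragment2", c(-596L, -337L),
      forward_primer = "ACAAACCAAACACAAAACCCCAT",
      reverse_primer = "TTTAGTTAATAGGAGTAGAGATG",
      cpg_sites = .mlh1_f2_sites))
}

#' The packaged synthetic MLH1 promoter reference
#'
#' Loads the synthetic 602-bp demonstration sequence shipped with the
#' package. It carries CG dinucleotides exactly at the assay's CpG
#' coordinates (and nowhere else) so that every pipeline stage can be
#' exercised without downloading genomic sequence; a user may substitute
#' the true GRCh37 promoter window via [load_promoter_reference()].
#'
#' @return A `promoter_reference` with both fragments registered.
#' @export
mlh1_promoter <- function() {
  fa <- system.file("extdata", "mlh1_promoter_synthetic.fa",
                    package = "methcart")
  load_promoter_reference(fa, -938L, mlh1_cpg_sites(),
                          fragments = mlh1_fragments())
}

.ref_chars <- function(ref) strsplit(ref$sequence, "", fixed = TRUE)[[1]]

#' In-silico minus-strand bisulfite conversion of a fragment window
#'
#' Returns the plus-sense sequence expected from sequencing the
#' bisulfite-converted minus strand of the fragment. A minus-strand C shows
#' up, in plus-sense reads, at a plus-strand G position: at a CpG site the
#' dinucleotide reads CG if the site is methylated and CA if not, and every
#' non-CpG minus-strand C is fully converted, i.e. its plus-strand G is
#' emitted as A.
#'
#' @param ref A `promoter_reference`.
#' @param fragment A `fragment_def` (or its name in `ref$fragments`).
#' @param methylation_state `"all_methylated"`, `"all_unmethylated"`, or a
#'   0/1 (or logical) vector with one entry per fragment CpG site, in site
#'   order.
#' @return Character scalar: the converted window sequence.
#' @export
#' @examples
#' ref <- promoter_reference("AACGTTGT", -8, cpg_sites = -6,
#'   fragments = list(fragment_def("f", c(-8, -1), "A", "A", -6)))
#' bisulfite_convert_minus(ref, "f", "all_methylated")    # "AACGTTAT"
#' bisulfite_convert_minus(ref, "f", "all_unmethylated")  # "AACATTAT"
bisulfite_convert_minus <- function(ref, fragment,
                                    methylation_state = "all_methylated") {
  fragment <- .resolve_fragment(ref, fragment)
  n_sites <- length(fragment$cpg_sites)
  if (is.character(methylation_state) && length(methylation_state) == 1) {
    state <- switch(methylation_state,
                    all_methylated = rep(1L, n_sites),
                    all_unmethylated = rep(0L, n_sites),
                    abort("unknown methylation_state sentinel"))
  } else {
    state <- as.integer(methylation_state)
    if (length(state) != n_sites || any(!state %in% c(0L, 1L))) {
      abort(sprintf(
        "methylation_state must be 0/1 of length %d (fragment CpG count)",
        n_sites))
    }
  }
  ch <- .ref_chars(ref)
  i1 <- .idx(ref$start_coord, fragment$window[1])
  i2 <- .idx(ref$start_coord, fragment$window[2])
  site_g <- .idx(ref$start_coord, fragment$cpg_sites) + 1L
  g_pos <- which(ch == "G")
  g_pos <- g_pos[g_pos >= i1 & g_pos <= i2]
  for (g in g_pos) {
    in_cpg <- g > 1 && ch[g - 1L] == "C"
    if (!in_cpg) {
      ch[g] <- "A"                       # full conversion of non-CpG C
    } else if (g %in% site_g) {
      if (state[match(g, site_g)] == 0L) ch[g] <- "A"
    }                                    # unlisted CpG G kept as G
  }
  paste(ch[i1:i2], collapse = "")
}

.resolve_fragment <- function(ref, fragment) {
  if (inherits(fragment, "fragment_def")) return(fragment)
  fr <- ref$fragments[[fragment]]
  if (is.null(fr)) abort(sprintf("no fragment named '%s'", fragment))
  fr
}

#' Build the theoretical fully-methylated bisulfite reference
#'
#' The read-frame reference every read is aligned against: the fragment
#' window converted assuming 100% CpG methylation. Each column is
#' classified as `cpg_g` (the informative G/A position of a listed CpG
#' site), `conversion` (a non-CpG minus-strand C, expected A after full
#' conversion), or `fixed`.
#'
#' @inheritParams bisulfite_convert_minus
#' @return An object of class `theoretical_reference` with fields
#'   `sequence`, `classes`, `site_g_cols`, `site_c_cols`, `window`,
#'   `fragment`, `n_sites`.
#' @export
build_theoretical_reference <- function(ref, fragment) {
  fragment <- .resolve_fragment(ref, fragment)
  seq_conv <- bisulfite_convert_minus(ref, fragment, "all_methylated")
  ch <- .ref_chars(ref)
  i1 <- .idx(ref$start_coord, fragment$window[1])
  i2 <- .idx(ref$start_coord, fragment$window[2])
  L <- i2 - i1 + 1L
  classes <- rep("fixed", L)
  site_g_abs <- .idx(ref$start_coord, fragment$cpg_sites) + 1L
  g_abs <- which(ch == "G")
  g_abs <- g_abs[g_abs >= i1 & g_abs <= i2]
  for (g in g_abs) {
    col <- g - i1 + 1L
    if (g %in% site_g_abs) {
      classes[col] <- "cpg_g"
    } else if (g == 1 || ch[g - 1L] != "C") {
      classes[col] <- "conversion"
    }
  }
  site_g_cols <- setNames(site_g_abs - i1 + 1L,
                          as.character(fragment$cpg_sites))
  structure(
    list(sequence = seq_conv,
         classes = classes,
         site_g_cols = site_g_cols,
         site_c_cols = site_g_cols - 1L,
         window = fragment$window,
         fragment = fragment$name,
         n_sites = length(fragment$cpg_sites),
         length = L),
    class = "theoretical_reference")
}

#' @export
print.theoretical_reference <- function(x, ...) {
  cat(sprintf(
    "<theoretical_reference> %s  %d columns: %d cpg_g, %d conversion\n",
    x$fragment, x$length, sum(x$classes == "cpg_g"),
    sum(x$classes == "conversion")))
  invisible(x)
}
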