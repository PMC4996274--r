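#' Demultiplex reads by exact 9-bp barcode match
#'
#' A read is assigned to a clone iff its first 9 bases exactly match that
#' clone's barcode. No mismatch tolerance is applied: the barcodes of a
#' well-designed sheet are mutually distant and a single substitution may
#' make a read ambiguous.
#'
#' @param reads Tibble with `read_id` and `sequence` columns.
#' @param sheet Sample sheet tibble with `clone_id` and `barcode` columns
#'   (unique 9-bp barcodes).
#' @return The read tibble with an added `clone_id` column (`NA` for
#'   unassigned reads). A per-clone tally, including an `"<unassigned>"`
#'   row, is attached as attribute `"demux_report"` and can be retrieved
#'   with [demux_report()].
#' @export
demultiplex <- function(reads, sheet) {
  if (anyDuplicated(sheet$barcode)) {
    abort("duplicate barcode in sample sheet")
  }
  if (any(nchar(sheet$barcode) != 9)) abort("barcodes must be 9 bp")
  reads <- as_tibble(reads)
  if ("clone_id" %in% names(reads)) {
    reads <- rename(reads, true_clone = "clone_id")
  }
  if (nrow(reads) == 0) {
    warn("no input reads")
    out <- mutate(reads, clone_id = character(0))
    attr(out, "demux_report") <- tibble(clone_id = character(0),
                                        n_reads = integer(0))
    return(out)
  }
  lookup <- setNames(sheet$clone_id, sheet$barcode)
  bc <- substr(reads$sequence, 1, 9)
  out <- mutate(reads, clone_id = unname(lookup[bc]))
  tallies <- table(factor(ifelse(is.na(out$clone_id), "<unassigned>",
                                 out$clone_id),
                          levels = c(sheet$clone_id, "<unassigned>")))
  attr(out, "demux_report") <- tibble(clone_id = names(tallies),
                                      n_reads = as.integer(tallies))
  out
}

#' @rdname demultiplex
#' @param demuxed Result of `demultiplex()`.
#' @export
demux_report <- function(demuxed) attr(demuxed, "demux_report")

.match_pass <- function(seqs, pattern, max_mismatch) {
  hits <- Biostrings::vmatchPattern(pattern, Biostrings::DNAStringSet(seqs),
                                    max.mismatch = max_mismatch,
                                    with.indels = FALSE)
  ends <- rep(NA_integer_, length(seqs))
  starts <- rep(NA_integer_, length(seqs))
  nh <- S4Vectors::elementNROWS(hits)
  all_start <- unlist(BiocGenerics::start(hits), use.names = FALSE)
  all_end <- unlist(BiocGenerics::end(hits), use.names = FALSE)
  idx <- rep(seq_along(seqs), nh)
  first <- !duplicated(idx)
  starts[idx[first]] <- all_start[first]
  ends[idx[first]] <- all_end[first]
  list(start = starts, end = ends)
}

# exact match first (fast fixed-string search); mismatch-tolerant search
# only for the reads the exact pass misses
.first_match_end <- function(seqs, pattern, max_mismatch) {
  pos <- regexpr(pattern, seqs, fixed = TRUE)
  starts <- ifelse(pos > 0, as.integer(pos), NA_integer_)
  ends <- starts + nchar(pattern) - 1L
  if (max_mismatch > 0) {
    miss <- which(is.na(ends))
    if (length(miss) > 0) {
      fuzzy <- .match_pass(seqs[miss], pattern, max_mismatch)
      starts[miss] <- fuzzy$start
      ends[miss] <- fuzzy$end
    }
  }
  list(start = starts, end = ends)
}

#' Trim barcode/primer scaffolding and orient reads
#'
#' Locates the fragment's forward primer in each read (or in its reverse
#' complement, for reverse-orientation reads), reverse-complements reverse
#' reads into the plus-sense read frame, and strips everything up to the
#' end of the forward primer and from the start of the reverse-primer
#' complement onwards. Reads in which neither primer orientation is found
#' are dropped and counted.
#'
#' @param reads Tibble with `read_id`, `sequence` (and typically
#'   `clone_id` from [demultiplex()]).
#' @param fragment A `fragment_def`.
#' @param max_mismatch Mismatches tolerated in the primer match
#'   (default 2).
#' @return Tibble with `read_id`, `clone_id` (if present), `insert` and
#'   `orientation`; the number of dropped reads is attached as attribute
#'   `"n_dropped"`.
#' @export
trim_reads <- function(reads, fragment, max_mismatch = 2) {
  reads <- as_tibble(reads)
  if (nrow(reads) == 0) {
    out <- tibble(read_id = character(0), insert = character(0),
                  orientation = character(0))
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  seqs <- reads$sequence
  fp <- fragment$forward_primer
  rp_rc <- .revcomp(fragment$reverse_primer)

  # exact primer match in either orientation first; the expensive
  # mismatch-tolerant search only runs for reads failing both
  fwd_hit <- .first_match_end(seqs, fp, 0L)
  orientation <- ifelse(is.na(fwd_hit$end), NA_character_, "+")
  miss <- which(is.na(fwd_hit$end))
  if (length(miss) > 0) {
    rc <- .revcomp(seqs[miss])
    rc_hit <- .first_match_end(rc, fp, 0L)
    if (max_mismatch > 0) {
      m2 <- which(is.na(rc_hit$end))
      if (length(m2) > 0) {
        fz <- .match_pass(seqs[miss][m2], fp, max_mismatch)
        still <- which(is.na(fz$end))
        fwd_hit$end[miss[m2]] <- fz$end
        orientation[miss[m2][!is.na(fz$end)]] <- "+"
        if (length(still) > 0) {
          fz_rc <- .match_pass(rc[m2][still], fp, max_mismatch)
          rc_hit$end[m2[still]] <- fz_rc$end
        }
      }
    }
    found <- which(!is.na(rc_hit$end))
    seqs[miss[found]] <- rc[found]
    fwd_hit$end[miss[found]] <- rc_hit$end[found]
    orientation[miss[found]] <- "-"
  }
  keep <- which(!is.na(orientation))
  n_dropped <- length(seqs) - length(keep)
  seqs <- seqs[keep]
  ins_start <- fwd_hit$end[keep] + 1L
  tail_hit <- .first_match_end(seqs, rp_rc, max_mismatch)
  ins_end <- ifelse(!is.na(tail_hit$start) & tail_hit$start > ins_start,
                    tail_hit$start - 1L, nchar(seqs))
  out <- tibble(read_id = reads$read_id[keep],
                insert = substr(seqs, ins_start, ins_end),
                orientation = orientation[keep])
  if ("clone_id" %in% names(reads)) {
    out <- dplyr::bind_cols(out["read_id"],
                            tibble(clone_id = reads$clone_id[keep]),
                            out[c("insert", "orientation")])
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Align inserts to the theoretical bisulfite reference
#'
#' Projects each insert onto the reference frame of the fully-methylated
#' theoretical reference and computes its identity: matching columns over
#' all reference columns, gaps and uncovered columns counting as
#' mismatches. Inserts whose length equals the reference length are
#' projected by direct column comparison (exact when the read has no
#' indels); other inserts are aligned by affine-gap dynamic programming
#' (match +1, mismatch -1, gap open -2, gap extend -1, end gaps free) via
#' `Biostrings::pairwiseAlignment`. `method = "dp"` forces dynamic
#' programming for every insert.
#'
#' Inserts shorter than `min_len_frac` of the reference are dropped and
#' counted in attribute `"n_dropped"`.
#'
#' @param inserts Tibble with `read_id` and `insert` columns (from
#'   [trim_reads()]).
#' @param theo A `theoretical_reference`.
#' @param method `"auto"` (default) or `"dp"`.
#' @param min_len_frac Minimum insert length as a fraction of the
#'   reference length (default 0.5).
#' @return Tibble with `read_id` (plus `clone_id` if present), `ref_frame`
#'   (read base per reference column, `-` for gaps) and `identity`.
#' @export
align_to_reference <- function(inserts, theo, method = c("auto", "dp"),
                               min_len_frac = 0.5) {
  method <- match.arg(method)
  inserts <- as_tibble(inserts)
  L <- theo$length
  len <- nchar(inserts$insert)
  keep <- len >= min_len_frac * L & len > 0
  n_dropped <- sum(!keep)
  inserts <- inserts[keep, , drop = FALSE]
  len <- len[keep]
  n <- nrow(inserts)
  ref_frame <- character(n)
  direct <- if (method == "auto") which(len == L) else integer(0)
  dp <- setdiff(seq_len(n), direct)
  if (length(direct) > 0) ref_frame[direct] <- inserts$insert[direct]
  if (length(dp) > 0) {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                    baseOnly = TRUE)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(inserts$insert[dp]),
      Biostrings::DNAString(theo$sequence),
      type = "overlap", substitutionMatrix = mat,
      gapOpening = 2, gapExtension = 1)
    # aligned() projects the read into subject coordinates: insertions
    # dropped, deletions and uncovered reference ends as "-", full
    # subject width
    ref_frame[dp] <- as.character(Biostrings::aligned(pa))
  }
  identity <- .frame_identity(ref_frame, theo$sequence)
  out <- dplyr::bind_cols(
    inserts[intersect(c("read_id", "clone_id"), names(inserts))],
    tibble(ref_frame = ref_frame, identity = identity))
  attr(out, "n_dropped") <- n_dropped
  out
}

# identity = matching columns / reference length
.frame_identity <- function(frames, ref_seq) {
  L <- nchar(ref_seq)
  ref_raw <- charToRaw(ref_seq)
  vapply(frames, function(f) sum(charToRaw(f) == ref_raw) / L, 0,
         USE.NAMES = FALSE)
}

#' Filter aligned reads by identity
#'
#' Retains reads whose identity is strictly greater than the threshold
#' (the assay's published filter keeps reads with > 70% identity).
#'
#' @param aligned Tibble from [align_to_reference()] with an `identity`
#'   column.
#' @param threshold Identity threshold in (0, 1); default 0.70.
#' @return The retained rows.
#' @export
identity_filter <- function(aligned, threshold = 0.70) {
  if (threshold <= 0 || threshold >= 1) abort("threshold must be in (0, 1)")
  filter(aligned, .data$identity > threshold)
}
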