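#' Simulation configuration
#'
#' Parameters controlling the synthetic read generator. Defaults emulate
#' the sequencing conditions the pipeline is designed for: near-complete
#' bisulfite conversion (99.99%), low substitution noise, and sparse
#' pyrosequencing-style indels.
#'
#' @param conversion_failure_rate Probability that a non-CpG minus-strand C
#'   escapes conversion (read base G instead of A). Default `1e-4`.
#' @param seq_error_rate Per-base substitution probability. Default `0.001`.
#' @param indel_rate Per-base insertion/deletion probability. Default
#'   `0.001`.
#' @param bias_b Amplification-efficiency ratio of unmethylated to
#'   methylated template (> 0); only used in `two_template` mode. Default 1
#'   (no bias).
#' @param mixture_mode `"pattern"` (per-site independent Bernoulli draws)
#'   or `"two_template"` (each molecule fully methylated or fully
#'   unmethylated, with unmethylated molecules over-sampled by `bias_b`).
#' @param bidirectional Emit reads in both orientations (default `TRUE`).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(conversion_failure_rate = 1e-4,
                       seq_error_rate = 0.001,
                       indel_rate = 0.001,
                       bias_b = 1,
                       mixture_mode = c("pattern", "two_template"),
                       bidirectional = TRUE) {
  mixture_mode <- match.arg(mixture_mode)
  rates <- c(conversion_failure_rate, seq_error_rate, indel_rate)
  if (any(rates < 0 | rates > 1)) abort("rates must lie in [0, 1]")
  if (!is.numeric(bias_b) || bias_b <= 0) abort("bias_b must be > 0")
  structure(list(conversion_failure_rate = conversion_failure_rate,
                 seq_error_rate = seq_error_rate,
                 indel_rate = indel_rate,
                 bias_b = bias_b,
                 mixture_mode = mixture_mode,
                 bidirectional = bidirectional),
            class = "sim_config")
}

#' Clone profile for read simulation
#'
#' @param clone_id Clone identifier.
#' @param barcode 9-character DNA barcode.
#' @param expression Binary MLH1 expression label (1 expressing, 0 not).
#' @param site_probs Per-CpG methylation probability vector (one value per
#'   fragment CpG site, in site order), all in `[0, 1]`.
#' @param n_molecules Number of molecules (reads) to emit.
#' @return A list of class `clone_profile`.
#' @export
clone_profile <- function(clone_id, barcode, expression, site_probs,
                          n_molecules) {
  if (nchar(barcode) != 9 || grepl("[^ACGT]", barcode)) {
    abort("barcode must be a 9-character DNA string")
  }
  if (any(site_probs < 0 | site_probs > 1)) {
    abort("site_probs must lie in [0, 1]")
  }
  if (n_molecules < 1) abort("n_molecules must be >= 1")
  structure(list(clone_id = clone_id, barcode = toupper(barcode),
                 expression = as.integer(expression),
                 site_probs = as.numeric(site_probs),
                 n_molecules = as.integer(n_molecules)),
            class = "clone_profile")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Exact sparse Bernoulli field over n_cells: draw the success count, then
# the success cells without replacement.
.bernoulli_cells <- function(n_cells, rate) {
  k <- rbinom(1, n_cells, rate)
  if (k == 0) integer(0) else sample.int(n_cells, k)
}

# Assemble insert strings: template split around the variable CpG G
# columns, with per-read G/A bases pasted in between the fixed segments.
.assemble_inserts <- function(template, g_cols, meth_matrix) {
  k <- length(g_cols)
  L <- nchar(template)
  starts <- c(1L, g_cols + 1L)
  ends <- c(g_cols - 1L, L)
  segs <- substring(template, starts, ends)
  args <- vector("list", 2L * k + 1L)
  args[[1]] <- segs[1]
  for (j in seq_len(k)) {
    args[[2L * j]] <- ifelse(meth_matrix[, j] == 1L, "G", "A")
    args[[2L * j + 1L]] <- segs[j + 1L]
  }
  do.call(paste0, args)
}

#' Simulate reads for one clone and one fragment
#'
#' Each read is `barcode + forward primer + converted insert +
#' revcomp(reverse primer)` (or its reverse complement, barcode kept at the
#' 5' end, for reverse-orientation reads). Per-site methylation is drawn
#' according to `cfg$mixture_mode`; bisulfite conversion failures flip the
#' expected A back to G at non-CpG conversion positions; substitution and
#' indel noise is applied over the whole read.
#'
#' In `two_template` mode `site_probs` must be constant (a single true
#' methylated fraction m); each molecule is then entirely methylated or
#' entirely unmethylated, and unmethylated molecules are sampled with
#' relative weight `bias_b`, so the expected observed methylated fraction
#' is `m / (m + bias_b * (1 - m))`.
#'
#' @param ref A `promoter_reference`.
#' @param fragment A `fragment_def` or fragment name.
#' @param profile A [clone_profile()].
#' @param cfg A [sim_config()].
#' @param seed Optional integer seed for reproducibility.
#' @return Tibble with columns `read_id`, `sequence`, `clone_id`,
#'   `orientation` (provenance columns are for testing; the demultiplexer
#'   never looks at them).
#' @export
simulate_clone_reads <- function(ref, fragment, profile, cfg = sim_config(),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fragment <- .resolve_fragment(ref, fragment)
  theo <- build_theoretical_reference(ref, fragment)
  n <- profile$n_molecules
  k <- theo$n_sites
  if (length(profile$site_probs) != k) {
    abort(sprintf("site_probs length %d but fragment has %d CpG sites",
                  length(profile$site_probs), k))
  }
  if (cfg$mixture_mode == "two_template") {
    m <- unique(profile$site_probs)
    if (length(m) != 1) {
      abort("two_template mode requires constant site_probs")
    }
    p_meth <- if (m == 0) 0 else m / (m + cfg$bias_b * (1 - m))
    z <- rbinom(n, 1L, p_meth)
    meth <- matrix(z, nrow = n, ncol = k)
  } else {
    meth <- matrix(rbinom(n * k, 1L,
                          rep(profile$site_probs, each = n)),
                   nrow = n, ncol = k)
  }
  inserts <- .assemble_inserts(theo$sequence, unname(theo$site_g_cols), meth)

  conv_cols <- which(theo$classes == "conversion")
  if (cfg$conversion_failure_rate > 0 && length(conv_cols) > 0) {
    cells <- .bernoulli_cells(n * length(conv_cols),
                              cfg$conversion_failure_rate)
    if (length(cells) > 0) {
      row <- ((cells - 1L) %% n) + 1L
      col <- conv_cols[((cells - 1L) %/% n) + 1L]
      for (e in seq_along(cells)) {
        substr(inserts[row[e]], col[e], col[e]) <- "G"
      }
    }
  }

  fwd <- paste0(profile$barcode, fragment$forward_primer, inserts,
                .revcomp(fragment$reverse_primer))
  if (cfg$bidirectional) {
    ori <- sample(c("+", "-"), n, replace = TRUE)
    rev_idx <- which(ori == "-")
    if (length(rev_idx) > 0) {
      core <- paste0(fragment$forward_primer, inserts[rev_idx],
                     .revcomp(fragment$reverse_primer))
      fwd[rev_idx] <- paste0(profile$barcode, .revcomp(core))
    }
  } else {
    ori <- rep("+", n)
  }
  reads <- fwd

  if (cfg$seq_error_rate > 0) {
    w <- nchar(reads[1])
    cells <- .bernoulli_cells(n * w, cfg$seq_error_rate)
    if (length(cells) > 0) {
      row <- ((cells - 1L) %% n) + 1L
      col <- ((cells - 1L) %/% n) + 1L
      keep <- col <= nchar(reads[row])
      row <- row[keep]; col <- col[keep]
      for (e in seq_along(row)) {
        old <- substr(reads[row[e]], col[e], col[e])
        substr(reads[row[e]], col[e], col[e]) <-
          sample(setdiff(c("A", "C", "G", "T"), old), 1)
      }
    }
  }
  if (cfg$indel_rate > 0) {
    w <- nchar(reads[1])
    cells <- .bernoulli_cells(n * w, cfg$indel_rate)
    if (length(cells) > 0) {
      row <- ((cells - 1L) %% n) + 1L
      col <- ((cells - 1L) %/% n) + 1L
      for (e in seq_along(row)) {
        s <- reads[row[e]]
        pos <- min(col[e], nchar(s))
        if (runif(1) < 0.5) {            # deletion
          reads[row[e]] <- paste0(substr(s, 1, pos - 1),
                                  substr(s, pos + 1, nchar(s)))
        } else {                         # insertion
          reads[row[e]] <- paste0(substr(s, 1, pos),
                                  sample(c("A", "C", "G", "T"), 1),
                                  substr(s, pos + 1, nchar(s)))
        }
      }
    }
  }

  tibble(read_id = sprintf("%s_%s_%06d", profile$clone_id, fragment$name,
                           seq_len(n)),
         sequence = reads,
         clone_id = profile$clone_id,
         orientation = ori)
}

#' Simulate methylation control mixtures
#'
#' Generates the three calibration read sets used to fit the hyperbolic
#' amplification-bias model: fully methylated (1:0), 1:1 mixed, and fully
#' unmethylated (0:1) template, all in two-template mode with the given
#' bias.
#'
#' @inheritParams simulate_clone_reads
#' @param bias_b Amplification-efficiency ratio of unmethylated to
#'   methylated template.
#' @param n Reads per control set (>= 100 recommended).
#' @param cfg A [sim_config()]; its `mixture_mode` and `bias_b` are
#'   overridden.
#' @return Named list of three read tibbles (`"1:0"`, `"1:1"`, `"0:1"`),
#'   each carrying its true methylated fraction in attribute `"m"` and its
#'   barcode in attribute `"barcode"`.
#' @export
simulate_controls <- function(ref, fragment, bias_b, n, cfg = sim_config(),
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fragment <- .resolve_fragment(ref, fragment)
  cfg$mixture_mode <- "two_template"
  cfg$bias_b <- bias_b
  ms <- c("1:0" = 1, "1:1" = 0.5, "0:1" = 0)
  barcodes <- c("1:0" = "ACACACACA", "1:1" = "AGAGAGAGA",
                "0:1" = "ATATATATA")
  out <- lapply(names(ms), function(nm) {
    pr <- clone_profile(paste0("control_", nm), barcodes[[nm]],
                        expression = 0L,
                        site_probs = rep(ms[[nm]], length(fragment$cpg_sites)),
                        n_molecules = n)
    rs <- simulate_clone_reads(ref, fragment, pr, cfg)
    attr(rs, "m") <- ms[[nm]]
    attr(rs, "barcode") <- barcodes[[nm]]
    rs
  })
  names(out) <- names(ms)
  out
}

.random_barcodes <- function(n) {
  repeat {
    bc <- vapply(seq_len(n), function(i) {
      paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE), collapse = "")
    }, "")
    if (!anyDuplicated(bc)) return(bc)
  }
}

#' Simulate a multiplexed clone cohort
#'
#' Builds clone profiles for the requested numbers of expressing and
#' non-expressing clones, simulates reads for every clone over the given
#' fragments, and interleaves them into one multiplexed read set with a
#' matching sample sheet. Expressing clones draw per-site methylation
#' probabilities from a low-methylation regime (Beta(2, 10)) and
#' non-expressing clones from a higher, heterogeneous regime (Beta(4, 6)),
#' each scaled by a clone-level factor drawn from Unif(0.5, 1.5) to mimic
#' the wide spread of clone-level methylation seen in real cohorts.
#'
#' @inheritParams simulate_clone_reads
#' @param n_expressing,n_nonexpressing Clone counts per class.
#' @param fragments List of fragments to sequence (default: all fragments
#'   registered in `ref`).
#' @param depth Length-2 numeric: per-clone molecule counts per fragment are
#'   drawn log-uniformly from `[depth[1], depth[2]]`. A single number fixes
#'   the depth.
#' @param barcodes Optional character vector of unique 9-bp barcodes, one
#'   per clone; defaults to the packaged cohort barcodes when the clone
#'   count allows, otherwise random distinct 9-mers.
#' @param out_dir If non-`NULL`, write `reads.fastq` and
#'   `sample_sheet.tsv` there.
#' @return List with elements `sample_sheet` (tibble), `reads` (tibble of
#'   all reads, interleaved), and `profiles` (list of lists of
#'   [clone_profile()] per fragment).
#' @export
simulate_cohort <- function(ref, n_expressing = 10, n_nonexpressing = 20,
                            fragments = NULL, cfg = sim_config(),
                            depth = c(600, 3000), barcodes = NULL,
                            out_dir = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_expressing < 1 || n_nonexpressing < 1) {
    abort("clone counts must be >= 1")
  }
  if (is.null(fragments)) fragments <- ref$fragments
  if (length(fragments) == 0) abort("no fragments to simulate")
  n_clones <- n_expressing + n_nonexpressing
  if (is.null(barcodes)) {
    cohort_bc <- mlh1_cohort()$barcode
    barcodes <- if (n_clones <= length(cohort_bc)) {
      cohort_bc[seq_len(n_clones)]
    } else {
      .random_barcodes(n_clones)
    }
  }
  if (anyDuplicated(barcodes)) abort("duplicate barcodes")
  if (length(barcodes) != n_clones) {
    abort("need one barcode per clone")
  }
  expression <- c(rep(1L, n_expressing), rep(0L, n_nonexpressing))
  clone_ids <- sprintf("%s%02d", ifelse(expression == 1, "EXP", "NON"),
                       c(seq_len(n_expressing), seq_len(n_nonexpressing)))
  if (length(depth) == 1) depth <- c(depth, depth)

  profiles <- lapply(seq_len(n_clones), function(i) {
    scale_i <- runif(1, 0.5, 1.5)
    lapply(fragments, function(fr) {
      k <- length(fr$cpg_sites)
      p <- if (expression[i] == 1) rbeta(k, 2, 10) else rbeta(k, 4, 6)
      p <- pmin(pmax(p * scale_i, 0), 1)
      n_mol <- as.integer(round(exp(runif(1, log(depth[1]), log(depth[2])))))
      clone_profile(clone_ids[i], barcodes[i], expression[i], p, n_mol)
    })
  })
  names(profiles) <- clone_ids

  reads <- bind_rows(lapply(profiles, function(per_frag) {
    bind_rows(lapply(names(per_frag), function(fn) {
      simulate_clone_reads(ref, fragments[[fn]], per_frag[[fn]], cfg)
    }))
  }))
  reads <- reads[sample.int(nrow(reads)), , drop = FALSE]

  sheet <- tibble(clone_id = clone_ids,
                  donor = "SIM",
                  age = NA_integer_,
                  barcode = barcodes,
                  expression = expression)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fastq(reads, file.path(out_dir, "reads.fastq"))
    readr::write_tsv(sheet, file.path(out_dir, "sample_sheet.tsv"))
  }
  list(sample_sheet = sheet, reads = reads, profiles = profiles)
}

#' Simulate a clone-by-site methylation frequency cohort
#'
#' Generates observed per-site methylation frequencies directly (binomial
#' sampling of per-site probabilities at a given read depth), skipping read
#' simulation. This is the natural input scale for the statistical and
#' tree-learning stages; optionally one site is "planted" with a clean
#' class difference so recovery of the informative site can be measured.
#' With a planted site, every other site is class-independent Beta(2, 2)
#' noise, making the planted site the only informative one; without,
#' sites follow the class regimes of [simulate_cohort()].
#'
#' @param n_expressing,n_nonexpressing Clone counts per class.
#' @param sites Integer vector of site coordinates.
#' @param depth Reads per clone used for the binomial sampling noise.
#' @param planted_site Optional site (must be in `sites`) given a fixed
#'   class-dependent methylation probability.
#' @param planted_p Named numeric `c(expressing =, nonexpressing =)` true
#'   probabilities at the planted site.
#' @param site_prefix Prefix for frequency column names (default `"f1."`).
#' @param seed Optional integer seed.
#' @return Wide tibble: `clone_id`, `expression`, one frequency column per
#'   site named `<site_prefix><site>`.
#' @export
simulate_frequency_cohort <- function(n_expressing = 10,
                                      n_nonexpressing = 20,
                                      sites = mlh1_cpg_sites("Fragment1"),
                                      depth = 2000,
                                      planted_site = NULL,
                                      planted_p = c(expressing = 0.2,
                                                    nonexpressing = 0.8),
                                      site_prefix = "f1.",
                                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_expressing + n_nonexpressing
  expression <- c(rep(1L, n_expressing), rep(0L, n_nonexpressing))
  k <- length(sites)
  probs <- matrix(NA_real_, n, k)
  if (is.null(planted_site)) {
    for (i in seq_len(n)) {
      probs[i, ] <- if (expression[i] == 1) rbeta(k, 2, 10)
                    else rbeta(k, 4, 6)
    }
  } else {
    # planted design: every other site is class-independent noise so the
    # planted site is the only informative one
    j <- match(planted_site, sites)
    if (is.na(j)) abort("planted_site must be one of sites")
    probs[] <- rbeta(n * k, 2, 2)
    probs[, j] <- ifelse(expression == 1, planted_p[["expressing"]],
                         planted_p[["nonexpressing"]])
  }
  freq <- matrix(rbinom(n * k, depth, probs) / depth, n, k)
  colnames(freq) <- paste0(site_prefix, sites)
  dplyr::bind_cols(
    tibble(clone_id = sprintf("%s%02d", ifelse(expression == 1, "EXP", "NON"),
                              c(seq_len(n_expressing),
                                seq_len(n_nonexpressing))),
           expression = expression),
    as_tibble(freq))
}

#' Write reads to FASTQ
#'
#' Constant Phred-33 quality (`I`, Q40) is used: the simulator models
#' errors directly, not quality scores.
#'
#' @param reads Tibble with `read_id` and `sequence` columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  dss <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  qual <- Biostrings::PhredQuality(
    Biostrings::BStringSet(strrep("I", Biostrings::width(dss))))
  qdss <- Biostrings::QualityScaledDNAStringSet(dss, qual)
  Biostrings::writeQualityScaledXStringSet(qdss, path)
  invisible(path)
}

#' Read a FASTA or FASTQ file into a read tibble
#'
#' @param path Input path.
#' @param format `"fastq"` (default) or `"fasta"`.
#' @return Tibble with `read_id` and `sequence`.
#' @export
read_reads <- function(path, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  dss <- Biostrings::readDNAStringSet(path, format = format)
  tibble(read_id = sub("\\s.*$", "", names(dss)),
         sequence = as.character(dss))
}
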