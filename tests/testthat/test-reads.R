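test_that("demultiplexing assigns by exact barcode only", {
  sheet <- sample_sheet(mlh1_cohort())
  pad <- strrep("A", 40)
  reads <- tibble::tibble(
    read_id = c("r1", "r2", "r3"),
    sequence = c(paste0("ATATCTCAA", pad),   # BMA01-C13's barcode
                 paste0("TTATCTCAA", pad),   # one substitution off
                 paste0("ACTAGGTCC", pad)))  # BMA01-C14's barcode
  dm <- demultiplex(reads, sheet)
  expect_identical(dm$clone_id, c("BMA01-C13", NA, "BMA01-C14"))
  rep <- demux_report(dm)
  expect_equal(rep$n_reads[rep$clone_id == "<unassigned>"], 1)
})

test_that("demultiplexing counts reads per clone", {
  sheet <- tibble::tibble(clone_id = c("A", "B"),
                          barcode = c("AAAAAAAAA", "CCCCCCCCC"),
                          expression = c(1L, 0L))
  reads <- tibble::tibble(
    read_id = sprintf("r%d", 1:20),
    sequence = c(rep(paste0("AAAAAAAAA", strrep("T", 30)), 10),
                 rep(paste0("CCCCCCCCC", strrep("T", 30)), 10)))
  dm <- demultiplex(reads, sheet)
  rep <- demux_report(dm)
  expect_equal(rep$n_reads, c(10L, 10L, 0L))
  expect_error(demultiplex(reads, dplyr::mutate(sheet, barcode = "AAAAAAAAA")),
               "duplicate")
  expect_warning(demultiplex(reads[0, ], sheet), "no input")
})

test_that("trimming strips scaffolding and reorients reverse reads", {
  ref <- tiny_ref()
  fr <- ref$fragments$tiny
  insert <- bisulfite_convert_minus(ref, fr, "all_methylated")
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(x)))
  fwd <- paste0("ACGTACGTA", fr$forward_primer, insert,
                rc(fr$reverse_primer))
  rev <- paste0("ACGTACGTA", rc(paste0(fr$forward_primer, insert,
                                       rc(fr$reverse_primer))))
  reads <- tibble::tibble(read_id = c("f", "r", "junk"),
                          sequence = c(fwd, rev, strrep("T", 90)))
  tr <- trim_reads(reads, fr)
  expect_equal(nrow(tr), 2)
  expect_identical(tr$insert[1], insert)
  expect_identical(tr$insert[2], insert)   # reverse-complement involution
  expect_identical(tr$orientation, c("+", "-"))
  expect_equal(attr(tr, "n_dropped"), 1L)
})

test_that("alignment identity matches the mismatch-count formula", {
  ref <- mlh1_promoter()
  theo <- build_theoretical_reference(ref, "Fragment1")
  L <- theo$length
  meth <- bisulfite_convert_minus(ref, "Fragment1", "all_methylated")
  unmeth <- bisulfite_convert_minus(ref, "Fragment1", "all_unmethylated")
  al <- align_to_reference(
    tibble::tibble(read_id = c("m", "u"), insert = c(meth, unmeth)), theo)
  expect_equal(al$identity[1], 1.0)
  # fully unmethylated read mismatches the 38 CpG columns only
  expect_equal(al$identity[2], (L - 38) / L)
  # one deletion costs at most a handful of columns
  del <- paste0(substr(meth, 1, 99), substr(meth, 101, L))
  al2 <- align_to_reference(
    tibble::tibble(read_id = "d", insert = del), theo, method = "dp")
  expect_gte(al2$identity, (L - 2) / L)
})

test_that("aligner score agrees with an ends-free DP oracle", {
  theo <- tiny_theo()
  set.seed(8)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  for (i in 1:25) {
    s <- strsplit(theo$sequence, "")[[1]]
    # random substitutions, deletions, insertions
    nmut <- sample(0:5, 1)
    for (m in seq_len(nmut)) {
      op <- sample(c("sub", "del", "ins"), 1)
      pos <- sample(length(s), 1)
      if (op == "sub") s[pos] <- sample(c("A", "C", "G", "T"), 1)
      if (op == "del") s <- s[-pos]
      if (op == "ins") s <- append(s, sample(c("A", "C", "G", "T"), 1), pos)
    }
    insert <- paste(s, collapse = "")
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(insert), Biostrings::DNAString(theo$sequence),
      type = "overlap", substitutionMatrix = mat,
      gapOpening = 2, gapExtension = 1)
    expect_equal(Biostrings::score(pa),
                 oracle_align_score(insert, theo$sequence))
  }
})

test_that("short inserts are dropped before alignment", {
  theo <- tiny_theo()
  al <- align_to_reference(
    tibble::tibble(read_id = c("ok", "short"),
                   insert = c(theo$sequence,
                              substr(theo$sequence, 1, 20))), theo)
  expect_equal(nrow(al), 1)
  expect_equal(attr(al, "n_dropped"), 1L)
})

test_that("identity filter is strict and monotone", {
  aligned <- tibble::tibble(read_id = c("a", "b", "c"),
                            ref_frame = "x",
                            identity = c(0.70, 0.71, 1.0))
  kept <- identity_filter(aligned, 0.70)
  expect_identical(kept$read_id, c("b", "c"))
  expect_error(identity_filter(aligned, 1.2), "threshold")
  # raising the threshold never increases the retained count
  set.seed(13)
  ids <- tibble::tibble(read_id = as.character(1:200), ref_frame = "x",
                        identity = runif(200))
  counts <- vapply(seq(0.05, 0.95, by = 0.05),
                   function(t) nrow(identity_filter(ids, t)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("noise-free cohorts demultiplex losslessly end to end", {
  ref <- tiny_ref()
  cfg <- sim_config(conversion_failure_rate = 0, seq_error_rate = 0,
                    indel_rate = 0)
  sim <- simulate_cohort(ref, 2, 3, cfg = cfg, depth = 20, seed = 31)
  dm <- demultiplex(sim$reads, sim$sample_sheet)
  expect_true(all(!is.na(dm$clone_id)))
  expect_identical(dm$clone_id, dm$true_clone)
})
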