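# Small fixtures and independent oracles shared across the suite.

# 60-bp synthetic promoter with CpG sites at -50, -40, -30 (and no other
# CG), 10 lone-G conversion positions, one plus-strand non-CpG C.
tiny_ref <- function() {
  seqs <- paste0("ATTATTCATT", "CGTTAGATTG", "CGATTAGTTA",
                 "CGTTAGGTTA", "TTGATTAGGT", "ATTAGGATTA")
  fr <- fragment_def("tiny", c(-60L, -1L),
                     forward_primer = "CCCCACCCC",
                     reverse_primer = "GGGGAGGGG",
                     cpg_sites = c(-50L, -40L, -30L))
  promoter_reference(seqs, -60L, c(-50L, -40L, -30L),
                     fragments = list(fr))
}

tiny_theo <- function(ref = tiny_ref()) {
  build_theoretical_reference(ref, "tiny")
}

# Ends-free affine-gap alignment score (Gotoh), gap of length g costing
# open + g * extend; independent of the package's aligner.
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               open = 2, extend = 1) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in a match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # gap in b (a consumed)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in a (b consumed)
  M[1, 1] <- 0
  X[, 1] <- 0                      # free end gaps
  Y[1, ] <- 0
  M[1, ] <- 0; M[, 1] <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (a[i - 1] == b[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1],
                     Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
    }
  }
  # free end gaps: best over last row and column
  max(M[n + 1, ], X[n + 1, ], Y[n + 1, ],
      M[, m + 1], X[, m + 1], Y[, m + 1])
}

# All (deviance, size) pairs over every pruned subtree rooted at `node`;
# exhaustive, independent of the package's pruning DP.
oracle_subtree_costs <- function(node) {
  leaf <- c(node$deviance, 1)
  if (is.null(node$split)) return(list(leaf))
  l <- oracle_subtree_costs(node$left)
  r <- oracle_subtree_costs(node$right)
  out <- list(leaf)
  for (a in l) for (b in r) {
    out[[length(out) + 1]] <- a + b
  }
  out
}

oracle_min_cost_complexity <- function(tree, k = 2) {
  costs <- oracle_subtree_costs(tree$root)
  min(vapply(costs, function(p) p[1] + k * p[2], 0))
}

# Exhaustive deviance-optimal single split: every site x every midpoint.
oracle_best_split <- function(x, y) {
  best <- NULL
  best_dev <- Inf
  for (j in seq_len(ncol(x))) {
    u <- sort(unique(x[, j]))
    if (length(u) < 2) next
    for (i in seq_len(length(u) - 1)) {
      thr <- (u[i] + u[i + 1]) / 2
      li <- x[, j] < thr
      d <- node_deviance(sum(y[li]), sum(li) - sum(y[li])) +
        node_deviance(sum(y[!li]), sum(!li) - sum(y[!li]))
      if (d < best_dev) {
        best_dev <- d
        best <- list(site = colnames(x)[j], threshold = thr,
                     child_deviance = d)
      }
    }
  }
  best
}

# Grid-search maximum-likelihood univariate logistic fit.
oracle_logistic_grid <- function(freq, labels, slope_range = c(-40, 40),
                                 int_range = c(-20, 20), steps = 5) {
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * freq
    sum(labels * eta - log1p(exp(eta)))
  }
  b0s <- seq(int_range[1], int_range[2], length.out = 121)
  b1s <- seq(slope_range[1], slope_range[2], length.out = 121)
  for (s in seq_len(steps)) {
    ll <- outer(b0s, b1s, Vectorize(loglik))
    ij <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    w0 <- diff(range(b0s)) / 10
    w1 <- diff(range(b1s)) / 10
    b0c <- b0s[ij[1]]; b1c <- b1s[ij[2]]
    b0s <- seq(b0c - w0, b0c + w0, length.out = 121)
    b1s <- seq(b1c - w1, b1c + w1, length.out = 121)
  }
  c(intercept = b0c, slope = b1c)
}

quiet_pipeline <- function(...) {
  suppressMessages(run_pipeline(...))
}
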