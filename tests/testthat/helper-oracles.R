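# Independent brute-force oracles and fixture helpers, written separately
# from the package internals so that agreement is a real cross-check.

random_mirna <- function(len = 21L, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

ref_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGTU", "TGCAA", toupper(seq)), "")[[1]]), collapse = "")
}

# Scalar per-position duplex scorer: direct transcription of the scoring
# rules, character by character, independent of the package's encoded
# lookup tables.
ref_score <- function(mirna, site, mismatch = 1, wobble = 0.5,
                      seed_start = 2, seed_end = 13, seed_multiplier = 2) {
  m <- strsplit(chartr("T", "U", toupper(mirna)), "")[[1]]
  s <- strsplit(chartr("T", "U", toupper(site)), "")[[1]]
  stopifnot(length(m) == length(s))
  L <- length(m)
  wc <- c(A = "U", U = "A", G = "C", C = "G")
  total <- 0
  for (i in seq_len(L)) {
    sb <- s[L - i + 1]
    pen <- if (!m[i] %in% names(wc) || !sb %in% c("A", "C", "G", "U")) {
      mismatch
    } else if (wc[[m[i]]] == sb) {
      0
    } else if ((m[i] == "G" && sb == "U") || (m[i] == "U" && sb == "G")) {
      wobble
    } else {
      mismatch
    }
    w <- if (i >= seed_start && i <= seed_end) seed_multiplier else 1
    total <- total + w * pen
  }
  total
}

# Exhaustive window enumeration over both strands of one contig; returns
# every window with its expectation (no cutoff, no collapsing).
ref_scan <- function(mirna, contig_seq, ...) {
  g <- toupper(contig_seq)
  L <- nchar(mirna)
  G <- nchar(g)
  if (G < L) return(data.frame(start0 = integer(), strand = character(), e = numeric()))
  starts <- 0:(G - L)
  e_plus <- vapply(starts, function(s0) {
    ref_score(mirna, substr(g, s0 + 1, s0 + L), ...)
  }, numeric(1))
  e_minus <- vapply(starts, function(s0) {
    ref_score(mirna, ref_revcomp(substr(g, s0 + 1, s0 + L)), ...)
  }, numeric(1))
  out <- rbind(
    data.frame(start0 = starts, strand = "+", e = e_plus, stringsAsFactors = FALSE),
    data.frame(start0 = starts, strand = "-", e = e_minus, stringsAsFactors = FALSE)
  )
  out[order(out$start0, out$strand), , drop = FALSE]
}

# Independent collapse of overlapping same-strand windows: chain windows
# whose starts are closer than L, keep the min-expectation one (ties ->
# smaller start).
ref_collapse <- function(df, L) {
  out <- list()
  for (st in unique(df$strand)) {
    sub <- df[df$strand == st, , drop = FALSE]
    sub <- sub[order(sub$start0), , drop = FALSE]
    i <- 1
    while (i <= nrow(sub)) {
      j <- i
      while (j < nrow(sub) && sub$start0[j + 1] - sub$start0[j] < L) j <- j + 1
      block <- sub[i:j, , drop = FALSE]
      best <- block[order(block$e, block$start0), , drop = FALSE][1, ]
      out[[length(out) + 1]] <- best
      i <- j + 1
    }
  }
  do.call(rbind, out)
}

# Exact hypergeometric upper tail P(X >= k) by direct pmf enumeration with
# choose(); exact in double precision for N <= 30.
ref_hyper_upper <- function(N, m, n, k) {
  j <- max(0, k):min(m, n)
  sum(choose(m, j) * choose(N - m, n - j)) / choose(N, n)
}

toy_count_table <- function() {
  counts <- matrix(
    c(12L, 15L, 10L, 0L, 1L, 0L,   # miR-A: called under (10, 1)
      12L, 9L, 30L, 0L, 0L, 0L,    # miR-B: one target sample below 10
      50L, 50L, 50L, 1L, 1L, 0L),  # miR-C: bulk total 2
    nrow = 3, byrow = TRUE,
    dimnames = list(c("miR-A", "miR-B", "miR-C"),
                    c("R1", "R2", "R3", "B1", "B2", "B3"))
  )
  count_table(counts, stats::setNames(rep(c("target", "bulk"), each = 3),
                                      colnames(counts)))
}
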