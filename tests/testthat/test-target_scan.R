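test_that("a planted perfect site is recovered as exactly one + strand hit", {
  g <- make_genome(500, seed = 21)
  m <- random_mirna(seed = 22)
  ps <- plant_sites(g, m, list(list(position = 100, strand = "+", mutate = integer(0))))
  hits <- scan_genome(mirna_catalog(c(mirX = m)), ps$genome)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start0, 100L)
  expect_equal(hits$end0, 121L)
  expect_equal(hits$strand, "+")
  expect_identical(hits$expectation, 0)
  expect_identical(hits$pairing_string, strrep("|", 21))
})

test_that("a site equal to the miRNA itself is reported on the - strand", {
  g <- make_genome(500, seed = 23)
  m <- random_mirna(seed = 24)
  chars <- strsplit(g[[1]], "")[[1]]
  chars[101:121] <- strsplit(chartr("U", "T", m), "")[[1]]
  g2 <- stats::setNames(paste(chars, collapse = ""), names(g))
  hits <- scan_genome(mirna_catalog(c(mirX = m)), g2)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start0, 100L)
  expect_equal(hits$strand, "-")
  expect_identical(hits$expectation, 0)
})

test_that("scan agrees with exhaustive brute-force enumeration on random instances", {
  withr::with_seed(501, {
    for (rep in 1:8) {
      g <- make_genome(sample(150:400, 1), seed = sample.int(1e6, 1))
      m <- random_mirna()
      cutoff <- sample(c(8, 12, 16), 1)  # high cutoffs so random windows pass
      p <- scoring_params(max_expectation = cutoff)
      got <- scan_genome(mirna_catalog(c(m1 = m)), g, p, collapse = FALSE)
      ref <- ref_scan(m, g[[1]])
      ref <- ref[ref$e <= cutoff, , drop = FALSE]
      ref <- ref[order(ref$start0, ref$strand), , drop = FALSE]
      expect_equal(nrow(got), nrow(ref))
      expect_equal(got$start0, ref$start0)
      expect_equal(got$strand, ref$strand)
      expect_equal(got$expectation, ref$e)
    }
  })
})

test_that("reverse-complementing the genome mirrors hits with mapped coordinates", {
  g <- make_genome(400, seed = 31)
  m <- random_mirna(seed = 32)
  ps <- plant_sites(g, m, list(list(position = 50, strand = "+", mutate = 5L),
                               list(position = 200, strand = "-", mutate = integer(0))))
  p <- scoring_params(max_expectation = 14)
  fwd <- scan_genome(mirna_catalog(c(m1 = m)), ps$genome, p, collapse = FALSE)
  G <- nchar(ps$genome[[1]])
  rc <- stats::setNames(ref_revcomp(chartr("U", "T", ps$genome[[1]])), names(g))
  rev <- scan_genome(mirna_catalog(c(m1 = m)), rc, p, collapse = FALSE)
  mapped <- data.frame(start0 = G - rev$end0,
                       strand = ifelse(rev$strand == "+", "-", "+"),
                       expectation = rev$expectation, stringsAsFactors = FALSE)
  mapped <- mapped[order(mapped$start0, mapped$strand), , drop = FALSE]
  fwd_key <- fwd[order(fwd$start0, fwd$strand), c("start0", "strand", "expectation")]
  rownames(mapped) <- rownames(fwd_key) <- NULL
  expect_equal(fwd_key, mapped)
})

test_that("raising the cutoff only adds hits; lowering it only removes them", {
  g <- make_genome(800, seed = 41)
  m <- random_mirna(seed = 42)
  key <- function(h) paste(h$start0, h$strand)
  prev <- character(0)
  for (cutoff in c(6, 10, 14, 18)) {
    h <- scan_genome(mirna_catalog(c(m1 = m)), g,
                     scoring_params(max_expectation = cutoff), collapse = FALSE)
    expect_true(all(prev %in% key(h)))
    expect_true(all(h$expectation <= cutoff))
    prev <- key(h)
  }
})

test_that("overlapping same-miRNA same-strand hits collapse to the best window", {
  g <- make_genome(2000, seed = 51)
  m <- random_mirna(seed = 52)
  p <- scoring_params(max_expectation = 16)
  full <- scan_genome(mirna_catalog(c(m1 = m)), g, p, collapse = FALSE)
  got <- scan_genome(mirna_catalog(c(m1 = m)), g, p, collapse = TRUE)
  ref <- ref_collapse(data.frame(start0 = full$start0, strand = full$strand,
                                 e = full$expectation), L = 21L)
  ref <- ref[order(ref$start0, ref$strand), , drop = FALSE]
  expect_equal(got$start0, ref$start0)
  expect_equal(got$strand, ref$strand)
  expect_equal(got$expectation, ref$e)
  expect_lte(nrow(got), nrow(full))
})

test_that("contigs shorter than the miRNA are skipped with a warning", {
  m <- random_mirna(seed = 61)
  genome <- c(short = "ACGT", long = make_genome(100, seed = 62)[[1]])
  expect_warning(hits <- scan_genome(mirna_catalog(c(m1 = m)), genome), "skipped")
  expect_true(all(hits$contig == "long"))
})

test_that("scan_genome refuses an empty miRNA set", {
  g <- make_genome(100, seed = 63)
  expect_error(scan_genome(mirna_catalog(character(0)), g),
               class = "rhizomir_contract_error")
})

test_that("scan_summary totals match the hit collection", {
  empty <- scan_summary(rhizomir:::empty_hits())
  expect_equal(empty$total, 0L)
  expect_equal(nrow(empty$per_mirna), 0L)

  hits <- rhizomir:::empty_hits()
  for (i in 1:3) hits[i, ] <- list("m1", "c1", 10L * i, 10L * i + 21L, "+", 1,
                                   strrep("|", 21), NA, NA, NA)
  for (i in 4:5) hits[i, ] <- list("m2", "c2", 10L * i, 10L * i + 21L, "-", 1,
                                   strrep("|", 21), NA, NA, NA)
  s <- scan_summary(hits)
  expect_equal(s$total, 5L)
  expect_equal(s$per_mirna$n_hits[s$per_mirna$mirna == "m1"], 3L)
  expect_equal(s$per_mirna$n_hits[s$per_mirna$mirna == "m2"], 2L)
  expect_equal(sum(s$per_contig$n_hits), 5L)
})

test_that("scan is deterministic: identical inputs give identical output files", {
  g <- make_genome(600, seed = 71)
  m <- random_mirna(seed = 72)
  p <- scoring_params(max_expectation = 12)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_hits(scan_genome(mirna_catalog(c(m1 = m)), g, p), f1)
  write_hits(scan_genome(mirna_catalog(c(m1 = m)), g, p), f2)
  expect_identical(readLines(f1), readLines(f2))
})
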