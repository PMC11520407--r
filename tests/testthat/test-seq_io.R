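test_that("read_fasta normalizes case and alphabet", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">m1", "acgu"), fa)
  expect_equal(read_fasta(fa, "rna"), c(m1 = "ACGU"))

  writeLines(c(">m1", "ACGT"), fa)
  expect_equal(read_fasta(fa, "rna"), c(m1 = "ACGU"))
  expect_equal(read_fasta(fa, "dna"), c(m1 = "ACGT"))

  writeLines(c(">g1", "ACGT", ">g1", "AAAA"), fa)
  expect_error(read_fasta(fa, "dna"), "duplicate", class = "rhizomir_format_error")

  writeLines(c(">g1", "ACGN"), fa)
  expect_warning(read_fasta(fa, "dna"), "ambiguity")

  writeLines(c(">g1", "ACGX"), fa)
  expect_error(suppressWarnings(read_fasta(fa, "dna")), "illegal",
               class = "rhizomir_format_error")
})

test_that("mirna_catalog enforces length, alphabet and name uniqueness", {
  expect_s3_class(mirna_catalog(c(m1 = "ACGUACGUACGUACGUACGUA")), "mirna_catalog")
  expect_error(mirna_catalog(c(m1 = "ACGU")), "length", class = "rhizomir_contract_error")
  expect_error(mirna_catalog(stats::setNames(rep("ACGUACGUACGUACGUA", 2), c("a", "a"))),
               "duplicate", class = "rhizomir_contract_error")
  # T on input becomes U
  expect_equal(mirna_catalog(c(m1 = "ACGTACGTACGTACGTA"))$sequence, "ACGUACGUACGUACGUA")
})

test_that("read_gff_cds converts 1-based inclusive to 0-based half-open", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\t.\tCDS\t11\t40\t.\t+\t0\tlocus_tag=LT1",
               "c1\t.\tCDS\t61\t90\t.\t-\t0\tID=cds2"), gff)
  cds <- read_gff_cds(gff)
  expect_equal(cds$start, c(10L, 60L))
  expect_equal(cds$end, c(40L, 90L))
  expect_equal(cds$end - cds$start, c(30L, 30L))  # length preserved
  expect_equal(cds$strand, c("+", "-"))
  expect_equal(cds$locus_tag, c("LT1", "cds2"))  # ID fallback
})

test_that("read_gff_cds warns and returns empty when no CDS present", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "c1\t.\tgene\t11\t40\t.\t+\t.\tID=g1"), gff)
  expect_warning(cds <- read_gff_cds(gff), "no CDS")
  expect_equal(nrow(cds), 0L)
})

test_that("GFF round-trip through write_gff_cds is lossless", {
  g <- make_genome(8000, seed = 11)
  cds <- make_gff(g, 4, seed = 2)
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff_cds(cds, path)
  back <- read_gff_cds(path)
  expect_equal(back, cds)
})

test_that("read_count_table validates cells and group coverage", {
  counts <- withr::local_tempfile(fileext = ".tsv")
  groups <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna\tR1\tR2\tB1", "m1\t5\t6\t0", "m2\t1\t0\t2"), counts)
  writeLines(c("sample\tgroup", "R1\ttarget", "R2\ttarget", "B1\tbulk"), groups)
  ct <- read_count_table(counts, groups)
  expect_s3_class(ct, "count_table")
  expect_equal(dim(ct$counts), c(2L, 3L))
  expect_equal(unname(ct$groups), c("target", "target", "bulk"))

  writeLines(c("mirna\tR1\tR2\tB1", "m1\t3.5\t6\t0"), counts)
  expect_error(read_count_table(counts, groups), "non-integer",
               class = "rhizomir_format_error")

  writeLines(c("mirna\tR1\tR4\tB1", "m1\t5\t6\t0"), counts)
  expect_error(read_count_table(counts, groups), "R4",
               class = "rhizomir_config_error")
})

test_that("hit tables round-trip through TSV exactly", {
  g <- make_genome(600, seed = 5)
  m <- random_mirna(seed = 6)
  ps <- plant_sites(g, m, list(list(position = 100, strand = "+", mutate = c(1L, 20L)),
                               list(position = 300, strand = "-", mutate = integer(0))))
  hits <- scan_genome(mirna_catalog(c(mirX = m)), ps$genome)
  cds <- data.frame(contig = "contig1", start = 80L, end = 200L, strand = "+",
                    locus_tag = "LT0001", stringsAsFactors = FALSE)
  ann <- annotate_hits(hits, cds)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits(ann, path)
  back <- read_hits(path)
  for (col in c("mirna", "contig", "start0", "end0", "strand", "expectation",
                "pairing_string", "nearest_locus_tag", "cds_distance", "cds_relation")) {
    expect_equal(back[[col]], ann[[col]], info = col)
  }
})

test_that("BED export normalizes scores and an empty hit set writes a header-only TSV", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_hits(rhizomir:::empty_hits(), tsv)
  expect_equal(length(readLines(tsv)), 1L)

  hits <- rhizomir:::empty_hits()
  hits[1L, ] <- list("mirX", "c1", 100L, 121L, "-", 0, strrep("|", 21),
                     NA_character_, NA_integer_, NA_character_)
  bed <- withr::local_tempfile(fileext = ".bed")
  write_hits(hits, bed, "bed")
  expect_equal(readLines(bed), "c1\t100\t121\tmirX\t1000\t-")
})

test_that("hit output is sorted by contig then start", {
  hits <- rhizomir:::empty_hits()
  hits[1L, ] <- list("m", "c2", 10L, 31L, "+", 1, strrep("x", 21), NA, NA, NA)
  hits[2L, ] <- list("m", "c1", 50L, 71L, "+", 1, strrep("x", 21), NA, NA, NA)
  hits[3L, ] <- list("m", "c1", 5L, 26L, "+", 1, strrep("x", 21), NA, NA, NA)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_hits(hits, path)
  back <- read_hits(path)
  expect_equal(back$contig, c("c1", "c1", "c2"))
  expect_equal(back$start0, c(5L, 50L, 10L))
})
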