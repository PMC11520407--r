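#' Read a FASTA file with alphabet normalization
#'
#' Reads sequence records through [Biostrings::readBStringSet()] and
#' normalizes them to a single internal alphabet: upper case, with `T`
#' mapped to `U` for `alphabet = "rna"` and `U` mapped to `T` for
#' `alphabet = "dna"`. Identifiers are the first whitespace-delimited token
#' of each header and must be unique. IUPAC ambiguity codes other than
#' `A/C/G/T/U` are preserved but flagged with a warning (downstream scoring
#' treats them as never pairing).
#'
#' @param path path to a FASTA file (plain or gzip).
#' @param alphabet `"dna"` (genomes) or `"rna"` (mature miRNA catalogs).
#' @return named character vector of sequences.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">m1", "acgt"), fa)
#' read_fasta(fa, "rna")   # "ACGU"
#' @export
read_fasta <- function(path, alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop_format("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop_format("malformed FASTA '", path, "': ", conditionMessage(e))
  )
  if (length(set) == 0L) stop_format("FASTA '", path, "' contains no records")
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  if (any(ids == "")) stop_format("FASTA '", path, "' has an empty header")
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop_format("duplicate sequence identifier(s) in '", path, "': ",
                paste(unique(dup), collapse = ", "))
  }
  seqs <- norm_alphabet(as.character(set), alphabet)
  if (any(nchar(seqs) == 0L)) {
    stop_format("empty sequence for record '", ids[which(nchar(seqs) == 0L)[1L]], "'")
  }
  core <- if (alphabet == "rna") "ACGU" else "ACGT"
  allowed <- c(strsplit(core, "")[[1]], .IUPAC_EXTRA)
  for (k in seq_along(seqs)) {
    chars <- unique(strsplit(seqs[[k]], "", fixed = TRUE)[[1]])
    bad <- setdiff(chars, allowed)
    if (length(bad)) {
      stop_format("illegal character(s) ", paste(bad, collapse = ""),
                  " in record '", ids[k], "' for ", alphabet, " alphabet")
    }
    amb <- setdiff(chars, strsplit(core, "")[[1]])
    if (length(amb)) {
      warning("record '", ids[k], "' contains IUPAC ambiguity code(s): ",
              paste(amb, collapse = ""), call. = FALSE)
    }
  }
  names(seqs) <- ids
  seqs
}

#' Validate a mature-miRNA catalog
#'
#' A catalog is a named set of mature miRNA sequences in the RNA alphabet.
#' Sequences must be 15-30 nt, strictly over `{A,C,G,U}`, with unique names.
#'
#' @param sequences named character vector (RNA alphabet; `T` is accepted and
#'   mapped to `U`).
#' @return a `data.frame` with columns `name` and `sequence`, classed
#'   `mirna_catalog`.
#' @export
mirna_catalog <- function(sequences) {
  if (is.null(names(sequences)) || any(names(sequences) == "")) {
    stop_contract("miRNA catalog sequences must be named")
  }
  if (anyDuplicated(names(sequences))) {
    stop_contract("duplicate miRNA name(s): ",
                  paste(unique(names(sequences)[duplicated(names(sequences))]), collapse = ", "))
  }
  seqs <- norm_alphabet(sequences, "rna")
  len <- nchar(seqs)
  if (any(len < 15L | len > 30L)) {
    stop_contract("miRNA length out of range 15-30 nt: ",
                  paste(names(seqs)[len < 15L | len > 30L], collapse = ", "))
  }
  if (any(grepl("[^ACGU]", seqs))) {
    stop_contract("miRNA sequences must be strictly A/C/G/U: ",
                  paste(names(seqs)[grepl("[^ACGU]", seqs)], collapse = ", "))
  }
  structure(
    data.frame(name = names(seqs), sequence = unname(seqs), stringsAsFactors = FALSE),
    class = c("mirna_catalog", "data.frame")
  )
}

#' Read a mature-miRNA catalog from FASTA
#'
#' @param path FASTA path.
#' @return a [mirna_catalog] data frame.
#' @export
read_mirna_fasta <- function(path) {
  mirna_catalog(read_fasta(path, "rna"))
}

#' Read CDS features from a GFF3 file
#'
#' Imports the annotation with [rtracklayer::import()], keeps features of
#' type `CDS`, and converts GFF 1-based inclusive coordinates to the
#' package-internal 0-based half-open convention. `locus_tag` is the
#' preferred identifier, with `ID` as fallback.
#'
#' @param path GFF3 path.
#' @return data.frame with columns `contig`, `start` (0-based inclusive),
#'   `end` (0-based exclusive), `strand`, `locus_tag`, sorted by
#'   `(contig, start)`.
#' @export
read_gff_cds <- function(path) {
  if (!file.exists(path)) stop_format("GFF3 file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop_format("malformed GFF3 '", path, "': ", conditionMessage(e))
  )
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "CDS"]
  if (length(gr) == 0L) {
    warning("no CDS features found in '", path, "'", call. = FALSE)
    return(empty_cds())
  }
  lt <- if ("locus_tag" %in% names(S4Vectors::mcols(gr))) as.character(gr$locus_tag) else rep(NA_character_, length(gr))
  id <- if ("ID" %in% names(S4Vectors::mcols(gr))) as.character(gr$ID) else rep(NA_character_, length(gr))
  tag <- ifelse(is.na(lt) | lt == "", id, lt)
  if (any(is.na(tag) | tag == "")) {
    stop_format("CDS record(s) ", paste(which(is.na(tag) | tag == ""), collapse = ", "),
                " in '", path, "' lack both locus_tag and ID")
  }
  out <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    locus_tag = tag,
    stringsAsFactors = FALSE
  )
  out$strand[!out$strand %in% c("+", "-")] <- "+"
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_cds <- function() {
  data.frame(contig = character(), start = integer(), end = integer(),
             strand = character(), locus_tag = character(), stringsAsFactors = FALSE)
}

#' Construct and validate a miRNA-by-sample count table
#'
#' @param counts integer matrix, miRNAs in rows, samples in columns; both
#'   dimensions named.
#' @param groups named character vector mapping every sample to `"target"`
#'   or `"bulk"`.
#' @return object of class `count_table`: a list with elements `counts`
#'   and `groups`.
#' @export
count_table <- function(counts, groups) {
  if (!is.matrix(counts) || is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_contract("counts must be a matrix with miRNA rownames and sample colnames")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_format("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  missing <- setdiff(colnames(counts), names(groups))
  if (length(missing)) {
    stop_config("sample(s) missing from the group map: ", paste(missing, collapse = ", "))
  }
  groups <- groups[colnames(counts)]
  if (!all(groups %in% c("target", "bulk"))) {
    stop_config("groups must be 'target' or 'bulk'; got: ",
                paste(unique(groups[!groups %in% c("target", "bulk")]), collapse = ", "))
  }
  structure(list(counts = counts, groups = groups), class = "count_table")
}

#' @export
print.count_table <- function(x, ...) {
  cat("miRNA count table: ", nrow(x$counts), " miRNAs x ", ncol(x$counts), " samples (",
      sum(x$groups == "target"), " target, ", sum(x$groups == "bulk"), " bulk)\n", sep = "")
  invisible(x)
}

#' Read a count table and its sample-group map from TSV
#'
#' The counts TSV has a header row of sample names and a first column of
#' miRNA names; the groups TSV has two columns, `sample` and `group`
#' (`target` or `bulk`).
#'
#' @param path counts TSV path.
#' @param groups_path groups TSV path.
#' @return a [count_table] object.
#' @export
read_count_table <- function(path, groups_path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop_format("count table '", path, "' needs a miRNA column plus >=1 sample")
  mirnas <- as.character(raw[[1L]])
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow = nrow(mat), dimnames = dimnames(mat)))
  if (any(is.na(num)) || any(num != round(num)) || any(num < 0)) {
    bad <- which(is.na(num) | num != round(num) | num < 0, arr.ind = TRUE)[1L, ]
    stop_format("non-integer count '", mat[bad[1L], bad[2L]], "' at miRNA '",
                mirnas[bad[1L]], "', sample '", colnames(mat)[bad[2L]], "'")
  }
  rownames(num) <- mirnas
  g <- utils::read.delim(groups_path, stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(g))) {
    stop_format("groups file '", groups_path, "' must have columns 'sample' and 'group'")
  }
  count_table(num, stats::setNames(g$group, g$sample))
}

.HIT_COLUMNS <- c("mirna", "contig", "start0", "end0", "strand", "expectation",
                  "pairing_string", "nearest_locus_tag", "cds_distance", "cds_relation")

#' Write target hits to TSV or BED6
#'
#' TSV output carries the full hit record (expectation serialized with fixed
#' 4-decimal precision); BED6 scores are `round(1000 * (1 - E/max_expectation))`
#' so that a perfect duplex (E = 0) scores 1000. Rows are stably sorted by
#' `(contig, start, mirna)`.
#'
#' @param hits hit data frame from [scan_genome()] / [annotate_hits()].
#' @param path output path.
#' @param format `"tsv"` or `"bed"`.
#' @param max_expectation expectation cutoff used for BED score scaling.
#' @export
write_hits <- function(hits, path, format = c("tsv", "bed"), max_expectation = 3) {
  format <- match.arg(format)
  hits <- as_hits(hits)
  ord <- order(hits$contig, hits$start0, hits$mirna)
  hits <- hits[ord, , drop = FALSE]
  con <- tryCatch(file(path, "w"), error = function(e) stop_format("cannot write '", path, "'"))
  on.exit(close(con))
  if (format == "tsv") {
    writeLines(paste(.HIT_COLUMNS, collapse = "\t"), con)
    if (nrow(hits)) {
      out <- hits[, .HIT_COLUMNS]
      out$expectation <- sprintf("%.4f", out$expectation)
      utils::write.table(out, con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE, na = "NA")
    }
  } else {
    if (nrow(hits)) {
      score <- as.integer(round(1000 * (1 - hits$expectation / max_expectation)))
      bed <- data.frame(hits$contig, hits$start0, hits$end0, hits$mirna, score, hits$strand)
      utils::write.table(bed, con, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(path)
}

#' Read a hit TSV written by [write_hits()]
#'
#' @param path TSV path.
#' @return hit data frame.
#' @export
read_hits <- function(path) {
  first <- readLines(path, n = 50L)
  skip <- sum(cumprod(startsWith(first, "#")))
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA", skip = skip,
                          colClasses = c(mirna = "character", contig = "character",
                                         start0 = "integer", end0 = "integer",
                                         strand = "character", expectation = "numeric",
                                         pairing_string = "character",
                                         nearest_locus_tag = "character",
                                         cds_distance = "integer", cds_relation = "character"))
  as_hits(df)
}

# Coerce/validate the hit-table contract.
as_hits <- function(hits) {
  if (!is.data.frame(hits)) stop_contract("hits must be a data frame")
  miss <- setdiff(.HIT_COLUMNS, names(hits))
  if (length(miss)) stop_contract("hit table missing column(s): ", paste(miss, collapse = ", "))
  hits
}

empty_hits <- function() {
  data.frame(mirna = character(), contig = character(), start0 = integer(),
             end0 = integer(), strand = character(), expectation = numeric(),
             pairing_string = character(), nearest_locus_tag = character(),
             cds_distance = integer(), cds_relation = character(),
             stringsAsFactors = FALSE)
}
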