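# Compartment-specific miRNA calling from small RNA-seq counts.
#
# A miRNA is compartment-specific when it is consistently present in every
# sample of the compartment of interest (rhizosphere, root, or the
# rhizosphere-bacterial fraction) while essentially absent from bulk-soil
# controls, where singletons are treated as sequencing artifacts. Two
# presets encode the published thresholds: rhizosphere/root requires >= 10
# reads in each target sample with at most 1 read summed over all bulk
# samples; the bacterial fraction, sequenced at lower depth, requires >= 5
# reads per target sample with total absence from bulk.

#' Calling rule for compartment-specific miRNAs
#'
#' @param min_reads_per_target_sample minimum count required in every
#'   target-compartment sample.
#' @param max_total_bulk_reads maximum count summed over all bulk samples.
#' @return list of class `call_rule`.
#' @export
call_rule <- function(min_reads_per_target_sample, max_total_bulk_reads) {
  if (min_reads_per_target_sample < 1L) stop_contract("min_reads_per_target_sample must be >= 1")
  if (max_total_bulk_reads < 0L) stop_contract("max_total_bulk_reads must be >= 0")
  structure(list(min_reads_per_target_sample = as.integer(min_reads_per_target_sample),
                 max_total_bulk_reads = as.integer(max_total_bulk_reads)),
            class = "call_rule")
}

#' Preset calling rules
#'
#' `"rhizosphere"` and `"root"` use (10, 1): at least 10 reads in each
#' target sample and at most one read in total across bulk-soil samples.
#' `"bacterial"` (the rhizosphere-bacterial fraction) uses (5, 0).
#'
#' @param preset one of `"rhizosphere"`, `"root"`, `"bacterial"`.
#' @return a [call_rule()].
#' @export
preset_rule <- function(preset = c("rhizosphere", "root", "bacterial")) {
  preset <- match.arg(preset)
  switch(preset,
         rhizosphere = call_rule(10L, 1L),
         root = call_rule(10L, 1L),
         bacterial = call_rule(5L, 0L))
}

#' Filter reads by length
#'
#' Retains sequences whose length is within `[min_len, max_len]`, inclusive
#' on both ends (default 18-27 nt, the size range kept for miRNA
#' profiling). Input order is preserved.
#'
#' @param reads character vector of read sequences.
#' @param min_len,max_len inclusive length bounds.
#' @return filtered character vector.
#' @export
filter_reads_by_length <- function(reads, min_len = 18L, max_len = 27L) {
  if (min_len < 0L || max_len < 0L) stop_contract("length bounds must be non-negative")
  if (min_len > max_len) stop_contract("min_len must be <= max_len")
  len <- nchar(reads)
  reads[len >= min_len & len <= max_len]
}

#' Assign reads to a mature-miRNA catalog by exact matching
#'
#' A read increments a miRNA's count for its sample iff it equals the mature
#' sequence exactly (U and T are equivalent); all other reads are tallied as
#' unassigned. Catalog entries with identical sequences are merged into one
#' canonical row named by the lexicographically first name, with synonyms
#' recorded. With `max_mismatch = 1`, reads within Hamming distance 1 of a
#' unique catalog sequence of the same length are also assigned (off by
#' default; exact matching is the reference behaviour).
#'
#' @param reads named list of character vectors, one per sample.
#' @param catalog a [mirna_catalog] data frame or named character vector.
#' @param groups optional named character vector mapping samples to
#'   `"target"`/`"bulk"`; when given, a [count_table] is returned.
#' @param max_mismatch 0 (exact, default) or 1.
#' @return when `groups` is `NULL`, a list with `counts` (matrix),
#'   `unassigned` (per-sample tally) and `synonyms`; otherwise a
#'   [count_table] with those two extras as attributes.
#' @export
assign_to_catalog <- function(reads, catalog, groups = NULL, max_mismatch = 0L) {
  if (!inherits(catalog, "mirna_catalog")) catalog <- mirna_catalog(catalog)
  if (nrow(catalog) == 0L) stop_contract("catalog is empty")
  if (!is.list(reads) || is.null(names(reads))) {
    stop_contract("reads must be a named list of per-sample sequence vectors")
  }
  if (!max_mismatch %in% c(0L, 1L)) stop_contract("max_mismatch must be 0 or 1")
  cat_dna <- mirna_as_dna(catalog$sequence)
  # merge identical sequences under the lexicographically first name
  canon <- vapply(split(catalog$name, cat_dna), function(nm) sort(nm)[1L], character(1))
  synonyms <- split(catalog$name, cat_dna)
  names(synonyms) <- canon[names(synonyms)]
  uniq_seq <- names(canon)
  uniq_name <- unname(canon)
  ord <- order(uniq_name)
  uniq_seq <- uniq_seq[ord]; uniq_name <- uniq_name[ord]

  counts <- matrix(0L, nrow = length(uniq_name), ncol = length(reads),
                   dimnames = list(uniq_name, names(reads)))
  unassigned <- stats::setNames(integer(length(reads)), names(reads))
  for (s in names(reads)) {
    rd <- chartr("U", "T", toupper(reads[[s]]))
    idx <- match(rd, uniq_seq)
    if (max_mismatch == 1L && anyNA(idx)) {
      for (r in which(is.na(idx))) {
        cand <- which(nchar(uniq_seq) == nchar(rd[r]))
        if (!length(cand)) next
        hd <- vapply(uniq_seq[cand], function(cs) {
          sum(strsplit(cs, "")[[1]] != strsplit(rd[r], "")[[1]])
        }, integer(1))
        hit <- cand[hd <= 1L]
        if (length(hit) == 1L) idx[r] <- hit
      }
    }
    tab <- table(factor(idx[!is.na(idx)], levels = seq_along(uniq_name)))
    counts[, s] <- as.integer(tab)
    unassigned[[s]] <- sum(is.na(idx))
  }
  synonyms <- synonyms[uniq_name]
  if (is.null(groups)) {
    list(counts = counts, unassigned = unassigned, synonyms = synonyms)
  } else {
    ct <- count_table(counts, groups)
    attr(ct, "unassigned") <- unassigned
    attr(ct, "synonyms") <- synonyms
    ct
  }
}

#' Call compartment-specific miRNAs
#'
#' Applies a [call_rule()] to a [count_table]: a miRNA is called iff its
#' count is at least `min_reads_per_target_sample` in every target-group
#' sample and the sum of its counts over all bulk samples is at most
#' `max_total_bulk_reads`.
#'
#' @param table a [count_table].
#' @param rule a [call_rule()] or preset name accepted by [preset_rule()].
#' @return data.frame with one row per miRNA: `mirna`, `min_target_count`,
#'   `bulk_total`, `called`; the called set is `subset(out, called)$mirna`.
#' @export
call_compartment_mirnas <- function(table, rule = preset_rule("rhizosphere")) {
  if (!inherits(table, "count_table")) stop_contract("table must be a count_table")
  if (is.character(rule)) rule <- preset_rule(rule)
  tgt <- table$counts[, table$groups == "target", drop = FALSE]
  blk <- table$counts[, table$groups == "bulk", drop = FALSE]
  if (ncol(tgt) == 0L || ncol(blk) == 0L) {
    stop_config("count table needs at least one target and one bulk sample")
  }
  min_target <- apply(tgt, 1L, min)
  bulk_total <- rowSums(blk)
  data.frame(
    mirna = rownames(table$counts),
    min_target_count = as.integer(min_target),
    bulk_total = as.integer(bulk_total),
    called = min_target >= rule$min_reads_per_target_sample &
      bulk_total <= rule$max_total_bulk_reads,
    stringsAsFactors = FALSE, row.names = NULL
  )
}
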