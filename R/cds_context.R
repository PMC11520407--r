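# Nearest-CDS annotation and the "too far from any coding sequence" filter.
#
# Distance is boundary-to-boundary on the contig (0 if the hit interval
# overlaps the CDS interval), with no operon or transcription-unit
# inference. Orientation (upstream/downstream) is taken relative to the
# CDS's own strand: upstream means 5' of the CDS start.

#' Annotate target hits with their nearest CDS
#'
#' Each hit gains `nearest_locus_tag`, `cds_distance` (0 when the hit
#' overlaps the CDS, otherwise the nucleotide gap to the nearest CDS
#' boundary on the same contig), `cds_relation` (`inside`, `upstream`,
#' `downstream`, or `none` for contigs without CDS) and `cds_strand` (the
#' nearest CDS's strand, used by the sense filter). Ties in distance are
#' broken by the leftmost CDS.
#'
#' @param hits hit data frame from [scan_genome()].
#' @param cds CDS data frame from [read_gff_cds()] or [make_gff()].
#' @return annotated hit data frame.
#' @export
annotate_hits <- function(hits, cds) {
  hits <- as_hits(hits)
  if (nrow(hits) == 0L) {
    hits$cds_strand <- character(0)
    return(hits)
  }
  if (nrow(cds) > 0L && !any(hits$contig %in% cds$contig)) {
    warning("no hit contig is present in the CDS annotation", call. = FALSE)
  }
  hits$cds_strand <- NA_character_
  for (j in seq_len(nrow(hits))) {
    feats <- cds[cds$contig == hits$contig[j], , drop = FALSE]
    if (nrow(feats) == 0L) {
      hits$nearest_locus_tag[j] <- NA_character_
      hits$cds_distance[j] <- NA_integer_
      hits$cds_relation[j] <- "none"
      next
    }
    h0 <- hits$start0[j]; h1 <- hits$end0[j]
    # gap is 0 when the half-open intervals overlap
    dist <- pmax(0L, pmax(feats$start - h1, h0 - feats$end))
    best <- which(dist == min(dist))
    best <- best[order(feats$start[best])][1L]
    f <- feats[best, ]
    hits$nearest_locus_tag[j] <- f$locus_tag
    hits$cds_distance[j] <- dist[best]
    hits$cds_strand[j] <- f$strand
    hits$cds_relation[j] <- if (dist[best] == 0L) {
      "inside"
    } else if (h1 <= f$start) {
      if (f$strand == "+") "upstream" else "downstream"
    } else {
      if (f$strand == "+") "downstream" else "upstream"
    }
  }
  hits
}

#' Filter annotated hits by distance to the nearest CDS
#'
#' Splits an annotated hit collection into the hits retained as plausibly
#' gene-associated (within `max_distance` nt of a CDS) and the hits removed
#' as too far from any coding sequence. The two parts always partition the
#' input.
#'
#' @param hits annotated hit data frame (see [annotate_hits()]).
#' @param max_distance maximum allowed distance to the nearest CDS, in nt
#'   (default 200; 0 retains only hits inside a CDS).
#' @param require_sense additionally require the hit strand to equal the
#'   nearest CDS strand (default `FALSE`).
#' @return list with elements `retained` and `removed`.
#' @export
filter_by_cds_distance <- function(hits, max_distance = 200L, require_sense = FALSE) {
  hits <- as_hits(hits)
  if (max_distance < 0) stop_contract("max_distance must be non-negative")
  if (nrow(hits) > 0L && all(is.na(hits$cds_relation))) {
    stop_contract("hits are not annotated; run annotate_hits() first")
  }
  ok <- !is.na(hits$cds_distance) & hits$cds_relation != "none" &
    hits$cds_distance <= max_distance
  if (require_sense) {
    if (!"cds_strand" %in% names(hits)) {
      stop_contract("hits lack cds_strand; run annotate_hits() first")
    }
    ok <- ok & !is.na(hits$cds_strand) & hits$strand == hits$cds_strand
  }
  list(retained = hits[ok, , drop = FALSE],
       removed = hits[!ok, , drop = FALSE])
}
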