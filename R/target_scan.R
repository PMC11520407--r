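# Exhaustive sliding-window target scan over both strands of a genome.
#
# Every window of miRNA length on every contig is scored on both strands
# (the "+" hit strand means the + strand sequence is the target-sense site;
# "-" means its reverse complement is). Window enumeration is exhaustive --
# no k-mer seeding -- so the scan is an exact reference: a window appears in
# the output iff its expectation is <= the cutoff.

#' Scan a genome for miRNA target sites
#'
#' Slides each miRNA over both strands of every contig, scores every window
#' with [score_duplex()] semantics, and emits the windows whose expectation
#' is at or below `params$max_expectation`. Overlapping hits of the same
#' miRNA on the same strand within one window length are collapsed to the
#' single lowest-expectation hit (ties broken by smaller start) when
#' `collapse = TRUE`.
#'
#' @param mirnas a [mirna_catalog] data frame or named character vector of
#'   mature miRNA sequences (RNA alphabet).
#' @param genome named character vector of contig sequences (DNA alphabet),
#'   e.g. from [read_fasta()].
#' @param params a [scoring_params()] list.
#' @param collapse collapse overlapping same-miRNA, same-strand hits
#'   (default `TRUE`).
#' @return hit data frame with columns `mirna`, `contig`, `start0`, `end0`
#'   (0-based half-open), `strand`, `expectation`, `pairing_string`, plus
#'   `nearest_locus_tag`, `cds_distance`, `cds_relation` (all `NA` until
#'   [annotate_hits()] has run), sorted by `(contig, start0, strand, mirna)`.
#' @export
scan_genome <- function(mirnas, genome, params = scoring_params(), collapse = TRUE) {
  if (!inherits(mirnas, "mirna_catalog")) mirnas <- mirna_catalog(mirnas)
  if (nrow(mirnas) == 0L) stop_contract("no miRNAs supplied")
  if (length(genome) == 0L) stop_contract("genome is empty")
  if (is.null(names(genome))) stop_contract("genome contigs must be named")
  pen_matrix <- matrix(class_penalties(params)[.PAIR_CLASS + 1L], 5L, 5L)
  comp_map <- c(4L, 3L, 2L, 1L, 5L)

  rows <- vector("list", 0L)
  for (contig in names(genome)) {
    gseq <- norm_alphabet(genome[[contig]], "dna")
    g <- encode_dna(gseq)
    gc <- comp_map[g]
    G <- length(g)
    for (k in seq_len(nrow(mirnas))) {
      mname <- mirnas$name[k]
      mseq <- mirnas$sequence[k]
      m <- encode_dna(mirna_as_dna(mseq))
      L <- length(m)
      if (G < L) {
        warning("contig '", contig, "' (", G, " nt) shorter than miRNA '",
                mname, "' (", L, " nt); skipped", call. = FALSE)
        next
      }
      nw <- G - L + 1L
      w <- position_weights(L, params)
      e_plus <- numeric(nw)
      e_minus <- numeric(nw)
      for (i in seq_len(L)) {
        # + strand: miRNA pos i faces genome pos s + L - i (0-based window start s)
        e_plus <- e_plus + w[i] * pen_matrix[m[i], g][(L - i + 1L):(L - i + nw)]
        # - strand: miRNA pos i faces the complement of genome pos s + i - 1
        e_minus <- e_minus + w[i] * pen_matrix[m[i], gc][i:(i + nw - 1L)]
      }
      for (strand in c("+", "-")) {
        e <- if (strand == "+") e_plus else e_minus
        pass <- which(e <= params$max_expectation)
        if (!length(pass)) next
        site <- substring(gseq, pass, pass + L - 1L)
        if (strand == "-") site <- revcomp_dna(site)
        pairing <- vapply(site, function(s) score_duplex(mseq, s, params)$pairing_string,
                          character(1), USE.NAMES = FALSE)
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = mname, contig = contig,
          start0 = pass - 1L, end0 = pass - 1L + L,
          strand = strand, expectation = e[pass], pairing_string = pairing,
          nearest_locus_tag = NA_character_, cds_distance = NA_integer_,
          cds_relation = NA_character_, stringsAsFactors = FALSE
        )
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else empty_hits()
  if (collapse && nrow(hits)) hits <- collapse_hits(hits)
  hits <- hits[order(hits$contig, hits$start0, hits$strand, hits$mirna), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

# Collapse overlapping same-miRNA same-strand hits: windows whose starts are
# within one window length of the previous window in the chain form one
# cluster, represented by its lowest-expectation window (ties -> smaller
# start).
collapse_hits <- function(hits) {
  key <- paste(hits$mirna, hits$contig, hits$strand, sep = "\r")
  keep <- logical(nrow(hits))
  for (grp in split(seq_len(nrow(hits)), key)) {
    idx <- grp[order(hits$start0[grp])]
    L <- hits$end0[idx[1L]] - hits$start0[idx[1L]]
    cluster <- cumsum(c(1L, diff(hits$start0[idx]) >= L))
    for (cl in split(idx, cluster)) {
      best <- cl[order(hits$expectation[cl], hits$start0[cl])][1L]
      keep[best] <- TRUE
    }
  }
  hits[keep, , drop = FALSE]
}

#' Summarize a hit collection
#'
#' @param hits hit data frame.
#' @return list with `per_mirna` and `per_contig` count data frames and the
#'   grand `total`; the total always equals `nrow(hits)`.
#' @export
scan_summary <- function(hits) {
  hits <- as_hits(hits)
  if (nrow(hits) == 0L) {
    return(list(per_mirna = data.frame(mirna = character(), n_hits = integer()),
                per_contig = data.frame(contig = character(), n_hits = integer()),
                total = 0L))
  }
  per_mirna <- as.data.frame(table(mirna = hits$mirna), stringsAsFactors = FALSE)
  names(per_mirna) <- c("mirna", "n_hits")
  per_contig <- as.data.frame(table(contig = hits$contig), stringsAsFactors = FALSE)
  names(per_contig) <- c("contig", "n_hits")
  list(per_mirna = per_mirna[order(per_mirna$mirna), , drop = FALSE],
       per_contig = per_contig[order(per_contig$contig), , drop = FALSE],
       total = nrow(hits))
}
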