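# Seeded synthetic generators: random genomes, planted miRNA target sites
# with known expectations, non-overlapping CDS annotations, and
# compartmentalized count tables with bulk-soil singleton noise. These
# emulate the statistical structure the analysis assumes and provide exact
# ground truth for recovery tests.

#' Generate a random genome sequence
#'
#' Bases are i.i.d. with `P(G) = P(C) = gc/2` and `P(A) = P(T) = (1-gc)/2`.
#'
#' @param length sequence length in nt (>= 1).
#' @param gc GC fraction in `[0, 1]` (default 0.5).
#' @param seed integer RNG seed.
#' @param name contig identifier (default `"contig1"`).
#' @return named character vector of length 1 (a genome contig).
#' @export
make_genome <- function(length, gc = 0.5, seed = 1L, name = "contig1") {
  if (length < 1L) stop_contract("length must be >= 1")
  if (gc < 0 || gc > 1) stop_contract("gc must be in [0, 1]")
  seq <- withr::with_seed(seed, {
    paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                 prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
          collapse = "")
  })
  stats::setNames(seq, name)
}

# Site base that neither Watson-Crick pairs nor wobbles with the given
# miRNA base (DNA encoding, U stored as T).
.NONPAIR_BASE <- c(A = "C", C = "A", G = "A", T = "C")

#' Plant miRNA target sites into a genome with known expectations
#'
#' Writes target-sense sites for a miRNA into a genome at chosen positions
#' and strands. A site with no mutations is the exact complement of the
#' miRNA (expectation 0); each entry of `mutate` names a miRNA position
#' (1-based from the 5' end) whose facing site base is replaced by a base
#' that neither pairs nor wobbles, adding that position's weighted mismatch
#' penalty to the constructed expectation.
#'
#' @param genome named character vector of length 1 (one contig).
#' @param mirna miRNA sequence (RNA alphabet).
#' @param placements list of `list(position =, strand =, mutate =)` entries:
#'   0-based start position, `"+"`/`"-"`, and an integer vector (possibly
#'   empty) of miRNA positions to mutate. Placements must not overlap.
#' @param params a [scoring_params()]; determines the truth expectations.
#' @return list with `genome` (modified contig) and `truth` (data.frame
#'   `start0`, `end0`, `strand`, `expectation`).
#' @export
plant_sites <- function(genome, mirna, placements, params = scoring_params()) {
  if (length(genome) != 1L || is.null(names(genome))) {
    stop_contract("genome must be a single named contig")
  }
  gseq <- norm_alphabet(genome[[1L]], "dna")
  G <- nchar(gseq)
  mdna <- mirna_as_dna(norm_alphabet(mirna, "rna"))
  L <- nchar(mdna)
  w <- position_weights(L, params)
  mbase <- strsplit(mdna, "", fixed = TRUE)[[1]]

  pos <- vapply(placements, function(p) as.integer(p$position), integer(1))
  if (any(pos < 0L | pos + L > G)) stop_contract("placement out of genome bounds")
  ord <- order(pos)
  if (length(pos) > 1L && any(diff(pos[ord]) < L)) {
    stop_contract("placements overlap")
  }

  truth <- data.frame(start0 = integer(), end0 = integer(), strand = character(),
                      expectation = numeric(), stringsAsFactors = FALSE)
  chars <- strsplit(gseq, "", fixed = TRUE)[[1]]
  for (p in placements) {
    strand <- p$strand
    if (!strand %in% c("+", "-")) stop_contract("placement strand must be '+' or '-'")
    mut <- as.integer(p$mutate %||% integer(0))
    if (any(mut < 1L | mut > L)) stop_contract("mutated miRNA position out of range")
    site <- strsplit(revcomp_dna(mdna), "", fixed = TRUE)[[1]]
    # miRNA position i faces site position L - i + 1
    for (i in mut) site[L - i + 1L] <- .NONPAIR_BASE[[mbase[i]]]
    insert <- if (strand == "+") site else strsplit(revcomp_dna(paste(site, collapse = "")), "")[[1]]
    chars[(p$position + 1L):(p$position + L)] <- insert
    truth <- rbind(truth, data.frame(
      start0 = as.integer(p$position), end0 = as.integer(p$position + L),
      strand = strand,
      expectation = sum(w[mut]) * params$mismatch,
      stringsAsFactors = FALSE
    ))
  }
  out <- stats::setNames(paste(chars, collapse = ""), names(genome))
  list(genome = out, truth = truth[order(truth$start0), , drop = FALSE])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a random non-overlapping CDS annotation
#'
#' Places `n_genes` non-overlapping CDS of 300-1500 nt with random strands
#' on the contig, tagged `LT0001`, `LT0002`, ... in positional order.
#'
#' @param genome named character vector of length 1.
#' @param n_genes number of CDS to place (>= 0).
#' @param seed integer RNG seed.
#' @param path optional path; when given, the annotation is also written as
#'   GFF3.
#' @return CDS data.frame in [read_gff_cds()] layout (0-based half-open).
#' @export
make_gff <- function(genome, n_genes, seed = 1L, path = NULL) {
  if (length(genome) != 1L || is.null(names(genome))) {
    stop_contract("genome must be a single named contig")
  }
  G <- nchar(genome[[1L]])
  if (n_genes < 0L) stop_contract("n_genes must be >= 0")
  feats <- withr::with_seed(seed, {
    starts <- integer(0); ends <- integer(0)
    tries <- 0L
    while (length(starts) < n_genes) {
      tries <- tries + 1L
      if (tries > 200L * max(1L, n_genes)) {
        stop_contract("cannot place ", n_genes, " non-overlapping CDS on a ",
                      G, " nt contig")
      }
      len <- sample(300:1500, 1L)
      if (len > G) next
      s <- sample.int(G - len + 1L, 1L) - 1L
      if (any(s < ends & s + len > starts)) next
      starts <- c(starts, s); ends <- c(ends, s + len)
    }
    data.frame(start = starts, end = ends,
               strand = sample(c("+", "-"), length(starts), replace = TRUE),
               stringsAsFactors = FALSE)
  })
  feats <- feats[order(feats$start), , drop = FALSE]
  cds <- data.frame(
    contig = rep(names(genome), nrow(feats)),
    start = as.integer(feats$start), end = as.integer(feats$end),
    strand = feats$strand,
    locus_tag = sprintf("LT%04d", seq_len(nrow(feats))),
    stringsAsFactors = FALSE
  )
  if (nrow(cds) == 0L) cds <- empty_cds()
  if (!is.null(path)) write_gff_cds(cds, path)
  cds
}

#' Write a CDS table as GFF3
#'
#' Converts the internal 0-based half-open coordinates back to GFF3's
#' 1-based inclusive convention.
#'
#' @param cds CDS data.frame ([read_gff_cds()] layout).
#' @param path output path.
#' @export
write_gff_cds <- function(cds, path) {
  lines <- "##gff-version 3"
  if (nrow(cds)) {
    lines <- c(lines, sprintf(
      "%s\trhizomir\tCDS\t%d\t%d\t.\t%s\t0\tID=cds%d;locus_tag=%s",
      cds$contig, cds$start + 1L, cds$end, cds$strand,
      seq_len(nrow(cds)), cds$locus_tag))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a compartmentalized miRNA count table with known truth
#'
#' Compartment-specific ("true positive") miRNAs draw target-sample counts
#' from a negative binomial with mean `nb_mean` and dispersion
#' `nb_dispersion` (variance `mu + dispersion * mu^2`), so the probability
#' of clearing a caller threshold is controlled by `nb_mean`; their
#' bulk-sample counts are 0 with probability `1 - bulk_singleton_rate` and
#' a singleton 1 otherwise, mimicking sequencing artifacts in bulk soil.
#' Background miRNAs draw low Poisson counts in every sample.
#'
#' @param n_mirnas total number of miRNAs (default 200).
#' @param n_target_samples,n_bulk_samples samples per group (default 3 + 3).
#' @param true_positive_fraction fraction of miRNAs that are
#'   compartment-specific (default 0.1).
#' @param nb_mean negative-binomial mean for true positives in target
#'   samples (default 30).
#' @param nb_dispersion negative-binomial dispersion (default 0.5).
#' @param bulk_singleton_rate per-bulk-sample singleton probability for
#'   true positives (default 0.3).
#' @param background_lambda Poisson mean for background miRNAs (default 0.5).
#' @param seed integer RNG seed.
#' @return list with `table` (a [count_table]) and `truth` (names of the
#'   compartment-specific miRNAs).
#' @export
make_count_table <- function(n_mirnas = 200L, n_target_samples = 3L,
                             n_bulk_samples = 3L, true_positive_fraction = 0.1,
                             nb_mean = 30, nb_dispersion = 0.5,
                             bulk_singleton_rate = 0.3,
                             background_lambda = 0.5, seed = 1L) {
  if (n_target_samples < 1L || n_bulk_samples < 1L) {
    stop_contract("need at least one target and one bulk sample")
  }
  if (true_positive_fraction < 0 || true_positive_fraction > 1 ||
      bulk_singleton_rate < 0 || bulk_singleton_rate > 1) {
    stop_contract("fractions must be in [0, 1]")
  }
  if (nb_mean <= 0) stop_contract("nb_mean must be > 0")
  mirnas <- sprintf("mir%04d", seq_len(n_mirnas))
  samples <- c(sprintf("R%d", seq_len(n_target_samples)),
               sprintf("B%d", seq_len(n_bulk_samples)))
  groups <- stats::setNames(rep(c("target", "bulk"),
                                c(n_target_samples, n_bulk_samples)), samples)
  n_tp <- round(n_mirnas * true_positive_fraction)
  res <- withr::with_seed(seed, {
    tp <- sort(sample(mirnas, n_tp))
    counts <- matrix(stats::rpois(n_mirnas * length(samples), background_lambda),
                     nrow = n_mirnas, dimnames = list(mirnas, samples))
    for (m in tp) {
      counts[m, seq_len(n_target_samples)] <- if (nb_dispersion > 0) {
        stats::rnbinom(n_target_samples, size = 1 / nb_dispersion, mu = nb_mean)
      } else {
        stats::rpois(n_target_samples, nb_mean)
      }
      counts[m, n_target_samples + seq_len(n_bulk_samples)] <-
        stats::rbinom(n_bulk_samples, 1L, bulk_singleton_rate)
    }
    list(counts = counts, truth = tp)
  })
  list(table = count_table(res$counts, groups), truth = res$truth)
}

#' Write a genome as FASTA
#'
#' @param genome named character vector of contig sequences.
#' @param path output path.
#' @export
write_fasta <- function(genome, path) {
  if (is.null(names(genome))) stop_contract("sequences must be named")
  writeLines(as.vector(rbind(paste0(">", names(genome)), unname(genome))), path)
  invisible(path)
}
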