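# Gene-set overlap against a random-sets null.
#
# The question: do predicted miRNA-target genes overlap differentially
# expressed genes more than two random sets of the same sizes drawn from
# the gene universe would? Under the null, the overlap k of a fixed set of
# size m and a uniformly random set of size n in a universe of size N is
# hypergeometric; the enrichment p-value is the upper tail P(X >= k), with
# expected overlap m*n/N. A seeded Monte-Carlo permutation version is
# provided as an independent check.

#' Hypergeometric overlap test for two gene sets
#'
#' @param set_a character vector of gene identifiers (e.g. predicted
#'   targets); must be a subset of `universe`.
#' @param set_b second gene set (e.g. DE genes); must be a subset of
#'   `universe`.
#' @param universe character vector of all genes considered (e.g. every
#'   annotated locus tag).
#' @param alternative `"greater"` (enrichment, default) or `"less"`
#'   (depletion: P(X <= k)).
#' @return object of class `overlap_result` with fields `universe_size`,
#'   `set_a_size`, `set_b_size`, `observed_overlap`, `expected_overlap`,
#'   `p_value` and `alternative`.
#' @examples
#' overlap_test(letters[1:5], letters[3:6], letters)
#' @export
overlap_test <- function(set_a, set_b, universe, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop_contract("universe is empty")
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  out_a <- setdiff(set_a, universe)
  out_b <- setdiff(set_b, universe)
  if (length(out_a) || length(out_b)) {
    stop_contract("gene(s) outside the universe: ",
                  paste(utils::head(c(out_a, out_b), 10L), collapse = ", "))
  }
  N <- length(universe); m <- length(set_a); n <- length(set_b)
  k <- length(intersect(set_a, set_b))
  p <- if (alternative == "greater") {
    stats::phyper(k - 1L, m, N - m, n, lower.tail = FALSE)
  } else {
    stats::phyper(k, m, N - m, n, lower.tail = TRUE)
  }
  structure(list(universe_size = N, set_a_size = m, set_b_size = n,
                 observed_overlap = k, expected_overlap = m * n / N,
                 p_value = p, alternative = alternative),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("Gene-set overlap vs. random-sets null (hypergeometric)\n")
  cat(sprintf("  universe N = %d, |A| = %d, |B| = %d\n",
              x$universe_size, x$set_a_size, x$set_b_size))
  cat(sprintf("  observed overlap k = %d, expected under null = %.3f\n",
              x$observed_overlap, x$expected_overlap))
  tail <- if (x$alternative == "greater") "P(X >= k)" else "P(X <= k)"
  cat(sprintf("  %s = %.4g\n", tail, x$p_value))
  invisible(x)
}

#' Monte-Carlo permutation version of the overlap test
#'
#' Draws `reps` independent pairs of uniform random subsets of the given
#' sizes from the universe and estimates the upper-tail probability as
#' `(1 + #{k_rep >= observed_k}) / (reps + 1)`.
#'
#' @param set_a_size,set_b_size subset sizes.
#' @param universe gene universe (character vector).
#' @param observed_k observed overlap to test.
#' @param reps number of permutations (default 10000).
#' @param seed integer RNG seed.
#' @return list with `p_empirical`, `overlap_mean`, `overlap_sd` and the
#'   drawn `overlaps`.
#' @export
permutation_overlap <- function(set_a_size, set_b_size, universe,
                                observed_k, reps = 10000L, seed = 1L) {
  universe <- unique(as.character(universe))
  N <- length(universe)
  if (reps < 1L) stop_contract("reps must be >= 1")
  if (set_a_size > N || set_b_size > N) {
    stop_contract("subset sizes exceed the universe size")
  }
  overlaps <- withr::with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      a <- sample.int(N, set_a_size)
      b <- sample.int(N, set_b_size)
      length(intersect(a, b))
    }, integer(1))
  })
  list(p_empirical = (1 + sum(overlaps >= observed_k)) / (reps + 1),
       overlap_mean = mean(overlaps),
       overlap_sd = stats::sd(overlaps),
       overlaps = overlaps)
}
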