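# Position-weighted duplex scoring in the psRNAtarget tradition.
#
# The expectation E of a miRNA/site duplex is the weighted sum of per-position
# pairing penalties: 0 for a Watson-Crick pair, 0.5 for a G:U wobble, 1 for a
# mismatch, with positions in the seed region (miRNA positions 2-13 by
# default, 1-based from the 5' end) weighted double. Pairing is antiparallel:
# miRNA position i faces site position L - i + 1, where the site is given
# target-sense (mRNA-like) 5'->3'. Lower E means better complementarity;
# E = 0 is a perfect duplex.

# Penalty-class matrix over the DNA-encoded alphabet (A,C,G,T,other):
# 0 = Watson-Crick, 1 = G:U wobble, 2 = mismatch. U is encoded as T.
.PAIR_CLASS <- local({
  m <- matrix(2L, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                        c("A", "C", "G", "T", "N")))
  m["A", "T"] <- 0L; m["T", "A"] <- 0L
  m["G", "C"] <- 0L; m["C", "G"] <- 0L
  m["G", "T"] <- 1L; m["T", "G"] <- 1L   # G:U wobble (site U stored as T)
  m
})

#' Scoring parameters for the duplex expectation
#'
#' @param mismatch penalty for a mismatched position (default 1).
#' @param wobble penalty for a G:U wobble pair (default 0.5).
#' @param seed_start,seed_end 1-based inclusive bounds of the seed region on
#'   the miRNA, counted from its 5' end (default 2-13).
#' @param seed_multiplier weight applied to penalties inside the seed
#'   (default 2).
#' @param max_expectation expectation cutoff: windows scoring above it are
#'   not reported by [scan_genome()] (default 3).
#' @return a list of class `scoring_params`.
#' @export
scoring_params <- function(mismatch = 1, wobble = 0.5, seed_start = 2L,
                           seed_end = 13L, seed_multiplier = 2,
                           max_expectation = 3) {
  if (seed_start < 1L || seed_end < seed_start) {
    stop_contract("seed region must satisfy 1 <= seed_start <= seed_end")
  }
  if (mismatch < 0 || wobble < 0 || seed_multiplier <= 0 || max_expectation < 0) {
    stop_contract("penalties, seed multiplier and cutoff must be non-negative")
  }
  structure(list(mismatch = mismatch, wobble = wobble,
                 seed_start = as.integer(seed_start), seed_end = as.integer(seed_end),
                 seed_multiplier = seed_multiplier, max_expectation = max_expectation),
            class = "scoring_params")
}

# Per-position weights for a miRNA of length L.
position_weights <- function(L, params) {
  w <- rep(1, L)
  sel <- seq_len(L) >= params$seed_start & seq_len(L) <= params$seed_end
  w[sel] <- params$seed_multiplier
  w
}

# Penalty value for each pairing class under the given parameters.
class_penalties <- function(params) c(0, params$wobble, params$mismatch)

#' Score one miRNA/site duplex
#'
#' Evaluates the antiparallel duplex between a miRNA and a candidate target
#' site of equal length, returning the expectation score and a per-position
#' pairing annotation over miRNA positions 1..L (`|` Watson-Crick, `o` G:U
#' wobble, `x` mismatch). The site is the target-sense sequence 5'->3'; its
#' alphabet may be RNA or DNA (U and T are equivalent). Positions containing
#' `N` or other ambiguity codes never pair.
#'
#' @param mirna miRNA sequence (RNA alphabet), 5'->3'.
#' @param site target-sense site sequence of the same length.
#' @param params a [scoring_params()] list.
#' @return list of class `duplex_score` with elements `expectation`,
#'   `pairing_string`, `penalties` (per miRNA position), `weights`,
#'   `seed_range`.
#' @examples
#' score_duplex("ACGUACGUACGUACGUACGUA", "UACGUACGUACGUACGUACGU")$expectation  # 0
#' @export
score_duplex <- function(mirna, site, params = scoring_params()) {
  check_single_string(mirna, "mirna")
  check_single_string(site, "site")
  m <- encode_dna(mirna_as_dna(mirna))
  s <- encode_dna(chartr("U", "T", toupper(site)))
  L <- length(m)
  if (L == 0L) stop_contract("empty sequence")
  if (length(s) != L) {
    stop_contract("site length (", length(s), ") must equal miRNA length (", L, ")")
  }
  cls <- .PAIR_CLASS[cbind(m, s[L - seq_len(L) + 1L])]
  pen <- class_penalties(params)[cls + 1L]
  w <- position_weights(L, params)
  structure(list(
    expectation = sum(w * pen),
    pairing_string = paste(c("|", "o", "x")[cls + 1L], collapse = ""),
    penalties = pen,
    weights = w,
    seed_range = c(params$seed_start, min(params$seed_end, L))
  ), class = "duplex_score")
}

#' @export
print.duplex_score <- function(x, ...) {
  cat("duplex expectation E =", format(x$expectation), "\n")
  cat("pairing (miRNA 5'->3'):", x$pairing_string, "\n")
  invisible(x)
}
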