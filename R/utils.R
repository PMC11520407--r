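# Internal helpers: alphabet normalization, base encoding, classed error conditions.

.DNA_BASES <- c("A", "C", "G", "T")
.IUPAC_EXTRA <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

stop_contract <- function(...) {
  stop(errorCondition(paste0(...), class = c("rhizomir_contract_error", "rhizomir_error")))
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("rhizomir_format_error", "rhizomir_error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("rhizomir_config_error", "rhizomir_error")))
}

#' Normalize a nucleotide string to an internal alphabet
#'
#' Upper-cases and maps between the RNA and DNA representations (`T` to `U`
#' for RNA, `U` to `T` for DNA). IUPAC ambiguity codes other than `N` are
#' preserved. Used at every module boundary so that miRNAs (RNA) and genomes
#' (DNA) compare under U = T.
#'
#' @param x character vector of sequences.
#' @param alphabet `"dna"` or `"rna"`.
#' @return character vector of normalized sequences.
#' @keywords internal
#' @noRd
norm_alphabet <- function(x, alphabet = c("dna", "rna")) {
  alphabet <- match.arg(alphabet)
  x <- toupper(x)
  if (alphabet == "rna") chartr("T", "U", x) else chartr("U", "T", x)
}

# Encode a DNA-alphabet string as integers 1..4 (A,C,G,T); anything else
# (N and other ambiguity codes) becomes 5 and never pairs.
encode_dna <- function(seq) {
  idx <- match(strsplit(seq, "", fixed = TRUE)[[1]], .DNA_BASES)
  idx[is.na(idx)] <- 5L
  idx
}

# Reverse complement on the DNA alphabet; ambiguity codes map to N.
revcomp_dna <- function(seq) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(seq))
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# miRNA (RNA) -> DNA representation used for genome matching.
mirna_as_dna <- function(seq) chartr("U", "T", toupper(seq))

check_single_string <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop_contract(what, " must be a single character string")
  }
}
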