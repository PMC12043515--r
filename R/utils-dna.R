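# DNA string helpers shared across the simulation, motif and PBM modules.

IUPAC_MAP <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Validate an IUPAC DNA string
#'
#' @param x character scalar.
#' @return invisibly `TRUE`; errors on any non-IUPAC character.
#' @keywords internal
assert_iupac <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  bad <- setdiff(strsplit(toupper(x), "")[[1]], names(IUPAC_MAP))
  if (length(bad)) {
    stop("invalid IUPAC DNA character(s): ", paste(unique(bad), collapse = ", "))
  }
  invisible(TRUE)
}

#' Reverse complement of DNA strings
#'
#' Vectorised; tolerates `N`. Uses Biostrings for speed on large vectors.
#'
#' @param x character vector of DNA strings over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Regex character classes for an IUPAC pattern (used for containment queries).
iupac_to_regex <- function(pattern) {
  assert_iupac(pattern)
  chars <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(chars, function(ch) {
    opts <- IUPAC_MAP[[ch]]
    if (length(opts) == 1L) opts else paste0("[", paste(opts, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# Random DNA of given length and GC content; assumes RNG state is set by caller.
random_dna <- function(n_seq, len, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n_seq), function(i) {
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

# Draw one concrete DNA realisation of an IUPAC motif.
sample_iupac <- function(pattern) {
  assert_iupac(pattern)
  chars <- strsplit(toupper(pattern), "")[[1]]
  paste(vapply(chars, function(ch) {
    opts <- IUPAC_MAP[[ch]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

# Write a named character vector of sequences as FASTA (plain text).
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

# Read FASTA into a named character vector.
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
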