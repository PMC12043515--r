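# Protein-binding-microarray z-score mining: normalization, pattern-
# containment subsets, strong-binding fractions and threshold splits.

#' Z-score normalize intensities
#'
#' `z_i = (x_i - mean) / sd` with the sample (n-1) standard deviation.
#'
#' @param x numeric vector, length >= 2, nonzero spread.
#' @return numeric vector of z-scores.
#' @export
zscore_normalize <- function(x) {
  stopifnot(length(x) >= 2)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero spread: z-scores undefined")
  (x - mean(x)) / s
}

#' Subset oligo records containing a sequence pattern
#'
#' Keeps records whose sequence contains the IUPAC pattern; under
#' `strand = "both"` a record also qualifies when its reverse complement
#' contains the pattern.
#'
#' @param records data.frame with a `sequence` column.
#' @param pattern IUPAC DNA string.
#' @param strand `"given"` (default; arrays print one strand) or `"both"`.
#' @return the matching rows of `records`.
#' @export
pattern_containing_set <- function(records, pattern,
                                   strand = c("given", "both")) {
  strand <- match.arg(strand)
  rx <- iupac_to_regex(pattern)
  hit <- grepl(rx, toupper(records$sequence))
  if (strand == "both") {
    hit <- hit | grepl(rx, revcomp(records$sequence))
  }
  records[hit, , drop = FALSE]
}

#' Fraction of records with z above a threshold
#'
#' Strict comparison (`z > threshold`), e.g. the strong-binding fraction
#' at z > 4.
#'
#' @param z numeric vector of z-scores (non-empty).
#' @param threshold z cutoff.
#' @return fraction in `[0, 1]`.
#' @export
strong_binding_fraction <- function(z, threshold = 4) {
  if (!length(z)) stop("empty subset")
  mean(z > threshold)
}

#' Split records by a z-score threshold
#'
#' Strict partition: values > threshold go high, values <= threshold go
#' low (values exactly at the threshold are assigned to the low group).
#'
#' @param records data.frame (or vector) to split.
#' @param z numeric z-scores aligned with `records`.
#' @param threshold z cutoff (default 9).
#' @return list with elements `high` and `low`.
#' @export
zscore_threshold_split <- function(records, z, threshold = 9) {
  high <- z > threshold
  if (is.data.frame(records)) {
    list(high = records[high, , drop = FALSE],
         low = records[!high, , drop = FALSE])
  } else {
    list(high = records[high], low = records[!high])
  }
}
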