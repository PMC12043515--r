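# Plain-text readers/writers for the formats the pipeline exchanges:
# BED peaks, TSV tables, CSV traces, FASTA sequence sets and aligned
# FASTA + metadata pairs.

#' Read a BED-like peak file
#'
#' First three columns chrom/start/end (0-based half-open); optional
#' fourth and fifth columns are taken as peak_id and score.
#'
#' @param path BED file path.
#' @return data.frame: chrom, start, end (+ peak_id, score when present).
#' @export
read_peaks_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  names(df)[1:3] <- c("chrom", "start", "end")
  if (ncol(df) >= 4) names(df)[4] <- "peak_id"
  if (ncol(df) >= 5) names(df)[5] <- "score"
  df
}

#' Write peaks as BED
#'
#' @param peaks data.frame with chrom, start, end and optionally peak_id,
#'   score.
#' @param path output path.
#' @export
write_peaks_bed <- function(peaks, path) {
  cols <- intersect(c("chrom", "start", "end", "peak_id", "score"),
                    names(peaks))
  utils::write.table(peaks[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write tab-separated tables with headers
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' @rdname read_tsv_table
#' @param df data.frame to write.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an aligned FASTA plus metadata TSV
#'
#' The metadata TSV must carry columns id, species, paralog and clade;
#' ids must match the FASTA headers.
#'
#' @param fasta_path aligned FASTA (protein) path.
#' @param meta_path metadata TSV path.
#' @return list with `alignment` (character matrix) and `meta`.
#' @export
read_alignment <- function(fasta_path, meta_path) {
  seqs <- Biostrings::readAAStringSet(fasta_path)
  meta <- read_tsv_table(meta_path)
  stopifnot(all(c("id", "species", "paralog", "clade") %in% names(meta)))
  if (!setequal(names(seqs), meta$id)) {
    stop("FASTA ids and metadata ids disagree")
  }
  seqs <- seqs[meta$id]
  widths <- Biostrings::width(seqs)
  if (length(unique(widths)) != 1L) {
    stop("aligned sequences must share one length")
  }
  aln <- do.call(rbind, strsplit(as.character(seqs), ""))
  rownames(aln) <- meta$id
  list(alignment = aln, meta = meta)
}
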