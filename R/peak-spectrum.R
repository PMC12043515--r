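# Comparative ChIP-seq occupancy spectra: reproducibility filtering, top-N
# selection, interval merging, RPKM-ratio spectra, equal-count binning,
# promoter annotation/ranking and group comparison.
#
# Interval convention: BED-style 0-based, half-open [start, end) on disk
# and in data.frames; conversion to 1-based IRanges happens internally.
# Book-ended intervals (end == start of the next) do not merge: merging
# requires >= 1 bp of overlap.

# BED-style data.frame -> GRanges (1-based closed internally).
peaks_to_gr <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)),
            all(df$start >= 0), all(df$end > df$start))
  GenomicRanges::GRanges(
    df$chrom, IRanges::IRanges(start = df$start + 1L, end = df$end))
}

gr_to_peaks <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Reproducibility filter across replicate peak sets
#'
#' A candidate region (a merged span of all replicate peaks) is kept when
#' at least `k` replicates contain a peak overlapping it with score >
#' `score_min` and RPKM > `rpkm_min`. The retained region carries the
#' maximum passing score and the mean passing RPKM across supporting
#' replicates.
#'
#' @param replicates list of BED-like data.frames (chrom, start, end,
#'   score, rpkm), one per replicate.
#' @param score_min,rpkm_min strict lower thresholds (defaults 19 and 3).
#' @param k minimum number of supporting replicates (default 2).
#' @return data.frame: chrom, start, end, score, rpkm, n_support.
#' @export
filter_reproducible <- function(replicates, score_min = 19, rpkm_min = 3,
                                k = 2L) {
  n <- length(replicates)
  if (k > n || k < 1L) stop("need 1 <= k <= number of replicates")
  all_gr <- do.call(c, lapply(replicates, peaks_to_gr))
  cand <- GenomicRanges::reduce(all_gr, min.gapwidth = 0L)
  support <- matrix(FALSE, length(cand), n)
  score_best <- matrix(NA_real_, length(cand), n)
  rpkm_best <- matrix(NA_real_, length(cand), n)
  for (i in seq_len(n)) {
    rep_i <- replicates[[i]]
    pass <- rep_i$score > score_min & rep_i$rpkm > rpkm_min
    if (!any(pass)) next
    gr_i <- peaks_to_gr(rep_i[pass, , drop = FALSE])
    ov <- GenomicRanges::findOverlaps(cand, gr_i, minoverlap = 1L)
    if (!length(ov)) next
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    support[unique(qh), i] <- TRUE
    sc <- tapply(rep_i$score[pass][sh], qh, max)
    rp <- tapply(rep_i$rpkm[pass][sh], qh, max)
    score_best[as.integer(names(sc)), i] <- sc
    rpkm_best[as.integer(names(rp)), i] <- rp
  }
  n_support <- rowSums(support)
  keep <- n_support >= k
  out <- gr_to_peaks(cand[keep])
  out$score <- apply(score_best[keep, , drop = FALSE], 1, max, na.rm = TRUE)
  out$rpkm <- rowMeans(rpkm_best[keep, , drop = FALSE], na.rm = TRUE)
  out$n_support <- n_support[keep]
  out
}

#' Select the strongest n peaks by score
#'
#' Ties at the boundary are broken by (chrom, start) lexicographic order so
#' the selection is deterministic. Returns all peaks when fewer than `n`
#' exist.
#'
#' @param peaks data.frame with chrom, start, end, score.
#' @param n number of peaks to keep.
#' @return the selected rows, strongest first.
#' @export
select_top_peaks <- function(peaks, n) {
  stopifnot(n >= 1)
  ord <- order(-peaks$score, peaks$chrom, peaks$start)
  peaks[ord[seq_len(min(n, nrow(peaks)))], , drop = FALSE]
}

#' Merge two factor-specific peak sets into a joint universe
#'
#' Takes the union of both interval sets and transitively merges any
#' intervals sharing at least 1 bp. Per-factor RPKM for each merged span is
#' recomputed from the read counts of the constituent peaks overlapping it:
#' `rpkm = sum(count) / (depth [M] * merged length [kb])`.
#'
#' @param peaks_a,peaks_b data.frames (chrom, start, end, and optionally
#'   count) for factors A and B.
#' @param depth_a,depth_b library depths in million reads.
#' @return data.frame: chrom, start, end, rpkm_a, rpkm_b.
#' @export
merge_peak_sets <- function(peaks_a, peaks_b, depth_a = 1, depth_b = 1) {
  # the two sets may legitimately cover disjoint chromosomes
  combined <- suppressWarnings(c(peaks_to_gr(peaks_a),
                                 peaks_to_gr(peaks_b)))
  merged_gr <- GenomicRanges::reduce(combined, min.gapwidth = 0L)
  out <- gr_to_peaks(merged_gr)
  len_kb <- (out$end - out$start) / 1000
  sum_counts <- function(peaks, depth) {
    cnt <- if (is.null(peaks$count)) rep(0, nrow(peaks)) else peaks$count
    ov <- GenomicRanges::findOverlaps(merged_gr, peaks_to_gr(peaks),
                                      minoverlap = 1L)
    tot <- rep(0, length(merged_gr))
    if (length(ov)) {
      agg <- tapply(cnt[S4Vectors::subjectHits(ov)],
                    S4Vectors::queryHits(ov), sum)
      tot[as.integer(names(agg))] <- agg
    }
    tot / (depth * len_kb)
  }
  out$rpkm_a <- sum_counts(peaks_a, depth_a)
  out$rpkm_b <- sum_counts(peaks_b, depth_b)
  out
}

#' RPKM-ratio spectrum over merged peaks
#'
#' Computes `ratio = (rpkm_a + eps) / (rpkm_b + eps)` per merged peak,
#' sorts the spectrum ascending and attaches percentile positions, plus a
#' summary: the median ratio, counts/fractions within requested closed
#' ratio ranges, and counts above requested cutoffs.
#'
#' @param merged data.frame from [merge_peak_sets()] (needs rpkm_a,
#'   rpkm_b).
#' @param pseudocount additive RPKM pseudocount `eps` (default 0.1).
#' @param ranges list of length-2 numeric vectors, closed intervals
#'   `[lo, hi]`.
#' @param cutoffs numeric; counts of peaks with ratio > cutoff.
#' @return object of class `ratio_spectrum`: list with `spectrum` (the
#'   sorted data.frame with ratio and percentile columns) and `summary`.
#' @export
ratio_spectrum <- function(merged, pseudocount = 0.1,
                           ranges = list(c(1.3, 3)), cutoffs = numeric(0)) {
  if (!nrow(merged)) stop("merged peak set is empty")
  ratio <- (merged$rpkm_a + pseudocount) / (merged$rpkm_b + pseudocount)
  ord <- order(ratio, merged$chrom, merged$start)
  spectrum <- merged[ord, , drop = FALSE]
  spectrum$ratio <- ratio[ord]
  n <- nrow(spectrum)
  spectrum$percentile <- seq_len(n) / n * 100
  range_tab <- do.call(rbind, lapply(ranges, function(rg) {
    k <- sum(spectrum$ratio >= rg[1] & spectrum$ratio <= rg[2])
    data.frame(lo = rg[1], hi = rg[2], count = k, fraction = k / n)
  }))
  cutoff_tab <- if (length(cutoffs)) {
    data.frame(cutoff = cutoffs,
               count = vapply(cutoffs, function(ct) {
                 sum(spectrum$ratio > ct)
               }, numeric(1)))
  } else {
    data.frame(cutoff = numeric(0), count = numeric(0))
  }
  structure(list(
    spectrum = spectrum,
    summary = list(n = n, median_ratio = stats::median(spectrum$ratio),
                   ranges = range_tab, cutoffs = cutoff_tab)),
    class = "ratio_spectrum")
}

#' @export
print.ratio_spectrum <- function(x, ...) {
  cat("Ratio spectrum over", x$summary$n, "merged peaks\n")
  cat("  median ratio:", format(x$summary$median_ratio, digits = 4), "\n")
  if (nrow(x$summary$ranges)) {
    with(x$summary$ranges, cat(sprintf(
      "  ratio in [%g, %g]: %d peaks (%.1f%%)\n",
      lo, hi, count, 100 * fraction), sep = ""))
  }
  invisible(x)
}

#' Partition a sorted spectrum into B equal-count bins
#'
#' Contiguous bins along the ascending-ratio order whose sizes differ by at
#' most one; when `n` is not divisible by `B`, the larger bins sit at the
#' low-ratio end.
#'
#' @param x a `ratio_spectrum` or an integer count `n`.
#' @param B number of bins (1 <= B <= n).
#' @return integer vector of bin indices (1 = lowest ratios), one per peak
#'   in ascending ratio order.
#' @export
bin_equal_count <- function(x, B) {
  n <- if (inherits(x, "ratio_spectrum")) nrow(x$spectrum) else as.integer(x)
  if (B < 1 || B > n) stop("need 1 <= B <= n")
  base <- n %/% B
  extra <- n %% B
  sizes <- rep(base, B) + c(rep(1L, extra), rep(0L, B - extra))
  rep(seq_len(B), times = sizes)
}

#' Annotate merged peaks to promoter windows
#'
#' Strand-aware promoter window: `[TSS - upstream, TSS + downstream)` in
#' gene orientation, i.e. reflected for minus-strand genes. A peak
#' overlapping several windows is assigned to the gene with the nearest TSS
#' (absolute signed distance); signed distance is measured from the peak
#' center to the TSS in gene orientation (negative = upstream).
#'
#' @param merged data.frame of merged peaks.
#' @param genes data.frame with gene_id, chrom, tss (0-based position) and
#'   strand (`+`/`-`).
#' @param upstream,downstream window extents in bp (defaults 1500 and 500).
#' @return the peak rows that fall in a promoter window, with gene_id and
#'   tss_distance columns appended.
#' @export
annotate_promoters <- function(merged, genes, upstream = 1500,
                               downstream = 500) {
  stopifnot(all(c("gene_id", "chrom", "tss", "strand") %in% names(genes)))
  plus <- genes$strand == "+"
  win <- data.frame(
    chrom = genes$chrom,
    start = ifelse(plus, genes$tss - upstream, genes$tss - downstream),
    end = ifelse(plus, genes$tss + downstream, genes$tss + upstream))
  win$start <- pmax(win$start, 0)
  ov <- GenomicRanges::findOverlaps(peaks_to_gr(merged), peaks_to_gr(win),
                                    minoverlap = 1L)
  if (!length(ov)) {
    out <- merged[0, , drop = FALSE]
    out$gene_id <- character(0)
    out$tss_distance <- numeric(0)
    return(out)
  }
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  center <- floor((merged$start[qh] + merged$end[qh]) / 2)
  dist <- ifelse(plus[sh], center - genes$tss[sh], genes$tss[sh] - center)
  # nearest TSS wins when a peak overlaps several promoter windows
  ord <- order(qh, abs(dist))
  first <- !duplicated(qh[ord])
  pick <- ord[first]
  out <- merged[qh[pick], , drop = FALSE]
  out$gene_id <- genes$gene_id[sh[pick]]
  out$tss_distance <- dist[pick]
  out
}

#' Rank promoter peaks by ratio
#'
#' Rank 1 is the highest ratio; ties are ordered deterministically by
#' (chrom, start). Percentile = rank / n * 100.
#'
#' @param promoter_peaks data.frame with a ratio column (e.g. promoter-
#'   annotated rows of a spectrum).
#' @return the input ordered by rank, with rank and rank_percentile
#'   columns.
#' @export
rank_promoter_peaks <- function(promoter_peaks) {
  if (!nrow(promoter_peaks)) stop("no promoter peaks to rank")
  ord <- order(-promoter_peaks$ratio, promoter_peaks$chrom,
               promoter_peaks$start)
  out <- promoter_peaks[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out$rank_percentile <- out$rank / nrow(out) * 100
  out
}

#' Select extreme or intermediate peaks from a spectrum
#'
#' `top` takes the k largest ratios, `bottom` the k smallest, and `middle`
#' a window of k peaks centred on the median position (offset
#' `floor((n - k) / 2)` from the top of the descending-ratio order).
#'
#' @param x a `ratio_spectrum` or a data.frame with a ratio column.
#' @param k subset size (k <= n).
#' @param which one of "top", "bottom", "middle".
#' @return the selected peak rows, ordered by descending ratio.
#' @export
select_extremes <- function(x, k, which = c("top", "bottom", "middle")) {
  which <- match.arg(which)
  df <- if (inherits(x, "ratio_spectrum")) x$spectrum else x
  n <- nrow(df)
  if (k > n || k < 1) stop("need 1 <= k <= n")
  desc <- df[order(-df$ratio, df$chrom, df$start), , drop = FALSE]
  idx <- switch(which,
                top = seq_len(k),
                bottom = seq.int(n - k + 1L, n),
                middle = {
                  off <- floor((n - k) / 2)
                  seq.int(off + 1L, off + k)
                })
  desc[idx, , drop = FALSE]
}

#' Welch's two-sample t-test between value groups
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value. When both groups have zero variance the
#' result is flagged degenerate (t = 0, p = 1 when the means agree;
#' otherwise the statistic is unbounded and reported as +/-Inf with p = 0).
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list: t, df, p, degenerate.
#' @export
welch_group_compare <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(list(t = if (same) 0 else sign(mean(x) - mean(y)) * Inf,
                df = NA_real_, p = if (same) 1 else 0, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}
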