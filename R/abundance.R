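# RPKM normalization, expressed-gene filtering, fold induction and
# knockout-dependence classification for WT/KO induction time courses.

#' RPKM-normalize a count table
#'
#' `RPKM_ij = count_ij / (depth_j [M reads] * length_i [kb])`.
#'
#' @param counts integer matrix, features x samples (non-negative).
#' @param depth numeric vector of library depths in million reads, one per
#'   column of `counts`.
#' @param length_kb numeric vector of feature lengths in kb, one per row.
#' @return numeric matrix of RPKMs with the same dimnames as `counts`.
#' @export
compute_rpkm <- function(counts, depth, length_kb) {
  counts <- as.matrix(counts)
  stopifnot(length(depth) == ncol(counts),
            length(length_kb) == nrow(counts))
  if (any(counts < 0)) stop("counts must be >= 0")
  if (any(depth <= 0)) stop("library depths must be > 0")
  if (any(length_kb <= 0)) stop("feature lengths must be > 0")
  sweep(sweep(counts, 2, depth, "/"), 1, length_kb, "/")
}

# Mean RPKM per feature x (genotype, timepoint) cell, averaging replicates.
condition_means <- function(rpkm, meta) {
  stopifnot(all(c("sample", "genotype", "timepoint") %in% names(meta)),
            all(colnames(rpkm) == meta$sample))
  key <- interaction(meta$genotype, meta$timepoint, drop = TRUE)
  means <- vapply(levels(key), function(k) {
    rowMeans(rpkm[, key == k, drop = FALSE])
  }, numeric(nrow(rpkm)))
  if (!is.matrix(means)) {
    means <- matrix(means, nrow = nrow(rpkm),
                    dimnames = list(rownames(rpkm), levels(key)))
  }
  cells <- do.call(rbind, strsplit(levels(key), ".", fixed = TRUE))
  list(means = means,
       genotype = cells[, 1], timepoint = as.numeric(cells[, 2]))
}

#' Expressed-feature filter
#'
#' Keeps features whose replicate-averaged RPKM exceeds `threshold` in at
#' least one (genotype, timepoint) cell of the given condition, e.g. RPKM
#' > 3 at any timepoint in stimulated WT samples.
#'
#' @param rpkm RPKM matrix from [compute_rpkm()].
#' @param meta sample metadata (columns sample, genotype, timepoint,
#'   replicate) aligned with `colnames(rpkm)`.
#' @param threshold RPKM threshold (strict `>`).
#' @param genotype genotype whose samples define the condition.
#' @param timepoints timepoints defining the condition (default: all
#'   stimulated, i.e. `> 0`... plus 0 if `include_baseline`).
#' @param include_baseline include the unstimulated timepoint in the
#'   condition.
#' @return character vector of retained feature ids.
#' @export
filter_expressed <- function(rpkm, meta, threshold = 3,
                             genotype = "WT", timepoints = NULL,
                             include_baseline = FALSE) {
  cm <- condition_means(rpkm, meta)
  sel <- cm$genotype == genotype
  if (is.null(timepoints)) {
    if (!include_baseline) sel <- sel & cm$timepoint > 0
  } else {
    sel <- sel & cm$timepoint %in% timepoints
  }
  if (!any(sel)) stop("condition selects no samples")
  keep <- apply(cm$means[, sel, drop = FALSE] > threshold, 1, any)
  rownames(rpkm)[keep]
}

#' Fold induction between two timepoints
#'
#' `fold = (mean stimulated RPKM + eps) / (mean baseline RPKM + eps)`,
#' replicates averaged arithmetically.
#'
#' @param rpkm,meta as in [filter_expressed()].
#' @param stim_time,baseline_time timepoints to compare.
#' @param genotype genotype the induction is computed in.
#' @param pseudocount additive RPKM pseudocount `eps`.
#' @return named numeric vector of fold inductions.
#' @export
fold_induction <- function(rpkm, meta, stim_time, baseline_time = 0,
                           genotype = "WT", pseudocount = 0.1) {
  cm <- condition_means(rpkm, meta)
  i_stim <- which(cm$genotype == genotype & cm$timepoint == stim_time)
  i_base <- which(cm$genotype == genotype & cm$timepoint == baseline_time)
  if (!length(i_stim) || !length(i_base)) {
    stop("requested timepoint absent for genotype ", genotype)
  }
  (cm$means[, i_stim] + pseudocount) / (cm$means[, i_base] + pseudocount)
}

#' Classify knockout dependence from KO/WT expression ratios
#'
#' A feature is dependent when its replicate-averaged KO/WT RPKM ratio
#' (with pseudocount) is at most `1/ratio_threshold` at some stimulated
#' timepoint -- the ten-fold rule when `ratio_threshold = 10`. Fold
#' induction in WT is carried along so callers can additionally require an
#' induction floor.
#'
#' @param rpkm,meta as in [filter_expressed()].
#' @param timepoints stimulated timepoints to evaluate (default all `> 0`).
#' @param ratio_threshold dependence fold threshold (default 10).
#' @param pseudocount additive RPKM pseudocount.
#' @param baseline_time unstimulated timepoint for the induction column.
#' @return data.frame: feature, one `log2_ratio_t<tp>` column per
#'   timepoint, `fold_induction` (maximum over the stimulated timepoints,
#'   in WT) and logical `dependent`.
#' @export
classify_dependence <- function(rpkm, meta, timepoints = NULL,
                                ratio_threshold = 10, pseudocount = 0.1,
                                baseline_time = 0) {
  cm <- condition_means(rpkm, meta)
  if (is.null(timepoints)) {
    timepoints <- sort(unique(cm$timepoint[cm$timepoint > 0]))
  }
  if (!length(timepoints)) stop("no stimulated timepoints in design")
  out <- data.frame(feature = rownames(rpkm), stringsAsFactors = FALSE)
  dep <- rep(FALSE, nrow(rpkm))
  fi <- rep(-Inf, nrow(rpkm))
  for (tp in timepoints) {
    i_wt <- which(cm$genotype == "WT" & cm$timepoint == tp)
    i_ko <- which(cm$genotype == "KO" & cm$timepoint == tp)
    if (!length(i_wt) || !length(i_ko)) {
      stop("both genotypes required at timepoint ", tp)
    }
    ratio <- (cm$means[, i_ko] + pseudocount) /
      (cm$means[, i_wt] + pseudocount)
    out[[sprintf("log2_ratio_t%g", tp)]] <- log2(ratio)
    dep <- dep | (ratio <= 1 / ratio_threshold)
    fi <- pmax(fi, fold_induction(rpkm, meta, tp, baseline_time,
                                  genotype = "WT",
                                  pseudocount = pseudocount))
  }
  out$fold_induction <- fi
  out$dependent <- dep
  out
}
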