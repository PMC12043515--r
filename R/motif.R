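# Motif scanning and enrichment: PWM log-odds scanning on both strands,
# ZOOPS (zero-or-one occurrence per sequence) counting, binomial
# enrichment, de novo k-mer discovery, and enrichment profiles across
# ratio bins.

BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param probs 4 x L numeric matrix of base probabilities (rows A,C,G,T;
#'   columns sum to 1).
#' @param background length-4 background base composition.
#' @param threshold_frac hit threshold as a fraction of the maximum
#'   attainable log-odds score (default 0.6).
#' @param name motif identifier.
#' @return object of class `pwm` with the probability matrix, log2-odds
#'   matrix, absolute score threshold and maximum score.
#' @export
pwm <- function(probs, background = rep(0.25, 4), threshold_frac = 0.6,
                name = "motif") {
  probs <- as.matrix(probs)
  stopifnot(nrow(probs) == 4, ncol(probs) >= 4,
            all(abs(colSums(probs) - 1) < 1e-9),
            length(background) == 4, all(background > 0))
  rownames(probs) <- BASES
  lodds <- log2(pmax(probs, 1e-9) / background)
  max_score <- sum(apply(lodds, 2, max))
  structure(list(name = name, probs = probs, lodds = lodds,
                 background = background,
                 threshold = threshold_frac * max_score,
                 max_score = max_score, length = ncol(probs)),
            class = "pwm")
}

#' PWM from an IUPAC consensus string
#'
#' Allowed bases at each position share `match_prob`; disallowed bases
#' split the remainder. With the default threshold fraction this yields a
#' near-exact-match scanner for the consensus.
#'
#' @param consensus IUPAC DNA string (length >= 4).
#' @param match_prob total probability on the allowed base set.
#' @inheritParams pwm
#' @return a [pwm()] object.
#' @export
pwm_from_consensus <- function(consensus, match_prob = 0.997,
                               background = rep(0.25, 4),
                               threshold_frac = 0.6, name = consensus) {
  assert_iupac(consensus)
  chars <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(length(chars) >= 4)
  probs <- vapply(chars, function(ch) {
    allowed <- IUPAC_MAP[[ch]]
    p <- rep((1 - match_prob) / (4 - length(allowed)), 4)
    names(p) <- BASES
    p[allowed] <- match_prob / length(allowed)
    if (length(allowed) == 4) p[] <- 0.25
    p
  }, numeric(4))
  pwm(probs, background, threshold_frac, name)
}

#' @export
print.pwm <- function(x, ...) {
  cat("PWM", x$name, "(length", x$length, ")\n")
  cat("  max log2-odds score:", format(x$max_score, digits = 4),
      " threshold:", format(x$threshold, digits = 4), "\n")
  invisible(x)
}

# Sliding log-odds scores for one encoded strand; N (NA code) scores 0.
slide_scores <- function(codes, lodds) {
  L <- ncol(lodds)
  nw <- length(codes) - L + 1L
  if (nw < 1L) return(numeric(0))
  sc <- numeric(nw)
  for (k in seq_len(L)) {
    v <- lodds[cbind(codes[k:(k + nw - 1L)], k)]
    v[is.na(v)] <- 0
    sc <- sc + v
  }
  sc
}

encode_dna <- function(seq) match(strsplit(toupper(seq), "")[[1]], BASES)

#' Scan a sequence with a PWM on both strands
#'
#' Reports every offset whose log2-odds score meets the PWM threshold.
#' `N` positions contribute a background (zero) score. Hits are returned
#' in coordinate order, forward strand first at equal offsets; minus-
#' strand hits are reported at their forward-strand offset.
#'
#' @param seq DNA string over `{A,C,G,T,N}`.
#' @param motif a [pwm()] object.
#' @return data.frame: offset (0-based), strand, score.
#' @export
scan_pwm <- function(seq, motif) {
  stopifnot(inherits(motif, "pwm"))
  n <- nchar(seq)
  L <- motif$length
  empty <- data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0))
  if (n < L) return(empty)
  fwd <- slide_scores(encode_dna(seq), motif$lodds)
  rvs <- slide_scores(encode_dna(revcomp(seq)), motif$lodds)
  i_f <- which(fwd >= motif$threshold)
  i_r <- which(rvs >= motif$threshold)
  hits <- rbind(
    data.frame(offset = i_f - 1L, strand = rep("+", length(i_f)),
               score = fwd[i_f]),
    data.frame(offset = n - L - (i_r - 1L),
               strand = rep("-", length(i_r)), score = rvs[i_r]))
  if (!nrow(hits)) return(empty)
  hits[order(hits$offset, hits$strand), , drop = FALSE]
}

# ZOOPS indicator: does each sequence contain >= 1 hit on either strand?
zoops_hits <- function(seqs, motif) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    if (n < motif$length) return(FALSE)
    if (any(slide_scores(encode_dna(s), motif$lodds) >= motif$threshold)) {
      return(TRUE)
    }
    any(slide_scores(encode_dna(revcomp(s)), motif$lodds) >=
          motif$threshold)
  }, logical(1), USE.NAMES = FALSE)
}

#' Extract fixed-width scan windows around peak centers
#'
#' Window = `[center - halfwidth, center + halfwidth)` with
#' `center = floor((start + end) / 2)`, clipped at chromosome ends.
#'
#' @param peaks BED-like data.frame (chrom, start, end, optional peak_id).
#' @param sequences named character vector of chromosome sequences.
#' @param halfwidth half window width in bp (default 200; must be >= 1).
#' @return named character vector of window sequences.
#' @export
extract_scan_windows <- function(peaks, sequences, halfwidth = 200) {
  if (halfwidth < 1) stop("halfwidth must be >= 1")
  missing_chr <- setdiff(unique(peaks$chrom), names(sequences))
  if (length(missing_chr)) {
    stop("peak(s) on missing chromosome(s): ",
         paste(missing_chr, collapse = ", "))
  }
  ids <- if (!is.null(peaks$peak_id)) peaks$peak_id else {
    sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)
  }
  out <- vapply(seq_len(nrow(peaks)), function(i) {
    chrom_seq <- sequences[[peaks$chrom[i]]]
    center <- floor((peaks$start[i] + peaks$end[i]) / 2)
    lo <- max(center - halfwidth, 0)
    hi <- min(center + halfwidth, nchar(chrom_seq))
    substr(chrom_seq, lo + 1L, hi)
  }, character(1))
  stats::setNames(out, ids)
}

binomial_tail <- function(k, n, p) {
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' ZOOPS binomial motif enrichment
#'
#' Counts the foreground and background sequences containing at least one
#' PWM hit (ZOOPS), estimates the background hit probability with Laplace
#' smoothing `p_bg = (k_bg + 1) / (n_bg + 2)`, and reports the binomial
#' upper-tail p-value `P(X >= k_fg)`, `X ~ Binomial(n_fg, p_bg)`, plus the
#' fold enrichment of the (smoothed) hit rates.
#'
#' @param fg,bg character vectors of foreground/background window
#'   sequences (non-empty).
#' @param motif a [pwm()] object.
#' @param smooth apply Laplace smoothing to both rates (default TRUE).
#' @return one-row data.frame: motif, n_fg, k_fg, n_bg, k_bg, p_bg, fold,
#'   p_value.
#' @export
zoops_binomial_enrichment <- function(fg, bg, motif, smooth = TRUE) {
  if (!length(fg) || !length(bg)) {
    stop("foreground and background must be non-empty")
  }
  k_fg <- sum(zoops_hits(fg, motif))
  k_bg <- sum(zoops_hits(bg, motif))
  zoops_binomial_from_counts(k_fg, length(fg), k_bg, length(bg),
                             smooth = smooth, motif = motif$name)
}

# Enrichment arithmetic on precomputed ZOOPS counts.
zoops_binomial_from_counts <- function(k_fg, n_fg, k_bg, n_bg,
                                       smooth = TRUE, motif = "motif") {
  if (smooth) {
    p_bg <- (k_bg + 1) / (n_bg + 2)
    fold <- ((k_fg + 1) / (n_fg + 2)) / p_bg
  } else {
    p_bg <- k_bg / n_bg
    fold <- (k_fg / n_fg) / p_bg
  }
  data.frame(motif = motif, n_fg = n_fg, k_fg = k_fg, n_bg = n_bg,
             k_bg = k_bg, p_bg = p_bg, fold = fold,
             p_value = binomial_tail(k_fg, n_fg, p_bg),
             stringsAsFactors = FALSE)
}

# Canonical k-mer: lexicographic minimum of a k-mer and its reverse
# complement, so both strands collapse to one key.
canonical_kmers <- function(kmers) {
  u <- unique(kmers)
  rc <- revcomp(u)
  canon <- ifelse(u <= rc, u, rc)
  canon[match(kmers, u)]
}

# Per-sequence sets of distinct canonical k-mers (the ZOOPS universe).
# Canonicalization runs once over the pooled k-mers for speed.
kmer_zoops_counts <- function(seqs, k) {
  per_seq <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    km <- substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
    unique(km[!grepl("N", km, fixed = TRUE)])
  })
  grp <- rep(seq_along(per_seq), lengths(per_seq))
  canon <- canonical_kmers(unlist(per_seq, use.names = FALSE))
  keep <- !duplicated(paste0(grp, "_", canon))
  table(canon[keep])
}

# Number of distinct canonical k-mers: (4^k + #palindromes)/2.
kmer_universe_size <- function(k) {
  pal <- if (k %% 2 == 0) 4^(k / 2) else 0
  (4^k + pal) / 2
}

#' De novo k-mer enrichment
#'
#' Every k-mer (collapsed with its reverse complement) observed in the
#' foreground or background is scored by ZOOPS counts and the smoothed
#' binomial tail of [zoops_binomial_enrichment()]. A Bonferroni-adjusted
#' p-value over the canonical k-mer universe is included. Ranking:
#' ascending p, ties broken by descending fold then lexicographic k-mer.
#'
#' @param fg,bg character vectors of window sequences.
#' @param k k-mer width (default 8).
#' @param top_m number of top-ranked k-mers to return (default 20).
#' @return data.frame of the `top_m` k-mers with counts, fold, p_value and
#'   p_bonferroni.
#' @export
denovo_kmer_enrichment <- function(fg, bg, k = 8L, top_m = 20L) {
  if (!length(fg) || !length(bg)) {
    stop("foreground and background must be non-empty")
  }
  if (k > min(nchar(c(fg, bg)))) stop("k exceeds window length")
  cnt_fg <- kmer_zoops_counts(fg, k)
  cnt_bg <- kmer_zoops_counts(bg, k)
  kmers <- union(names(cnt_fg), names(cnt_bg))
  k_fg <- as.integer(cnt_fg[kmers])
  k_fg[is.na(k_fg)] <- 0L
  k_bg <- as.integer(cnt_bg[kmers])
  k_bg[is.na(k_bg)] <- 0L
  n_fg <- length(fg)
  n_bg <- length(bg)
  p_bg <- (k_bg + 1) / (n_bg + 2)
  fold <- ((k_fg + 1) / (n_fg + 2)) / p_bg
  p <- binomial_tail(k_fg, n_fg, p_bg)
  out <- data.frame(kmer = kmers, n_fg = n_fg, k_fg = k_fg, n_bg = n_bg,
                    k_bg = k_bg, fold = fold, p_value = p,
                    p_bonferroni = pmin(p * kmer_universe_size(k), 1),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, -out$fold, out$kmer), , drop = FALSE]
  utils::head(out, top_m)
}

#' Motif enrichment across spectrum bins
#'
#' For each equal-count ratio bin, computes ZOOPS binomial enrichment of
#' each motif with the bin as foreground. The default background policy
#' uses all windows outside the bin; a fixed background set may be
#' supplied instead.
#'
#' @param windows character vector of scan windows in ascending-ratio
#'   order (aligned with `bins`).
#' @param bins integer bin assignment from [bin_equal_count()].
#' @param motifs a [pwm()] or named list of them.
#' @param background `"other_bins"` (default) or a character vector of
#'   background windows shared by all bins.
#' @return data.frame: bin, then the [zoops_binomial_enrichment()] columns
#'   per bin x motif, ordered by bin.
#' @export
enrichment_across_bins <- function(windows, bins, motifs,
                                   background = "other_bins") {
  stopifnot(length(windows) == length(bins))
  if (inherits(motifs, "pwm")) motifs <- stats::setNames(list(motifs),
                                                         motifs$name)
  bin_ids <- sort(unique(bins))
  if (!all(tabulate(bins) > 0)) stop("empty bin in assignment")
  fixed_bg <- is.character(background) && !identical(background,
                                                     "other_bins")
  rows <- list()
  for (m in names(motifs)) {
    hits <- zoops_hits(windows, motifs[[m]])
    bg_hits <- if (fixed_bg) zoops_hits(background, motifs[[m]]) else NULL
    for (b in bin_ids) {
      in_bin <- bins == b
      k_fg <- sum(hits[in_bin])
      n_fg <- sum(in_bin)
      if (fixed_bg) {
        k_bg <- sum(bg_hits)
        n_bg <- length(bg_hits)
      } else {
        k_bg <- sum(hits[!in_bin])
        n_bg <- sum(!in_bin)
      }
      if (!n_bg) stop("background empty for bin ", b)
      res <- zoops_binomial_from_counts(k_fg, n_fg, k_bg, n_bg, motif = m)
      rows[[length(rows) + 1L]] <- cbind(bin = b, res)
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$bin, out$motif), , drop = FALSE]
}
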