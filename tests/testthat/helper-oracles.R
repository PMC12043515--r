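# Independent oracles and small fixture builders used across the suite.

# Quadratic all-pairs interval merge oracle: build the full pairwise
# overlap adjacency (>= 1 bp, i.e. strict start < end crossing), take its
# transitive closure by boolean matrix powering, and span each connected
# component. Deliberately independent of the IRanges-based implementation.
merge_oracle <- function(df) {
  out <- lapply(split(df, df$chrom), function(d) {
    n <- nrow(d)
    lt <- outer(d$start, d$end, "<")       # [i, j]: start_i < end_j
    reach <- (lt & t(lt)) | diag(n) > 0
    repeat {
      closed <- ((reach + 0) %*% (reach + 0)) > 0
      if (identical(closed, reach)) break
      reach <- closed
    }
    comp <- apply(reach, 1, function(r) min(which(r)))
    do.call(rbind, lapply(unique(comp), function(cid) {
      sel <- comp == cid
      data.frame(chrom = d$chrom[1], start = min(d$start[sel]),
                 end = max(d$end[sel]))
    }))
  })
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Textbook Welch statistic: t, Welch-Satterthwaite df, two-sided p.
welch_oracle <- function(x, y) {
  vx <- var(x) / length(x)
  vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Exhaustive enumeration of P(X >= k), X = sum of n independent
# Bernoulli(p) hit indicators, over all 2^n outcomes.
binom_tail_oracle <- function(k, n, p) {
  outcomes <- as.matrix(expand.grid(rep(list(0:1), n)))
  probs <- apply(outcomes, 1, function(x) prod(ifelse(x == 1, p, 1 - p)))
  sum(probs[rowSums(outcomes) >= k])
}

# Naive O(n * L) PWM rescoring on both strands; returns the same
# (offset, strand, score) table as scan_pwm for cross-checking.
scan_oracle <- function(seq, motif) {
  L <- motif$length
  score_at <- function(s, off) {
    chars <- strsplit(substr(s, off + 1, off + L), "")[[1]]
    sum(vapply(seq_len(L), function(k) {
      i <- match(chars[k], c("A", "C", "G", "T"))
      if (is.na(i)) 0 else motif$lodds[i, k]
    }, numeric(1)))
  }
  n <- nchar(seq)
  rc <- revcomp(seq)
  rows <- list()
  for (off in 0:(n - L)) {
    sf <- score_at(seq, off)
    if (sf >= motif$threshold) {
      rows[[length(rows) + 1]] <- data.frame(offset = off, strand = "+",
                                             score = sf)
    }
    sr <- score_at(rc, off)
    if (sr >= motif$threshold) {
      rows[[length(rows) + 1]] <- data.frame(offset = n - L - off,
                                             strand = "-", score = sr)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(offset = integer(0), strand = character(0),
                      score = numeric(0)))
  }
  out <- out[order(out$offset, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Random interval set on a couple of chromosomes.
random_intervals <- function(n, span = 1000L) {
  start <- sample.int(span, n, replace = TRUE) - 1L
  width <- sample.int(50L, n, replace = TRUE)
  data.frame(chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
             start = start, end = start + width,
             stringsAsFactors = FALSE)
}

# Windows with a literal 8-mer planted at the given prevalence.
planted_kmer_windows <- function(n, prevalence, kmer, len = 100L) {
  s <- relspectra:::random_dna(n, len)
  hit <- runif(n) < prevalence
  for (i in which(hit)) {
    off <- sample.int(len - nchar(kmer) + 1L, 1L)
    substr(s[i], off, off + nchar(kmer) - 1L) <- kmer
  }
  s
}

# Run the simulate -> merge -> spectrum pipeline for one seed and
# affinity table; returns the spectrum plus peak classes in spectrum
# order.
run_spectrum_sim <- function(seed, affinity = NULL, n_peaks = 2000L) {
  args <- list(seed = seed, n_peaks = n_peaks)
  if (!is.null(affinity)) args$affinity <- affinity
  cfg <- do.call(sim_config, args)
  u <- gen_peak_universe(cfg)
  cc <- simulate_chip_counts(u$peaks, u$truth, cfg)
  pa <- u$peaks
  pa$count <- cc$counts$count_A
  pb <- u$peaks
  pb$count <- cc$counts$count_B
  sp <- ratio_spectrum(merge_peak_sets(pa, pb, cc$depths[["A"]],
                                       cc$depths[["B"]]))
  cls <- u$truth$class[match(sp$spectrum$start, u$peaks$start)]
  list(spectrum = sp, classes = cls)
}
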