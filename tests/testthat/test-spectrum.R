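# Peak spectrum: reproducibility filter, top-N, merging, ratios, bins,
# promoter annotation/ranking, extremes, Welch comparison.

test_that("reproducibility filter requires k supporting replicates", {
  peak <- function(start, score, rpkm) {
    data.frame(chrom = "chr1", start = start, end = start + 100,
               score = score, rpkm = rpkm)
  }
  reps <- list(
    rbind(peak(0, 25, 5), peak(500, 25, 5)),
    rbind(peak(10, 30, 4)),
    rbind(peak(20, 10, 5)))   # fails the score threshold
  out <- filter_reproducible(reps, score_min = 19, rpkm_min = 3, k = 2)
  expect_equal(nrow(out), 1)          # only the 0-120 cluster has 2 passes
  expect_equal(out$n_support, 2)
  out1 <- filter_reproducible(reps[1], k = 1)  # identity filter
  expect_equal(nrow(out1), 2)
  expect_error(filter_reproducible(reps, k = 4), "k <=")
})

test_that("top-N selection is score-ordered with deterministic ties", {
  peaks <- data.frame(chrom = "chr1", start = c(30, 10, 20),
                      end = c(40, 20, 30), score = c(5, 9, 7))
  top <- select_top_peaks(peaks, 2)
  expect_equal(top$score, c(9, 7))
  expect_equal(nrow(select_top_peaks(peaks, 10)), 3)
  ties <- data.frame(chrom = "chr1", start = c(50, 10, 30),
                     end = c(60, 20, 40), score = c(7, 7, 7))
  expect_equal(select_top_peaks(ties, 2)$start, c(10, 30))
})

test_that("merging unions overlapping intervals transitively", {
  a <- data.frame(chrom = "chr1", start = 100, end = 200)
  b <- data.frame(chrom = "chr1", start = c(150, 400), end = c(250, 450))
  m <- merge_peak_sets(a, b)
  expect_equal(m$start, c(100, 400))
  expect_equal(m$end, c(250, 450))
  chain <- data.frame(chrom = "chr1", start = c(0, 5, 12),
                      end = c(10, 15, 20))
  m2 <- merge_peak_sets(chain, chain[0, ])
  expect_equal(nrow(m2), 1)
  expect_equal(c(m2$start, m2$end), c(0, 20))
  # book-ended intervals do not merge
  be <- merge_peak_sets(data.frame(chrom = "chr1", start = 0, end = 10),
                        data.frame(chrom = "chr1", start = 10, end = 20))
  expect_equal(nrow(be), 2)
  # disjoint sets: sizes add
  d1 <- data.frame(chrom = "chr1", start = c(0, 100, 200),
                   end = c(10, 110, 210))
  d2 <- data.frame(chrom = "chr2", start = c(0, 100, 200, 300),
                   end = c(10, 110, 210, 310))
  expect_equal(nrow(merge_peak_sets(d1, d2)), 7)
})

test_that("merge agrees with the quadratic all-pairs oracle and is idempotent", {
  set.seed(101)
  for (i in 1:50) {
    a <- random_intervals(sample(2:100, 1))
    b <- random_intervals(sample(2:100, 1))
    got <- merge_peak_sets(a, b)[, c("chrom", "start", "end")]
    got <- got[order(got$chrom, got$start), ]
    rownames(got) <- NULL
    expect_equal(got, merge_oracle(rbind(a, b)))
    again <- merge_peak_sets(got, got)[, c("chrom", "start", "end")]
    again <- again[order(again$chrom, again$start), ]
    rownames(again) <- NULL
    expect_equal(again, got)
  }
})

test_that("merged RPKM is recomputed from counts over the merged span", {
  a <- data.frame(chrom = "chr1", start = c(0, 50), end = c(60, 100),
                  count = c(30, 30))
  b <- data.frame(chrom = "chr1", start = 20, end = 80, count = 10)
  m <- merge_peak_sets(a, b, depth_a = 10, depth_b = 5)
  expect_equal(nrow(m), 1)
  expect_equal(m$rpkm_a, 60 / (10 * 0.1))   # both A peaks pooled, 100 bp
  expect_equal(m$rpkm_b, 10 / (5 * 0.1))
})

test_that("ratio spectrum sorts, summarises ranges and handles zero RPKM", {
  merged <- data.frame(chrom = "chr1", start = c(0, 100, 200, 300),
                       end = c(50, 150, 250, 350),
                       rpkm_a = c(1, 1.5, 2, 3.5), rpkm_b = rep(1, 4))
  sp <- ratio_spectrum(merged, pseudocount = 0, ranges = list(c(1.3, 3)))
  expect_equal(sp$summary$median_ratio, 1.75)
  expect_equal(sp$summary$ranges$count, 2)
  expect_equal(sp$summary$ranges$fraction, 0.5)
  expect_false(is.unsorted(sp$spectrum$ratio))
  expect_equal(sp$spectrum$percentile, c(25, 50, 75, 100))
  # median of {1,2,3}
  m3 <- data.frame(chrom = "c", start = 0:2 * 10, end = 0:2 * 10 + 5,
                   rpkm_a = c(1, 2, 3), rpkm_b = 1)
  expect_equal(ratio_spectrum(m3, pseudocount = 0)$summary$median_ratio, 2)
  zero <- data.frame(chrom = "c", start = 0, end = 10, rpkm_a = 1,
                     rpkm_b = 0)
  expect_true(is.finite(ratio_spectrum(zero)$spectrum$ratio))
  expect_error(ratio_spectrum(merged[0, ]), "empty")
})

test_that("equal-count binning puts the remainder at the low-ratio end", {
  expect_equal(tabulate(bin_equal_count(10L, 5)), rep(2, 5))
  expect_equal(tabulate(bin_equal_count(5L, 2)), c(3, 2))
  sizes <- tabulate(bin_equal_count(8134L, 27))
  expect_equal(sum(sizes), 8134)
  expect_equal(sort(unique(sizes)), c(301, 302))
  expect_equal(sum(sizes == 302), 7)
  expect_equal(sizes[1:7], rep(302, 7))   # larger bins first
  expect_lte(max(sizes) - min(sizes), 1)
  expect_error(bin_equal_count(5L, 6), "B <= n")
})

test_that("promoter windows are strand-aware and assign the nearest TSS", {
  genes <- data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                      tss = c(10000, 10000), strand = c("+", "-"))
  peak <- data.frame(chrom = "chr1", start = 9000, end = 9200)
  ann_p <- annotate_promoters(peak, genes[1, ])
  expect_equal(ann_p$gene_id, "gp")   # window [8500, 10500)
  expect_equal(ann_p$tss_distance, 9100 - 10000)
  # minus strand: window [9500, 11500); a peak at [9000,9200) misses it
  expect_equal(nrow(annotate_promoters(peak, genes[2, ])), 0)
  peak2 <- data.frame(chrom = "chr1", start = 9600, end = 9700)
  ann_m <- annotate_promoters(peak2, genes[2, ])
  expect_equal(ann_m$gene_id, "gm")
  expect_equal(ann_m$tss_distance, 10000 - 9650)
  # several windows: nearest TSS wins
  two <- data.frame(gene_id = c("near", "far"), chrom = "chr1",
                    tss = c(9300, 10400), strand = "+")
  expect_equal(annotate_promoters(peak, two)$gene_id, "near")
  none <- data.frame(chrom = "chr1", start = 50000, end = 50100)
  expect_equal(nrow(annotate_promoters(none, genes)), 0)
})

test_that("promoter ranking is ratio-descending with percentiles", {
  pp <- data.frame(chrom = "chr1", start = c(0, 10, 20),
                   end = c(5, 15, 25), ratio = c(5, 9, 1))
  rk <- rank_promoter_peaks(pp)
  expect_equal(rk$ratio, c(9, 5, 1))
  expect_equal(rk$rank, 1:3)
  expect_equal(rk$rank_percentile, (1:3) / 3 * 100)
  set.seed(1)
  big <- rank_promoter_peaks(
    data.frame(chrom = "c", start = seq_len(1050) * 10,
               end = seq_len(1050) * 10 + 5, ratio = runif(1050)))
  expect_equal(big$rank_percentile[big$rank == 15], 15 / 1050 * 100)
  tied <- data.frame(chrom = "chr1", start = c(30, 10), end = c(35, 15),
                     ratio = c(2, 2))
  expect_equal(rank_promoter_peaks(tied)$start, c(10, 30))
})

test_that("extreme-set selection returns top, bottom and centred middle", {
  df <- data.frame(chrom = "c", start = seq_len(1000) * 10,
                   end = seq_len(1000) * 10 + 5, ratio = seq_len(1000))
  top <- select_extremes(df, 300, "top")
  expect_equal(range(top$ratio), c(701, 1000))
  bottom <- select_extremes(df, 300, "bottom")
  expect_equal(range(bottom$ratio), c(1, 300))
  middle <- select_extremes(df, 300, "middle")
  expect_equal(sort(middle$ratio), 351:650)
  expect_equal(nrow(select_extremes(df, 1000, "middle")), 1000)
  expect_error(select_extremes(df, 1001, "top"), "k <= n")
})

test_that("Welch comparison matches the textbook formula and handles degeneracy", {
  x <- c(0.1, 0.2, 0.3, 0.2)
  y <- c(1.1, 1.3, 1.2, 1.4)
  got <- welch_group_compare(x, y)
  ora <- welch_oracle(x, y)
  expect_equal(got$t, ora$t, tolerance = 1e-10)
  expect_equal(got$df, ora$df, tolerance = 1e-10)
  expect_equal(got$p, ora$p, tolerance = 1e-10)
  set.seed(7)
  for (i in 1:20) {
    a <- rnorm(sample(3:12, 1))
    b <- rnorm(sample(3:12, 1), mean = runif(1, -1, 1))
    expect_equal(welch_group_compare(a, b)$p, welch_oracle(a, b)$p,
                 tolerance = 1e-10)
  }
  same <- welch_group_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  degen <- welch_group_compare(c(2, 2), c(2, 2))
  expect_true(degen$degenerate)
  expect_equal(degen$p, 1)
})

test_that("symmetric simulations centre the spectrum near ratio 1", {
  res <- run_spectrum_sim(seed = 21, n_peaks = 2000)
  expect_gt(res$spectrum$summary$median_ratio, 0.95)
  expect_lt(res$spectrum$summary$median_ratio, 1.05)
})

test_that("factor-A-favoured peaks concentrate in the top ratio decile", {
  res <- run_spectrum_sim(
    seed = 22,
    affinity = list(consensus = c(A = 1, B = 1),
                    nonconsensus = c(A = 4, B = 1),
                    background = c(A = 0.2, B = 0.2)))
  n <- nrow(res$spectrum$spectrum)
  dec <- floor(n / 10)
  top_frac <- mean(res$classes[(n - dec + 1):n] == "nonconsensus")
  bot_frac <- mean(res$classes[seq_len(dec)] == "nonconsensus")
  expect_gte(top_frac, 2 * max(bot_frac, 1e-9))
})
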