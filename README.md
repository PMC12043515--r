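# relspectra

Comparative binding analytics for transcription-factor paralogs.

## What this is for

Paralogous transcription factors -- the motivating system is the NF-κB
pair Rel and RelA in macrophages -- bind nearly identical DNA motifs yet
drive different genes. Attributing function to one paralog takes several
measurements analysed jointly, and `relspectra` implements that joint
analysis for R users working with such data:

* **Knockout dependence** from nascent-transcript RNA-seq: RPKM
  normalization (`count / (depth[M] × length[kb])`), an expressed-gene
  filter (RPKM > 3), fold induction, and the fold-change dependence
  rule (gene dependent ⇔ KO/WT RPKM ratio ≤ 1/10 at a stimulated
  timepoint).
* **Occupancy spectra** from paralog ChIP-seq: replicate
  reproducibility filtering (score > 19, RPKM > 3 in k of n
  replicates), top-N peak selection, interval merging (≥ 1 bp overlap,
  transitive), per-peak RPKM ratios `(rpkm_A + ε)/(rpkm_B + ε)` with
  ε = 0.1, equal-count binning, promoter annotation in a strand-aware
  [TSS − 1500, TSS + 500) window, ranking, extreme-set selection and
  Welch's two-sided t-test between groups.
* **Motif enrichment**: PWM log-odds scanning of both strands over
  ±200-bp peak windows, ZOOPS counting (zero or one occurrence per
  sequence), binomial enrichment `P(X ≥ k_fg)` with a Laplace-smoothed
  background rate, de novo k-mer discovery with reverse-complement
  collapsing and Bonferroni correction, and enrichment profiles across
  spectrum bins.
* **PBM z-score mining**: z-normalization, pattern-containment subsets,
  strong-binding fractions (z > 4) and threshold splits (z > 9 vs
  z < 9).
* **Dissociation kinetics**: single-exponential off-rate fits
  `S(t) = R0·e^(−koff·t) (+ c)`, shared-koff global fits across curves,
  half-lives `t½ = ln(2)/koff`, t₀ normalization to 100% and replicate
  mean ± SD profiles.
* **Residue scanning** on clade-labelled paralog alignments: conserved
  core, mismatch counts, paralog-distinguishing columns, paralog-bias
  scores of unassigned sequences, and clade-restricted divergence
  detection (with an optional residue-class mode that sees, e.g., a
  Cys-versus-{Tyr,Phe} contrast).

A synthetic-data module generates every input type with planted ground
truth (motif classes and offsets, dependence factors, true off-rates,
diagnostic alignment columns), so the whole pipeline is testable without
any external download.

## Worked example

Simulate a 2,000-peak universe in which one motif class binds factor A
four-fold more strongly, build the ratio spectrum, and test whether the
favoured motif is enriched in the top-300 peaks:

```r
library(relspectra)

cfg <- sim_config(seed = 1, n_peaks = 2000,
                  affinity = list(consensus    = c(A = 1,   B = 1),
                                  nonconsensus = c(A = 4,   B = 1),
                                  background   = c(A = 0.2, B = 0.2)))
u  <- gen_peak_universe(cfg)
cc <- simulate_chip_counts(u$peaks, u$truth, cfg)
pa <- u$peaks; pa$count <- cc$counts$count_A
pb <- u$peaks; pb$count <- cc$counts$count_B

sp <- ratio_spectrum(merge_peak_sets(pa, pb, 10, 10), ranges = list(c(1.3, 3)))
sp
#> Ratio spectrum over 2000 merged peaks
#>   median ratio: 1.376
#>   ratio in [1.3, 3]: 592 peaks (29.6%)

top <- select_extremes(sp, 300, "top")
win <- extract_scan_windows(u$peaks, u$sequences)         # ±200 bp windows
ids <- u$peaks$peak_id[match(top$start, u$peaks$start)]
zoops_binomial_enrichment(win[ids], win[setdiff(names(win), ids)],
                          pwm_from_consensus("GGGGGTTTTT"))
#>        motif n_fg k_fg n_bg k_bg      p_bg     fold       p_value
#> 1 GGGGGTTTTT  300  281 1700  283 0.1668625 5.596073 5.125557e-191
```

The planted factor-A-favoured motif sits in 281 of the 300 top-ratio
peaks but only 283 of the other 1,700 -- a 5.6-fold ZOOPS enrichment --
while the spectrum median (1.38) reflects the asymmetric affinity table.
Kinetics work the same way:

```r
tr  <- simulate_decay_traces(data.frame(trace = "consensus", R0 = 100, koff = 0.05),
                             relative_noise = 0.05, seed = 2)
fit <- fit_exponential_dissociation(tr)
fit
#> Exponential dissociation fit
#>   koff  = 0.0491364 per time unit
#>   t1/2  = 14.1066 time units
#>   amplitude(s): 99.384
```

The fitted off-rate recovers the planted 0.05/min within the 5%
measurement noise, and the reported half-life is exactly `ln(2)/koff`.

See `vignettes/paralog-binding-analytics.Rmd` for the models,
assumptions, parameter defaults and numerical choices.

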