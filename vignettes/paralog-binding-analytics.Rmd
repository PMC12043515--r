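---
title: "Comparative binding analytics for transcription-factor paralogs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative binding analytics for transcription-factor paralogs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relspectra)
```

## The scientific problem

Closely related transcription-factor paralogs -- the motivating case is
the NF-κB family pair Rel and RelA -- often recognise nearly identical
DNA motifs yet support distinct regulatory programs. Telling their
contributions apart requires several complementary measurements, each
with its own analysis:

* **Knockout dependence.** Nascent-transcript RNA-seq in wild-type and
  knockout cells, stimulated over a short time course, identifies the
  genes whose induction genuinely requires one paralog.
* **Genomic occupancy spectra.** ChIP-seq for both paralogs over a
  shared peak universe yields a per-peak RPKM ratio; ordering peaks by
  that ratio produces a *spectrum* whose extremes mark selective
  binding.
* **Motif preferences.** Enrichment of consensus and nonconsensus κB
  motifs across the spectrum, plus de novo k-mer discovery in extreme
  peak sets, connects selective occupancy to sequence.
* **Intrinsic affinity.** Protein-binding microarrays (relative
  preferences, as per-oligo z-scores) and dissociation kinetics
  (SPR sensorgrams, EMSA competition chases) quantify binding strength;
  the dissociation rate `koff` maps to a half-life `t1/2 = ln(2)/koff`.
* **Sequence determinants.** Aligning both paralogs across many species
  and asking which residues distinguish them -- and in which clades --
  points to the substitutions behind an affinity difference.

`relspectra` implements each stage as composable functions over plain
data structures (data frames, matrices), and pairs them with seeded
generators that produce synthetic inputs with planted ground truth, so
every stage can be validated end to end without external data.

## Dependence classification

RPKM is computed exactly as `count / (depth[Mreads] * length[kb])`
(`compute_rpkm()`). Genes are kept when their replicate-averaged RPKM
exceeds 3 at some stimulated timepoint in wild-type cells
(`filter_expressed()`; the threshold is an argument). Fold induction
divides mean stimulated RPKM by mean unstimulated RPKM; dependence uses
the fold-change rule: a gene is dependent when the KO/WT RPKM ratio is
at most 1/10 at *some* stimulated timepoint (`classify_dependence()`).
Where the design leaves open whether one or both stimulated timepoints
must qualify, we accept either, which is the permissive reading; callers
can tighten it by passing a single timepoint.

All ratios share an additive pseudocount of 0.1 RPKM. This bounds
log-ratios when a condition is silent and is negligible two orders of
magnitude below the expressed-gene threshold. We do not compute
shrinkage-based differential-expression statistics; the dependence call
is deliberately the transparent fold rule, and its operating
characteristics are measured on synthetic data (sensitivity and
specificity both at or near 1 for genes with 1/100 dependence and
expression above the filter -- see `tests/testthat/test-acceptance.R`,
which computes them).

## The occupancy spectrum

Peaks are BED-style 0-based half-open intervals. The pipeline follows
the field-standard sequence of steps after peak calling (peak calling
itself is out of scope; peak tables are inputs):

1. `filter_reproducible()`: keep regions supported by at least *k* of
   *n* replicates with peak score > 19 and RPKM > 3 (defaults; both are
   arguments).
2. `select_top_peaks()`: the strongest *N* peaks per factor, ties at
   the boundary broken by coordinate so selection is deterministic.
3. `merge_peak_sets()`: transitive union of the two sets. Merging
   requires at least 1 bp of overlap -- book-ended intervals stay
   separate. Per-factor RPKM of a merged span is recomputed from the
   constituent counts over the merged length.
4. `ratio_spectrum()`: `ratio = (rpkm_a + 0.1)/(rpkm_b + 0.1)`, sorted
   ascending with percentile positions, plus closed-interval range
   counts (e.g. how many peaks fall in [1.3, 3]) and cutoff counts.
5. `bin_equal_count()`: *B* contiguous bins whose sizes differ by at
   most one. "Equal bins" is read as equal-count over the ratio-sorted
   spectrum; heavy-tailed ratio distributions make equal-width bins
   near-empty at the extremes, which is why equal-count is the default
   interpretation. The remainder bins sit deterministically at the
   low-ratio end: 8,134 peaks in 27 bins gives seven bins of 302 then
   twenty of 301.
6. `annotate_promoters()`: strand-aware window `[TSS - 1500, TSS + 500)`
   in gene orientation; a peak overlapping several windows goes to the
   nearest TSS. `rank_promoter_peaks()` ranks by descending ratio with
   rank percentiles.
7. `select_extremes()`: top/bottom/middle *k* of the spectrum, the
   middle window centred via offset `floor((n-k)/2)`.
8. `welch_group_compare()`: Welch's two-sample t-test (unequal
   variances, Welch--Satterthwaite degrees of freedom, two-sided). Two
   zero-variance groups are flagged degenerate rather than tested.

## Motif scanning and enrichment

`pwm()` builds a position probability matrix with a log2-odds scoring
matrix against a background composition; the hit threshold defaults to
60% of the maximum attainable score (configurable), and
`pwm_from_consensus()` turns an IUPAC consensus into a near-exact-match
scanner. Scanning covers both strands; `N` bases score zero
(background). Windows are ±200 bp around the peak center, clipped at
chromosome ends.

Enrichment uses ZOOPS counting -- a sequence contributes at most one
hit however many matches it contains -- and a binomial upper tail:
`k_fg` of `n_fg` foreground sequences hit, against a background hit
probability estimated with Laplace smoothing `(k_bg + 1)/(n_bg + 2)` so
an empty background never yields a zero probability. De novo discovery
(`denovo_kmer_enrichment()`) scores every k-mer collapsed with its
reverse complement the same way and reports Bonferroni-adjusted
p-values over the canonical k-mer universe (`(4^k + 4^{k/2})/2` for
even k) -- conservative and assumption-free. Ranking ties break by
descending fold then lexicographic k-mer, so output order is stable.

`enrichment_across_bins()` profiles motifs across the spectrum bins.
The default background for a bin is *all windows outside it*. The
motivating study used HOMER's internal background model, which is not
reconstructable from its description; absolute p-values from this
module are therefore comparable within a run but not to published
values -- only orderings and trends across bins are meaningful, and
that is what the tests assert.

## PBM z-scores

`zscore_normalize()` is the plain `(x - mean)/sd` with the sample
standard deviation, refusing degenerate zero-spread input.
Pattern-containment subsets default to the printed strand (`given`),
since arrays report a specific oligo strand; `both` additionally
matches the reverse complement. Strong-binding fractions and the z = 9
group split use strict inequalities; a value exactly at the threshold
goes to the low group, because the motivating comparisons are printed
as strict `> 9` and `< 9` with no equality case.

## Dissociation kinetics

Competition chases and SPR dissociation phases are fitted as
`S(t) = R0 * exp(-koff * t)` with an optional constant floor
(`fit_exponential_dissociation()`). Rebinding of dissociated protein to
the labelled probe is assumed negligible under the large unlabelled
competitor excess, which is what justifies the single-exponential form.
Fits initialize from a log-linear regression on background-subtracted
signal and run Levenberg--Marquardt least squares to a 1e-10 relative
tolerance (maximum 500 iterations); `koff <= 0` or non-convergence is
reported as a flagged failure, never silently. `t1/2 = ln(2)/koff`
holds to machine precision by construction. For multi-concentration SPR
data, `fit_dissociation_global()` shares one `koff` across curves with
per-curve amplitudes: amplitudes are profiled out linearly and `koff`
is found by one-dimensional minimization on the log scale, the standard
1:1 dissociation treatment. Replicate EMSA profiles are normalized to
100% at t = 0 and aggregated as per-timepoint mean ± sample SD
(`normalize_decay()`, `aggregate_replicates()`); profiles can also be
fitted, supporting both reporting modes.

## Residue scanning

Alignments are character matrices with metadata (species, paralog A/B
or unassigned, clade; clades must partition species). Group consensus
at a column requires a single residue to reach an identity threshold
among non-gap entries; a group with more than 50% gaps is ineligible,
which avoids spurious contrasts at indel-rich positions. Gaps count as
mismatches against the conserved core. Defaults: conserved core
θ = 0.95, within-paralog consensus θ = 0.90 -- chosen once so that
the synthetic 159-conserved-column and 22-distinguishing-column
scenarios behave as designed; no published thresholds exist for these
quantities.

`clade_restricted_divergence()` flags columns where the paralogs hold
different confident states inside a focal clade while sharing one state
in every control clade. The default compares residue identities; the
`class` mode runs the same logic over a fixed residue grouping
(aliphatic, aromatic, positive, negative, polar, and cysteine/glycine/
proline as singletons), which is what makes a Cys-versus-{Tyr,Phe}
contrast detectable as "cysteine differs from one shared aromatic
state". Cysteine is deliberately its own group for that reason.
Position numbering is alignment-based; mapping to a reference numbering
(e.g. an RHR coordinate system) is the caller's responsibility via
`region_restrict()` and their own offset table.

## What the generators emulate -- and what they do not

The synthetic-data module generates every input with known truth:

* **Peak universe**: non-overlapping peaks on one synthetic
  chromosome, each carrying exactly one planted motif instance on a
  uniformly chosen strand (or none for background class), at a
  configurable GC content. Default 2,000 peaks of 400 bp.
* **ChIP counts**: expected count = depth × class weight × length ×
  scale, Poisson or negative-binomial (dispersion 0.1 by default --
  mild overdispersion typical of count data). The affinity table is the
  planted truth: symmetric weights give a ratio spectrum centred on 1;
  a 4× factor-A weight on one class drives that class into the top
  decile.
* **Expression time course**: 0/60/120-min design, two replicates,
  lognormal baselines, a planted induced fraction and a planted
  dependent fraction whose stimulated KO expression is scaled by the
  dependence factor.
* **PBM tables**: oligo intensity = max window affinity + Gaussian
  noise, z-scored per protein.
* **Decay traces**: exact exponential plus absolute or relative
  Gaussian noise on a grid that defaults to the 5-point chase
  {0, 1, 5, 10, 20} min.
* **Paralog alignments**: a 16-mammal/11-nonmammal species panel by
  default, with background columns perturbed by a per-site substitution
  process and three kinds of planted truth (invariant columns,
  paralog-contrast columns, clade-restricted diagnostic columns).
  Planted columns are exact: the residues they model are strictly
  conserved within their groups in real comparative panels -- that
  conservation is what makes them diagnostic -- so the substitution
  noise models the *other* columns, where false positives would arise.

The generators do not simulate reads (no FASTQ, fragment sizes or
mappability bias), array spatial artefacts, alignment errors or
phylogenetic correlation between species; passing tests demonstrate
correctness of the analytics under the stated generative models, not
robustness to every artefact of real data.

## Problem sizes and numerical choices

The validation suite runs at the scales the analyses target: 2,000-peak
spectra over 20 seeds for median-ratio calibration; 300 foreground and
300 background windows of 100 bp at 80%/5% planted prevalence over 100
seeds for discovery power; 200 seeded fits on the 5-point kinetic grid;
100 seeded alignments for scanner recall; 1,000 random interval
instances against a quadratic all-pairs merge oracle; exhaustive
binomial enumeration up to n = 12. These sizes give stable Monte-Carlo
estimates while keeping the whole suite quick to run.

Key fixed choices, in one place: pseudocount 0.1 RPKM everywhere a
ratio is formed; ≥ 1 bp overlap for merging; Laplace smoothing for
background hit rates; PWM threshold 60% of maximum score; Bonferroni
for k-mer multiplicity; strict thresholds with equality going to the
low group; remainder bins at the low-ratio end; ties broken by genomic
coordinate; fit tolerance 1e-10 with log-linear initialization.

## Limitations

Absolute motif enrichment p-values depend on the background policy and
are not comparable to HOMER's; peak calling, read alignment and
phylogeny estimation are upstream of this package; the dependence rule
is a fold-change classifier, not an inferential test; and the residue
scanner assumes a trustworthy input alignment -- misalignment shows up
as spurious divergence that no threshold fully suppresses.
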