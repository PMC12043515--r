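# Seeded synthetic-data generators with planted ground truth.
#
# Every generator takes an explicit integer seed (or a sim_config carrying
# one) and is bit-reproducible: same configuration, same output. The
# generators emulate the study designs the analysis modules consume --
# two-factor ChIP read counts over peaks with planted kB-like motifs,
# WT/knockout induction time courses, PBM oligo intensity tables,
# exponential dissociation traces, and clade-structured paralog alignments.

#' Simulation configuration
#'
#' Bundles the knobs shared by the sequence/count generators. Defaults
#' describe the baseline synthetic study: 2,000 peaks of 400 bp at GC 0.5,
#' two factors sequenced to 10 M reads each, negative-binomial counts with
#' mild overdispersion, and three peak classes (consensus motif,
#' nonconsensus motif, background without a planted site).
#'
#' @param seed integer seed; drives every random draw.
#' @param n_peaks number of peaks to simulate.
#' @param peak_length_bp peak width in bp.
#' @param gc_content GC fraction in `[0,1]` for background sequence.
#' @param depth_per_factor named numeric, library depth in million reads per
#'   factor.
#' @param motifs named character, IUPAC motif per planted class. Classes not
#'   listed here (e.g. `"background"`) get no planted site.
#' @param affinity named list: per class, named numeric binding weight per
#'   factor (dimensionless, >= 0). Expected RPKM of a peak is
#'   `weight * read_scale`.
#' @param class_prob named numeric, sampling probability per class.
#' @param read_scale expected count per (million reads x kb x unit weight).
#' @param noise_model `"poisson"` or `"negative_binomial"`.
#' @param dispersion negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); ignored for Poisson.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_peaks = 2000L,
                       peak_length_bp = 400L,
                       gc_content = 0.5,
                       depth_per_factor = c(A = 10, B = 10),
                       motifs = c(consensus = "GGGAATTTCC",
                                  nonconsensus = "GGGGGTTTTT"),
                       affinity = list(
                         consensus = c(A = 1, B = 1),
                         nonconsensus = c(A = 1, B = 1),
                         background = c(A = 0.2, B = 0.2)),
                       class_prob = c(consensus = 0.4,
                                      nonconsensus = 0.3,
                                      background = 0.3),
                       read_scale = 10,
                       noise_model = c("negative_binomial", "poisson"),
                       dispersion = 0.1) {
  noise_model <- match.arg(noise_model)
  stopifnot(length(seed) == 1L, is.finite(seed),
            n_peaks >= 1L, peak_length_bp >= 20L,
            gc_content >= 0, gc_content <= 1,
            all(depth_per_factor >= 0),
            dispersion >= 0, read_scale > 0,
            abs(sum(class_prob) - 1) < 1e-8)
  for (m in motifs) assert_iupac(m)
  for (cls in names(affinity)) {
    w <- affinity[[cls]]
    if (any(w < 0)) stop("binding weights must be >= 0 (class ", cls, ")")
  }
  structure(list(
    seed = as.integer(seed), n_peaks = as.integer(n_peaks),
    peak_length_bp = as.integer(peak_length_bp), gc_content = gc_content,
    depth_per_factor = depth_per_factor, motifs = motifs,
    affinity = affinity, class_prob = class_prob, read_scale = read_scale,
    noise_model = noise_model, dispersion = dispersion
  ), class = "sim_config")
}

# Deterministic sub-stream: offset the master seed per generator so the
# same cfg can feed several generators without correlated draws.
sub_seed <- function(seed, offset) {
  set.seed((as.integer(seed) + as.integer(offset)) %% .Machine$integer.max)
}

draw_counts <- function(mu, cfg) {
  mu <- pmax(mu, 0)
  if (cfg$noise_model == "poisson" || cfg$dispersion == 0) {
    stats::rpois(length(mu), mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion)
  }
}

#' Simulate a peak universe with planted motifs
#'
#' Lays `n_peaks` non-overlapping peaks along one synthetic chromosome.
#' Each peak is assigned a motif class; classes with a motif in
#' `cfg$motifs` receive exactly one planted instance at a uniformly chosen
#' offset and strand, recorded in the truth table. Background classes get
#' pure random sequence at the configured GC content.
#'
#' @param cfg a [sim_config()].
#' @param gap_bp spacing between consecutive peaks.
#' @return list with `sequences` (named character, one chromosome),
#'   `peaks` (BED-like data.frame: chrom, start, end, peak_id, score) and
#'   `truth` (data.frame: peak_id, class, motif, motif_offset within the
#'   peak, motif_start genomic, strand; `NA` offsets for unplanted classes).
#' @export
gen_peak_universe <- function(cfg, gap_bp = 200L) {
  stopifnot(inherits(cfg, "sim_config"))
  sub_seed(cfg$seed, 101L)
  n <- cfg$n_peaks
  L <- cfg$peak_length_bp
  classes <- sample(names(cfg$class_prob), n, replace = TRUE,
                    prob = cfg$class_prob)
  starts <- (seq_len(n) - 1L) * (L + gap_bp)
  seqs <- random_dna(n, L, cfg$gc_content)
  offs <- rep(NA_integer_, n)
  strands <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    motif <- cfg$motifs[classes[i]]
    if (is.na(motif)) next
    inst <- sample_iupac(motif)
    ml <- nchar(inst)
    off <- sample.int(L - ml + 1L, 1L) - 1L
    strand <- sample(c("+", "-"), 1L)
    if (strand == "-") inst <- revcomp(inst)
    substr(seqs[i], off + 1L, off + ml) <- inst
    offs[i] <- off
    strands[i] <- strand
  }
  genome <- paste(vapply(seq_len(n), function(i) {
    paste0(seqs[i], strrep("N", gap_bp))
  }, character(1)), collapse = "")
  ids <- sprintf("peak_%05d", seq_len(n))
  peaks <- data.frame(
    chrom = "sim1", start = starts, end = starts + L,
    peak_id = ids, score = round(stats::runif(n, 20, 100), 3),
    stringsAsFactors = FALSE)
  truth <- data.frame(
    peak_id = ids, class = classes,
    motif = unname(cfg$motifs[classes]),
    motif_offset = offs,
    motif_start = starts + offs,
    strand = strands, stringsAsFactors = FALSE)
  list(sequences = c(sim1 = genome), peaks = peaks, truth = truth)
}

#' Simulate two-factor ChIP read counts over peaks
#'
#' Expected count for factor f at peak i is
#' `depth_f (M reads) * weight_f(class_i) * length_i (kb) * read_scale`,
#' so the expected RPKM equals `weight * read_scale` and the A/B RPKM
#' ratio directly reflects the affinity table. Counts are noised per
#' `cfg$noise_model`.
#'
#' @param peaks,truth as returned by [gen_peak_universe()].
#' @param cfg a [sim_config()]; `cfg$affinity` must cover every class in
#'   `truth$class`.
#' @return list with `counts` (data.frame peak_id, count_A, count_B, rpkm_A,
#'   rpkm_B) and `depths` (named numeric, million reads).
#' @export
simulate_chip_counts <- function(peaks, truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  missing_cls <- setdiff(unique(truth$class), names(cfg$affinity))
  if (length(missing_cls)) {
    stop("affinity table lacks class weight(s): ",
         paste(missing_cls, collapse = ", "))
  }
  sub_seed(cfg$seed, 202L)
  len_kb <- (peaks$end - peaks$start) / 1000
  depths <- cfg$depth_per_factor
  counts <- data.frame(peak_id = peaks$peak_id, stringsAsFactors = FALSE)
  for (f in names(depths)) {
    w <- vapply(truth$class, function(cl) cfg$affinity[[cl]][[f]], numeric(1))
    mu <- depths[[f]] * w * len_kb * cfg$read_scale
    cnt <- draw_counts(mu, cfg)
    counts[[paste0("count_", f)]] <- cnt
    counts[[paste0("rpkm_", f)]] <- if (depths[[f]] > 0) {
      cnt / (depths[[f]] * len_kb)
    } else {
      rep(0, length(cnt))
    }
  }
  list(counts = counts, depths = depths)
}

#' Simulate a WT/KO induction time-course count table
#'
#' Emulates a nascent-transcript RNA-seq design: genes with lognormal
#' baseline expression, a subset induced upon stimulation, and a subset of
#' the induced genes dependent on the knocked-out factor (their stimulated
#' expression in KO is scaled by `dependence_factor`). Unstimulated
#' expression is genotype-independent.
#'
#' @param cfg a [sim_config()] (seed, depth of factor "A", noise model).
#' @param n_genes number of genes.
#' @param timepoints numeric, minutes; must include 0.
#' @param replicates biological replicates per genotype x timepoint.
#' @param frac_induced fraction of genes induced at stimulated timepoints.
#' @param frac_dependent fraction of induced genes that are KO-dependent.
#' @param dependence_factor KO/WT expression ratio at stimulated
#'   timepoints for dependent genes (e.g. 0.01 for 1/100 dependence).
#' @param induction_log2_range log2 fold-induction range for induced genes.
#' @return list with `counts` (gene x sample integer matrix), `meta`
#'   (data.frame sample, genotype, timepoint, replicate, depth), `length_kb`
#'   (named numeric) and `truth` (data.frame gene, baseline_rpkm, induction,
#'   dependence_factor, dependent).
#' @export
simulate_expression_counts <- function(cfg,
                                       n_genes = 500L,
                                       timepoints = c(0, 60, 120),
                                       replicates = 2L,
                                       frac_induced = 0.3,
                                       frac_dependent = 0.1,
                                       dependence_factor = 0.01,
                                       induction_log2_range = c(2.5, 10)) {
  stopifnot(inherits(cfg, "sim_config"), replicates >= 1L,
            length(timepoints) >= 1L, 0 %in% timepoints,
            n_genes >= 1L)
  sub_seed(cfg$seed, 303L)
  genes <- sprintf("gene_%04d", seq_len(n_genes))
  baseline <- stats::rlnorm(n_genes, meanlog = log(5), sdlog = 1)
  induced <- stats::runif(n_genes) < frac_induced
  induction <- ifelse(
    induced,
    2^stats::runif(n_genes, induction_log2_range[1], induction_log2_range[2]),
    1)
  dependent <- induced & (stats::runif(n_genes) < frac_dependent)
  depf <- ifelse(dependent, dependence_factor, 1)
  length_kb <- stats::rlnorm(n_genes, meanlog = log(2), sdlog = 0.5)
  names(length_kb) <- genes

  design <- expand.grid(replicate = seq_len(replicates),
                        timepoint = sort(timepoints),
                        genotype = c("WT", "KO"),
                        stringsAsFactors = FALSE)
  design$sample <- sprintf("%s_t%03d_r%d", design$genotype,
                           design$timepoint, design$replicate)
  depth <- unname(cfg$depth_per_factor[1])
  design$depth <- depth

  counts <- matrix(0L, n_genes, nrow(design),
                   dimnames = list(genes, design$sample))
  for (j in seq_len(nrow(design))) {
    stim <- design$timepoint[j] > 0
    rpkm_expect <- baseline *
      (if (stim) induction else 1) *
      (if (stim && design$genotype[j] == "KO") depf else 1)
    mu <- rpkm_expect * depth * length_kb
    counts[, j] <- draw_counts(mu, cfg)
  }
  truth <- data.frame(gene = genes, baseline_rpkm = baseline,
                      induction = induction, dependence_factor = depf,
                      dependent = dependent, stringsAsFactors = FALSE)
  list(counts = counts, meta = design[, c("sample", "genotype", "timepoint",
                                          "replicate", "depth")],
       length_kb = length_kb, truth = truth)
}

#' Affinity function over k-mer windows built from literal patterns
#'
#' Returns a function mapping DNA windows to affinities: the maximum weight
#' of any listed pattern contained in the window, plus `base`.
#'
#' @param patterns character vector of DNA substrings.
#' @param weights numeric vector, same length.
#' @param base baseline affinity for windows containing no pattern.
#' @return function(character) -> numeric.
#' @export
pbm_affinity_patterns <- function(patterns, weights, base = 0) {
  stopifnot(length(patterns) == length(weights))
  function(windows) {
    a <- rep(base, length(windows))
    for (i in seq_along(patterns)) {
      hit <- grepl(patterns[i], windows, fixed = TRUE)
      a[hit] <- pmax(a[hit], base + weights[i])
    }
    a
  }
}

#' Simulate a PBM oligo intensity/z-score table
#'
#' Each oligo's intensity for a protein is the maximum affinity over all
#' k-mer windows of the oligo plus Gaussian noise; z-scores are computed
#' per protein over all oligos (z = 0 everywhere when the intensity spread
#' is zero).
#'
#' @param cfg a [sim_config()] (seed, gc_content).
#' @param affinity_fn a function(character windows) -> numeric, or a named
#'   list of such functions (one per protein).
#' @param proteins protein labels; recycled over `affinity_fn` if a single
#'   function is given.
#' @param n_oligos,oligo_len table dimensions.
#' @param k window width the affinity function sees.
#' @param noise_sd Gaussian intensity noise.
#' @return data.frame: sequence, then `intensity_<p>` and `z_<p>` per
#'   protein.
#' @export
simulate_pbm_table <- function(cfg, affinity_fn,
                               proteins = c("A", "B"),
                               n_oligos = 2000L, oligo_len = 36L,
                               k = 10L, noise_sd = 1) {
  stopifnot(inherits(cfg, "sim_config"), oligo_len >= k)
  if (is.function(affinity_fn)) {
    affinity_fn <- stats::setNames(rep(list(affinity_fn), length(proteins)),
                                   proteins)
  }
  stopifnot(all(proteins %in% names(affinity_fn)))
  sub_seed(cfg$seed, 404L)
  oligos <- random_dna(n_oligos, oligo_len, cfg$gc_content)
  n_win <- oligo_len - k + 1L
  windows <- substring(rep(oligos, each = n_win),
                       rep(seq_len(n_win), n_oligos),
                       rep(seq_len(n_win), n_oligos) + k - 1L)
  out <- data.frame(sequence = oligos, stringsAsFactors = FALSE)
  grp <- rep(seq_len(n_oligos), each = n_win)
  for (p in proteins) {
    aff <- affinity_fn[[p]](windows)
    base_int <- vapply(split(aff, grp), max, numeric(1))
    intensity <- base_int + stats::rnorm(n_oligos, sd = noise_sd)
    s <- stats::sd(intensity)
    z <- if (s == 0) rep(0, n_oligos) else (intensity - mean(intensity)) / s
    out[[paste0("intensity_", p)]] <- intensity
    out[[paste0("z_", p)]] <- z
  }
  out
}

#' Simulate exponential dissociation traces
#'
#' Signal follows `R0 * exp(-koff * t) + baseline` plus Gaussian noise,
#' either absolute (`noise_sd`) or relative to the noiseless signal
#' (`relative_noise`, e.g. 0.05 for 5%).
#'
#' @param truth data.frame with columns trace, R0, koff (> 0) and
#'   optionally baseline (default 0).
#' @param time numeric grid, sorted ascending and including 0 (minutes for
#'   EMSA-style chases, seconds for SPR).
#' @param replicates traces per truth row.
#' @param noise_sd absolute Gaussian noise SD.
#' @param relative_noise relative noise fraction (SD = fraction x signal).
#' @param seed integer seed.
#' @return data.frame: trace, replicate, time, signal.
#' @export
simulate_decay_traces <- function(truth, time = c(0, 1, 5, 10, 20),
                                  replicates = 1L, noise_sd = 0,
                                  relative_noise = 0, seed = 1L) {
  stopifnot(is.data.frame(truth), all(c("trace", "R0", "koff") %in%
                                        names(truth)))
  if (any(truth$koff <= 0)) stop("koff must be > 0")
  if (is.unsorted(time, strictly = TRUE)) {
    stop("time grid must be strictly increasing")
  }
  if (!0 %in% time) stop("time grid must include t = 0")
  if (is.null(truth$baseline)) truth$baseline <- 0
  set.seed(as.integer(seed))
  rows <- lapply(seq_len(nrow(truth)), function(i) {
    do.call(rbind, lapply(seq_len(replicates), function(r) {
      s0 <- truth$R0[i] * exp(-truth$koff[i] * time) + truth$baseline[i]
      sd_t <- noise_sd + relative_noise * abs(s0)
      data.frame(trace = truth$trace[i], replicate = r, time = time,
                 signal = s0 + stats::rnorm(length(time), sd = sd_t),
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Reference species panel for paralog-alignment simulations
#'
#' Sixteen mammalian and eleven nonmammalian vertebrate species labels,
#' matching the comparative panel the residue scanner targets.
#'
#' @return data.frame with columns species and clade.
#' @export
default_species_panel <- function() {
  data.frame(
    species = c(sprintf("mammal_%02d", 1:16),
                sprintf("nonmammal_%02d", 1:11)),
    clade = c(rep("mammal", 16), rep("nonmammal", 11)),
    stringsAsFactors = FALSE)
}

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Split "Y/F" style state specs into candidate residue sets.
split_states <- function(x) strsplit(x, "/", fixed = TRUE)[[1]]

#' Simulate a clade-structured paralog alignment with planted columns
#'
#' Builds an alignment with one paralog-A and one paralog-B sequence per
#' species. Background columns share a random consensus residue, perturbed
#' by a per-site substitution process at rate `background_noise`. Three
#' kinds of truth can be planted (all noise-free, since the residues they
#' model are strictly conserved within their groups):
#' * `invariant_columns`: one residue across all sequences (conserved core),
#' * `contrast`: paralog A carries `a_state` and paralog B `b_state` in
#'   every clade (paralog-distinguishing columns),
#' * `diagnostic`: within `focal_clade`, A carries `focal_a` and B carries
#'   `other`; outside the focal clade both paralogs carry `other`
#'   (clade-restricted divergence). `other` may list alternatives as
#'   `"Y/F"`, sampled per sequence.
#'
#' @param species data.frame with columns species and clade (a partition:
#'   each species has exactly one clade label).
#' @param n_columns alignment length.
#' @param diagnostic data.frame(column, focal_a, other) or NULL.
#' @param contrast data.frame(column, a_state, b_state) or NULL.
#' @param invariant_columns integer column indices.
#' @param focal_clade clade label for the diagnostic pattern.
#' @param background_noise per-site substitution probability in background
#'   columns.
#' @param seed integer seed.
#' @return list with `alignment` (character matrix, rows named
#'   `<species>|<paralog>`), `meta` (data.frame id, species, paralog,
#'   clade) and `truth` (the planted specifications).
#' @export
simulate_paralog_alignment <- function(species = default_species_panel(),
                                       n_columns = 200L,
                                       diagnostic = NULL,
                                       contrast = NULL,
                                       invariant_columns = integer(0),
                                       focal_clade = "mammal",
                                       background_noise = 0,
                                       seed = 1L) {
  stopifnot(is.data.frame(species),
            all(c("species", "clade") %in% names(species)))
  if (anyDuplicated(species$species)) {
    stop("clade labels must partition species (duplicated species)")
  }
  planted_cols <- c(if (!is.null(diagnostic)) diagnostic$column,
                    if (!is.null(contrast)) contrast$column,
                    invariant_columns)
  if (anyDuplicated(planted_cols)) stop("planted columns must be distinct")
  if (length(planted_cols) && max(planted_cols) > n_columns) {
    stop("planted column index exceeds alignment length")
  }
  set.seed(as.integer(seed))
  meta <- data.frame(
    id = c(paste0(species$species, "|A"), paste0(species$species, "|B")),
    species = rep(species$species, 2),
    paralog = rep(c("A", "B"), each = nrow(species)),
    clade = rep(species$clade, 2),
    stringsAsFactors = FALSE)
  n_seq <- nrow(meta)
  consensus <- sample(AA, n_columns, replace = TRUE)
  aln <- matrix(rep(consensus, each = n_seq), nrow = n_seq,
                dimnames = list(meta$id, NULL))
  if (background_noise > 0) {
    free_cols <- setdiff(seq_len(n_columns), planted_cols)
    for (j in free_cols) {
      mut <- stats::runif(n_seq) < background_noise
      if (any(mut)) {
        aln[mut, j] <- vapply(which(mut), function(i) {
          sample(setdiff(AA, aln[i, j]), 1L)
        }, character(1))
      }
    }
  }
  if (length(invariant_columns)) {
    for (j in invariant_columns) aln[, j] <- sample(AA, 1L)
  }
  if (!is.null(contrast)) {
    for (r in seq_len(nrow(contrast))) {
      j <- contrast$column[r]
      aln[meta$paralog == "A", j] <- contrast$a_state[r]
      aln[meta$paralog == "B", j] <- contrast$b_state[r]
    }
  }
  if (!is.null(diagnostic)) {
    if (!focal_clade %in% species$clade) {
      stop("focal_clade not present in species table")
    }
    for (r in seq_len(nrow(diagnostic))) {
      j <- diagnostic$column[r]
      others <- split_states(diagnostic$other[r])
      fill <- sample(others, n_seq, replace = TRUE)
      aln[, j] <- fill
      aln[meta$paralog == "A" & meta$clade == focal_clade, j] <-
        diagnostic$focal_a[r]
    }
  }
  list(alignment = aln, meta = meta,
       truth = list(diagnostic = diagnostic, contrast = contrast,
                    invariant = invariant_columns))
}
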