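# Residue scanner: conserved core, mismatches, distinguishing columns,
# bias scores, clade-restricted divergence.

toy_alignment <- function(cols) {
  # cols: list of per-column residue vectors over 6 sequences
  # (2 species x A/B in clade M, 1 species x A/B in clade N)
  meta <- data.frame(
    id = c("s1|A", "s2|A", "s3|A", "s1|B", "s2|B", "s3|B"),
    species = rep(c("s1", "s2", "s3"), 2),
    paralog = rep(c("A", "B"), each = 3),
    clade = rep(c("M", "M", "N"), 2))
  aln <- do.call(cbind, cols)
  rownames(aln) <- meta$id
  list(alignment = aln, meta = meta)
}

test_that("conserved core keeps high-identity columns only", {
  toy <- toy_alignment(list(rep("R", 6), c("R", "R", "R", "Q", "Q", "Q"),
                            c("K", "K", "K", "K", "K", "E")))
  core <- conserved_core(toy$alignment, toy$meta, theta = 0.9)
  expect_equal(core$column, 1)
  expect_equal(core$consensus, "R")
  core_all <- conserved_core(toy$alignment, toy$meta, theta = 0.5)
  expect_true(all(c(1, 3) %in% core_all$column))
  # monotone in theta: larger theta gives a subset
  expect_true(all(core$column %in% core_all$column))
  # a column with > 50% gaps is ineligible at any theta
  gappy <- toy_alignment(list(c("R", "-", "-", "-", "-", "R")))
  expect_equal(nrow(conserved_core(gappy$alignment, gappy$meta, 0.1)), 0)
})

test_that("mismatch counting treats gaps as mismatches", {
  toy <- toy_alignment(list(rep("R", 6), rep("W", 6), rep("C", 6)))
  core <- conserved_core(toy$alignment, toy$meta, 0.95)
  expect_equal(mismatch_counts(c("R", "W", "C"), core), 0)
  expect_equal(mismatch_counts(c("R", "A", "C"), core), 1)
  expect_equal(mismatch_counts(c("R", "-", "C"), core), 1)
  expect_equal(mismatch_counts("RWC", core), 0)
  expect_error(mismatch_counts(c("R"), core), "shorter")
  # planted mismatch counts recovered exactly
  set.seed(17)
  al <- simulate_paralog_alignment(n_columns = 159,
                                   invariant_columns = 1:159, seed = 17)
  core2 <- conserved_core(al$alignment, al$meta, 0.95)
  expect_equal(nrow(core2), 159)
  planted <- c(10, 12, 11, 13)
  for (k in planted) {
    q <- al$alignment[1, ]
    flip <- sample(159, k)
    q[flip] <- vapply(q[flip], function(r) {
      setdiff(relspectra:::AA, r)[1]
    }, character(1))
    expect_equal(mismatch_counts(q, core2), k)
  }
})

test_that("distinguishing columns need confident opposing consensi", {
  toy <- toy_alignment(list(
    c("R", "R", "R", "Q", "Q", "Q"),   # clean contrast
    c("R", "K", "R", "Q", "Q", "Q"),   # A mixed below theta
    rep("G", 6)))                       # identical
  d <- distinguishing_residues(toy$alignment, toy$meta,
                               theta_within = 0.9)
  expect_equal(d$column, 1)
  expect_equal(d$a_state, "R")
  expect_equal(d$b_state, "Q")
  d2 <- distinguishing_residues(toy$alignment, toy$meta,
                                theta_within = 0.6)
  expect_true(all(c(1, 2) %in% d2$column))
  expect_equal(d2$column[1], 1)   # ranked by min within-paralog identity
})

test_that("22 planted contrast columns are recovered exactly at zero noise", {
  contrast <- data.frame(column = seq(5, 110, by = 5),
                         a_state = rep(c("R", "K"), 11),
                         b_state = rep(c("Q", "E"), 11))
  al <- simulate_paralog_alignment(n_columns = 120, contrast = contrast,
                                   seed = 19)
  d <- distinguishing_residues(al$alignment, al$meta)
  expect_setequal(d$column, contrast$column)
  expect_equal(nrow(d), 22)
})

test_that("paralog bias score counts diagnostic matches", {
  diag <- data.frame(column = 1:22, a_state = "R", b_state = "Q")
  all_a <- rep("R", 22)
  expect_equal(paralog_bias_score(all_a, diag)$bias, 1)
  half <- c(rep("R", 11), rep("Q", 11))
  expect_equal(paralog_bias_score(half, diag)$bias, 0)
  mix <- c(rep("R", 15), rep("Q", 5), rep("W", 2))
  sc <- paralog_bias_score(mix, diag)
  expect_equal(sc$matches_A, 15)
  expect_equal(sc$matches_B, 5)
  expect_equal(sc$bias, 0.5)
  none <- rep("W", 22)
  expect_true(is.na(paralog_bias_score(none, diag)$bias))
})

test_that("clade-restricted scan flags the Arg101-type pattern", {
  diag <- data.frame(column = 101, focal_a = "R", other = "Q")
  al <- simulate_paralog_alignment(n_columns = 150, diagnostic = diag,
                                   seed = 23)
  hit <- clade_restricted_divergence(al$alignment, al$meta, "mammal")
  expect_equal(hit$column, 101)
  expect_equal(hit$focal_a, "R")
  expect_equal(hit$focal_b, "Q")
  expect_equal(hit$control_state, "Q")
  # no planted columns, zero noise: empty result
  al0 <- simulate_paralog_alignment(n_columns = 80, seed = 24)
  expect_equal(nrow(clade_restricted_divergence(al0$alignment, al0$meta,
                                                "mammal")), 0)
})

test_that("Cys137-type patterns need class mode to be seen as shared", {
  diag <- data.frame(column = c(101, 137), focal_a = c("R", "C"),
                     other = c("Q", "Y/F"))
  al <- simulate_paralog_alignment(n_columns = 150, diagnostic = diag,
                                   seed = 25)
  strict <- clade_restricted_divergence(al$alignment, al$meta, "mammal")
  expect_equal(strict$column, 101)   # Tyr/Phe mixture breaks identity
  classy <- clade_restricted_divergence(al$alignment, al$meta, "mammal",
                                        mode = "class")
  expect_setequal(classy$column, c(101, 137))
  c137 <- classy[classy$column == 137, ]
  expect_equal(c137$focal_a, "C")
  expect_true(c137$focal_b %in% c("F/Y", "F", "Y"))
})

test_that("scanner results are invariant to sequence order", {
  diag <- data.frame(column = 40, focal_a = "R", other = "Q")
  al <- simulate_paralog_alignment(n_columns = 60, diagnostic = diag,
                                   background_noise = 0.02, seed = 26)
  perm <- sample(nrow(al$alignment))
  h1 <- clade_restricted_divergence(al$alignment, al$meta, "mammal")
  h2 <- clade_restricted_divergence(al$alignment[perm, ],
                                    al$meta[perm, ], "mammal")
  expect_equal(h1, h2)
})

test_that("region restriction intersects column sets", {
  cols <- c(101, 137, 150)
  expect_equal(region_restrict(cols, c(95, 140)), c(101, 137))
  expect_equal(region_restrict(cols, c(1, 200)), cols)
  expect_equal(length(region_restrict(cols, c(10, 5))), 0)
  df <- data.frame(column = cols, state = c("R", "C", "G"))
  expect_equal(region_restrict(df, c(95, 140))$column, c(101, 137))
})

test_that("noisy planted scans keep perfect recall with high precision", {
  diag <- data.frame(column = c(101, 137), focal_a = c("R", "C"),
                     other = c("Q", "Y/F"))
  recalled <- 0
  extra <- 0
  for (s in 1:25) {
    al <- simulate_paralog_alignment(n_columns = 150, diagnostic = diag,
                                     background_noise = 0.02, seed = s)
    hits <- clade_restricted_divergence(al$alignment, al$meta, "mammal",
                                        mode = "class")
    recalled <- recalled + sum(c(101, 137) %in% hits$column)
    extra <- extra + sum(!hits$column %in% c(101, 137))
  }
  expect_gte(recalled / 50, 0.95)
  expect_lte(extra / 25, 0.5)
})
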