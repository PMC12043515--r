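# Comparative residue analytics on clade-labelled paralog alignments:
# conserved core, mismatch counts, paralog-distinguishing columns,
# paralog-bias scoring and clade-restricted divergence detection.
#
# Alignments are character matrices (one row per sequence, gap = "-")
# with a metadata data.frame carrying id, species, paralog ("A", "B" or
# "unassigned") and clade per row.

GAP <- "-"

# Fixed residue grouping for the optional class mode. Cysteine sits in
# its own group so Cys-vs-aromatic contrasts (the Tyr/Phe case) are
# visible.
RESIDUE_CLASS <- c(
  A = "aliphatic", V = "aliphatic", L = "aliphatic", I = "aliphatic",
  M = "aliphatic",
  F = "aromatic", W = "aromatic", Y = "aromatic",
  K = "positive", R = "positive", H = "positive",
  D = "negative", E = "negative",
  S = "polar", T = "polar", N = "polar", Q = "polar",
  C = "cysteine", G = "glycine", P = "proline")

check_alignment <- function(aln, meta) {
  stopifnot(is.matrix(aln), is.data.frame(meta),
            nrow(aln) == nrow(meta),
            all(c("species", "paralog", "clade") %in% names(meta)))
  per_species_clades <- tapply(meta$clade, meta$species,
                               function(x) length(unique(x)))
  if (any(per_species_clades > 1)) {
    stop("clade labels must partition species")
  }
  invisible(TRUE)
}

# Consensus state of a group of residues at one column. A group with
# > 50% gaps is ineligible (state NA). In class mode the tally runs over
# residue classes and `residues` lists the member residues observed.
group_state <- function(cells, theta, mode = "identity") {
  gaps <- cells == GAP
  if (mean(gaps) > 0.5) {
    return(list(state = NA_character_, identity = NA_real_,
                residues = NA_character_))
  }
  res <- cells[!gaps]
  keys <- if (mode == "class") unname(RESIDUE_CLASS[res]) else res
  tab <- sort(table(keys), decreasing = TRUE)
  ident <- tab[1] / length(keys)
  if (ident < theta) {
    return(list(state = NA_character_, identity = unname(ident),
                residues = NA_character_))
  }
  state <- names(tab)[1]
  members <- if (mode == "class") {
    paste(sort(unique(res[keys == state])), collapse = "/")
  } else {
    state
  }
  list(state = state, identity = unname(ident), residues = members)
}

#' Conserved core of a paralog alignment
#'
#' Columns where one residue is shared by at least `theta` of all non-gap
#' entries, pooled over both paralogs. Columns with more than 50% gaps
#' are ineligible.
#'
#' @param aln character alignment matrix.
#' @param meta row metadata (species, paralog, clade).
#' @param theta identity fraction threshold (default 0.95).
#' @return data.frame: column, consensus, identity.
#' @export
conserved_core <- function(aln, meta, theta = 0.95) {
  check_alignment(aln, meta)
  rows <- lapply(seq_len(ncol(aln)), function(j) {
    st <- group_state(aln[, j], theta)
    if (is.na(st$state)) return(NULL)
    data.frame(column = j, consensus = st$state, identity = st$identity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(column = integer(0), consensus = character(0),
                      identity = numeric(0))
  }
  out
}

#' Mismatches of a sequence against the conserved core
#'
#' Number of core columns where the sequence differs from the consensus;
#' gaps count as mismatches.
#'
#' @param seq aligned sequence: a character vector of residues or a
#'   single string of the full alignment length.
#' @param core data.frame from [conserved_core()].
#' @param n_columns alignment length, for validation when `seq` is a
#'   string.
#' @return integer mismatch count.
#' @export
mismatch_counts <- function(seq, core, n_columns = NULL) {
  if (is.character(seq) && length(seq) == 1L && nchar(seq) > 1L) {
    seq <- strsplit(seq, "")[[1]]
  }
  if (!is.null(n_columns) && length(seq) != n_columns) {
    stop("sequence length does not match the alignment")
  }
  if (nrow(core) && max(core$column) > length(seq)) {
    stop("sequence shorter than the core coordinate system")
  }
  sum(seq[core$column] != core$consensus)
}

#' Paralog-distinguishing columns
#'
#' Columns where the within-paralog consensus of A (identity >=
#' `theta_within`) differs from that of B. Ranked by the minimum of the
#' two within-paralog identities, so the most consistent contrasts come
#' first.
#'
#' @param aln,meta alignment and metadata.
#' @param theta_within within-paralog identity threshold (default 0.9).
#' @return data.frame: column, a_state, b_state, a_identity, b_identity,
#'   min_identity; ordered by descending min_identity.
#' @export
distinguishing_residues <- function(aln, meta, theta_within = 0.9) {
  check_alignment(aln, meta)
  ia <- meta$paralog == "A"
  ib <- meta$paralog == "B"
  if (sum(ia) < 2 || sum(ib) < 2) {
    stop("both paralogs must be present in >= 2 sequences")
  }
  rows <- lapply(seq_len(ncol(aln)), function(j) {
    sa <- group_state(aln[ia, j], theta_within)
    sb <- group_state(aln[ib, j], theta_within)
    if (is.na(sa$state) || is.na(sb$state) || sa$state == sb$state) {
      return(NULL)
    }
    data.frame(column = j, a_state = sa$state, b_state = sb$state,
               a_identity = sa$identity, b_identity = sb$identity,
               min_identity = min(sa$identity, sb$identity),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(column = integer(0), a_state = character(0),
                      b_state = character(0), a_identity = numeric(0),
                      b_identity = numeric(0), min_identity = numeric(0)))
  }
  out[order(-out$min_identity, out$column), , drop = FALSE]
}

#' Paralog-bias score of an unassigned sequence
#'
#' Counts distinguishing columns where the sequence carries the A state
#' or the B state; `bias = (matches_A - matches_B) / (matches_A +
#' matches_B)`. Columns matching neither state are excluded from the
#' denominator; when no column matches either state the bias is `NA`.
#'
#' @param seq aligned sequence (residue vector or single string).
#' @param diag data.frame from [distinguishing_residues()].
#' @return list: matches_A, matches_B, bias.
#' @export
paralog_bias_score <- function(seq, diag) {
  if (!nrow(diag)) stop("distinguishing column set is empty")
  if (is.character(seq) && length(seq) == 1L && nchar(seq) > 1L) {
    seq <- strsplit(seq, "")[[1]]
  }
  obs <- seq[diag$column]
  ma <- sum(obs == diag$a_state)
  mb <- sum(obs == diag$b_state)
  list(matches_A = ma, matches_B = mb,
       bias = if (ma + mb == 0) NA_real_ else (ma - mb) / (ma + mb))
}

#' Clade-restricted divergent columns
#'
#' Flags columns where, within the focal clade, the two paralogs hold
#' different consensus states (each with identity >= `theta_within`),
#' while in every control clade both paralogs pooled share one consensus
#' state. `mode = "class"` runs the same logic over a fixed residue
#' grouping, so e.g. a Tyr/Phe mixture counts as one shared aromatic
#' state.
#'
#' @param aln,meta alignment and metadata.
#' @param focal_clade clade in which the paralogs must differ.
#' @param control_clades clades in which they must agree (default: all
#'   other clades present).
#' @param theta_within identity threshold within each group (default
#'   0.9).
#' @param mode `"identity"` (default) or `"class"`.
#' @return data.frame: column, focal_a, focal_b, control_state (per-clade
#'   states joined with ";"), mode.
#' @export
clade_restricted_divergence <- function(aln, meta, focal_clade,
                                        control_clades = NULL,
                                        theta_within = 0.9,
                                        mode = c("identity", "class")) {
  mode <- match.arg(mode)
  check_alignment(aln, meta)
  if (is.null(control_clades)) {
    control_clades <- setdiff(unique(meta$clade), focal_clade)
  }
  if (!length(control_clades)) stop("no control clades available")
  sel <- function(paralog, clade) {
    meta$paralog == paralog & meta$clade == clade
  }
  for (cl in c(focal_clade, control_clades)) {
    if (sum(sel("A", cl)) < 2 || sum(sel("B", cl)) < 2) {
      stop("clade ", cl, " needs both paralogs in >= 2 species")
    }
  }
  rows <- lapply(seq_len(ncol(aln)), function(j) {
    fa <- group_state(aln[sel("A", focal_clade), j], theta_within, mode)
    fb <- group_state(aln[sel("B", focal_clade), j], theta_within, mode)
    if (is.na(fa$state) || is.na(fb$state) || fa$state == fb$state) {
      return(NULL)
    }
    ctrl <- character(length(control_clades))
    for (i in seq_along(control_clades)) {
      cl <- control_clades[i]
      pooled <- meta$clade == cl & meta$paralog %in% c("A", "B")
      cs <- group_state(aln[pooled, j], theta_within, mode)
      if (is.na(cs$state)) return(NULL)
      ctrl[i] <- cs$residues
    }
    data.frame(column = j, focal_a = fa$residues, focal_b = fb$residues,
               control_state = paste(ctrl, collapse = ";"),
               mode = mode, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(column = integer(0), focal_a = character(0),
                      focal_b = character(0), control_state = character(0),
                      mode = character(0))
  }
  out
}

#' Restrict flagged columns to a coordinate range
#'
#' @param columns integer vector of column indices, or a data.frame with a
#'   `column` column.
#' @param range length-2 integer vector `c(lo, hi)` (inclusive).
#' @return the subset inside the range (same type as the input).
#' @export
region_restrict <- function(columns, range) {
  stopifnot(length(range) == 2, range[1] <= range[2] || TRUE)
  if (range[1] > range[2]) {
    keep <- logical(if (is.data.frame(columns)) nrow(columns) else
      length(columns))
  } else if (is.data.frame(columns)) {
    keep <- columns$column >= range[1] & columns$column <= range[2]
  } else {
    keep <- columns >= range[1] & columns <= range[2]
  }
  if (is.data.frame(columns)) columns[keep, , drop = FALSE] else
    columns[keep]
}
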