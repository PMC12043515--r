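# Minimal position-probability-matrix text format, MEME-like layout:
#
#   >motif_name
#   A C G T
#   0.997 0.001 0.001 0.001
#   ...
#
# One row per motif position; columns sum to 1.

#' Write a PWM to the package's text format
#'
#' @param motif a [pwm()] object.
#' @param path output path.
#' @export
write_pwm <- function(motif, path) {
  stopifnot(inherits(motif, "pwm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", motif$name), con)
  writeLines("A C G T", con)
  apply(motif$probs, 2, function(col) {
    writeLines(paste(format(col, digits = 6), collapse = " "), con)
  })
  invisible(path)
}

#' Read a PWM from the package's text format
#'
#' @param path file path.
#' @inheritParams pwm
#' @return a [pwm()] object.
#' @export
read_pwm <- function(path, background = rep(0.25, 4),
                     threshold_frac = 0.6) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!startsWith(lines[1], ">")) stop("missing >name header line")
  name <- sub("^>", "", lines[1])
  body <- lines[-(1:2)]   # drop header and the A C G T line
  probs <- t(vapply(body, function(l) {
    as.numeric(strsplit(trimws(l), "[[:space:]]+")[[1]])
  }, numeric(4), USE.NAMES = FALSE))
  pwm(t(probs), background, threshold_frac, name)
}

#' Packaged NF-kB motif models
#'
#' The dimeric consensus κB motif (GGGAATTTCC-style) and a 5-bp
#' half-site model, shipped as plain-text probability matrices under
#' `inst/extdata/`.
#'
#' @inheritParams pwm
#' @return named list of [pwm()] objects.
#' @export
nfkb_motifs <- function(threshold_frac = 0.6) {
  dir <- system.file("extdata", package = "relspectra")
  list(
    consensus = read_pwm(file.path(dir, "nfkb_consensus.pwm"),
                         threshold_frac = threshold_frac),
    halfsite = read_pwm(file.path(dir, "nfkb_halfsite.pwm"),
                        threshold_frac = threshold_frac))
}
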