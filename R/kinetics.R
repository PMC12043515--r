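# Dissociation-kinetics fitting: t0 normalization, single-exponential
# off-rate fits (optionally with a floor), shared-koff global fits across
# curves, half-lives and replicate aggregation.

#' Normalize a decay series to 100% at t = 0
#'
#' @param series data.frame with time and signal columns; must contain
#'   t = 0 with positive signal.
#' @return the series with signal rescaled so signal(0) = 100.
#' @export
normalize_decay <- function(series) {
  i0 <- which(series$time == 0)
  if (!length(i0)) stop("series lacks a t = 0 point")
  s0 <- series$signal[i0[1]]
  if (s0 <= 0) stop("signal at t = 0 must be > 0")
  series$signal <- series$signal * (100 / s0)
  series
}

# Log-linear starting values for S(t) = R0 exp(-koff t) + c.
exp_start_values <- function(time, signal, fit_baseline) {
  c0 <- if (fit_baseline) min(signal) - 0.05 * abs(min(signal)) else 0
  y <- signal - c0
  ok <- y > 0
  if (sum(ok) < 2) stop("cannot initialize: too few positive points")
  fit <- stats::lm(log(y[ok]) ~ time[ok])
  koff0 <- max(-unname(stats::coef(fit)[2]), 1e-6)
  list(R0 = exp(unname(stats::coef(fit)[1])), koff = koff0, c = c0)
}

#' Fit an exponential dissociation model
#'
#' Least-squares fit of `S(t) = R0 * exp(-koff * t)` (plus a constant
#' floor `c` when `fit_baseline = TRUE`), initialized from a log-linear
#' regression. Standard errors come from the fit covariance; the half-life
#' is `ln(2) / koff` in the reciprocal of the time unit.
#'
#' @param series data.frame with time and signal columns (>= 3 points,
#'   >= 4 when the baseline is fitted). Replicate rows may share
#'   timepoints; all are used.
#' @param fit_baseline also estimate a constant floor.
#' @return object of class `kinetic_fit`: coefficients (R0, koff,
#'   optionally c), standard errors, t_half, residual norm, convergence
#'   flag.
#' @export
fit_exponential_dissociation <- function(series, fit_baseline = FALSE) {
  time <- series$time
  signal <- series$signal
  stopifnot(all(is.finite(time)), all(is.finite(signal)))
  npar <- if (fit_baseline) 3L else 2L
  if (length(time) < npar + 1L) {
    stop("need at least ", npar + 1L, " time points")
  }
  fail <- function(reason) {
    structure(list(coefficients = c(R0 = NA_real_, koff = NA_real_),
                   se = NULL, t_half = NA_real_, rss = NA_real_,
                   converged = FALSE, reason = reason,
                   fit_baseline = fit_baseline, data = series),
              class = "kinetic_fit")
  }
  start <- tryCatch(exp_start_values(time, signal, fit_baseline),
                    error = function(e) NULL)
  if (is.null(start)) return(fail("initialization failed"))
  fit <- tryCatch({
    if (fit_baseline) {
      minpack.lm::nlsLM(signal ~ R0 * exp(-koff * time) + c,
                        start = start[c("R0", "koff", "c")],
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-10, ptol = 1e-10))
    } else {
      minpack.lm::nlsLM(signal ~ R0 * exp(-koff * time),
                        start = start[c("R0", "koff")],
                        control = minpack.lm::nls.lm.control(
                          maxiter = 500, ftol = 1e-10, ptol = 1e-10))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) return(fail("non-convergence"))
  cf <- stats::coef(fit)
  if (!is.finite(cf[["koff"]]) || cf[["koff"]] <= 0) {
    return(fail("koff estimate <= 0 (unidentifiable decay)"))
  }
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) NULL)
  structure(list(coefficients = cf, se = se,
                 t_half = log(2) / cf[["koff"]],
                 rss = sum(stats::resid(fit)^2),
                 converged = TRUE, reason = NULL,
                 fit_baseline = fit_baseline, data = series),
            class = "kinetic_fit")
}

#' Global dissociation fit with a shared off-rate
#'
#' Joint least squares across several dissociation curves under a 1:1
#' model: one shared `koff`, one amplitude `R0` per curve. For a fixed
#' koff the amplitudes are linear, so they are profiled out and koff is
#' found by one-dimensional minimization on the log scale; its standard
#' error comes from the numerical curvature of the profiled sum of
#' squares.
#'
#' @param traces data.frame with curve, time and signal columns.
#' @return object of class `kinetic_fit` with the shared koff, per-curve
#'   amplitudes and t_half.
#' @export
fit_dissociation_global <- function(traces) {
  stopifnot(all(c("curve", "time", "signal") %in% names(traces)))
  curves <- split(traces, traces$curve)
  if (length(curves) < 1L) stop("no curves to fit")
  profiled_rss <- function(log_koff) {
    koff <- exp(log_koff)
    sum(vapply(curves, function(d) {
      e <- exp(-koff * d$time)
      r0 <- sum(d$signal * e) / sum(e^2)
      sum((d$signal - r0 * e)^2)
    }, numeric(1)))
  }
  start <- exp_start_values(curves[[1]]$time, curves[[1]]$signal, FALSE)
  opt <- stats::optim(log(start$koff), profiled_rss, method = "Brent",
                      lower = log(start$koff) - 10,
                      upper = log(start$koff) + 10,
                      control = list(reltol = 1e-12))
  koff <- exp(opt$par)
  r0 <- vapply(curves, function(d) {
    e <- exp(-koff * d$time)
    sum(d$signal * e) / sum(e^2)
  }, numeric(1))
  # curvature of RSS(log koff) -> SE on the log scale -> delta method
  h <- 1e-4
  d2 <- (profiled_rss(opt$par + h) - 2 * opt$value +
           profiled_rss(opt$par - h)) / h^2
  n_obs <- nrow(traces)
  npar <- length(curves) + 1L
  sigma2 <- opt$value / max(n_obs - npar, 1L)
  se_log <- if (d2 > 0) sqrt(2 * sigma2 / d2) else NA_real_
  structure(list(coefficients = c(koff = koff, R0 = r0),
                 se = c(koff = koff * se_log),
                 t_half = log(2) / koff, rss = opt$value,
                 converged = koff > 0, reason = NULL,
                 fit_baseline = FALSE, data = traces),
            class = "kinetic_fit")
}

#' Half-life from an off-rate
#'
#' `t_half = ln(2) / koff`, in the reciprocal time unit of `koff`.
#'
#' @param koff dissociation rate constant(s), > 0.
#' @return half-life (same vector shape).
#' @export
half_life <- function(koff) {
  if (any(koff <= 0)) stop("koff must be > 0")
  log(2) / koff
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Dissociation fit FAILED:", x$reason, "\n")
    return(invisible(x))
  }
  cat("Exponential dissociation fit\n")
  cat("  koff  =", format(x$coefficients[["koff"]], digits = 6),
      "per time unit\n")
  cat("  t1/2  =", format(x$t_half, digits = 6), "time units\n")
  amps <- x$coefficients[names(x$coefficients) != "koff"]
  cat("  amplitude(s):", paste(format(amps, digits = 5), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
coef.kinetic_fit <- function(object, ...) object$coefficients

#' @export
summary.kinetic_fit <- function(object, ...) {
  cf <- object$coefficients
  out <- data.frame(estimate = cf,
                    se = if (is.null(object$se)) NA_real_ else {
                      object$se[match(names(cf), names(object$se))]
                    })
  attr(out, "t_half") <- object$t_half
  attr(out, "rss") <- object$rss
  attr(out, "converged") <- object$converged
  out
}

#' @export
predict.kinetic_fit <- function(object, time = NULL, ...) {
  if (!object$converged) stop("cannot predict from a failed fit")
  if (is.null(time)) time <- object$data$time
  cf <- object$coefficients
  base <- if (object$fit_baseline) cf[["c"]] else 0
  r0 <- if ("R0" %in% names(cf)) cf[["R0"]] else cf[[2]]
  r0 * exp(-cf[["koff"]] * time) + base
}

#' @export
residuals.kinetic_fit <- function(object, ...) {
  object$data$signal - predict(object)
}

#' @export
plot.kinetic_fit <- function(x, ...) {
  plot(x$data$time, x$data$signal, xlab = "time", ylab = "signal",
       main = "Dissociation fit", ...)
  if (x$converged) {
    tt <- seq(min(x$data$time), max(x$data$time), length.out = 200)
    graphics::lines(tt, predict(x, tt))
  }
  invisible(x)
}

#' Aggregate normalized replicate decay profiles
#'
#' Per-timepoint mean and sample (n-1) standard deviation across
#' replicates sharing a common time grid; the SD is reported as `NA` for
#' a single replicate.
#'
#' @param traces data.frame with replicate, time and signal columns; every
#'   replicate must cover the identical time grid.
#' @return data.frame: time, mean, sd, n.
#' @export
aggregate_replicates <- function(traces) {
  reps <- split(traces, traces$replicate)
  grid <- sort(unique(reps[[1]]$time))
  same <- vapply(reps, function(d) {
    identical(sort(unique(d$time)), grid) && nrow(d) == length(grid)
  }, logical(1))
  if (!all(same)) stop("replicates do not share a common time grid")
  mat <- vapply(reps, function(d) d$signal[order(d$time)],
                numeric(length(grid)))
  mat <- matrix(mat, nrow = length(grid))
  data.frame(time = grid,
             mean = rowMeans(mat),
             sd = if (ncol(mat) > 1) apply(mat, 1, stats::sd) else
               NA_real_,
             n = ncol(mat))
}
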