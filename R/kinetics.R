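#' Dwell-time histogram
#'
#' Bins single-molecule residence times into half-open bins `[k*w, (k+1)*w)`
#' with left edges at zero. The first bin is dropped by default: dwells
#' shorter than one bin width are depleted by the finite scan rate and
#' detection threshold, and retaining the undercounted first bin biases the
#' exponential fit.
#'
#' @param dwells Numeric vector of dwell times (s), all > 0; >= 20 required.
#' @param bin_width_s Bin width, seconds (default 1).
#' @param drop_first Drop the first bin before fitting (default TRUE).
#' @return A list of class `dwell_histogram`: `mids`, `counts` (after the
#'   optional drop), `bin_width_s`, `first_bin_dropped`,
#'   `dropped_fraction`, `n`.
#' @export
dwell_histogram <- function(dwells, bin_width_s = 1, drop_first = TRUE) {
  d <- as.numeric(dwells)
  if (length(d) < 20L) stop("need at least 20 dwell times")
  if (any(d <= 0)) stop("dwell times must be positive")
  stopifnot(bin_width_s > 0)
  breaks <- seq(0, (floor(max(d) / bin_width_s) + 1) * bin_width_s,
                by = bin_width_s)
  h <- graphics::hist(d, breaks = breaks, right = FALSE, plot = FALSE)
  mids <- h$mids
  counts <- h$counts
  dropped_fraction <- counts[1L] / length(d)
  if (drop_first) {
    mids <- mids[-1L]
    counts <- counts[-1L]
  }
  structure(list(mids = mids, counts = counts, bin_width_s = bin_width_s,
                 first_bin_dropped = drop_first,
                 dropped_fraction = dropped_fraction, n = length(d)),
            class = "dwell_histogram")
}

#' Fit a single-exponential decay to a dwell-time histogram
#'
#' Unweighted nonlinear least squares of `y = A * exp(-k_off * t) + y0` to
#' the binned dwell-time counts, the standard histogram route to the
#' dissociation rate constant.
#'
#' @param hist A [dwell_histogram()], or a list with `mids` and `counts`.
#' @return An object of class `exp_fit_result`: `k_off`, `stderr`,
#'   `amplitude`, `baseline`, `r_squared`, `rmse`, `bin_width_s`,
#'   `first_bin_dropped`, `converged`.
#' @export
fit_koff <- function(hist) {
  t <- hist$mids
  y <- hist$counts
  if (sum(y > 0) < 4L) stop("need at least 4 occupied bins")
  k0 <- tryCatch({
    pos <- y > 0
    -unname(stats::coef(stats::lm(log(y[pos]) ~ t[pos]))[2L])
  }, error = function(e) NA_real_)
  if (!is.finite(k0) || k0 <= 0) k0 <- 1 / max(mean(t), 1e-6)
  a0 <- max(y) * exp(k0 * t[1L])
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-k * t) + y0,
                      data = data.frame(t = t, y = y),
                      start = list(a = a0, k = k0, y0 = max(y) * 1e-4),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit) || stats::coef(fit)["k"] <= 0) {
    return(structure(list(k_off = NA_real_, stderr = NA_real_,
                          amplitude = NA_real_, baseline = NA_real_,
                          r_squared = NA_real_, rmse = NA_real_,
                          bin_width_s = hist$bin_width_s %||% NA_real_,
                          first_bin_dropped =
                            hist$first_bin_dropped %||% NA,
                          converged = FALSE),
                     class = "exp_fit_result"))
  }
  co <- stats::coef(fit)
  res <- stats::resid(fit)
  structure(list(k_off = unname(co["k"]),
                 stderr =
                   unname(summary(fit)$coefficients["k", "Std. Error"]),
                 amplitude = unname(co["a"]), baseline = unname(co["y0"]),
                 r_squared = 1 - sum(res^2) / sum((y - mean(y))^2),
                 rmse = sqrt(mean(res^2)),
                 bin_width_s = hist$bin_width_s %||% NA_real_,
                 first_bin_dropped = hist$first_bin_dropped %||% NA,
                 converged = TRUE),
            class = "exp_fit_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.exp_fit_result <- function(x, ...) {
  if (!x$converged) {
    cat("Exponential fit: did not converge\n")
  } else {
    cat(sprintf(
      "k_off = %.3f +/- %.3f s^-1 (R^2 = %.3f, RMSE = %.2f)\n",
      x$k_off, x$stderr, x$r_squared, x$rmse))
  }
  invisible(x)
}

#' Unbound time of a kymograph
#'
#' The per-kymograph time available for new binding: total observation time
#' minus the summed residence times of all traces, clamped at zero. A
#' negative raw value (overlapping simultaneous traces) is flagged.
#'
#' @param kymo_duration_s Observation time, seconds, > 0.
#' @param traces List of `trace` objects, or a numeric vector of residence
#'   times.
#' @return A list: `t_on_s`, `occupied_s`, `overlap` (raw value negative).
#' @export
unbound_time <- function(kymo_duration_s, traces = list()) {
  stopifnot(kymo_duration_s > 0)
  occupied <- if (is.numeric(traces)) {
    sum(traces)
  } else {
    sum(vapply(traces, function(tr) tr$residence_time_s, numeric(1)))
  }
  raw <- kymo_duration_s - occupied
  list(t_on_s = max(raw, 0), occupied_s = occupied, overlap = raw < 0)
}

#' Association rate constant from unbound times
#'
#' `k_on = 1 / ([C] * mean(t_on))`: the mean per-kymograph unbound time at a
#' known protein concentration gives the association rate constant.
#'
#' @param t_on_values Unbound times (s), at least one positive.
#' @param concentration Protein concentration, molar, > 0.
#' @return A list of class `kon_estimate`: `k_on` (M^-1 s^-1), `mean_t_on_s`,
#'   `per_kymograph_k_on`, `concentration`, `n`.
#' @export
fit_kon <- function(t_on_values, concentration) {
  t_on <- as.numeric(t_on_values)
  if (!is.numeric(concentration) || concentration <= 0) {
    stop("concentration must be positive")
  }
  if (!length(t_on) || any(t_on <= 0)) {
    stop("t_on values must be positive")
  }
  mean_t <- mean(t_on)
  structure(list(k_on = 1 / (concentration * mean_t),
                 mean_t_on_s = mean_t,
                 per_kymograph_k_on = 1 / (concentration * t_on),
                 concentration = concentration, n = length(t_on)),
            class = "kon_estimate")
}

#' @export
print.kon_estimate <- function(x, ...) {
  cat(sprintf(
    "k_on = %.3g M^-1 s^-1 (mean t_on %.3g s at %.3g M, n = %d)\n",
    x$k_on, x$mean_t_on_s, x$concentration, x$n))
  invisible(x)
}

#' Association rate constant from a bulk observed assembly rate
#'
#' For an irreversibly assembling complex (k_off assumed zero, valid for
#' permanently attached oligomers) the bulk observed rate divided by the
#' protein concentration gives k_on.
#'
#' @param k_obs Observed assembly rate.
#' @param concentration Protein concentration, molar, > 0.
#' @param unit Unit of `k_obs`: "per_min" or "per_s".
#' @return k_on in M^-1 s^-1 (unrounded; print with two significant
#'   figures).
#' @export
kon_from_bulk_kobs <- function(k_obs, concentration,
                               unit = c("per_min", "per_s")) {
  unit <- match.arg(unit)
  stopifnot(k_obs > 0, concentration > 0)
  k_obs_s <- if (unit == "per_min") k_obs / 60 else k_obs
  k_obs_s / concentration
}

#' Equilibrium dissociation constant
#'
#' `K_D = k_off / k_on`.
#'
#' @param k_off Dissociation rate constant, s^-1, > 0.
#' @param k_on Association rate constant, M^-1 s^-1, > 0.
#' @return K_D in molar.
#' @export
dissociation_constant <- function(k_off, k_on) {
  stopifnot(is.numeric(k_off), is.numeric(k_on),
            all(k_off > 0), all(k_on > 0))
  k_off / k_on
}

#' Dwell times eligible for dissociation-rate fitting
#'
#' Applies the selection rule for k_off analysis: only traces that begin
#' after the first scan line are eligible (left-censored traces bias the
#' residence time), and traces still present in the last line
#' (right-censored) are excluded because their dwell is truncated. Both
#' kinds still count toward occupancy in [unbound_time()].
#'
#' @param traces List of `trace` objects.
#' @return Numeric vector of residence times (s) of the eligible traces.
#' @export
eligible_dwells <- function(traces) {
  keep <- vapply(traces, function(tr) {
    !tr$left_censored && !tr$right_censored
  }, logical(1))
  vapply(traces[keep], function(tr) tr$residence_time_s, numeric(1))
}
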