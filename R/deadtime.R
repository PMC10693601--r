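#' Idealized detector dead-time model
#'
#' Avalanche photodiode detectors are blind for a fixed interval `tau` after
#' each registered photon. Under the idealized (non-paralyzable) model the
#' detector is unaffected by photons arriving during the dead time, so a
#' measured rate `m` underestimates the true rate `n` by the fraction of time
#' the detector is dead, `m * tau`.
#'
#' @param tau_s Dead time in seconds (default 35 ns).
#' @param window_s Window over which per-sample photon counts are converted to
#'   rates, typically the confocal pixel dwell time (default 50 microseconds).
#'
#' @return An object of class `dead_time_model`.
#' @examples
#' m <- dead_time_model()
#' true_rate(220e3, m)
#' @export
dead_time_model <- function(tau_s = 35e-9, window_s = 50e-6) {
  stopifnot(is.numeric(tau_s), length(tau_s) == 1L, tau_s >= 0,
            is.numeric(window_s), length(window_s) == 1L, window_s > 0)
  structure(list(tau_s = tau_s, window_s = window_s),
            class = "dead_time_model")
}

#' @export
print.dead_time_model <- function(x, ...) {
  cat(sprintf("Dead-time model: tau = %.3g ns, window = %.3g us\n",
              x$tau_s * 1e9, x$window_s * 1e6))
  invisible(x)
}

#' True photon rate from a measured (dead-time-censored) rate
#'
#' Inverts the dead-time loss: `n = m / (1 - m * tau)`. The correction is only
#' defined while the detector is not saturated (`m * tau < 1`).
#'
#' @param m Measured photon rate(s), photons per second.
#' @param model A [dead_time_model()].
#' @return True photon rate(s), photons per second; always `>= m`.
#' @export
true_rate <- function(m, model = dead_time_model()) {
  stopifnot(is.numeric(m), all(m >= 0))
  loss <- m * model$tau_s
  if (any(loss >= 1)) {
    stop("measured rate saturates the detector (m * tau >= 1); ",
         "correction undefined")
  }
  m / (1 - loss)
}

#' Measured rate expected for a given true photon rate
#'
#' Algebraic inverse of [true_rate()]: `m = n / (1 + n * tau)`. Used on the
#' simulation side to censor emitted photons the way the detector would.
#'
#' @param n True photon rate(s), photons per second.
#' @inheritParams true_rate
#' @return Measured rate(s), photons per second.
#' @export
measured_rate <- function(n, model = dead_time_model()) {
  stopifnot(is.numeric(n), all(n >= 0))
  n / (1 + n * model$tau_s)
}

#' Fraction of photons lost to detector dead time
#'
#' `(true_rate(m) - m) / true_rate(m)`, which simplifies to `m * tau`: the
#' fraction of time the detector is dead at measured rate `m`.
#'
#' @inheritParams true_rate
#' @return Underestimation fraction(s) in `[0, 1)`.
#' @export
underestimation_fraction <- function(m, model = dead_time_model()) {
  stopifnot(is.numeric(m), all(m >= 0))
  loss <- m * model$tau_s
  if (any(loss >= 1)) stop("m * tau >= 1: detector saturated")
  loss
}

#' Dead-time-correct a photon count measured over the model window
#'
#' Converts a per-window count to a rate, applies [true_rate()], and converts
#' back. The natural window is the pixel dwell time, so the correction is
#' applied per pixel sample, where the detector actually operates.
#'
#' @param counts Photon count(s) per window.
#' @inheritParams true_rate
#' @return Corrected (true) photon count(s) per window, real-valued.
#' @export
correct_counts <- function(counts, model = dead_time_model()) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  true_rate(counts / model$window_s, model) * model$window_s
}

#' Censor a photon count the way the detector would
#'
#' Deterministic expected-count thinning: the count is converted to a rate
#' over the model window, passed through [measured_rate()], and rounded back
#' to an integer count.
#'
#' @param counts True photon count(s) per window.
#' @inheritParams true_rate
#' @return Censored integer count(s) per window.
#' @export
censor_counts <- function(counts, model = dead_time_model()) {
  stopifnot(is.numeric(counts), all(counts >= 0))
  round(measured_rate(counts / model$window_s, model) * model$window_s)
}
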