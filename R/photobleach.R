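# Optimal least-squares segmentation of a trajectory into n_seg constant
# plateaus (dynamic programming over breakpoints, O(n_seg * n^2)). Returns
# 1-based segment start indices and the residual sum of squares. Exact: for
# a given n_seg this is the global RSS minimum over all placements.
optimal_segmentation <- function(y, n_seg) {
  n <- length(y)
  stopifnot(n_seg >= 1L, n_seg <= n)
  cs <- c(0, cumsum(y))
  cs2 <- c(0, cumsum(y^2))
  cost_to <- function(i, j) {
    # vectorized over i (segment start), fixed end j
    len <- j - i + 1
    s <- cs[j + 1] - cs[i]
    (cs2[j + 1] - cs2[i]) - s^2 / len
  }
  dp <- matrix(Inf, n_seg, n)
  back <- matrix(NA_integer_, n_seg, n)
  dp[1L, ] <- cost_to(1L, 1:n)
  back[1L, ] <- 1L
  if (n_seg > 1L) {
    for (s in 2:n_seg) {
      for (j in s:n) {
        i <- s:j  # start of the last segment
        tot <- dp[s - 1L, i - 1L] + cost_to(i, j)
        b <- which.min(tot)
        dp[s, j] <- tot[b]
        back[s, j] <- i[b]
      }
    }
  }
  starts <- integer(n_seg)
  j <- n
  for (s in n_seg:1) {
    starts[s] <- back[s, j]
    j <- starts[s] - 1L
  }
  list(starts = starts, rss = max(dp[n_seg, n], 0))
}

segment_levels <- function(y, starts) {
  n <- length(y)
  ends <- c(starts[-1L] - 1L, n)
  vapply(seq_along(starts),
         function(s) mean(y[starts[s]:ends[s]]), numeric(1))
}

#' Decompose an intensity trajectory into photobleaching steps
#'
#' Fits a piecewise-constant model to a photon-count trajectory by exact
#' least-squares segmentation, adding one step at a time. Because photon
#' counts carry Poisson noise whose variance tracks the level, the
#' segmentation is performed on the variance-stabilized (Anscombe) scale
#' `2 * sqrt(y + 3/8)`, where the noise is approximately unit-variance at
#' every level. A candidate fit with one more step is accepted while it
#' reduces the transformed residual sum of squares by at least `penalty`
#' (default `3 * log(n)`, a BIC-like change-point penalty) and every step
#' magnitude on the original scale is at least `min_step` photons. Plateau
#' levels and step sizes are reported as raw photon-count means. This
#' reproduces a "smallest-steps" visual analysis without inspection:
#' plateau means before and after each intensity drop define the step
#' sizes.
#'
#' @param trajectory Photon counts per line, length >= 4.
#' @param min_step Minimum accepted step magnitude, photons. Default 5,
#'   about half the unitary single-fluorophore intensity.
#' @param max_steps Maximum number of steps to consider.
#' @param penalty Minimum reduction of the variance-stabilized RSS to
#'   accept one more step; default `3 * log(length(trajectory))`.
#' @return An object of class `step_fit`: `plateaus` (data.frame start_line,
#'   end_line, level; 0-based inclusive line indices), `steps` (data.frame
#'   line, size, sign; line is the first line of the new plateau), and
#'   `rss` (raw-scale residual sum of squares of the plateau fit).
#' @export
detect_steps <- function(trajectory, min_step = 5, max_steps = 20L,
                         penalty = NULL) {
  y <- as.numeric(trajectory)
  n <- length(y)
  if (n < 4L) stop("trajectory must have at least 4 lines")
  if (any(!is.finite(y)) || any(y < 0)) {
    stop("trajectory must be finite and non-negative")
  }
  if (is.null(penalty)) penalty <- 3 * log(n)
  z <- 2 * sqrt(y + 0.375)

  best <- optimal_segmentation(z, 1L)
  k <- 0L
  while (k < max_steps && length(best$starts) < n) {
    cand <- optimal_segmentation(z, k + 2L)
    sizes <- diff(segment_levels(y, cand$starts))
    ok_size <- all(abs(sizes) >= min_step)
    ok_gain <- (best$rss - cand$rss) >= penalty
    if (!(ok_size && ok_gain)) break
    best <- cand
    k <- k + 1L
  }
  starts <- best$starts
  ends <- c(starts[-1L] - 1L, n)
  levels <- segment_levels(y, starts)
  plateaus <- data.frame(start_line = starts - 1L, end_line = ends - 1L,
                         level = levels)
  steps <- if (k > 0L) {
    data.frame(line = starts[-1L] - 1L, size = diff(levels),
               sign = sign(diff(levels)))
  } else {
    data.frame(line = integer(0), size = numeric(0), sign = numeric(0))
  }
  fitted <- rep(levels, ends - starts + 1L)
  structure(list(plateaus = plateaus, steps = steps,
                 rss = sum((y - fitted)^2), n_lines = n),
            class = "step_fit")
}

#' @export
print.step_fit <- function(x, ...) {
  cat(sprintf("Step fit: %d plateaus, %d steps, RSS %.4g\n",
              nrow(x$plateaus), nrow(x$steps), x$rss))
  invisible(x)
}

#' Reconstruct the piecewise-constant fit of a step decomposition
#' @param fit A `step_fit`.
#' @return Numeric vector of fitted levels, one per line.
#' @export
step_fit_reconstruction <- function(fit) {
  rep(fit$plateaus$level,
      fit$plateaus$end_line - fit$plateaus$start_line + 1L)
}

#' Calibrate the unitary single-fluorophore intensity from bleaching steps
#'
#' Takes the smallest-magnitude downward step of each trajectory as a
#' single-fluorophore photobleaching event, histograms the magnitudes at
#' `bin_width` (left edges at zero), and fits a Gaussian to the histogram
#' counts by least squares. Upward steps (binding or blinking-on) are
#' excluded. When the candidates occupy fewer than three histogram bins the
#' Gaussian is degenerate and the sample mean and s.d. are reported instead.
#'
#' @param stepfits A list of `step_fit` objects (one per trajectory).
#' @param bin_width Histogram bin width in photon counts (default 3).
#' @return An object of class `unitary_intensity`: `mean`, `sd` (photons per
#'   fluorophore per line sample), `n_steps`, `histogram_bin_width`,
#'   `candidates`, and `method` ("gaussian" or "moments").
#' @export
unitary_intensity <- function(stepfits, bin_width = 3) {
  if (inherits(stepfits, "step_fit")) stepfits <- list(stepfits)
  cand <- vapply(stepfits, function(f) {
    down <- f$steps$size[f$steps$sign < 0]
    if (!length(down)) NA_real_ else min(abs(down))
  }, numeric(1))
  cand <- cand[!is.na(cand)]
  if (length(cand) < 10L) {
    stop("need at least 10 single-step candidates, got ", length(cand))
  }
  breaks <- seq(0, ceiling(max(cand) / bin_width + 1) * bin_width,
                by = bin_width)
  h <- graphics::hist(cand, breaks = breaks, plot = FALSE)
  occupied <- sum(h$counts > 0)
  fit_mean <- NA_real_
  fit_sd <- NA_real_
  method <- "moments"
  if (occupied >= 3L) {
    df <- data.frame(x = h$mids, y = h$counts)
    mu0 <- sum(df$x * df$y) / sum(df$y)
    sd0 <- max(sqrt(sum(df$y * (df$x - mu0)^2) / sum(df$y)), bin_width / 2)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a * exp(-(x - mu)^2 / (2 * s^2)), data = df,
                        start = list(a = max(df$y), mu = mu0, s = sd0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      co <- stats::coef(fit)
      fit_mean <- unname(co["mu"])
      fit_sd <- abs(unname(co["s"]))
      method <- "gaussian"
    }
  }
  if (method == "moments") {
    fit_mean <- mean(cand)
    fit_sd <- stats::sd(cand)
    if (is.na(fit_sd)) fit_sd <- 0
  }
  structure(list(mean = fit_mean, sd = fit_sd, n_steps = length(cand),
                 histogram_bin_width = bin_width, candidates = cand,
                 method = method),
            class = "unitary_intensity")
}

#' @export
print.unitary_intensity <- function(x, ...) {
  cat(sprintf(
    "Unitary intensity: %.2f +/- %.2f photons/fluorophore (n = %d, %s fit)\n",
    x$mean, x$sd, x$n_steps, x$method))
  invisible(x)
}

#' Photobleaching decay rate of an intensity trajectory
#'
#' Least-squares fit of `I(t) = I0 * exp(-k t) + c` to a decaying photon
#' count trajectory; reports the decay rate `k` per second.
#'
#' @param trajectory Photon counts per line, length >= 10.
#' @param line_period_s Seconds per line.
#' @return A list: `rate` (s^-1), `stderr`, `i0`, `baseline`, `r_squared`,
#'   `rmse`, `converged`.
#' @export
decay_rate <- function(trajectory, line_period_s) {
  y <- as.numeric(trajectory)
  if (length(y) < 10L) stop("trajectory must have at least 10 lines")
  stopifnot(line_period_s > 0)
  t <- (seq_along(y) - 0.5) * line_period_s
  if (stats::sd(y) == 0) {
    return(list(rate = 0, stderr = 0, i0 = 0, baseline = y[1L],
                r_squared = 1, rmse = 0, converged = TRUE))
  }
  c0 <- nonzero_start(min(y), max(y))
  i0 <- max(y) - min(y)
  pos <- pmax(y - c0, i0 * 1e-3)
  k0 <- tryCatch({
    sl <- stats::coef(stats::lm(log(pos) ~ t))[2L]
    max(-unname(sl), 1e-3)
  }, error = function(e) 0.5)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-k * t) + c0f,
                      data = data.frame(y = y, t = t),
                      start = list(a = i0, k = k0, c0f = c0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(rate = NA_real_, stderr = NA_real_, i0 = NA_real_,
                baseline = NA_real_, r_squared = NA_real_, rmse = NA_real_,
                converged = FALSE))
  }
  co <- stats::coef(fit)
  res <- stats::resid(fit)
  list(rate = unname(co["k"]),
       stderr = unname(summary(fit)$coefficients["k", "Std. Error"]),
       i0 = unname(co["a"]), baseline = unname(co["c0f"]),
       r_squared = 1 - sum(res^2) / sum((y - mean(y))^2),
       rmse = sqrt(mean(res^2)), converged = TRUE)
}
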