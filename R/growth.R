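#' Oligomer growth rate from time-stamped photon counts
#'
#' The growth rate is the difference between final and initial photon counts
#' divided by the total observation time, reported both in photons/s and,
#' via the unitary intensity and labeling efficiency, in molecules/s.
#'
#' @param times_s Time stamps, seconds, strictly increasing, >= 2 points.
#' @param counts Photon counts at each time (background-corrected window
#'   sums).
#' @param unit A `unitary_intensity` or photons per fluorophore (default
#'   11). Pass `unit = 1` with `labeling_efficiency = 1` if `counts` are
#'   already molecule numbers.
#' @param labeling_efficiency Fraction of molecules carrying a fluorophore.
#' @return An object of class `growth_record`: `rate_photons_per_s`,
#'   `rate_molecules_per_s`, `start_molecules`, `end_molecules`,
#'   `duration_s`, `monotone_trend` (Kendall-type fraction of upward
#'   increments > 0.5).
#' @export
growth_rate <- function(times_s, counts, unit = 11,
                        labeling_efficiency = 1) {
  t <- as.numeric(times_s)
  y <- as.numeric(counts)
  if (length(t) < 2L) stop("need at least 2 time points")
  if (length(t) != length(y)) stop("times and counts lengths differ")
  if (any(diff(t) <= 0)) stop("times must be strictly increasing")
  unit_mean <- if (inherits(unit, "unitary_intensity")) unit$mean else unit
  stopifnot(unit_mean > 0, labeling_efficiency > 0, labeling_efficiency <= 1)
  dt <- t[length(t)] - t[1L]
  dphot <- y[length(y)] - y[1L]
  to_mol <- function(c) c / unit_mean / labeling_efficiency
  incr <- diff(y)
  structure(list(times_s = t, counts = y,
                 rate_photons_per_s = dphot / dt,
                 rate_molecules_per_s = to_mol(dphot) / dt,
                 start_molecules = to_mol(y[1L]),
                 end_molecules = to_mol(y[length(y)]),
                 duration_s = dt,
                 monotone_trend = if (length(incr)) {
                   mean(incr > 0) > 0.5
                 } else NA),
            class = "growth_record")
}

#' @export
print.growth_record <- function(x, ...) {
  cat(sprintf(
    "Growth: %.2f -> %.2f molecules in %.3g s (%.1f photons/s, %.1f molecules/s)\n",
    x$start_molecules, x$end_molecules, x$duration_s,
    x$rate_photons_per_s, x$rate_molecules_per_s))
  invisible(x)
}

#' Photon counts of a cluster over a frame sequence
#'
#' Sums photon counts in a square window (default 7 x 7 pixels) anchored on
#' the cluster in every frame. The window center is the brightest pixel of
#' the time-summed stack, which coincides with the cluster's
#' maximum-intensity point.
#'
#' @param frames ny x nx x n_frames array of photon counts.
#' @param times_s Frame time stamps.
#' @param window Window side in pixels (odd; default 7).
#' @param background Per-pixel background to subtract (scalar; default 0).
#' @return A data.frame with `time_s` and `counts`.
#' @export
measure_cluster_counts <- function(frames, times_s, window = 7L,
                                   background = 0) {
  stopifnot(length(dim(frames)) == 3L, window %% 2 == 1)
  n_frames <- dim(frames)[3L]
  stopifnot(length(times_s) == n_frames)
  half <- (window - 1L) %/% 2L
  total <- apply(frames, c(1L, 2L), sum)
  ctr <- which(total == max(total), arr.ind = TRUE)[1L, ]
  ys <- max(1L, ctr[1L] - half):min(nrow(total), ctr[1L] + half)
  xs <- max(1L, ctr[2L] - half):min(ncol(total), ctr[2L] + half)
  counts <- vapply(seq_len(n_frames), function(f) {
    sum(frames[ys, xs, f]) - background * length(ys) * length(xs)
  }, numeric(1))
  data.frame(time_s = times_s, counts = pmax(counts, 0))
}

# Background-subtracted, clamped profile restricted to a window around the
# cluster; moment-based centroid and FWHM (2.355 * weighted s.d.). The
# window is shared between the frames being compared so their statistics
# are commensurable.
profile_window <- function(w, frac = 0.15, pad = 3L) {
  above <- which(w > frac * max(w))
  if (!length(above)) return(seq_along(w))
  max(1L, min(above) - pad):min(length(w), max(above) + pad)
}

profile_stats <- function(profile, window) {
  bg <- stats::quantile(profile$intensity, 0.25, names = FALSE)
  w <- pmax(profile$intensity - bg, 0)[window]
  # relative clamp: amplitude-invariant width, suppresses the noise floor
  w[w < 0.15 * max(w)] <- 0
  pos <- profile$position_nm[window]
  tot <- sum(w)
  if (tot <= 0) {
    return(list(mass = 0, centroid_nm = NA_real_, fwhm_nm = NA_real_))
  }
  ctr <- sum(pos * w) / tot
  sdv <- sqrt(sum(w * (pos - ctr)^2) / tot)
  list(mass = tot, centroid_nm = ctr,
       fwhm_nm = 2 * sqrt(2 * log(2)) * sdv)
}

#' Classify the growth direction of a DNA-bound cluster
#'
#' Compares mean-intensity profiles along the DNA axis and perpendicular to
#' it between the start and the end of a frame sequence. Growth by new
#' molecules binding adjacent DNA shifts the along-axis intensity centroid
#' (label "left" or "right"); growth by direct protein-protein stacking
#' broadens the perpendicular profile without moving the centroid (label
#' "perpendicular"); both signatures give "mixed"; no significant intensity
#' gain gives "none". The centroid and width changes are estimated as
#' linear trends over all frames evaluated at the first and last time
#' stamps, which suppresses single-frame shot noise while measuring the
#' same first-to-last change.
#'
#' @param frames ny x nx x n_frames photon-count array; the DNA axis is x
#'   (columns).
#' @param roi Optional ROI (0-based `x0`, `y0`, `width`, `height`)
#'   containing the cluster in all frames.
#' @param pixel_size_nm Pixel size, nm.
#' @param shift_threshold_px Centroid shift (pixels) above which along-axis
#'   growth is called.
#' @param fwhm_gain_threshold Relative perpendicular FWHM gain above which
#'   stacking growth is called.
#' @param gain_threshold Minimum relative total-intensity gain to call any
#'   growth.
#' @param n_average Number of frames averaged at each end of the sequence
#'   to suppress shot noise before profiling (default 2).
#' @return A list of class `direction_call`: `direction` ("left", "right",
#'   "perpendicular", "mixed", "none"), `centroid_shift_px`, `fwhm_gain`,
#'   `intensity_gain`, and the four profiles.
#' @export
classify_direction <- function(frames, roi = NULL, pixel_size_nm = 100,
                               shift_threshold_px = 1,
                               fwhm_gain_threshold = 0.15,
                               gain_threshold = 0.10,
                               n_average = 2L) {
  stopifnot(length(dim(frames)) == 3L, dim(frames)[3L] >= 2L)
  n_frames <- dim(frames)[3L]
  n_average <- min(n_average, floor(n_frames / 2))
  avg <- function(idx) {
    apply(frames[, , idx, drop = FALSE], c(1L, 2L), mean)
  }
  first <- avg(seq_len(n_average))
  last <- avg((n_frames - n_average + 1L):n_frames)
  if (!is.null(roi)) {
    roi <- as.list(roi)
    crop <- function(img) {
      img[(roi$y0 + 1L):(roi$y0 + roi$height),
          (roi$x0 + 1L):(roi$x0 + roi$width), drop = FALSE]
    }
    if (roi$x0 < 0 || roi$y0 < 0 ||
        roi$x0 + roi$width > ncol(first) ||
        roi$y0 + roi$height > nrow(first)) {
      stop("ROI outside frame bounds")
    }
    first <- crop(first)
    last <- crop(last)
  }
  p_first_x <- roi_profile(first, NULL, "x", pixel_size_nm)
  p_last_x <- roi_profile(last, NULL, "x", pixel_size_nm)

  win_for <- function(p0, p1) {
    q <- function(p) stats::quantile(p$intensity, 0.25, names = FALSE)
    w <- pmax(p0$intensity - q(p0), 0) + pmax(p1$intensity - q(p1), 0)
    profile_window(w)
  }
  win_x <- win_for(p_first_x, p_last_x)
  # perpendicular profiles restricted to the cluster's along-axis window so
  # the empty flanks do not dilute the signal
  p_first_y <- roi_profile(first[, win_x, drop = FALSE], NULL, "y",
                           pixel_size_nm)
  p_last_y <- roi_profile(last[, win_x, drop = FALSE], NULL, "y",
                          pixel_size_nm)
  win_y <- win_for(p_first_y, p_last_y)

  # per-frame centroid, width and mass inside the shared windows; the
  # first-to-last change is read off a linear trend over all frames
  per_frame <- lapply(seq_len(n_frames), function(f) {
    img <- frames[, , f]
    if (!is.null(roi)) img <- crop(img)
    sx <- profile_stats(roi_profile(img, NULL, "x", pixel_size_nm), win_x)
    sy <- profile_stats(roi_profile(img[, win_x, drop = FALSE], NULL, "y",
                                    pixel_size_nm), win_y)
    c(mass = sx$mass, cx = sx$centroid_nm, fy = sy$fwhm_nm)
  })
  pf <- do.call(rbind, per_frame)
  tt <- seq_len(n_frames)
  endpoint_change <- function(v) {
    ok <- is.finite(v)
    if (sum(ok) < 3L) {
      return(c(v[1L], v[length(v)]))
    }
    co <- stats::coef(stats::lm(v[ok] ~ tt[ok]))
    unname(c(co[1L] + co[2L] * tt[1L], co[1L] + co[2L] * tt[n_frames]))
  }
  mass01 <- endpoint_change(pf[, "mass"])
  cx01 <- endpoint_change(pf[, "cx"])
  fy01 <- endpoint_change(pf[, "fy"])

  gain <- (mass01[2L] - mass01[1L]) / max(mass01[1L], .Machine$double.eps)
  shift_px <- (cx01[2L] - cx01[1L]) / pixel_size_nm
  fwhm_gain <- if (!all(is.finite(fy01)) || fy01[1L] <= 0) {
    NA_real_
  } else {
    (fy01[2L] - fy01[1L]) / fy01[1L]
  }

  # normalized scores: 1 = at threshold; dominance resolves double hits
  along_n <- if (is.finite(shift_px)) abs(shift_px) / shift_threshold_px else 0
  perp_n <- if (is.finite(fwhm_gain)) fwhm_gain / fwhm_gain_threshold else 0
  along_label <- if (is.finite(shift_px) && shift_px > 0) "right" else "left"
  direction <- if (gain < gain_threshold) {
    "none"
  } else if (along_n >= 1 && perp_n >= 1) {
    if (along_n >= 2 * perp_n) {
      along_label
    } else if (perp_n >= 2 * along_n) {
      "perpendicular"
    } else {
      "mixed"
    }
  } else if (along_n >= 1) {
    along_label
  } else if (perp_n >= 1) {
    "perpendicular"
  } else if (max(along_n, perp_n) >= 2 / 3) {
    if (along_n > perp_n) along_label else "perpendicular"
  } else {
    "mixed"
  }
  structure(list(direction = direction, centroid_shift_px = shift_px,
                 fwhm_gain = fwhm_gain, intensity_gain = gain,
                 profiles = list(first_x = p_first_x, last_x = p_last_x,
                                 first_y = p_first_y, last_y = p_last_y)),
            class = "direction_call")
}

#' @export
print.direction_call <- function(x, ...) {
  cat(sprintf(
    "Growth direction: %s (centroid shift %.2f px, perpendicular FWHM gain %.1f%%, intensity gain %.1f%%)\n",
    x$direction, x$centroid_shift_px, 100 * x$fwhm_gain,
    100 * x$intensity_gain))
  invisible(x)
}

#' Mean-squared-displacement diffusion test for a trace
#'
#' Computes the MSD of a trace's sub-pixel positions versus lag time and
#' fits a line through it. For free 1D diffusion the slope is `2 D`; for a
#' static molecule the MSD is a flat localization-noise floor and the slope
#' is indistinguishable from zero. The verdict threshold is calibrated so
#' static traces observed with sub-pixel localization noise stay below it.
#'
#' @param trace A `trace` object with >= 11 samples.
#' @param pixel_size_nm Pixel size, nm.
#' @param line_period_s Seconds per line.
#' @param n_lags Number of MSD lags (default 10).
#' @param slope_threshold_nm2_s MSD slope above which the trace is called
#'   diffusive (default 1e4 nm^2/s, i.e. D = 0.005 um^2/s).
#' @return A list of class `diffusion_stats`: `msd_nm2` (per lag),
#'   `lag_s`, `msd_slope_nm2_s`, `d_um2_s` (slope / 2), `drift_nm_s`,
#'   `verdict` ("static" or "diffusive").
#' @export
diffusion_stats <- function(trace, pixel_size_nm = 100,
                            line_period_s = NULL, n_lags = 10L,
                            slope_threshold_nm2_s = 1e4) {
  stopifnot(inherits(trace, "trace"))
  s <- trace$samples
  if (nrow(s) < n_lags + 1L) {
    stop("trace too short: need at least ", n_lags + 1L, " samples")
  }
  if (is.null(line_period_s)) {
    line_period_s <- stats::median(diff(s$time_s) / diff(s$line))
  }
  x_nm <- s$position_px * pixel_size_nm
  # MSD over integer line lags; samples may have gaps, so pair by line index
  lags <- seq_len(n_lags)
  msd <- vapply(lags, function(L) {
    i <- match(s$line + L, s$line)
    ok <- !is.na(i)
    if (sum(ok) < 3L) return(NA_real_)
    mean((x_nm[i[ok]] - x_nm[ok])^2)
  }, numeric(1))
  lag_s <- lags * line_period_s
  ok <- is.finite(msd)
  if (sum(ok) < 3L) stop("too few valid lags for MSD")
  slope <- unname(stats::coef(stats::lm(msd[ok] ~ lag_s[ok]))[2L])
  drift <- (x_nm[nrow(s)] - x_nm[1L]) / (s$time_s[nrow(s)] - s$time_s[1L])
  structure(list(msd_nm2 = msd, lag_s = lag_s,
                 msd_slope_nm2_s = slope,
                 d_um2_s = slope / 2 * 1e-6,
                 drift_nm_s = drift,
                 verdict = if (is.finite(slope) &&
                               slope > slope_threshold_nm2_s) {
                   "diffusive"
                 } else {
                   "static"
                 }),
            class = "diffusion_stats")
}

#' @export
print.diffusion_stats <- function(x, ...) {
  cat(sprintf(
    "Diffusion: %s (MSD slope %.3g nm^2/s, D %.3g um^2/s, drift %.3g nm/s)\n",
    x$verdict, x$msd_slope_nm2_s, x$d_um2_s, x$drift_nm_s))
  invisible(x)
}
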