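# Independent oracles and shared fixtures for the test suite.

# Exhaustive enumeration of all piecewise-constant segmentations of y into
# n_seg segments, minimizing the residual sum of squares. Brute force over
# all breakpoint placements; only usable for short inputs.
exhaustive_segmentation <- function(y, n_seg) {
  n <- length(y)
  seg_rss <- function(starts) {
    ends <- c(starts[-1L] - 1L, n)
    sum(vapply(seq_along(starts), function(s) {
      seg <- y[starts[s]:ends[s]]
      sum((seg - mean(seg))^2)
    }, numeric(1)))
  }
  if (n_seg == 1L) {
    return(list(starts = 1L, rss = seg_rss(1L)))
  }
  combos <- utils::combn(2:n, n_seg - 1L)
  best_rss <- Inf
  best_starts <- NULL
  for (j in seq_len(ncol(combos))) {
    starts <- c(1L, combos[, j])
    r <- seg_rss(starts)
    if (r < best_rss) {
      best_rss <- r
      best_starts <- starts
    }
  }
  list(starts = best_starts, rss = best_rss)
}

# Simulate a set of photobleaching staircases and calibrate the unitary
# intensity from them (the step-counting pipeline under test conditions:
# 20 ms lines, 12 s trajectories, 1-3 fluorophores each).
calibrate_from_staircases <- function(seed, n_traj = 50, unit = 11,
                                      min_step = 5) {
  cfg <- sim_config(line_period_s = 0.02, duration_s = 12,
                    unit_intensity = unit, background_rate = 0.2,
                    seed = seed)
  set.seed(seed * 1000L)
  nfl <- sample(1:3, n_traj, replace = TRUE)
  fits <- lapply(seq_len(n_traj), function(i) {
    tr <- simulate_photobleach_trace(nfl[i], cfg, seed = seed * 1000L + i)
    detect_steps(tr$intensity, min_step = min_step)
  })
  unitary_intensity(fits)
}

# Match ground-truth binding events to tracked traces by time overlap and
# position proximity. Returns a data.frame with one row per event that was
# visible for at least min_lines, and the matched trace position error.
match_events_to_traces <- function(truth, traces, config,
                                   min_lines = 2L, tol_px = 1.5) {
  ev <- truth$events
  if (!nrow(ev)) {
    return(data.frame(event_id = integer(0), recovered = logical(0),
                      pos_err_px = numeric(0)))
  }
  fl <- truth$fluorophores
  dark_end <- vapply(ev$event_id, function(id) {
    b <- fl$bleach_time_s[fl$event_id == id]
    if (!length(b)) -Inf else max(b)
  }, numeric(1))
  t_end_vis <- pmin(ifelse(is.na(ev$unbind_time_s), config$duration_s,
                           ev$unbind_time_s),
                    dark_end, config$duration_s)
  visible_s <- pmax(t_end_vis - ev$bind_time_s, 0)
  keep <- visible_s >= min_lines * config$line_period_s
  ev <- ev[keep, , drop = FALSE]
  t_end_vis <- t_end_vis[keep]
  pos_px <- ev$position_nm / config$pixel_size_nm
  rec <- logical(nrow(ev))
  err <- rep(NA_real_, nrow(ev))
  for (i in seq_len(nrow(ev))) {
    for (tr in traces) {
      overlap <- tr$t_start_s < t_end_vis[i] &&
        tr$t_end_s > ev$bind_time_s[i]
      if (!overlap) next
      d <- abs(mean(tr$samples$position_px) - pos_px[i])
      if (d <= tol_px) {
        rec[i] <- TRUE
        err[i] <- d
        break
      }
    }
  }
  data.frame(event_id = ev$event_id, recovered = rec, pos_err_px = err,
             visible_s = visible_s[keep][seq_len(nrow(ev))])
}

# End-to-end cluster-size recovery: render a static cluster of known size
# through the imaging model (PSF, background, per-pixel dead-time
# censoring), measure it with a window sum (per-pixel dead-time
# corrected), and convert photons to molecules.
recover_cluster_size <- function(true_size, seed, labeling = 0.9,
                                 dead_time_ns = 35) {
  cfg <- sim_config(bleach_rate = 0, labeling_efficiency = labeling,
                    dead_time_ns = dead_time_ns, background_rate = 0.2,
                    seed = seed)
  g <- simulate_growth_frames("bleach", start_molecules = true_size,
                              growth_rate = 0, n_frames = 10,
                              frame_period_s = 0.1, ny = 21, nx = 21,
                              config = cfg, seed = seed)
  dt <- config_deadtime(cfg)
  frames_corr <- array(correct_counts(g$frames, dt), dim = dim(g$frames))
  meas <- measure_cluster_counts(frames_corr, g$times_s, window = 11L,
                                 background = cfg$background_rate)
  m <- count_molecules(mean(meas$counts), background = 0, unit = 11,
                       labeling_efficiency = labeling,
                       deadtime = dead_time_model(tau_s = 0))
  m$n_molecules
}
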