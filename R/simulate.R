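#' Simulation configuration for single-molecule kymograph experiments
#'
#' Collects every generative parameter of the ground-truth simulator. The
#' defaults reproduce the experimental regime of the optical-tweezers confocal
#' assay this package analyses: lambda-phage dsDNA (48,502 bp, 0.34 nm/bp,
#' ~16.5 um) scanned at 100 nm pixels and 50 us pixel dwell, one line every
#' 10 ms; a single fluorophore emitting on average 11 photons per line sample;
#' per-fluorophore photobleaching at 0.43 s^-1; 90% labeling efficiency; a
#' 35 ns detector dead time; and monomer dissociation at 0.29 s^-1 with
#' permanent attachment of clusters of 3 or more protomers.
#'
#' @param k_off_monomer Monomer dissociation rate, s^-1.
#' @param dimer_k_off Dimer dissociation rate, s^-1. Dimers can detach but no
#'   separate rate is known, so the default equals `k_off_monomer`.
#' @param arrival_rate Binding events per second over the whole DNA
#'   (encodes k_on * concentration * available sites).
#' @param concentration Protein concentration, molar.
#' @param dna_length_bp Tether length in base pairs.
#' @param pixel_size_nm Confocal pixel size, nm.
#' @param pixel_dwell_us Pixel dwell time, microseconds.
#' @param line_period_s Time between successive scan lines, seconds.
#' @param duration_s Kymograph duration, seconds.
#' @param unit_intensity Mean photons emitted per fluorophore per line sample.
#' @param bleach_rate Per-fluorophore photobleaching rate, s^-1.
#' @param labeling_efficiency Fraction of protomers carrying a fluorophore,
#'   in (0, 1].
#' @param dead_time_ns Detector dead time, nanoseconds.
#' @param permanence_threshold Cluster size at and above which the detachment
#'   rate is zero.
#' @param primary_growth_rate Per-cluster rate (s^-1) of protomer addition via
#'   DNA binding adjacent to the cluster (extends along the DNA axis).
#' @param secondary_growth_rate Per-cluster rate (s^-1) of protomer addition
#'   via direct protein-protein stacking (position on DNA unchanged).
#' @param psf_fwhm_nm Emission point-spread-function FWHM, nm.
#' @param background_rate Mean background photons per pixel per line.
#' @param footprint_bp DNA footprint per protomer, base pairs.
#' @param blinking Reserved switch for fluorophore blinking; must stay FALSE
#'   (no blinking rate is available to parameterize it).
#' @param seed Integer seed; fixing it fixes every simulator output.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(k_off_monomer = 0.29,
                       dimer_k_off = k_off_monomer,
                       arrival_rate = 0.5,
                       concentration = 1e-9,
                       dna_length_bp = 48502L,
                       pixel_size_nm = 100,
                       pixel_dwell_us = 50,
                       line_period_s = 0.01,
                       duration_s = 60,
                       unit_intensity = 11,
                       bleach_rate = 0.43,
                       labeling_efficiency = 0.90,
                       dead_time_ns = 35,
                       permanence_threshold = 3L,
                       primary_growth_rate = 0,
                       secondary_growth_rate = 0,
                       psf_fwhm_nm = 350,
                       background_rate = 0.2,
                       footprint_bp = 10,
                       blinking = FALSE,
                       seed = 1L) {
  cfg <- list(k_off_monomer = k_off_monomer, dimer_k_off = dimer_k_off,
              arrival_rate = arrival_rate, concentration = concentration,
              dna_length_bp = as.integer(dna_length_bp),
              pixel_size_nm = pixel_size_nm, pixel_dwell_us = pixel_dwell_us,
              line_period_s = line_period_s, duration_s = duration_s,
              unit_intensity = unit_intensity, bleach_rate = bleach_rate,
              labeling_efficiency = labeling_efficiency,
              dead_time_ns = dead_time_ns,
              permanence_threshold = as.integer(permanence_threshold),
              primary_growth_rate = primary_growth_rate,
              secondary_growth_rate = secondary_growth_rate,
              psf_fwhm_nm = psf_fwhm_nm, background_rate = background_rate,
              footprint_bp = footprint_bp, blinking = isTRUE(blinking),
              seed = as.integer(seed))
  rates <- c(cfg$k_off_monomer, cfg$dimer_k_off, cfg$arrival_rate,
             cfg$bleach_rate, cfg$primary_growth_rate,
             cfg$secondary_growth_rate, cfg$background_rate)
  if (any(!is.finite(rates)) || any(rates < 0)) {
    stop("all rates must be finite and >= 0")
  }
  if (cfg$labeling_efficiency <= 0 || cfg$labeling_efficiency > 1) {
    stop("labeling_efficiency must lie in (0, 1]")
  }
  if (cfg$duration_s <= 0) stop("duration_s must be > 0")
  if (cfg$blinking) stop("blinking is not parameterized; leave FALSE")
  n_px <- n_pixels(cfg)
  if (cfg$pixel_dwell_us * 1e-6 * n_px > cfg$line_period_s) {
    stop("pixel_dwell_us * pixels per line exceeds line_period_s")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Simulation config: %d bp DNA (%d px at %g nm), %g s at %g ms/line\n",
    "  k_off (monomer) %g /s, arrivals %g /s, unit intensity %g photons,\n",
    "  bleach %g /s, labeling %g, dead time %g ns, permanence >= %d\n"),
    x$dna_length_bp, n_pixels(x), x$pixel_size_nm, x$duration_s,
    x$line_period_s * 1e3, x$k_off_monomer, x$arrival_rate,
    x$unit_intensity, x$bleach_rate, x$labeling_efficiency,
    x$dead_time_ns, x$permanence_threshold))
  invisible(x)
}

# number of position pixels covering the tether
n_pixels <- function(config) {
  as.integer(ceiling(config$dna_length_bp * 0.34 / config$pixel_size_nm))
}

#' Dead-time model implied by a simulation config
#' @param config A [sim_config()].
#' @return A [dead_time_model()] with the config's dead time and pixel dwell.
#' @export
config_deadtime <- function(config) {
  dead_time_model(tau_s = config$dead_time_ns * 1e-9,
                  window_s = config$pixel_dwell_us * 1e-6)
}

#' Simulate exponential single-molecule dwell times
#'
#' Draws `n` independent dwell times from the exponential distribution with
#' rate `k_off` (mean `1/k_off`), the ground-truth model for monomer
#' residence on DNA.
#'
#' @param k_off Dissociation rate, s^-1; must be > 0.
#' @param n Number of dwell times; must be >= 1.
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of `n` dwell times in seconds.
#' @export
simulate_dwell_times <- function(k_off, n, seed = NULL) {
  if (!is.numeric(k_off) || length(k_off) != 1L || !is.finite(k_off) ||
      k_off <= 0) {
    stop("k_off must be a single positive number")
  }
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop("n must be a positive integer")
  }
  if (!is.null(seed)) set.seed(seed)
  stats::rexp(as.integer(n), rate = k_off)
}

#' Simulate a photobleaching intensity staircase
#'
#' Each of `n_fluor` fluorophores emits Poisson(`unit_intensity`) photons per
#' line sample until its own exponential(`bleach_rate`) bleach time; the
#' trajectory is the per-line sum plus Poisson background. The true bleach
#' (step) times are returned alongside.
#'
#' @param n_fluor Number of fluorophores, >= 1.
#' @param config A [sim_config()]; uses `unit_intensity`, `bleach_rate`,
#'   `line_period_s`, `background_rate`, `duration_s` and `seed`.
#' @param duration_s Trajectory length, seconds (defaults to config value).
#' @param seed Integer seed (defaults to config value).
#' @return A list with `intensity` (photon counts per line), `time_s`,
#'   `bleach_times_s` (all fluorophores) and `step_times_s` (those inside the
#'   observation window, i.e. the true steps).
#' @export
simulate_photobleach_trace <- function(n_fluor, config = sim_config(),
                                       duration_s = config$duration_s,
                                       seed = config$seed) {
  if (!is.numeric(n_fluor) || length(n_fluor) != 1L || n_fluor < 1 ||
      n_fluor != round(n_fluor)) {
    stop("n_fluor must be a positive integer")
  }
  if (!is.null(seed)) set.seed(seed)
  n_fluor <- as.integer(n_fluor)
  n_lines <- max(1L, as.integer(round(duration_s / config$line_period_s)))
  t_mid <- (seq_len(n_lines) - 0.5) * config$line_period_s
  bleach <- if (config$bleach_rate > 0) {
    stats::rexp(n_fluor, rate = config$bleach_rate)
  } else {
    rep(Inf, n_fluor)
  }
  active <- vapply(t_mid, function(t) sum(bleach > t), integer(1))
  intensity <- stats::rpois(n_lines, config$unit_intensity * active) +
    stats::rpois(n_lines, config$background_rate)
  list(intensity = intensity,
       time_s = t_mid,
       bleach_times_s = bleach,
       step_times_s = sort(bleach[bleach <= duration_s]))
}

# Gillespie evolution of one cluster: returns protomer table and unbind time.
# Primary growth extends the cluster along the DNA axis (footprint spacing,
# one side chosen at random per cluster); secondary growth stacks protomers
# at the seed position (perpendicular to the DNA, so the kymograph position
# is unchanged).
simulate_cluster <- function(bind_time, position_nm, config) {
  footprint_nm <- config$footprint_bp * 0.34
  side <- sample(c(-1, 1), 1L)
  prot <- data.frame(attach_time_s = bind_time, offset_nm = 0,
                     perpendicular = FALSE)
  t <- bind_time
  unbind <- NA_real_
  n_primary <- 0L
  repeat {
    size <- nrow(prot)
    detach_rate <- if (size >= config$permanence_threshold) 0 else if
      (size == 1L) config$k_off_monomer else config$dimer_k_off
    total <- detach_rate + config$primary_growth_rate +
      config$secondary_growth_rate
    if (total <= 0) break
    t <- t + stats::rexp(1L, rate = total)
    if (t >= config$duration_s) break
    u <- stats::runif(1L) * total
    if (u < detach_rate) {
      unbind <- t
      break
    } else if (u < detach_rate + config$primary_growth_rate) {
      n_primary <- n_primary + 1L
      prot <- rbind(prot, data.frame(attach_time_s = t,
                                     offset_nm = side * n_primary * footprint_nm,
                                     perpendicular = FALSE))
    } else {
      prot <- rbind(prot, data.frame(attach_time_s = t, offset_nm = 0,
                                     perpendicular = TRUE))
    }
  }
  prot$position_nm <- position_nm + prot$offset_nm
  list(protomers = prot, unbind_time_s = unbind, max_size = nrow(prot))
}

#' Simulate a kymograph with ground truth
#'
#' Binding events arrive as a Poisson process at `arrival_rate` with uniform
#' positions along the tether. Monomers and dimers detach at their configured
#' rates; clusters that reach `permanence_threshold` protomers never detach.
#' Clusters gain protomers by primary (along-DNA) and secondary
#' (perpendicular) growth. Each labeled protomer carries a fluorophore that
#' emits Poisson(`unit_intensity`) photons per line until it photobleaches;
#' photons are spread over position pixels by a Gaussian PSF, summed with
#' Poisson background, and finally dead-time censored per pixel.
#'
#' @param config A [sim_config()].
#' @return A list with `kymograph` (a [kymograph()] object) and `truth`, the
#'   ground truth: `events` (one row per binding event: id, bind/unbind time,
#'   seed position, final and max size), `fluorophores` (one row per
#'   fluorophore: event id, position, attach and bleach times) and
#'   `total_emitted_photons` (signal photons before background and
#'   censoring).
#' @export
simulate_kymograph <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L_nm <- config$dna_length_bp * 0.34
  n_px <- n_pixels(config)
  n_lines <- as.integer(round(config$duration_s / config$line_period_s))
  if (n_lines < 1L) stop("duration shorter than one line period")

  n_ev <- stats::rpois(1L, config$arrival_rate * config$duration_s)
  events <- data.frame(event_id = integer(0), bind_time_s = numeric(0),
                       unbind_time_s = numeric(0), position_nm = numeric(0),
                       final_size = integer(0), max_size = integer(0))
  fluor <- data.frame(event_id = integer(0), position_nm = numeric(0),
                      attach_time_s = numeric(0), bleach_time_s = numeric(0))
  if (n_ev > 0) {
    bind_times <- sort(stats::runif(n_ev, 0, config$duration_s))
    positions <- stats::runif(n_ev, 0, L_nm)
    for (i in seq_len(n_ev)) {
      cl <- simulate_cluster(bind_times[i], positions[i], config)
      events <- rbind(events, data.frame(
        event_id = i, bind_time_s = bind_times[i],
        unbind_time_s = cl$unbind_time_s, position_nm = positions[i],
        final_size = nrow(cl$protomers), max_size = cl$max_size))
      labeled <- stats::runif(nrow(cl$protomers)) <= config$labeling_efficiency
      if (any(labeled)) {
        p <- cl$protomers[labeled, , drop = FALSE]
        life <- if (config$bleach_rate > 0) {
          stats::rexp(nrow(p), rate = config$bleach_rate)
        } else {
          rep(Inf, nrow(p))
        }
        fluor <- rbind(fluor, data.frame(
          event_id = i, position_nm = p$position_nm,
          attach_time_s = p$attach_time_s,
          bleach_time_s = p$attach_time_s + life))
      }
    }
  }

  signal <- matrix(0L, nrow = n_px, ncol = n_lines)
  total_emitted <- 0L
  sigma_px <- config$psf_fwhm_nm / (2 * sqrt(2 * log(2))) / config$pixel_size_nm
  t_mid <- (seq_len(n_lines) - 0.5) * config$line_period_s
  if (nrow(fluor) > 0) {
    unbind <- events$unbind_time_s[fluor$event_id]
    unbind[is.na(unbind)] <- Inf
    bindt <- events$bind_time_s[fluor$event_id]
    for (f in seq_len(nrow(fluor))) {
      on <- t_mid >= fluor$attach_time_s[f] & t_mid < fluor$bleach_time_s[f] &
        t_mid >= bindt[f] & t_mid < unbind[f]
      lines_on <- which(on)
      if (!length(lines_on)) next
      # Gaussian PSF integrated per pixel, normalized over the image so that
      # emitted photons are conserved in the rendered counts
      pos_px <- fluor$position_nm[f] / config$pixel_size_nm
      edges <- 0:n_px
      w <- diff(stats::pnorm(edges, mean = pos_px, sd = sigma_px))
      w <- w / sum(w)
      nph <- stats::rpois(length(lines_on), config$unit_intensity)
      total_emitted <- total_emitted + sum(nph)
      for (j in seq_along(lines_on)) {
        if (nph[j] > 0) {
          signal[, lines_on[j]] <- signal[, lines_on[j]] +
            stats::rmultinom(1L, nph[j], w)[, 1L]
        }
      }
    }
  }
  counts <- signal + matrix(stats::rpois(n_px * n_lines,
                                         config$background_rate),
                            nrow = n_px)
  if (config$dead_time_ns > 0) {
    counts <- matrix(censor_counts(counts, config_deadtime(config)),
                     nrow = n_px)
  }
  storage.mode(counts) <- "integer"
  truth <- list(events = events, fluorophores = fluor,
                total_emitted_photons = total_emitted)
  list(kymograph = kymograph(counts,
                             pixel_size_nm = config$pixel_size_nm,
                             line_period_s = config$line_period_s,
                             channel = "blue"),
       truth = truth)
}

#' Simulate time-stamped 2D scan frames of a growing cluster
#'
#' Renders a sequence of confocal frames of a single DNA-bound cluster for
#' growth-rate and growth-direction analysis. The DNA axis is the x (column)
#' axis. `mechanism = "primary"` adds protomers along the DNA at footprint
#' spacing on one side of the seed; `"secondary"` stacks protomers
#' perpendicular to the DNA (y axis) at the same spacing; `"bleach"` adds no
#' protomers and lets the starting fluorophores photobleach.
#'
#' @param mechanism One of "primary", "secondary", "bleach".
#' @param start_molecules Number of protomers at the first frame.
#' @param growth_rate Mean protomer additions per second (Poisson process).
#' @param n_frames Number of frames.
#' @param frame_period_s Time between frames, seconds.
#' @param ny,nx Frame size in pixels (y = perpendicular, x = DNA axis).
#' @param side +1 to grow toward larger x, -1 toward smaller x (primary only).
#' @param config A [sim_config()]; supplies optics, unit intensity, labeling
#'   efficiency, background and seed. Bleaching applies only for
#'   `mechanism = "bleach"`.
#' @param seed Integer seed (defaults to config value).
#' @return A list with `frames` (ny x nx x n_frames array of photon counts),
#'   `times_s`, and `truth` (emitter positions/times and molecule counts per
#'   frame).
#' @export
simulate_growth_frames <- function(mechanism = c("primary", "secondary",
                                                 "bleach"),
                                   start_molecules = 10,
                                   growth_rate = 10,
                                   n_frames = 8L,
                                   frame_period_s = 0.5,
                                   ny = 21L, nx = 41L,
                                   side = 1,
                                   config = sim_config(),
                                   seed = config$seed) {
  mechanism <- match.arg(mechanism)
  if (!is.null(seed)) set.seed(seed)
  footprint_nm <- config$footprint_bp * 0.34
  duration <- n_frames * frame_period_s
  times <- (seq_len(n_frames) - 0.5) * frame_period_s
  # seed protomers sit at the frame center, laid along the DNA axis
  x0 <- (nx / 2) * config$pixel_size_nm
  y0 <- (ny / 2) * config$pixel_size_nm
  k <- seq_len(start_molecules) - (start_molecules + 1) / 2
  em <- data.frame(x_nm = x0 + k * footprint_nm, y_nm = y0,
                   attach_time_s = 0)
  if (mechanism != "bleach" && growth_rate > 0) {
    n_add <- stats::rpois(1L, growth_rate * duration)
    if (n_add > 0) {
      at <- sort(stats::runif(n_add, 0, duration))
      off <- (seq_len(n_add) + floor(start_molecules / 2)) * footprint_nm
      add <- if (mechanism == "primary") {
        data.frame(x_nm = x0 + side * off, y_nm = y0, attach_time_s = at)
      } else {
        data.frame(x_nm = x0, y_nm = y0 + off, attach_time_s = at)
      }
      em <- rbind(em, add)
    }
  }
  labeled <- stats::runif(nrow(em)) <= config$labeling_efficiency
  bleach <- if (mechanism == "bleach" && config$bleach_rate > 0) {
    em$attach_time_s + stats::rexp(nrow(em), rate = config$bleach_rate)
  } else {
    rep(Inf, nrow(em))
  }
  sigma_px <- config$psf_fwhm_nm / (2 * sqrt(2 * log(2))) / config$pixel_size_nm
  wx <- function(x_px) {
    w <- diff(stats::pnorm(0:nx, mean = x_px, sd = sigma_px)); w / sum(w)
  }
  wy <- function(y_px) {
    w <- diff(stats::pnorm(0:ny, mean = y_px, sd = sigma_px)); w / sum(w)
  }
  frames <- array(0L, dim = c(ny, nx, n_frames))
  molecules <- integer(n_frames)
  for (fr in seq_len(n_frames)) {
    t <- times[fr]
    molecules[fr] <- sum(em$attach_time_s <= t)
    img <- matrix(0L, ny, nx)
    on <- which(labeled & em$attach_time_s <= t & bleach > t)
    for (e in on) {
      nph <- stats::rpois(1L, config$unit_intensity)
      if (nph > 0) {
        # separable 2D PSF: drop photons into pixels by product weights
        px <- stats::rmultinom(1L, nph, wx(em$x_nm[e] / config$pixel_size_nm))
        for (cx in which(px > 0)) {
          img[, cx] <- img[, cx] +
            stats::rmultinom(1L, px[cx],
                             wy(em$y_nm[e] / config$pixel_size_nm))[, 1L]
        }
      }
    }
    img <- img + matrix(stats::rpois(ny * nx, config$background_rate), ny, nx)
    if (config$dead_time_ns > 0) {
      img <- matrix(censor_counts(img, config_deadtime(config)), ny, nx)
    }
    frames[, , fr] <- img
  }
  list(frames = frames, times_s = times,
       truth = list(emitters = em, labeled = labeled,
                    bleach_times_s = bleach, molecules = molecules,
                    mechanism = mechanism, side = side))
}

#' Simulate a positional trace for diffusion analysis
#'
#' Generates per-line sub-pixel positions of a bound molecule: Brownian
#' motion with diffusion coefficient `d_um2_s` plus Gaussian localization
#' noise. `d_um2_s = 0` gives a static molecule observed with noise only.
#'
#' @param n_lines Number of scan lines, >= 10.
#' @param d_um2_s Diffusion coefficient, um^2/s.
#' @param loc_noise_px Localization noise s.d. in pixels.
#' @param config A [sim_config()] (pixel size and line period).
#' @param seed Integer seed.
#' @return A `trace` object (see [track_traces()]) with constant unit counts.
#' @export
simulate_position_trace <- function(n_lines = 100L, d_um2_s = 0,
                                    loc_noise_px = 0.3,
                                    config = sim_config(), seed = 1L) {
  stopifnot(n_lines >= 10)
  if (!is.null(seed)) set.seed(seed)
  dt <- config$line_period_s
  step_sd_nm <- sqrt(2 * d_um2_s * 1e6 * dt)  # 1D MSD = 2 D t
  true_nm <- cumsum(c(0, stats::rnorm(n_lines - 1L, 0, step_sd_nm)))
  obs_px <- true_nm / config$pixel_size_nm +
    stats::rnorm(n_lines, 0, loc_noise_px)
  samples <- data.frame(line = seq_len(n_lines) - 1L,
                        time_s = (seq_len(n_lines) - 0.5) * dt,
                        position_px = obs_px,
                        counts = rep(config$unit_intensity, n_lines))
  new_trace(1L, samples, config$line_period_s, n_total_lines = n_lines + 1L)
}
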