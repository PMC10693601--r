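#' Write a kymograph as 16-bit TIFF plus JSON sidecar
#'
#' Photon counts are stored as a 16-bit grayscale TIFF; acquisition metadata
#' (pixel size, line period, channel, duration) go into `<prefix>.json`.
#'
#' @param kymo A [kymograph()].
#' @param prefix Output path prefix; writes `<prefix>.tif` and
#'   `<prefix>.json`.
#' @return The prefix, invisibly.
#' @export
write_kymograph <- function(kymo, prefix) {
  stopifnot(inherits(kymo, "kymograph"))
  if (max(kymo$counts) > 65535L) stop("counts exceed 16-bit range")
  tiff::writeTIFF(kymo$counts / 65535, paste0(prefix, ".tif"),
                  bits.per.sample = 16L)
  jsonlite::write_json(
    list(kind = "kymograph",
         pixel_size_nm = kymo$pixel_size_nm,
         line_period_s = kymo$line_period_s,
         channel = kymo$channel,
         total_duration_s = kymo$total_duration_s),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

required_sidecar_keys <- c("pixel_size_nm", "line_period_s", "channel")

#' Read a kymograph written by [write_kymograph()]
#'
#' @param prefix Path prefix of the `.tif`/`.json` pair.
#' @return A [kymograph()]; the counts round-trip bit-identically.
#' @export
read_kymograph <- function(prefix) {
  tif <- paste0(prefix, ".tif")
  sidecar <- paste0(prefix, ".json")
  if (!file.exists(tif)) stop("missing image file: ", tif)
  if (!file.exists(sidecar)) stop("missing sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  missing <- setdiff(required_sidecar_keys, names(meta))
  if (length(missing)) {
    stop("sidecar is missing required keys: ",
         paste(missing, collapse = ", "))
  }
  counts <- read_count_image(tif)
  kymograph(counts, pixel_size_nm = meta$pixel_size_nm,
            line_period_s = meta$line_period_s, channel = meta$channel)
}

#' Read a TIFF as an integer photon-count matrix
#'
#' Reads a grayscale or RGB TIFF without intensity rescaling. For RGB
#' images one channel is extracted (the photon-count data live in the blue
#' channel of instrument RGB exports).
#'
#' @param path TIFF file path.
#' @param channel For RGB input: "red", "green" or "blue" (default
#'   "blue").
#' @return Integer matrix of counts (rows x columns as stored).
#' @export
read_count_image <- function(path, channel = c("blue", "red", "green")) {
  channel <- match.arg(channel)
  img <- tryCatch(tiff::readTIFF(path, as.is = TRUE),
                  error = function(e) stop("unreadable TIFF: ", path,
                                           " (", conditionMessage(e), ")"))
  # 16-bit grayscale comes back as integers; 8-bit (RGB exports) is
  # normalized to [0,1] and is rescaled to its native 0-255 range
  if (!is.integer(img)) img <- img * 255
  if (length(dim(img)) == 3L) {
    idx <- c(red = 1L, green = 2L, blue = 3L)[[channel]]
    if (dim(img)[3L] < idx) stop("image has no ", channel, " channel")
    img <- img[, , idx]
  }
  counts <- round(img)
  storage.mode(counts) <- "integer"
  counts
}

#' Write tracked traces to CSV
#' @param traces List of `trace` objects.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_traces <- function(traces, path) {
  utils::write.csv(traces_to_df(traces), path, row.names = FALSE)
  invisible(path)
}

#' Read a traces CSV back into `trace` objects
#' @param path CSV written by [write_traces()].
#' @param line_period_s Seconds per line.
#' @param n_total_lines Number of lines in the source kymograph (for
#'   censoring flags); defaults to one past the largest line index so
#'   flags are taken from the stored columns instead.
#' @return A list of `trace` objects.
#' @export
read_traces <- function(path, line_period_s, n_total_lines = NULL) {
  df <- utils::read.csv(path)
  lapply(split(df, df$trace_id), function(d) {
    tr <- new_trace(d$trace_id[1L],
                    d[, c("line", "time_s", "position_px", "counts")],
                    line_period_s,
                    n_total_lines %||% (max(d$line) + 2L))
    tr$left_censored <- as.logical(d$left_censored[1L])
    tr$right_censored <- as.logical(d$right_censored[1L])
    tr
  })
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the full chain on one or more kymograph datasets: ingest (or
#' simulate) each kymograph, track traces, calibrate the unitary intensity
#' from photobleaching steps of bright traces (falling back to the
#' configured unit when too few steps are found), convert traces to
#' molecule counts, and fit dissociation and association kinetics overall
#' and per concentration.
#'
#' @param manifest A list with `datasets` (each element a list with either
#'   `path` to a kymograph prefix or `config`, a [sim_config()] to
#'   simulate, plus `concentration` in molar) and optional `settings`
#'   (`unit_intensity`, `labeling_efficiency`, `dead_time_ns`,
#'   `pixel_dwell_us`, `bin_width_s`, `drop_first`, `min_counts`,
#'   `max_gap_lines`, `link_radius_px`).
#' @return A list of class `pipeline_report`: `calibration`, `k_off`
#'   (overall `exp_fit_result`), `k_off_by_concentration`, `k_on_by_concentration`,
#'   `K_D_range_M`, `size_distribution`, `traces` (per dataset), `t_on`,
#'   and `settings` (the full effective configuration).
#' @export
run_pipeline <- function(manifest) {
  if (is.null(manifest$datasets) || !length(manifest$datasets)) {
    stop("manifest contains no datasets")
  }
  s <- manifest$settings %||% list()
  settings <- list(
    unit_intensity = s$unit_intensity %||% 11,
    labeling_efficiency = s$labeling_efficiency %||% 0.9,
    dead_time_ns = s$dead_time_ns %||% 35,
    pixel_dwell_us = s$pixel_dwell_us %||% 50,
    bin_width_s = s$bin_width_s %||% 1,
    drop_first = s$drop_first %||% TRUE,
    min_counts = s$min_counts %||% 4,
    max_gap_lines = s$max_gap_lines %||% 3L,
    link_radius_px = s$link_radius_px %||% 2,
    min_dwells_per_group = s$min_dwells_per_group %||% 20L)
  dt_model <- dead_time_model(settings$dead_time_ns * 1e-9,
                              settings$pixel_dwell_us * 1e-6)

  per_ds <- lapply(seq_along(manifest$datasets), function(i) {
    d <- manifest$datasets[[i]]
    kymo <- if (!is.null(d$path)) {
      read_kymograph(d$path)
    } else if (!is.null(d$config)) {
      simulate_kymograph(d$config)$kymograph
    } else {
      stop("dataset ", i, ": needs either a path or a config")
    }
    traces <- track_traces(kymo, min_counts = settings$min_counts,
                           max_gap_lines = settings$max_gap_lines,
                           link_radius_px = settings$link_radius_px)
    list(id = i, concentration = d$concentration %||% NA_real_,
         duration_s = kymo$total_duration_s, kymo = kymo, traces = traces)
  })

  # calibration: photobleaching steps from multi-fluorophore traces
  stepfits <- list()
  for (ds in per_ds) {
    for (tr in ds$traces) {
      if (nrow(tr$samples) >= 10L && tr$mean_counts >
          1.5 * settings$unit_intensity) {
        stepfits[[length(stepfits) + 1L]] <-
          detect_steps(tr$samples$counts)
      }
    }
  }
  calibration <- tryCatch(unitary_intensity(stepfits),
                          error = function(e) NULL)
  unit_mean <- if (!is.null(calibration)) {
    calibration$mean
  } else {
    settings$unit_intensity
  }

  all_traces <- unlist(lapply(per_ds, `[[`, "traces"), recursive = FALSE)
  sizes <- lapply(all_traces, function(tr) {
    count_molecules(tr$mean_counts, background = 0, unit = unit_mean,
                    labeling_efficiency = settings$labeling_efficiency,
                    deadtime = dt_model)
  })
  size_dist <- if (length(sizes)) size_distribution(sizes) else NULL

  conc <- vapply(per_ds, `[[`, numeric(1), "concentration")
  dwells_by_ds <- lapply(per_ds, function(ds) eligible_dwells(ds$traces))
  all_dwells <- unlist(dwells_by_ds)
  fit_or_null <- function(dw) {
    if (length(dw) < settings$min_dwells_per_group) return(NULL)
    tryCatch(fit_koff(dwell_histogram(dw, settings$bin_width_s,
                                      settings$drop_first)),
             error = function(e) NULL)
  }
  koff_all <- fit_or_null(all_dwells)
  koff_by_conc <- lapply(split(seq_along(per_ds), conc), function(idx) {
    fit_or_null(unlist(dwells_by_ds[idx]))
  })

  t_on <- lapply(per_ds, function(ds) {
    unbound_time(ds$duration_s, ds$traces)
  })
  t_on_s <- vapply(t_on, `[[`, numeric(1), "t_on_s")
  kon_by_conc <- lapply(split(seq_along(per_ds), conc), function(idx) {
    v <- t_on_s[idx]
    c0 <- conc[idx][1L]
    if (!is.finite(c0) || any(v <= 0)) return(NULL)
    fit_kon(v, c0)
  })
  kons <- unlist(lapply(kon_by_conc, function(k) {
    if (is.null(k)) NULL else k$k_on
  }))
  kd_range <- if (!is.null(koff_all) && koff_all$converged &&
                  length(kons)) {
    range(dissociation_constant(koff_all$k_off, kons))
  } else {
    NULL
  }

  structure(list(calibration = calibration,
                 k_off = koff_all,
                 k_off_by_concentration = koff_by_conc,
                 k_on_by_concentration = kon_by_conc,
                 K_D_range_M = kd_range,
                 size_distribution = size_dist,
                 t_on = t_on,
                 traces = lapply(per_ds, `[[`, "traces"),
                 n_traces = length(all_traces),
                 settings = settings),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  cat(sprintf("  traces: %d\n", x$n_traces))
  if (!is.null(x$calibration)) {
    cat(sprintf("  unitary intensity: %.2f +/- %.2f photons (n = %d)\n",
                x$calibration$mean, x$calibration$sd,
                x$calibration$n_steps))
  }
  if (!is.null(x$k_off) && isTRUE(x$k_off$converged)) {
    cat(sprintf("  k_off: %.3f +/- %.3f s^-1 (R^2 %.3f)\n",
                x$k_off$k_off, x$k_off$stderr, x$k_off$r_squared))
  }
  if (!is.null(x$K_D_range_M)) {
    cat(sprintf("  K_D: %.3g - %.3g M\n",
                x$K_D_range_M[1L], x$K_D_range_M[2L]))
  }
  invisible(x)
}
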