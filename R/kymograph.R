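#' Kymograph photon-count container
#'
#' A kymograph is a space-time image built from repeated confocal line scans
#' along a tethered DNA molecule: rows are position pixels, columns are scan
#' lines. Counts are non-negative integers (detected photons).
#'
#' @param counts Non-negative integer matrix, position pixel x scan line.
#' @param pixel_size_nm Pixel size along the DNA axis, nm.
#' @param line_period_s Time between successive lines, seconds.
#' @param channel "blue" or "red" emission channel.
#' @return An object of class `kymograph`.
#' @export
kymograph <- function(counts, pixel_size_nm, line_period_s,
                      channel = c("blue", "red")) {
  channel <- match.arg(channel)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  stopifnot(pixel_size_nm > 0, line_period_s > 0)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts,
                 pixel_size_nm = pixel_size_nm,
                 line_period_s = line_period_s,
                 channel = channel,
                 total_duration_s = ncol(counts) * line_period_s),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf(
    "Kymograph (%s channel): %d px x %d lines, %g nm/px, %g ms/line, %g s\n",
    x$channel, nrow(x$counts), ncol(x$counts), x$pixel_size_nm,
    x$line_period_s * 1e3, x$total_duration_s))
  invisible(x)
}

#' @export
dim.kymograph <- function(x) dim(x$counts)
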