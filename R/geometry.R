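#' Fit a Gaussian profile to an intensity-versus-position curve
#'
#' Least-squares fit of a Gaussian plus constant offset, used both to
#' characterize the microscope PSF (fluorescent bead profiles) and to size
#' clusters: the FWHM of the fitted Gaussian serves as the apparent cluster
#' diameter.
#'
#' @param position_nm Positions, nm.
#' @param intensity Mean intensity at each position (>= 5 points,
#'   non-constant).
#' @return An object of class `gaussian_profile_fit`: `amplitude`,
#'   `center_nm`, `sigma_nm`, `fwhm_nm` (`2 * sqrt(2 log 2) * sigma`),
#'   `offset`, `rss`, `converged`.
#' @export
fit_profile <- function(position_nm, intensity) {
  x <- as.numeric(position_nm)
  y <- as.numeric(intensity)
  if (length(x) != length(y)) stop("position and intensity lengths differ")
  if (length(x) < 5L) stop("need at least 5 profile points")
  if (stats::sd(y) == 0) stop("constant profile: no peak to fit")
  off0 <- min(y)
  amp0 <- max(y) - off0
  w <- pmax(y - off0, 0)
  mu0 <- sum(x * w) / sum(w)
  sd0 <- sqrt(sum(w * (x - mu0)^2) / sum(w))
  if (!is.finite(sd0) || sd0 <= 0) sd0 <- diff(range(x)) / 4
  mu0 <- nonzero_start(mu0, sd0)
  off0 <- nonzero_start(off0, amp0)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(x - mu)^2 / (2 * s^2)) + off,
                      data = data.frame(x = x, y = y),
                      start = list(a = amp0, mu = mu0, s = sd0, off = off0),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(amplitude = NA_real_, center_nm = NA_real_,
                          sigma_nm = NA_real_, fwhm_nm = NA_real_,
                          offset = NA_real_, rss = NA_real_,
                          converged = FALSE),
                     class = "gaussian_profile_fit"))
  }
  co <- stats::coef(fit)
  sigma <- abs(unname(co["s"]))
  structure(list(amplitude = unname(co["a"]), center_nm = unname(co["mu"]),
                 sigma_nm = sigma,
                 fwhm_nm = 2 * sqrt(2 * log(2)) * sigma,
                 offset = unname(co["off"]),
                 rss = sum(stats::resid(fit)^2), converged = TRUE),
            class = "gaussian_profile_fit")
}

#' @export
print.gaussian_profile_fit <- function(x, ...) {
  if (!x$converged) {
    cat("Gaussian profile fit: did not converge\n")
  } else {
    cat(sprintf(
      "Gaussian profile fit: FWHM %.1f nm, center %.1f nm, amplitude %.3g\n",
      x$fwhm_nm, x$center_nm, x$amplitude))
  }
  invisible(x)
}

#' Mean-intensity profile of an image ROI
#'
#' Averages pixel intensity across the axis perpendicular to the requested
#' profile direction inside a rectangular ROI, returning intensity versus
#' position. This is the standard profile-plot reduction used before
#' [fit_profile()].
#'
#' @param image Numeric matrix (rows = y, columns = x).
#' @param roi List or vector with 0-based pixel fields `x0`, `y0`, `width`,
#'   `height`; NULL uses the whole image.
#' @param axis "x" (profile along columns, averaging rows) or "y".
#' @param pixel_size_nm Pixel size, nm.
#' @return A data.frame with `position_nm` (pixel centers) and `intensity`.
#' @export
roi_profile <- function(image, roi = NULL, axis = c("x", "y"),
                        pixel_size_nm = 100) {
  axis <- match.arg(axis)
  stopifnot(is.matrix(image))
  if (is.null(roi)) {
    roi <- list(x0 = 0L, y0 = 0L, width = ncol(image), height = nrow(image))
  }
  roi <- as.list(roi)
  xs <- (roi$x0 + 1L):(roi$x0 + roi$width)
  ys <- (roi$y0 + 1L):(roi$y0 + roi$height)
  if (min(xs) < 1L || max(xs) > ncol(image) ||
      min(ys) < 1L || max(ys) > nrow(image)) {
    stop("ROI outside image bounds")
  }
  sub <- image[ys, xs, drop = FALSE]
  if (axis == "x") {
    data.frame(position_nm = (xs - 0.5) * pixel_size_nm,
               intensity = colMeans(sub))
  } else {
    data.frame(position_nm = (ys - 0.5) * pixel_size_nm,
               intensity = rowMeans(sub))
  }
}

#' Circular cluster area from its Gaussian FWHM diameter
#'
#' Treats the profile FWHM as the diameter of a circular cluster:
#' `area = pi * (fwhm / 2)^2`, returned in um^2.
#'
#' @param fwhm_nm FWHM in nm, > 0.
#' @return Area in um^2.
#' @export
area_from_fwhm <- function(fwhm_nm) {
  stopifnot(is.numeric(fwhm_nm), all(fwhm_nm > 0))
  pi * (fwhm_nm / 2)^2 * 1e-6
}

#' Circular-equivalent diameter from a cluster surface area
#'
#' `d = 2 * sqrt(area / pi)`, returned in nm.
#'
#' @param area_um2 Area in um^2, > 0.
#' @return Diameter in nm.
#' @export
diameter_from_area <- function(area_um2) {
  stopifnot(is.numeric(area_um2), all(area_um2 > 0))
  2 * sqrt(area_um2 / pi) * 1e3
}

#' Contour length of B-form dsDNA
#'
#' 0.34 nm per base pair.
#'
#' @param bp Base pairs, >= 0.
#' @return Contour length in nm.
#' @export
dna_contour_length <- function(bp) {
  stopifnot(is.numeric(bp), all(bp >= 0))
  bp * 0.34
}

#' Protomer capacity of a dsDNA fragment
#'
#' Number of protein protomers a dsDNA fragment can host, given the
#' crystallographic footprint of one DNA-binding domain (default 10 bp per
#' protomer), floored to an integer.
#'
#' @param bp Base pairs, >= 0.
#' @param footprint_bp DNA footprint per protomer, bp.
#' @return Integer number of protomers.
#' @export
protomer_capacity <- function(bp, footprint_bp = 10) {
  stopifnot(is.numeric(bp), all(bp >= 0), footprint_bp > 0)
  as.integer(floor(bp / footprint_bp))
}

# numericDeriv uses relative perturbations, so an exactly-zero start value
# yields a zero Jacobian column; nudge such starts off zero.
nonzero_start <- function(v, scale) if (v == 0) scale * 1e-4 else v
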