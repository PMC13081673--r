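#' Through-focus MTF curve
#'
#' Container for a sampled through-focus modulation transfer function at a
#' single spatial frequency, as reported in bench characterizations of
#' intraocular lenses. The defocus axis is in diopters at the IOL plane
#' (negative values toward near); values are MTF ratios in `[0, 1]`.
#'
#' @param defocus numeric vector of defocus positions in diopters, strictly
#'   increasing.
#' @param value numeric vector of MTF values, same length as `defocus`,
#'   finite and non-negative.
#' @param nu spatial frequency in cycles/degree (default 15).
#' @param pupil_mm pupil diameter in mm (default 3).
#' @param wavelength wavelength in nm, or `"white"` for broadband sources
#'   (treated as 555 nm where a wavelength is needed).
#' @param normalized logical; `TRUE` once the curve has been divided by the
#'   diffraction-limited MTF.
#'
#' @return An object of class `"tfmtf"`: a list with elements `defocus`,
#'   `value`, `nu`, `pupil_mm`, `wavelength`, `normalized`.
#' @export
#' @examples
#' tfmtf_curve(seq(-2, 1, 0.25), exp(-seq(-2, 1, 0.25)^2), wavelength = 546)
tfmtf_curve <- function(defocus, value, nu = 15, pupil_mm = 3,
                        wavelength = "white", normalized = FALSE) {
  defocus <- as.numeric(defocus)
  value <- as.numeric(value)
  if (length(defocus) != length(value)) {
    stop("`defocus` and `value` must have the same length", call. = FALSE)
  }
  if (length(defocus) < 2L || any(diff(defocus) <= 0)) {
    stop("`defocus` must be strictly increasing with at least 2 points",
         call. = FALSE)
  }
  if (!all(is.finite(value)) || any(value < 0)) {
    stop("MTF values must be finite and >= 0", call. = FALSE)
  }
  if (!is.numeric(nu) || nu < 0) stop("`nu` must be >= 0", call. = FALSE)
  if (!is.numeric(pupil_mm) || pupil_mm <= 0) {
    stop("`pupil_mm` must be > 0", call. = FALSE)
  }
  if (is.numeric(wavelength) && wavelength <= 0) {
    stop("`wavelength` must be > 0 nm", call. = FALSE)
  }
  structure(
    list(defocus = defocus, value = value, nu = nu, pupil_mm = pupil_mm,
         wavelength = wavelength, normalized = isTRUE(normalized)),
    class = "tfmtf"
  )
}

#' Through-focus visual Strehl curve
#'
#' The estimated through-focus visual Strehl ratio (TFVS) as a function of
#' defocus: the smoothed, diffraction-limit-normalized MTF at the working
#' spatial frequency. Tagged with the optical plane the defocus axis refers
#' to (`"IOL"` or `"entrance_pupil"`).
#'
#' @param defocus uniform, strictly increasing defocus grid in diopters.
#' @param value visual Strehl values.
#' @param plane `"IOL"` or `"entrance_pupil"`.
#' @return An object of class `"tfvs"`.
#' @export
tfvs_curve <- function(defocus, value, plane = c("IOL", "entrance_pupil")) {
  plane <- match.arg(plane)
  defocus <- as.numeric(defocus)
  value <- as.numeric(value)
  if (length(defocus) != length(value)) {
    stop("`defocus` and `value` must have the same length", call. = FALSE)
  }
  if (length(defocus) < 2L || any(diff(defocus) <= 0)) {
    stop("`defocus` must be strictly increasing", call. = FALSE)
  }
  steps <- diff(defocus)
  if (max(steps) - min(steps) > 1e-8) {
    stop("`defocus` grid must be uniform", call. = FALSE)
  }
  if (!all(is.finite(value))) stop("values must be finite", call. = FALSE)
  structure(list(defocus = defocus, value = value, plane = plane),
            class = "tfvs")
}

#' Defocus visual acuity curve
#'
#' logMAR visual acuity versus imposed vergence for one subject (or a
#' group average) under one lens condition. The canonical grid runs from
#' +1.00 D to -4.00 D in 0.50 D steps; curves are stored sorted by
#' decreasing vergence (far to near).
#'
#' @param vergence vergence levels in diopters.
#' @param logmar logMAR acuity at each vergence (lower is better).
#' @param label lens / condition identifier.
#' @param subject_id optional subject identifier.
#' @return An object of class `"dfva"`.
#' @export
dfva_curve <- function(vergence, logmar, label = "lens", subject_id = NA_character_) {
  vergence <- as.numeric(vergence)
  logmar <- as.numeric(logmar)
  if (length(vergence) != length(logmar)) {
    stop("`vergence` and `logmar` must have the same length", call. = FALSE)
  }
  if (anyDuplicated(vergence)) stop("duplicated vergence levels", call. = FALSE)
  if (!all(is.finite(logmar))) stop("logMAR values must be finite", call. = FALSE)
  o <- order(vergence, decreasing = TRUE)
  structure(list(vergence = vergence[o], logmar = logmar[o],
                 label = as.character(label),
                 subject_id = as.character(subject_id)),
            class = "dfva")
}

#' @export
print.tfmtf <- function(x, ...) {
  cat(sprintf(
    "<tfmtf> %d points, defocus [%.2f, %.2f] D, nu = %g cpd, pupil = %g mm, lambda = %s%s\n",
    length(x$defocus), min(x$defocus), max(x$defocus), x$nu, x$pupil_mm,
    if (is.numeric(x$wavelength)) paste0(x$wavelength, " nm") else x$wavelength,
    if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' @export
print.tfvs <- function(x, ...) {
  cat(sprintf("<tfvs> %d points, defocus [%.2f, %.2f] D, plane = %s, peak = %.3f\n",
              length(x$defocus), min(x$defocus), max(x$defocus), x$plane,
              max(x$value)))
  invisible(x)
}

#' @export
print.dfva <- function(x, ...) {
  cat(sprintf("<dfva> '%s'%s, %d vergences [%.2f, %.2f] D, logMAR [%.2f, %.2f]\n",
              x$label,
              if (!is.na(x$subject_id)) paste0(" subject ", x$subject_id) else "",
              length(x$vergence), min(x$vergence), max(x$vergence),
              min(x$logmar), max(x$logmar)))
  invisible(x)
}

# Linear resampling of a sampled curve onto `grid`; outside the original
# support the curve is extended with `fill` (NA drops those points later).
resample_curve <- function(x, y, grid, fill = 0) {
  stats::approx(x, y, xout = grid, method = "linear",
                yleft = fill, yright = fill)$y
}

#' Resample a through-focus curve to a uniform grid
#'
#' @param curve a `"tfmtf"` or `"tfvs"` object.
#' @param step grid step in diopters (default 0.05 D, the addition step used
#'   by the temporal-multiplexing solver).
#' @return An object of the same class on the uniform grid.
#' @export
resample_uniform <- function(curve, step = 0.05) {
  lo <- ceiling(min(curve$defocus) / step) * step
  hi <- floor(max(curve$defocus) / step) * step
  grid <- seq(lo, hi, by = step)
  vals <- stats::approx(curve$defocus, curve$value, xout = grid)$y
  if (inherits(curve, "tfmtf")) {
    tfmtf_curve(grid, vals, nu = curve$nu, pupil_mm = curve$pupil_mm,
                wavelength = curve$wavelength, normalized = curve$normalized)
  } else {
    tfvs_curve(grid, vals, plane = curve$plane)
  }
}
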