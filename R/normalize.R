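#' Luminous efficiency weights for polychromatic averaging
#'
#' Relative photopic luminous efficiency at the red/green/blue measurement
#' wavelengths used for bench through-focus MTF data (650, 546 and 480 nm).
#' The weights are used normalized by their sum.
#'
#' @param red,green,blue positive weights.
#' @return Named numeric vector of class `"luminous_weights"`.
#' @export
luminous_weights <- function(red = 0.11, green = 0.99, blue = 0.15) {
  w <- c(red = red, green = green, blue = blue)
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("luminous weights must be positive", call. = FALSE)
  }
  structure(w, class = "luminous_weights")
}

#' Normalize a through-focus MTF curve by the diffraction limit
#'
#' Divides every MTF value by the diffraction-limited MTF of the matching
#' pupil and wavelength at the curve's spatial frequency, turning the bench
#' MTF into a visual Strehl-like ratio. Values exceeding 1 after
#' normalization (digitization noise) are clipped to 1; the number of
#' clipped samples is recorded in attribute `"n_clipped"` and reported with
#' a warning.
#'
#' @param curve a `"tfmtf"` object.
#' @return The normalized `"tfmtf"` object (`normalized = TRUE`).
#' @export
normalize_tfmtf <- function(curve) {
  stopifnot(inherits(curve, "tfmtf"))
  wl <- if (is.numeric(curve$wavelength)) curve$wavelength else 555
  dl <- diffraction_limited_mtf(curve$nu, curve$pupil_mm, wl)
  if (dl <= 0) {
    stop("diffraction-limited MTF is 0 at this spatial frequency; ",
         "cannot normalize", call. = FALSE)
  }
  vals <- curve$value / dl
  n_clip <- sum(vals > 1)
  if (n_clip > 0) {
    warning(sprintf("%d normalized value(s) exceeded 1 and were clipped",
                    n_clip), call. = FALSE)
    vals <- pmin(vals, 1)
  }
  out <- tfmtf_curve(curve$defocus, vals, nu = curve$nu,
                     pupil_mm = curve$pupil_mm, wavelength = curve$wavelength,
                     normalized = TRUE)
  attr(out, "n_clipped") <- n_clip
  out
}

#' Polychromatic average of per-wavelength through-focus MTF curves
#'
#' Pointwise weighted mean of through-focus MTF curves measured at several
#' wavelengths, weighted by the photopic luminous efficiency of each
#' wavelength (weights normalized to sum 1). Curves are first resampled to
#' their common defocus support. A single-curve input is returned unchanged.
#'
#' @param curves list of `"tfmtf"` objects sharing `nu` and `pupil_mm`.
#' @param weights either a numeric vector parallel to `curves`, or a
#'   [luminous_weights()] object, in which case each curve is assigned the
#'   red/green/blue weight nearest its wavelength (>= 600 nm red, <= 500 nm
#'   blue, otherwise green).
#' @param step defocus step of the common grid (default 0.05 D).
#' @return A `"tfmtf"` object with `wavelength = "white"`.
#' @export
polychromatic_average <- function(curves, weights = luminous_weights(),
                                  step = 0.05) {
  if (length(curves) == 0L) stop("`curves` is empty", call. = FALSE)
  stopifnot(all(vapply(curves, inherits, logical(1), "tfmtf")))
  if (length(curves) == 1L) return(curves[[1]])
  nus <- vapply(curves, `[[`, numeric(1), "nu")
  pupils <- vapply(curves, `[[`, numeric(1), "pupil_mm")
  if (length(unique(nus)) != 1L || length(unique(pupils)) != 1L) {
    stop("curves must share `nu` and `pupil_mm`", call. = FALSE)
  }
  if (inherits(weights, "luminous_weights")) {
    w <- vapply(curves, function(cv) {
      wl <- cv$wavelength
      if (!is.numeric(wl)) return(unname(weights["green"]))
      if (wl >= 600) unname(weights["red"])
      else if (wl <= 500) unname(weights["blue"])
      else unname(weights["green"])
    }, numeric(1))
  } else {
    w <- as.numeric(weights)
    if (length(w) != length(curves)) {
      stop("`weights` must match `curves` in length", call. = FALSE)
    }
  }
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  w <- w / sum(w)
  lo <- max(vapply(curves, function(cv) min(cv$defocus), numeric(1)))
  hi <- min(vapply(curves, function(cv) max(cv$defocus), numeric(1)))
  if (hi - lo < step) stop("curves have disjoint defocus grids", call. = FALSE)
  grid <- seq(ceiling(lo / step) * step, floor(hi / step) * step, by = step)
  acc <- numeric(length(grid))
  for (i in seq_along(curves)) {
    acc <- acc + w[i] * stats::approx(curves[[i]]$defocus, curves[[i]]$value,
                                      xout = grid)$y
  }
  tfmtf_curve(grid, acc, nu = nus[1], pupil_mm = pupils[1],
              wavelength = "white",
              normalized = all(vapply(curves, `[[`, logical(1), "normalized")))
}
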