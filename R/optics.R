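#' Diffraction-limited MTF of a circular pupil
#'
#' Incoherent modulation transfer function of an aberration-free circular
#' aperture, used to normalize bench through-focus MTF values into visual
#' Strehl-like ratios. The classical closed form is
#' \deqn{MTF(s) = \frac{2}{\pi}\left(\arccos s - s\sqrt{1 - s^2}\right),
#'   \quad s = \nu/\nu_c,}
#' with cutoff \eqn{\nu_c = (\pi/180)\, d / \lambda} in cycles/degree for
#' pupil diameter \eqn{d} and wavelength \eqn{\lambda}. For a 3-mm pupil at
#' 555 nm the cutoff is about 94.3 cycles/degree and the value at
#' 15 cycles/degree about 0.798.
#'
#' @param nu spatial frequency in cycles/degree (scalar or vector, >= 0).
#' @param pupil_mm pupil diameter in mm (> 0).
#' @param wavelength_nm wavelength in nm (> 0).
#' @return MTF ratio in `[0, 1]`; 0 at and beyond the cutoff.
#' @export
#' @examples
#' diffraction_limited_mtf(0, 3, 555)   # 1
#' diffraction_limited_mtf(15, 3, 555)  # ~0.798
diffraction_limited_mtf <- function(nu, pupil_mm, wavelength_nm) {
  if (!is.numeric(pupil_mm) || length(pupil_mm) != 1L || pupil_mm <= 0) {
    stop("`pupil_mm` must be a positive scalar", call. = FALSE)
  }
  if (!is.numeric(wavelength_nm) || length(wavelength_nm) != 1L ||
      wavelength_nm <= 0) {
    stop("`wavelength_nm` must be a positive scalar", call. = FALSE)
  }
  if (any(nu < 0)) stop("`nu` must be >= 0", call. = FALSE)
  cutoff <- (pupil_mm * 1e-3) / (wavelength_nm * 1e-9) * pi / 180
  s <- pmin(nu / cutoff, 1)
  (2 / pi) * (acos(s) - s * sqrt(pmax(1 - s^2, 0)))
}

#' Through-focus MTF of a defocused diffraction-limited pupil
#'
#' MTF at one spatial frequency of a circular pupil carrying pure defocus.
#' For a defocus wavefront \eqn{W(r) = \Delta D\, r^2 / 2} the optical
#' transfer function at pupil shear \eqn{\Delta} reduces to the real
#' overlap integral
#' \deqn{OTF(\nu; \Delta D) = \frac{1}{\pi a^2}\int\!\!\int_{\cap}
#'   \cos(k\, \Delta D\, \Delta\, x)\; dx\, dy,}
#' which is evaluated here by one-dimensional quadrature over the lens
#' overlap region (the phase difference of sheared defocus is linear in the
#' pupil coordinate, so the integral is real).
#'
#' @param defocus_D defocus in diopters (scalar or vector, signed).
#' @param nu spatial frequency in cycles/degree.
#' @param pupil_mm pupil diameter in mm.
#' @param wavelength_nm wavelength in nm.
#' @param n_quad number of quadrature nodes.
#' @return signed OTF value(s); the modulus is the MTF, negative lobes
#'   indicate phase reversal (spurious resolution).
#' @export
defocus_otf <- function(defocus_D, nu, pupil_mm = 3, wavelength_nm = 555,
                        n_quad = 2001) {
  if (pupil_mm <= 0 || wavelength_nm <= 0) {
    stop("pupil and wavelength must be positive", call. = FALSE)
  }
  a <- pupil_mm * 1e-3 / 2
  shear <- wavelength_nm * 1e-9 * nu * 180 / pi  # pupil shift in meters
  if (shear >= 2 * a) return(rep(0, length(defocus_D)))
  k <- 2 * pi / (wavelength_nm * 1e-9)
  xm <- a - shear / 2
  x <- seq(0, xm, length.out = n_quad)
  h <- 2 * sqrt(pmax(a^2 - (x + shear / 2)^2, 0))
  dx <- x[2] - x[1]
  vapply(defocus_D, function(d) {
    integrand <- h * cos(k * d * shear * x)
    2 * sum((integrand[-1] + integrand[-n_quad]) / 2) * dx / (pi * a^2)
  }, numeric(1))
}

#' Monofocal through-focus visual Strehl kernel
#'
#' The elementary through-focus response of a single focal state of the
#' tunable lens: the diffraction-limited defocus MTF at the working spatial
#' frequency, rectified (negative, phase-reversed lobes set to zero) and
#' normalized to peak 1 at zero defocus. The temporal-multiplexing profile
#' is a dwell-weighted mixture of shifted copies of this kernel.
#'
#' @param pupil_mm pupil diameter in mm.
#' @param nu spatial frequency in cycles/degree.
#' @param wavelength_nm wavelength in nm.
#' @param offsets symmetric defocus offset grid in diopters.
#' @return An object of class `"mono_kernel"`: list with `offsets`,
#'   `values` (even-symmetric, in `[0, 1]`, value 1 at 0).
#' @export
#' @examples
#' k <- monofocal_vs_kernel()
#' k$values[k$offsets == 0]  # 1
monofocal_vs_kernel <- function(pupil_mm = 3, nu = 15, wavelength_nm = 555,
                                offsets = seq(-3, 3, by = 0.05)) {
  offsets <- round(as.numeric(offsets), 10)
  if (max(abs(offsets + rev(offsets))) > 1e-9) {
    stop("`offsets` must be symmetric about 0", call. = FALSE)
  }
  half <- offsets[offsets >= 0]
  vals_half <- pmax(defocus_otf(half, nu, pupil_mm, wavelength_nm), 0)
  vals <- c(rev(vals_half[-1])[seq_len(sum(offsets < 0))], vals_half)
  # mirror guarantees exact even symmetry
  vals <- vals / max(vals)
  structure(list(offsets = offsets, values = vals,
                 pupil_mm = pupil_mm, nu = nu, wavelength_nm = wavelength_nm),
            class = "mono_kernel")
}

#' Gaussian through-focus kernel
#'
#' Smooth alternative to [monofocal_vs_kernel()] for sensitivity analyses:
#' a unit-peak Gaussian in defocus.
#'
#' @param sigma standard deviation in diopters.
#' @param offsets symmetric defocus offset grid in diopters.
#' @return A `"mono_kernel"` object.
#' @export
gaussian_kernel <- function(sigma = 0.35, offsets = seq(-3, 3, by = 0.05)) {
  if (sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  structure(list(offsets = as.numeric(offsets),
                 values = exp(-0.5 * (offsets / sigma)^2),
                 pupil_mm = NA_real_, nu = NA_real_, wavelength_nm = NA_real_),
            class = "mono_kernel")
}

# Evaluate a kernel at arbitrary defocus offsets (0 outside support).
kernel_at <- function(kernel, x) {
  resample_curve(kernel$offsets, kernel$values, x, fill = 0)
}

#' @export
print.mono_kernel <- function(x, ...) {
  cat(sprintf("<mono_kernel> offsets [%.2f, %.2f] D (step %.3g), peak 1 at 0\n",
              min(x$offsets), max(x$offsets), x$offsets[2] - x$offsets[1]))
  invisible(x)
}
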