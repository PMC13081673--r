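#' Low-pass filter specification for TFVS smoothing
#'
#' Design parameters of the Kaiser-window FIR used to smooth normalized
#' through-focus MTF curves into the estimated through-focus visual Strehl
#' (TFVS). Band edges are expressed as fractions of the Nyquist frequency
#' of the resampled defocus signal (the convention of MATLAB-style filter
#' design tools); at the default 0.05 D sampling step (Nyquist 10 D^-1) the
#' passband edge 0.05 corresponds to 0.5 D^-1 and the stopband edge 0.5 to
#' 5 D^-1.
#'
#' @param passband passband edge as a fraction of Nyquist (default 0.05).
#' @param stopband stopband edge as a fraction of Nyquist (default 0.5).
#' @param ripple_db maximum passband ripple in dB (default 0.05).
#' @param atten_db minimum stopband attenuation in dB (default 10).
#' @param method design method; only `"kaiser"` is implemented.
#' @return Object of class `"filter_spec"`.
#' @export
filter_spec <- function(passband = 0.05, stopband = 0.5, ripple_db = 0.05,
                        atten_db = 10, method = "kaiser") {
  method <- match.arg(method, "kaiser")
  if (!(passband > 0 && passband < stopband && stopband < 1)) {
    stop("need 0 < passband < stopband < 1 (fractions of Nyquist)",
         call. = FALSE)
  }
  if (ripple_db <= 0 || atten_db <= 0) {
    stop("ripple and attenuation must be positive dB values", call. = FALSE)
  }
  structure(list(passband = passband, stopband = stopband,
                 ripple_db = ripple_db, atten_db = atten_db, method = method),
            class = "filter_spec")
}

#' Design the TFVS smoothing FIR
#'
#' Kaiser-window low-pass FIR meeting a [filter_spec()] single-pass. The
#' order returned by the Kaiser estimate is rounded up to even so the
#' filter is an odd-length type-I symmetric FIR (exactly linear phase); the
#' taps are normalized to unit DC gain.
#'
#' @param spec a [filter_spec()].
#' @return Numeric vector of filter taps (odd length, symmetric).
#' @export
design_tfvs_filter <- function(spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  dp <- (10^(spec$ripple_db / 20) - 1) / (10^(spec$ripple_db / 20) + 1)
  ds <- 10^(-spec$atten_db / 20)
  ko <- signal::kaiserord(c(spec$passband, spec$stopband), c(1, 0),
                          c(dp, ds), 2)
  n <- ko$n
  if (n %% 2L == 1L) n <- n + 1L
  taps <- signal::fir1(n, ko$Wc, type = "low",
                       window = signal::kaiser(n + 1L, ko$beta))
  taps <- as.numeric(taps)
  taps / sum(taps)
}

#' Frequency response of an FIR filter
#'
#' Magnitude response evaluated by direct discrete-time Fourier transform
#' of the taps.
#'
#' @param taps FIR coefficients.
#' @param freq frequencies as fractions of Nyquist (0..1).
#' @return Magnitude response (linear scale) at `freq`.
#' @export
fir_response <- function(taps, freq) {
  vapply(freq, function(f) {
    Mod(sum(taps * exp(-1i * pi * f * (seq_along(taps) - 1))))
  }, numeric(1))
}

# Zero-phase application of a symmetric FIR: odd-reflection padding of at
# least one filter length at both ends, centered convolution, crop.
zero_phase_pass <- function(x, taps) {
  n <- length(x)
  nt <- length(taps)
  np <- min(nt, n - 1L)
  pre <- 2 * x[1] - x[seq(np + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - np)]
  padded <- c(pre, x, post)
  y <- as.numeric(stats::filter(padded, taps, method = "convolution",
                                sides = 2))
  y[(np + 1L):(np + n)]
}

#' Smooth a normalized through-focus MTF into a TFVS curve
#'
#' Resamples the curve to a uniform defocus grid (linear interpolation,
#' default step 0.05 D), then applies the Kaiser-designed low-pass FIR
#' forward and backward (zero phase; the stopband attenuation is doubled
#' relative to the single-pass design). Edge transients are suppressed by
#' odd-reflection padding of one filter length. Small negative excursions
#' in the stopband ripple are clamped to zero.
#'
#' @param curve a normalized `"tfmtf"` object (see [normalize_tfmtf()]).
#' @param spec a [filter_spec()].
#' @param resample_step uniform grid step in diopters.
#' @return A `"tfvs"` object tagged plane `"IOL"`, same defocus span.
#' @export
smooth_to_tfvs <- function(curve, spec = filter_spec(), resample_step = 0.05) {
  stopifnot(inherits(curve, "tfmtf"))
  if (!curve$normalized) {
    warning("curve does not appear to be normalized; smoothing anyway",
            call. = FALSE)
  }
  rc <- resample_uniform(curve, step = resample_step)
  taps <- design_tfvs_filter(spec)
  if (length(rc$defocus) < 3L * length(taps)) {
    stop(sprintf(
      "insufficient support: %d samples < 3 filter lengths (%d)",
      length(rc$defocus), 3L * length(taps)), call. = FALSE)
  }
  sm <- zero_phase_pass(zero_phase_pass(rc$value, taps), taps)
  tfvs_curve(rc$defocus, pmax(sm, 0), plane = "IOL")
}

#' Convert a TFVS curve between optical planes
#'
#' Rescales the defocus axis by a dimensionless factor to express the
#' curve at the entrance pupil rather than the IOL plane. The exact
#' conversion factor depends on the pseudophakic eye model; it is exposed
#' as a configurable scalar and defaults to 1 (identity). The operation is
#' inverted by `1/factor`.
#'
#' @param curve a `"tfvs"` object tagged `"IOL"` (or `"entrance_pupil"`
#'   when inverting).
#' @param factor positive scale factor applied to the defocus axis.
#' @return A `"tfvs"` object tagged with the other plane.
#' @export
convert_plane <- function(curve, factor = 1) {
  stopifnot(inherits(curve, "tfvs"))
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0) {
    stop("`factor` must be a positive scalar", call. = FALSE)
  }
  to <- if (curve$plane == "IOL") "entrance_pupil" else "IOL"
  tfvs_curve(curve$defocus * factor, curve$value, plane = to)
}
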