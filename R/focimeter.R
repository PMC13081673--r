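#' Simulate high-speed focimetry of a temporal profile
#'
#' Emulates the bench validation of a programmed lens: the optotunable
#' lens is driven through the profile's states (laid out in one cycle in
#' ascending-addition order) and its instantaneous optical power is
#' recorded at high rate. The lens is modeled as a first-order lag with
#' time constant `time_constant_ms`; the driver applies a saturated
#' deadbeat (overdrive) command — it overshoots the commanded level by up
#' to `overdrive_D` diopters to slew the lens quickly, as optotunable-lens
#' drivers do, then holds the target. With `overdrive_D = 0` the command
#' is the plain staircase and the response is the textbook
#' \eqn{1 - e^{-t/\tau}} step response.
#'
#' The recorded power trace (last cycle of several, so the response is
#' periodic) is binned into 0.05 D bins to form the effective dwell
#' fractions actually realized by the lens, and the reconstruction from
#' those effective dwells is returned.
#'
#' @param profile a `"temporal_profile"`.
#' @param kernel a `"mono_kernel"` used for the reconstruction.
#' @param grid defocus grid for the reconstructed curve.
#' @param time_constant_ms lens first-order time constant in ms (>= 0).
#' @param sample_rate_khz focimeter sampling rate in kHz.
#' @param overdrive_D driver overdrive headroom in diopters beyond the
#'   extreme programmed additions (default 5).
#' @param n_cycles number of cycles simulated before recording.
#' @param bin_D power bin width in diopters (default 0.05).
#' @return A `"tfvs"` object: the dwell-weighted reconstruction from the
#'   effective (dynamics-affected) dwell fractions, with the effective
#'   profile attached as attribute `"effective_profile"`.
#' @export
simulate_focimeter <- function(profile, kernel, grid,
                               time_constant_ms = 1, sample_rate_khz = 100,
                               overdrive_D = 5, n_cycles = 6, bin_D = 0.05) {
  stopifnot(inherits(profile, "temporal_profile"),
            inherits(kernel, "mono_kernel"))
  if (time_constant_ms < 0) stop("`time_constant_ms` must be >= 0", call. = FALSE)
  adds <- profile$additions          # already sorted ascending
  dw <- profile$dwell_fractions
  cycle <- profile$cycle_ms
  dt <- 1 / sample_rate_khz          # ms
  if (dt > min(dw) * cycle) {
    stop(sprintf(
      "undersampling: sample interval %.3f ms exceeds shortest dwell %.3f ms",
      dt, min(dw) * cycle), call. = FALSE)
  }
  nt <- round(cycle / dt)
  tgrid <- (seq_len(nt) - 1) * dt
  bounds <- cycle * cumsum(c(0, dw))
  target <- adds[pmin(findInterval(tgrid, bounds), length(adds))]
  lo <- min(adds) - overdrive_D
  hi <- max(adds) + overdrive_D
  alpha <- if (time_constant_ms <= 0) 1 else 1 - exp(-dt / time_constant_ms)
  p <- target[1]
  trace <- numeric(nt)
  for (cyc in seq_len(n_cycles)) {
    for (i in seq_len(nt)) {
      cmd <- if (alpha >= 1) target[i] else (target[i] - p * (1 - alpha)) / alpha
      cmd <- min(max(cmd, lo), hi)
      p <- p + alpha * (cmd - p)
      if (cyc == n_cycles) trace[i] <- p
    }
  }
  bins <- round(trace / bin_D)
  tab <- table(bins)
  eff_adds <- as.numeric(names(tab)) * bin_D
  eff_dw <- as.numeric(tab) / nt
  eff <- temporal_profile(eff_adds, eff_dw / sum(eff_dw),
                          cycle_ms = cycle, rate_hz = profile$rate_hz,
                          fitted_scale = profile$fitted_scale)
  out <- reconstruct_tfvs(eff, kernel, grid, scale = "dwell")
  attr(out, "effective_profile") <- eff
  out
}

#' First-order lens step response
#'
#' Closed-form response of the lens model to a power step, for
#' characterization plots and sanity checks: `1 - exp(-t/tau)` of the
#' commanded change (no overdrive).
#'
#' @param t time in ms (vector).
#' @param time_constant_ms time constant in ms.
#' @return Fraction of the commanded step reached at `t`.
#' @export
lens_step_response <- function(t, time_constant_ms) {
  if (time_constant_ms <= 0) return(as.numeric(t >= 0))
  ifelse(t < 0, 0, 1 - exp(-t / time_constant_ms))
}
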