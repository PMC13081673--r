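#' Temporal multiplexing profile
#'
#' The programmed state of the optotunable lens over one multiplexing
#' cycle: a set of additions (focal power offsets, in diopters on a 0.05 D
#' grid) and the fraction of the cycle dwelt at each. At the default 50 Hz
#' rate one cycle lasts 20 ms, so a dwell fraction of 0.25 means 5 ms at
#' that focal state per cycle.
#'
#' @param additions additions in diopters (unique; stored sorted
#'   ascending). Positive additions correspond to near foci (negative
#'   defocus/vergence).
#' @param dwell_fractions dwell fractions in `(0, 1]`, summing to 1 within
#'   `1e-9`.
#' @param cycle_ms cycle duration in ms.
#' @param rate_hz multiplexing rate in Hz (`1000 / cycle_ms`).
#' @param fitted_scale optional amplitude of the fitted mixture before
#'   renormalization of the coefficients to sum 1 (kept so the fitted TFVS
#'   can be reproduced exactly).
#' @return Object of class `"temporal_profile"`.
#' @export
temporal_profile <- function(additions, dwell_fractions, cycle_ms = 20,
                             rate_hz = 1000 / cycle_ms, fitted_scale = 1) {
  additions <- as.numeric(additions)
  dwell_fractions <- as.numeric(dwell_fractions)
  if (length(additions) != length(dwell_fractions) || length(additions) == 0L) {
    stop("`additions` and `dwell_fractions` must be non-empty and matched",
         call. = FALSE)
  }
  if (anyDuplicated(round(additions, 6))) {
    stop("`additions` must be unique", call. = FALSE)
  }
  if (any(dwell_fractions <= 0) || abs(sum(dwell_fractions) - 1) > 1e-9) {
    stop("dwell fractions must be positive and sum to 1", call. = FALSE)
  }
  o <- order(additions)
  structure(list(additions = additions[o],
                 dwell_fractions = dwell_fractions[o],
                 cycle_ms = cycle_ms, rate_hz = rate_hz,
                 fitted_scale = fitted_scale),
            class = "temporal_profile")
}

#' @export
print.temporal_profile <- function(x, ...) {
  cat(sprintf("<temporal_profile> %d states, %g ms cycle (%g Hz)\n",
              length(x$additions), x$cycle_ms, x$rate_hz))
  df <- data.frame(addition_D = x$additions,
                   dwell_fraction = round(x$dwell_fractions, 4),
                   dwell_ms = round(x$dwell_fractions * x$cycle_ms, 3))
  print(df, row.names = FALSE)
  invisible(x)
}

# Inner nonnegative least-squares fit restricted to a support set.
nnls_on <- function(A, y, support) {
  cf <- numeric(ncol(A))
  if (length(support) > 0L) {
    cf[support] <- pracma::lsqnonneg(A[, support, drop = FALSE], y)$x
  }
  cf
}

#' Solve the temporal coefficients for a target TFVS
#'
#' Finds the sparse nonnegative mixture of shifted monofocal kernels whose
#' dwell-weighted sum reproduces the target through-focus visual Strehl
#' curve:
#' \deqn{TFVS(d) \approx \sum_k c_k\, K(d + a_k),}
#' where \eqn{a_k} are candidate additions on a 0.05 D grid and \eqn{K} is
#' the monofocal through-focus kernel. The solve proceeds in three stages:
#' \enumerate{
#'   \item dense nonnegative least squares over the full addition grid
#'     (Lawson-Hanson);
#'   \item iterative threshold pruning: coefficients holding less than
#'     `prune_fraction` of the cycle are dropped and the remainder refit,
#'     until stable;
#'   \item greedy backward elimination: the smallest coefficient is
#'     dropped and the rest refit while the residual RMSE grows by at most
#'     `rmse_tol_frac * max(target)` per elimination.
#' }
#' The surviving coefficients are renormalized to dwell fractions summing
#' to 1; the pre-normalization amplitude is kept in `fitted_scale`.
#'
#' @param target a `"tfvs"` object (IOL or entrance-pupil plane).
#' @param kernel a `"mono_kernel"` from [monofocal_vs_kernel()] or
#'   [gaussian_kernel()].
#' @param addition_grid candidate additions in diopters (default -0.50 to
#'   +4.50 D in 0.05 D steps, covering vergences +0.5 to -4.5 D).
#' @param prune_fraction dwell fraction below which a state is considered
#'   unrealizable and pruned (default 0.01, i.e. 0.2 ms of a 20 ms cycle).
#' @param rmse_tol_frac tolerated residual-RMSE increase per backward
#'   elimination, as a fraction of the target's peak (default 0.01).
#' @param cycle_ms,rate_hz cycle parameters passed to the profile.
#' @return A `"temporal_profile"`; attribute `"rmse"` holds the final
#'   fit residual RMSE in target units.
#' @export
solve_temporal_coefficients <- function(target, kernel,
                                        addition_grid = seq(-0.5, 4.5, by = 0.05),
                                        prune_fraction = 0.01,
                                        rmse_tol_frac = 0.01,
                                        cycle_ms = 20, rate_hz = 50) {
  stopifnot(inherits(target, "tfvs"), inherits(kernel, "mono_kernel"))
  y <- target$value
  if (all(y == 0)) stop("target TFVS is identically zero", call. = FALSE)
  d <- target$defocus
  kern_width <- diff(range(kernel$offsets))
  if (kern_width > diff(range(d)) * 2) {
    warning("kernel support much wider than target support; fit may be ill-posed",
            call. = FALSE)
  }
  A <- vapply(addition_grid, function(a) kernel_at(kernel, d + a),
              numeric(length(d)))
  rmse_of <- function(cf) sqrt(mean((as.numeric(A %*% cf) - y)^2))

  cf <- pracma::lsqnonneg(A, y)$x
  # stage 2: threshold pruning until stable
  repeat {
    keep <- which(cf / sum(cf) >= prune_fraction)
    if (length(keep) == 0L) {
      keep <- which.max(cf)
    }
    if (length(keep) == sum(cf > 0)) break
    cf <- nnls_on(A, y, keep)
  }
  # stage 3: backward elimination of the smallest coefficient
  tol <- rmse_tol_frac * max(y)
  repeat {
    nz <- which(cf > 0)
    if (length(nz) <= 1L) break
    # on exact ties drop the highest addition, keeping the lowest
    mins <- nz[cf[nz] == min(cf[nz])]
    smallest <- mins[length(mins)]
    cf_try <- nnls_on(A, y, setdiff(nz, smallest))
    if (rmse_of(cf_try) - rmse_of(cf) <= tol) cf <- cf_try else break
  }
  nz <- which(cf > 0)
  prof <- temporal_profile(additions = addition_grid[nz],
                           dwell_fractions = cf[nz] / sum(cf[nz]),
                           cycle_ms = cycle_ms, rate_hz = rate_hz,
                           fitted_scale = sum(cf[nz]))
  attr(prof, "rmse") <- rmse_of(cf)
  prof
}

#' Reconstruct the multiplexed TFVS from a temporal profile
#'
#' Dwell-weighted sum of monofocal kernels shifted to each programmed
#' addition, evaluated on `grid`. With `scale = "fitted"` the sum is
#' multiplied by the profile's `fitted_scale`, reproducing the
#' least-squares fit of the target curve; with `scale = "dwell"` the raw
#' dwell-weighted mixture (peak at most ~1) is returned.
#'
#' @param profile a `"temporal_profile"`.
#' @param kernel a `"mono_kernel"`.
#' @param grid defocus grid in diopters.
#' @param scale `"fitted"` or `"dwell"`.
#' @return A `"tfvs"` object on `grid`.
#' @export
reconstruct_tfvs <- function(profile, kernel, grid,
                             scale = c("fitted", "dwell")) {
  stopifnot(inherits(profile, "temporal_profile"),
            inherits(kernel, "mono_kernel"))
  scale <- match.arg(scale)
  acc <- numeric(length(grid))
  for (i in seq_along(profile$additions)) {
    acc <- acc + profile$dwell_fractions[i] *
      kernel_at(kernel, grid + profile$additions[i])
  }
  if (scale == "fitted") acc <- acc * profile$fitted_scale
  tfvs_curve(grid, acc, plane = "IOL")
}
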