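#' Agreement metrics between two through-focus curves
#'
#' Compares two curves of the same kind (TFVS or defocus visual acuity) on
#' the first curve's grid: zero-lag Pearson cross-correlation, root mean
#' square error, and the largest defocus shift between matched local
#' maxima. The second curve is resampled onto the first curve's grid by
#' linear interpolation; points outside the common support are dropped.
#'
#' Peaks are local maxima at least `peak_threshold` times the curve
#' maximum; peaks of `a` are matched greedily to the nearest peak of `b`
#' and `peak_shift` is the largest absolute defocus difference over
#' matches (0 when both curves are peak-free or identical, `NA` when only
#' one has peaks).
#'
#' @param a,b `"tfvs"` or `"dfva"` objects (same class).
#' @param peak_threshold relative height for a local maximum to count as a
#'   peak (default 0.2).
#' @return Object of class `"agreement"`: list with `cross_correlation`,
#'   `rmse`, `peak_shift`, and `n` (number of compared samples).
#' @export
compare_curves <- function(a, b, peak_threshold = 0.2) {
  ax <- curve_axis(a); ay <- curve_values(a)
  bx <- curve_axis(b); by <- curve_values(b)
  lo <- max(min(ax), min(bx)); hi <- min(max(ax), max(bx))
  sel <- ax >= lo & ax <= hi
  if (sum(sel) < 3L) stop("fewer than 3 common points", call. = FALSE)
  x <- ax[sel]
  ya <- ay[sel]
  yb <- stats::approx(bx, by, xout = x)$y
  if (stats::sd(ya) == 0 || stats::sd(yb) == 0) {
    stop("zero variance: correlation undefined", call. = FALSE)
  }
  r <- stats::cor(ya, yb)
  rmse <- sqrt(mean((ya - yb)^2))
  pa <- x[local_peaks(ya, peak_threshold)]
  pb <- x[local_peaks(yb, peak_threshold)]
  peak_shift <- if (length(pa) == 0L && length(pb) == 0L) {
    0
  } else if (length(pa) == 0L || length(pb) == 0L) {
    NA_real_
  } else {
    max(vapply(pa, function(p) min(abs(p - pb)), numeric(1)))
  }
  structure(list(cross_correlation = r, rmse = rmse, peak_shift = peak_shift,
                 n = length(x)),
            class = "agreement")
}

#' @export
print.agreement <- function(x, ...) {
  cat(sprintf("<agreement> r = %.4f, RMSE = %.4f, peak shift = %s D (n = %d)\n",
              x$cross_correlation, x$rmse,
              ifelse(is.na(x$peak_shift), "NA", sprintf("%.3f", x$peak_shift)),
              x$n))
  invisible(x)
}

curve_axis <- function(cv) {
  if (inherits(cv, "dfva")) cv$vergence else cv$defocus
}
curve_values <- function(cv) {
  if (inherits(cv, "dfva")) cv$logmar else cv$value
}

# Indices of interior local maxima above a relative height threshold.
local_peaks <- function(y, threshold = 0.2) {
  n <- length(y)
  if (n < 3L) return(integer(0))
  idx <- which(diff(sign(diff(y))) == -2) + 1L
  idx[y[idx] >= threshold * max(y)]
}

#' Peak-normalize a TFVS curve
#'
#' Scales the curve to unit maximum, the form in which validation
#' comparisons between estimated and reconstructed TFVS are made.
#'
#' @param curve a `"tfvs"` object.
#' @return The curve scaled to `max(value) == 1` (unchanged if the
#'   maximum is not positive).
#' @export
peak_normalize <- function(curve) {
  m <- max(curve$value)
  if (m <= 0) return(curve)
  tfvs_curve(curve$defocus, curve$value / m, plane = curve$plane)
}
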