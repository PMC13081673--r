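#' Offset between two defocus visual acuity curves
#'
#' The additive logMAR constant that minimizes the RMSE between a
#' simulated curve and a reference curve over their common vergences. For
#' the quadratic RMSE criterion the minimizer has the closed form
#' `mean(reference - simulated)`; applying the offset to the simulated
#' curve changes its baseline but not its shape.
#'
#' @param simulated,reference `"dfva"` objects with at least 3 common
#'   vergences.
#' @return The offset in logMAR (add to the simulated curve).
#' @export
estimate_offset <- function(simulated, reference) {
  stopifnot(inherits(simulated, "dfva"), inherits(reference, "dfva"))
  common <- intersect(round(simulated$vergence, 6), round(reference$vergence, 6))
  if (length(common) < 3L) stop("fewer than 3 common vergences", call. = FALSE)
  s <- simulated$logmar[match(common, round(simulated$vergence, 6))]
  r <- reference$logmar[match(common, round(reference$vergence, 6))]
  mean(r - s)
}

#' Apply a logMAR offset to a defocus curve
#'
#' @param curve a `"dfva"` object.
#' @param offset logMAR constant to add.
#' @return The shifted `"dfva"` object.
#' @export
apply_offset <- function(curve, offset) {
  dfva_curve(curve$vergence, curve$logmar + offset,
             label = curve$label, subject_id = curve$subject_id)
}

#' Depth of focus of a defocus curve
#'
#' The total dioptric range within `range_limits` over which the linearly
#' interpolated logMAR acuity is strictly better (lower) than `threshold`.
#' Sub-intervals are summed, so bimodal curves that re-cross the criterion
#' contribute every segment below it, not just the first. Values exactly
#' at the threshold do not count. The range is intersected with the
#' curve's support (no extrapolation).
#'
#' @param curve a `"dfva"` object.
#' @param threshold criterion acuity in logMAR (default 0.20).
#' @param range_limits length-2 numeric, the vergence window to evaluate
#'   (default `c(-3, 0)`; use `c(-4, 0)` for trifocal designs).
#' @return Depth of focus in diopters.
#' @export
#' @examples
#' cv <- dfva_curve(c(0, -0.5, -1, -1.5), c(0.10, 0.12, 0.15, 0.25))
#' compute_dof(cv)  # crosses 0.20 at -1.25 D -> 1.25 D
compute_dof <- function(curve, threshold = 0.20, range_limits = c(-3, 0)) {
  stopifnot(inherits(curve, "dfva"))
  if (!is.finite(threshold)) stop("`threshold` must be finite", call. = FALSE)
  lo <- max(min(range_limits), min(curve$vergence))
  hi <- min(max(range_limits), max(curve$vergence))
  if (hi <= lo) return(0)
  # work on an increasing axis
  o <- order(curve$vergence)
  x <- curve$vergence[o]
  y <- curve$logmar[o]
  total <- 0
  for (i in seq_len(length(x) - 1L)) {
    x0 <- max(x[i], lo); x1 <- min(x[i + 1L], hi)
    if (x1 <= x0) next
    y0 <- stats::approx(x, y, x0)$y
    y1 <- stats::approx(x, y, x1)$y
    below0 <- y0 < threshold
    below1 <- y1 < threshold
    if (below0 && below1) {
      total <- total + (x1 - x0)
    } else if (below0 != below1) {
      xc <- x0 + (threshold - y0) / (y1 - y0) * (x1 - x0)
      total <- total + if (below0) (xc - x0) else (x1 - xc)
    }
  }
  total
}

#' Visual benefit / degradation relative to a monofocal reference
#'
#' logMAR differences `monofocal - multifocal` at far (0 D), intermediate
#' (-1.50 D) and near (-2.50 D) vergences. Positive values mean the
#' multifocal gives better (lower) logMAR acuity at that distance;
#' negative values mean the monofocal is better (a degradation, typical at
#' far).
#'
#' @param mono,miol `"dfva"` objects containing the three vergences
#'   (no extrapolation is performed).
#' @return Object of class `"benefit_triple"`: named list `far`,
#'   `intermediate`, `near`.
#' @export
visual_benefit <- function(mono, miol) {
  stopifnot(inherits(mono, "dfva"), inherits(miol, "dfva"))
  at <- function(cv, v) {
    i <- which(abs(cv$vergence - v) < 1e-6)
    if (length(i) != 1L) {
      stop(sprintf("curve '%s' has no point at %.2f D", cv$label, v),
           call. = FALSE)
    }
    cv$logmar[i]
  }
  out <- list(far = at(mono, 0) - at(miol, 0),
              intermediate = at(mono, -1.5) - at(miol, -1.5),
              near = at(mono, -2.5) - at(miol, -2.5))
  structure(out, class = "benefit_triple")
}

#' @export
print.benefit_triple <- function(x, ...) {
  cat(sprintf("<benefit> far %+0.3f, intermediate %+0.3f, near %+0.3f logMAR\n",
              x$far, x$intermediate, x$near))
  invisible(x)
}

#' Compare a simulated defocus curve to a reference curve
#'
#' Implements the shape comparison used for simulator validation: the
#' RMSE-minimizing offset is estimated and applied to the simulated curve
#' (never to the reference), then agreement metrics are computed, along
#' with the per-vergence differences `reference - offset-corrected
#' simulated`.
#'
#' @param simulated,reference `"dfva"` objects.
#' @return List with `offset` (logMAR), `agreement` (an `"agreement"`
#'   object), `corrected` (the offset-corrected simulated curve) and
#'   `differences` (data frame `vergence_D`, `difference`).
#' @export
compare_to_reference <- function(simulated, reference) {
  offset <- estimate_offset(simulated, reference)
  corrected <- apply_offset(simulated, offset)
  agr <- compare_curves(corrected, reference)
  common <- intersect(round(corrected$vergence, 6), round(reference$vergence, 6))
  common <- sort(common, decreasing = TRUE)
  s <- corrected$logmar[match(common, round(corrected$vergence, 6))]
  r <- reference$logmar[match(common, round(reference$vergence, 6))]
  list(offset = offset, agreement = agr, corrected = corrected,
       differences = data.frame(vergence_D = common, difference = r - s))
}
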