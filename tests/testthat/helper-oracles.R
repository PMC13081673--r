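# Independent oracles used by the unit and acceptance tests. These
# deliberately avoid the package's own computational paths.

# Diffraction MTF by brute-force 2-D autocorrelation of the sampled
# circular pupil with a defocus phase term.
oracle_defocus_mtf_2d <- function(defocus_D, nu_cpd, pupil_mm, wavelength_nm,
                                  n = 301) {
  a <- pupil_mm * 1e-3 / 2
  shear <- wavelength_nm * 1e-9 * nu_cpd * 180 / pi
  xs <- seq(-a, a, length.out = n)
  g <- expand.grid(x = xs, y = xs)
  k <- 2 * pi / (wavelength_nm * 1e-9)
  w <- function(x, y) defocus_D / 2 * (x^2 + y^2)   # defocus wavefront (m)
  p1 <- (g$x + shear / 2)^2 + g$y^2 <= a^2
  p2 <- (g$x - shear / 2)^2 + g$y^2 <= a^2
  both <- p1 & p2
  phase <- k * (w(g$x + shear / 2, g$y) - w(g$x - shear / 2, g$y))
  area <- sum((g$x^2 + g$y^2) <= a^2)
  Mod(sum(exp(1i * phase[both]))) / area
}

# Projected-gradient solver for min ||Ax - y||^2 s.t. x >= 0. Dense,
# slow, and entirely independent of the Lawson-Hanson routine.
oracle_nnls_pg <- function(A, y, n_iter = 200000, tol = 1e-14) {
  L <- max(eigen(crossprod(A), symmetric = TRUE, only.values = TRUE)$values)
  x <- rep(0, ncol(A))
  z <- x
  t_k <- 1
  obj <- function(x) sum((A %*% x - y)^2)
  last <- obj(x)
  for (i in seq_len(n_iter)) {
    grad <- 2 * crossprod(A, A %*% z - y)
    x_new <- pmax(z - grad / (2 * L), 0)
    t_new <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    z <- x_new + (t_k - 1) / t_new * (x_new - x)
    x <- x_new
    t_k <- t_new
    if (i %% 500 == 0) {
      cur <- obj(x)
      if (abs(last - cur) < tol * max(1, cur)) break
      last <- cur
    }
  }
  x
}

# Magnitude response of an FIR filter by explicit DTFT sum (frequencies
# as fractions of Nyquist).
oracle_fir_response <- function(taps, freq_frac) {
  vapply(freq_frac, function(f) {
    Mod(sum(taps * exp(-1i * pi * f * (seq_along(taps) - 1))))
  }, numeric(1))
}

# Brute-force search for the offset minimizing RMSE between two aligned
# logMAR vectors.
oracle_offset_grid <- function(sim, ref, lo = -0.5, hi = 0.5, step = 1e-4) {
  offs <- seq(lo, hi, by = step)
  rmse <- vapply(offs, function(o) sqrt(mean((ref - (sim + o))^2)), numeric(1))
  offs[which.min(rmse)]
}

# Small synthetic trifocal target built from planted kernel copies.
planted_mixture <- function(kernel, weights, additions, grid) {
  vals <- numeric(length(grid))
  for (i in seq_along(weights)) {
    vals <- vals + weights[i] *
      stats::approx(kernel$offsets, kernel$values, grid + additions[i],
                    yleft = 0, yright = 0)$y
  }
  tfvs_curve(grid, vals, plane = "IOL")
}
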