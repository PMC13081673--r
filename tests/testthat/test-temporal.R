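kern <- monofocal_vs_kernel()
grid_d <- seq(-4.5, 1, 0.05)

test_that("a pure monofocal target yields a single coefficient at 0 D", {
  target <- planted_mixture(kern, 1, 0, grid_d)
  prof <- solve_temporal_coefficients(target, kern)
  expect_length(prof$additions, 1)
  expect_equal(prof$additions, 0)
  expect_equal(prof$dwell_fractions, 1)
  expect_equal(prof$fitted_scale, 1, tolerance = 1e-6)
})

test_that("a planted two-component mixture is recovered within 0.02", {
  target <- planted_mixture(kern, c(0.6, 0.4), c(0, 2.5), grid_d)
  prof <- solve_temporal_coefficients(target, kern)
  expect_length(prof$additions, 2)
  expect_equal(prof$additions, c(0, 2.5))
  expect_equal(prof$dwell_fractions, c(0.6, 0.4), tolerance = 0.02)
})

test_that("planted mixtures with up to 5 components are recovered", {
  set.seed(7)
  for (rep in 1:5) {
    k_n <- sample(2:5, 1)
    adds <- sort(sample(seq(0, 4, by = 0.05), k_n))
    while (min(diff(c(-1, adds))) < 0.6) {
      adds <- sort(sample(seq(0, 4, by = 0.05), k_n))
    }
    w <- runif(k_n, 0.05, 1)
    w <- w / sum(w)
    if (any(w < 0.05)) next
    target <- planted_mixture(kern, w, adds, grid_d)
    prof <- solve_temporal_coefficients(target, kern)
    expect_length(prof$additions, k_n)
    for (i in seq_len(k_n)) {
      j <- which.min(abs(prof$additions - adds[i]))
      expect_lte(abs(prof$additions[j] - adds[i]), 0.05)
      expect_lte(abs(prof$dwell_fractions[j] - w[i]), 0.02)
    }
  }
})

test_that("solver matches an independent projected-gradient QP oracle", {
  # small dense problems: <= 7 candidate additions, <= 41 defocus samples
  small_grid <- seq(-3, 1, 0.1)
  adds <- seq(0, 3, by = 0.5)
  A <- vapply(adds, function(a) {
    approx(kern$offsets, kern$values, small_grid + a, yleft = 0, yright = 0)$y
  }, numeric(length(small_grid)))
  set.seed(11)
  for (rep in 1:4) {
    w <- rep(0, length(adds))
    w[sample(seq_along(adds), 3)] <- runif(3, 0.2, 1)
    y <- as.numeric(A %*% w) + rnorm(length(small_grid), 0, 0.01)
    y <- pmax(y, 0)
    ours <- pracma::lsqnonneg(A, y)$x
    oracle <- oracle_nnls_pg(A, y)
    res_ours <- sum((A %*% ours - y)^2)
    res_oracle <- sum((A %*% oracle - y)^2)
    expect_lte(abs(res_ours - res_oracle), 1e-6)
    expect_identical(which(ours > 1e-6), which(oracle > 1e-6))
  }
})

test_that("pruning never increases the coefficient count", {
  target <- planted_mixture(kern, c(0.5, 0.3, 0.2), c(0, 1.75, 3.5), grid_d)
  noisy <- tfvs_curve(grid_d,
                      pmax(target$value + 0.01 * sin(20 * grid_d), 0),
                      plane = "IOL")
  A <- vapply(seq(-0.5, 4.5, 0.05), function(a) {
    approx(kern$offsets, kern$values, grid_d + a, yleft = 0, yright = 0)$y
  }, numeric(length(grid_d)))
  dense_nnz <- sum(pracma::lsqnonneg(A, noisy$value)$x > 0)
  prof <- solve_temporal_coefficients(noisy, kern)
  expect_lte(length(prof$additions), dense_nnz)
})

test_that("profiles enforce the dwell-time budget", {
  prof <- temporal_profile(c(0, 1.75, 3.5), c(0.5, 0.3, 0.2))
  expect_equal(sum(prof$dwell_fractions), 1)
  expect_equal(sum(prof$dwell_fractions * prof$cycle_ms), 20)
  expect_equal(prof$rate_hz, 50)
  expect_error(temporal_profile(c(0, 1), c(0.5, 0.4)), "sum to 1")
  expect_error(temporal_profile(c(0, 0), c(0.5, 0.5)), "unique")
  expect_error(temporal_profile(c(0, 1), c(1.1, -0.1)), "positive")
})

test_that("reconstruction translates and superposes kernels linearly", {
  single <- temporal_profile(2, 1)
  rec <- reconstruct_tfvs(single, kern, grid_d, scale = "dwell")
  expect_equal(rec$value,
               approx(kern$offsets, kern$values, grid_d + 2,
                      yleft = 0, yright = 0)$y)
  p1 <- temporal_profile(c(0, 2.5), c(0.6, 0.4))
  ra <- reconstruct_tfvs(temporal_profile(0, 1), kern, grid_d, scale = "dwell")
  rb <- reconstruct_tfvs(temporal_profile(2.5, 1), kern, grid_d, scale = "dwell")
  rc <- reconstruct_tfvs(p1, kern, grid_d, scale = "dwell")
  expect_equal(rc$value, 0.6 * ra$value + 0.4 * rb$value, tolerance = 1e-12)
})

test_that("reconstruction of a solved planted mixture matches the target", {
  target <- planted_mixture(kern, c(0.6, 0.4), c(0, 2.5), grid_d)
  prof <- solve_temporal_coefficients(target, kern)
  rec <- reconstruct_tfvs(prof, kern, grid_d, scale = "fitted")
  expect_lt(sqrt(mean((rec$value - target$value)^2)), 0.02)
})

test_that("agreement metrics match hand-computed values", {
  a <- tfvs_curve(c(-1, 0, 1), c(0, 0.1, 0.2))
  b <- tfvs_curve(c(-1, 0, 1), c(0.1, 0.1, 0.3))
  rep_ <- compare_curves(a, b)
  expect_equal(rep_$cross_correlation, 0.8660254, tolerance = 1e-6)
  expect_equal(rep_$rmse, 0.08164966, tolerance = 1e-6)
})

test_that("identical curves and affine transforms behave as expected", {
  g <- seq(-3, 1, 0.05)
  a <- tfvs_curve(g, exp(-(g + 1)^2))
  same <- compare_curves(a, a)
  expect_equal(same$cross_correlation, 1)
  expect_equal(same$rmse, 0)
  expect_equal(same$peak_shift, 0)
  b <- tfvs_curve(g, 0.5 * a$value + 0.1)
  expect_equal(compare_curves(a, b)$cross_correlation, 1, tolerance = 1e-12)
})

test_that("degenerate comparisons are rejected", {
  a <- tfvs_curve(c(0, 1), c(0, 1))
  b <- tfvs_curve(c(0, 1), c(1, 0))
  expect_error(compare_curves(a, b), "3 common points")
  flat <- tfvs_curve(c(-1, 0, 1), c(0.5, 0.5, 0.5))
  bumpy <- tfvs_curve(c(-1, 0, 1), c(0.4, 0.6, 0.4))
  expect_error(compare_curves(flat, bumpy), "zero variance")
})
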