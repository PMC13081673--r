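vg <- seq(1, -4, by = -0.5)

test_that("offset equals the mean difference and the grid-search minimum", {
  set.seed(3)
  for (rep in 1:5) {
    sim <- dfva_curve(vg, runif(length(vg), -0.1, 0.6), label = "sim")
    ref <- dfva_curve(vg, sim$logmar + rnorm(length(vg), 0.05, 0.08),
                      label = "ref")
    off <- estimate_offset(sim, ref)
    expect_equal(off, mean(ref$logmar - sim$logmar), tolerance = 1e-12)
    expect_lt(abs(off - oracle_offset_grid(sim$logmar, ref$logmar)), 1e-4)
  }
})

test_that("offset of identical and uniformly shifted curves is exact", {
  cv <- dfva_curve(vg, 0.1 + 0.1 * (vg + 1.5)^2)
  expect_equal(estimate_offset(cv, cv), 0)
  shifted <- dfva_curve(vg, cv$logmar + 0.05)
  expect_equal(estimate_offset(cv, shifted), 0.05, tolerance = 1e-12)
})

test_that("depth of focus integrates all sub-threshold intervals", {
  flat <- dfva_curve(seq(0, -3, -0.5), rep(0.1, 7))
  expect_equal(compute_dof(flat, range_limits = c(-3, 0)), 3)
  bad <- dfva_curve(seq(0, -3, -0.5), seq(0.25, 0.85, 0.1))
  expect_equal(compute_dof(bad, range_limits = c(-3, 0)), 0)
  # tabulated 4-point example: crossing at -1.25 D
  ex <- dfva_curve(c(0, -0.5, -1, -1.5), c(0.10, 0.12, 0.15, 0.25))
  expect_equal(compute_dof(ex, range_limits = c(-3, 0)), 1.25)
})

test_that("bimodal curves contribute every interval below threshold", {
  # below 0.20 on [0,-1] and around -2.5 (re-crossing)
  cv <- dfva_curve(seq(0, -3, -0.5), c(0.1, 0.1, 0.3, 0.3, 0.1, 0.1, 0.3))
  # crossings at -0.75, -1.75(down at -2: y=0.3->0.1 crossing -1.75? compute)
  dof <- compute_dof(cv, range_limits = c(-3, 0))
  # segments: [0,-0.75] below; [-1.75... interpolate: crossing between -1.5
  # (0.3) and -2.0 (0.1) at -1.75; below until crossing between -2.5 (0.1)
  # and -3.0 (0.3) at -2.75 -> 0.75 + 1.0 = 1.75
  expect_equal(dof, 1.75)
})

test_that("strictly-at-threshold acuity does not count toward DOF", {
  cv <- dfva_curve(seq(0, -3, -0.5), rep(0.20, 7))
  expect_equal(compute_dof(cv, range_limits = c(-3, 0)), 0)
})

test_that("DOF is monotone in acuity and bounded by the window", {
  set.seed(9)
  g <- seq(0, -4, -0.5)
  for (rep in 1:10) {
    y <- runif(length(g), 0, 0.5)
    cv <- dfva_curve(g, y)
    better <- dfva_curve(g, y - runif(length(g), 0, 0.2))
    expect_gte(compute_dof(better, range_limits = c(-4, 0)),
               compute_dof(cv, range_limits = c(-4, 0)))
    expect_lte(compute_dof(cv, range_limits = c(-4, 0)), 4)
  }
})

test_that("benefit triple follows the sign convention", {
  mono <- dfva_curve(vg, rep(0.0, length(vg)), label = "mono")
  miol <- dfva_curve(vg, rep(0.0, length(vg)), label = "miol")
  z <- visual_benefit(mono, miol)
  expect_equal(unlist(z), c(far = 0, intermediate = 0, near = 0))
  miol2 <- dfva_curve(vg, ifelse(vg == 0, 0.10, 0.0))
  expect_equal(visual_benefit(mono, miol2)$far, -0.10)   # degradation at far
  mono3 <- dfva_curve(vg, ifelse(vg == -2.5, 0.40, 0.0))
  miol3 <- dfva_curve(vg, ifelse(vg == -2.5, 0.15, 0.0))
  expect_equal(visual_benefit(mono3, miol3)$near, 0.25)  # benefit at near
})

test_that("benefit is antisymmetric and refuses missing vergences", {
  set.seed(4)
  a <- dfva_curve(vg, runif(length(vg)))
  b <- dfva_curve(vg, runif(length(vg)))
  ab <- visual_benefit(a, b); ba <- visual_benefit(b, a)
  expect_equal(unlist(ab), -unlist(ba))
  short <- dfva_curve(c(0, -1, -2), c(0.1, 0.2, 0.3))
  expect_error(visual_benefit(a, short), "no point at")
})

test_that("reference comparison removes a constant offset completely", {
  set.seed(5)
  sim <- dfva_curve(vg, runif(length(vg), 0, 0.5), label = "sim")
  ref <- dfva_curve(vg, sim$logmar + 0.13, label = "ref")
  cmp <- compare_to_reference(sim, ref)
  expect_equal(cmp$offset, 0.13, tolerance = 1e-12)
  expect_equal(cmp$agreement$cross_correlation, 1, tolerance = 1e-9)
  expect_equal(cmp$agreement$rmse, 0, tolerance = 1e-9)
  expect_equal(cmp$differences$difference, rep(0, length(vg)),
               tolerance = 1e-12)
})

test_that("offset correction never worsens RMSE and never changes correlation", {
  set.seed(6)
  for (rep in 1:5) {
    sim <- dfva_curve(vg, runif(length(vg), 0, 0.5))
    ref <- dfva_curve(vg, runif(length(vg), 0, 0.5))
    raw <- compare_curves(sim, ref)
    cmp <- compare_to_reference(sim, ref)
    expect_lte(cmp$agreement$rmse, raw$rmse + 1e-12)
    expect_equal(cmp$agreement$cross_correlation, raw$cross_correlation,
                 tolerance = 1e-12)
  }
})

test_that("agreement RMSE tracks injected noise at the Monte Carlo level", {
  set.seed(8)
  base <- 0.1 + 0.1 * (vg + 1.5)^2
  rmses <- replicate(200, {
    sim <- dfva_curve(vg, base + rnorm(length(vg), 0, 0.05))
    ref <- dfva_curve(vg, base)
    compare_to_reference(sim, ref)$agreement$rmse
  })
  expect_lt(abs(mean(rmses) - 0.05), 0.01)
})
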