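test_that("synthetic trifocal curves peak exactly at the published adds", {
  spec <- iol_fixtures()$trifocal_175_350
  cv <- make_synthetic_tfmtf(spec)
  peaks <- cv$defocus[which(diff(sign(diff(cv$value))) == -2) + 1]
  peaks <- peaks[cv$value[match(peaks, cv$defocus)] > 0.05 * max(cv$value)]
  expect_equal(sort(peaks), c(-3.5, -1.75, 0))
})

test_that("the monofocal fixture has a single dominant maximum at 0 D", {
  cv <- make_synthetic_tfmtf(iol_fixtures()$monofocal)
  expect_equal(cv$defocus[which.max(cv$value)], 0)
  peaks <- which(diff(sign(diff(cv$value))) == -2) + 1
  big <- peaks[cv$value[peaks] > 0.2 * max(cv$value)]
  expect_length(big, 1)
})

test_that("EDOF plateaus stay within 10% of the maximum", {
  spec <- iol_fixtures()$edof_190
  cv <- make_synthetic_tfmtf(spec)
  sel <- cv$defocus <= 0 & cv$defocus >= -spec$plateau_extent
  expect_true(all(cv$value[sel] >= 0.9 * max(cv$value)))
})

test_that("fixture generation is deterministic and nonnegative", {
  a <- make_synthetic_tfmtf(iol_fixtures()$trifocal_217_325)
  b <- make_synthetic_tfmtf(iol_fixtures()$trifocal_217_325)
  expect_identical(a$value, b$value)
  for (fx in iol_fixtures()) {
    cv <- make_synthetic_tfmtf(fx)
    expect_true(all(cv$value >= 0))
    expect_equal(max(cv$value), fx$peak_mtf)
  }
})

test_that("design-spec validation catches malformed lenses", {
  expect_error(iol_design_spec("trifocal", 1.75), "exactly 2")
  expect_error(iol_design_spec("edof"), "1 intermediate")
  expect_error(iol_design_spec("trifocal", c(-1, 2)), ">= 0")
  expect_warning(iol_design_spec("trifocal", c(0.1, 3.5)), "overlap")
})

make_profiles <- function() {
  kern <- monofocal_vs_kernel()
  g <- seq(-4.5, 1, 0.05)
  list(
    monofocal = reconstruct_tfvs(temporal_profile(0, 1), kern, g,
                                 scale = "dwell"),
    trifocal = reconstruct_tfvs(
      temporal_profile(c(0, 1.75, 3.5), c(0.4, 0.3, 0.3)), kern, g,
      scale = "dwell"))
}

test_that("a noiseless cohort reproduces the lens templates exactly", {
  profs <- make_profiles()
  spec <- cohort_spec(n_subjects = 3, residual_sd = 0, intercept_sd = 0,
                      seed = 42)
  df <- make_synthetic_cohort(spec, profs)
  one <- df[df$lens == "trifocal", ]
  per_subj <- split(one$logmar, one$subject_id)
  expect_equal(per_subj[[1]], per_subj[[2]])
  expect_equal(per_subj[[2]], per_subj[[3]])
  expect_true(all(df$logmar >= -0.1 - 1e-9 & df$logmar <= 0.8 + 1e-9))
})

test_that("cohort noise reproduces the configured residual SD", {
  profs <- make_profiles()
  spec <- cohort_spec(n_subjects = 200, residual_sd = 0.11, intercept_sd = 0,
                      seed = 7)
  df <- make_synthetic_cohort(spec, profs["monofocal"])
  tmpl <- tapply(df$logmar, df$vergence_D, mean)
  resid <- df$logmar - tmpl[as.character(df$vergence_D)]
  expect_equal(stats::sd(resid), 0.11, tolerance = 0.02)
})

test_that("the cohort generator is seed-reproducible", {
  profs <- make_profiles()
  s <- cohort_spec(n_subjects = 5, seed = 99)
  expect_identical(make_synthetic_cohort(s, profs),
                   make_synthetic_cohort(s, profs))
  s2 <- cohort_spec(n_subjects = 5, seed = 100)
  expect_false(identical(make_synthetic_cohort(s, profs),
                         make_synthetic_cohort(s2, profs)))
  expect_error(cohort_spec(n_subjects = 5), "seed")
})

test_that("planted cohort structure survives the full analysis loop", {
  # trifocal lens should show a clearly larger DOF than the monofocal;
  # grid-aligned adds so the 0.50 D vergence sampling hits the foci
  kern <- monofocal_vs_kernel()
  g <- seq(-4.5, 1, 0.05)
  profs <- list(
    monofocal = reconstruct_tfvs(temporal_profile(0, 1), kern, g,
                                 scale = "dwell"),
    trifocal = reconstruct_tfvs(
      temporal_profile(c(0, 1.5, 3), c(0.34, 0.33, 0.33)), kern, g,
      scale = "dwell"))
  spec <- cohort_spec(n_subjects = 12, residual_sd = 0.05, seed = 31)
  df <- make_synthetic_cohort(spec, profs)
  mean_dof <- function(lens) {
    curves <- split(df[df$lens == lens, ], df$subject_id[df$lens == lens])
    mean(vapply(curves, function(d) {
      compute_dof(dfva_curve(d$vergence_D, d$logmar), threshold = 0.2,
                  range_limits = c(-4, 0))
    }, numeric(1)))
  }
  expect_gt(mean_dof("trifocal"), mean_dof("monofocal") + 0.5)
})
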