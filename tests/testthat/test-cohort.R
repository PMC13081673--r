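make_blocks <- function(mat, lenses = paste0("L", seq_len(ncol(mat)))) {
  data.frame(
    subject_id = rep(sprintf("S%02d", seq_len(nrow(mat))), ncol(mat)),
    lens = rep(lenses, each = nrow(mat)),
    value = as.vector(mat))
}

test_that("perfect ordering over 15 subjects gives the Friedman worked value", {
  # one lens uniformly worst, one middle, one best: rank sums 15/30/45
  mat <- matrix(rep(c(1, 2, 3), each = 15), 15, 3)
  res <- omnibus_and_posthoc(make_blocks(mat))
  expect_identical(res$branch, "friedman")   # deterministic data fail normality
  expect_equal(res$statistic, 30)
  expect_lt(res$omnibus_p, 0.001)
})

test_that("fully tied data give a zero Friedman statistic", {
  mat <- matrix(0.25, 8, 3)
  res <- omnibus_and_posthoc(make_blocks(mat))
  expect_identical(res$branch, "friedman")
  expect_equal(res$statistic, 0)
  expect_equal(res$omnibus_p, 1)
})

test_that("the Friedman branch is invariant to monotone transforms", {
  set.seed(21)
  mat <- matrix(rexp(45)^3, 15, 3)  # heavily skewed, fails normality
  r1 <- omnibus_and_posthoc(make_blocks(mat))
  r2 <- omnibus_and_posthoc(make_blocks(sqrt(mat)))  # still skewed
  expect_identical(r1$branch, "friedman")
  expect_identical(r2$branch, "friedman")
  expect_equal(r1$statistic, r2$statistic)
  expect_equal(r1$pairwise$p, r2$pairwise$p)
})

test_that("normal data take the RM-ANOVA branch with Bonferroni-corrected pairs", {
  set.seed(22)
  n <- 12
  subj <- rnorm(n, 0, 0.3)
  mat <- outer(subj, c(0, 0.4, 0.1), `+`) + matrix(rnorm(3 * n, 0, 0.1), n, 3)
  res <- omnibus_and_posthoc(make_blocks(mat))
  expect_identical(res$branch, "rm_anova")
  expect_lt(res$omnibus_p, 0.01)
  raw <- vapply(list(c(1, 2), c(1, 3), c(2, 3)), function(ij) {
    t.test(mat[, ij[1]], mat[, ij[2]], paired = TRUE)$p.value
  }, numeric(1))
  expect_equal(res$pairwise$p, pmin(raw * 3, 1), tolerance = 1e-12)
  expect_true(all(res$pairwise$p >= raw))
  # the branch decision is deterministic given the data
  res2 <- omnibus_and_posthoc(make_blocks(mat))
  expect_identical(res2$branch, res$branch)
  expect_equal(res2$omnibus_p, res$omnibus_p)
})

test_that("incomplete blocks are dropped with a warning, tiny cohorts refused", {
  mat <- matrix(rnorm(18), 6, 3)
  df <- make_blocks(mat)
  df <- df[-1, ]  # subject S01 loses lens L1
  expect_warning(res <- omnibus_and_posthoc(df), "incomplete")
  expect_equal(res$n, 5)
  expect_error(
    suppressWarnings(omnibus_and_posthoc(df[df$subject_id %in%
      sprintf("S%02d", 1:4), ])),
    "fewer than 5")
})

test_that("gain regression recovers a planted slope and flags the session null", {
  df <- make_synthetic_dof_gains(n_subjects = 30, seed = 101)
  res <- dof_gain_regression(df)
  tri <- res$slopes[res$slopes$group == "trifocal", ]
  edof <- res$slopes[res$slopes$group == "EDOF", ]
  expect_lt(abs(tri$slope - (-0.96)), 2.5 * tri$se)
  expect_lt(abs(edof$slope - (-0.57)), 2.5 * edof$se)
  expect_gt(res$session_p, 0.001)  # no planted session effect
})

test_that("a null slope is estimated near zero", {
  df <- make_synthetic_dof_gains(
    n_subjects = 25, slopes = c(trifocal = 0, EDOF = 0), seed = 55)
  res <- dof_gain_regression(df)
  for (i in seq_len(nrow(res$slopes))) {
    expect_lt(abs(res$slopes$slope[i]), 2 * res$slopes$se[i] + 1e-9)
  }
})

test_that("duplicating every record leaves the point estimates unchanged", {
  df <- make_synthetic_dof_gains(n_subjects = 12, seed = 77)
  res1 <- dof_gain_regression(df)
  df2 <- rbind(df, df)
  res2 <- dof_gain_regression(df2)
  expect_equal(res2$slopes$slope, res1$slopes$slope, tolerance = 1e-6)
})

test_that("degenerate regression inputs are refused", {
  df <- make_synthetic_dof_gains(n_subjects = 12, seed = 1)
  expect_error(dof_gain_regression(df[df$subject_id %in%
    sprintf("S%02d", 1:3), ]), "5 subjects")
  expect_error(dof_gain_regression(df[, 1:3]), "columns")
})
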