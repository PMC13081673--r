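#' Mixed-effect regression of depth-of-focus gain on monofocal baseline
#'
#' Fits the relationship between each subject's baseline monofocal depth
#' of focus and the gain achieved with a multifocal or EDOF design,
#' allowing different slopes per design group:
#' \deqn{gain_{ij} = \alpha_{g(j)} + \beta_{g(j)}\, baseline_i +
#'   \gamma\, session_{ij} + u_i + \varepsilon_{ij}}
#' with a per-subject random intercept \eqn{u_i}, fit by REML
#' (`lmerTest`). Negative slopes mean subjects with wider monofocal depth
#' of focus gain less from the multifocal design.
#'
#' @param records data frame with columns `subject_id`, `lens`, `group`
#'   (`"trifocal"` / `"EDOF"`), `session` (`"I"` / `"II"`), `dof`,
#'   `baseline_dof` (diopters; shared within subject). A `gain` column is
#'   computed as `dof - baseline_dof` if absent.
#' @return List with `slopes` (data frame: group, slope, SE, lower/upper
#'   95% CI), `interaction_p` (test that the slopes differ between
#'   groups), `session_p` (session fixed effect), and `model` (the fitted
#'   `lmerMod`).
#' @export
dof_gain_regression <- function(records) {
  req <- c("subject_id", "lens", "group", "session", "dof", "baseline_dof")
  if (!all(req %in% names(records))) {
    stop("records must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(records$subject_id)) < 5L) {
    stop("need at least 5 subjects", call. = FALSE)
  }
  if (is.null(records$gain)) records$gain <- records$dof - records$baseline_dof
  records$group <- factor(records$group)
  records$session <- factor(records$session)
  if (any(table(unique(records[c("lens", "group")])$group) < 2L)) {
    stop("need at least 2 lenses per group", call. = FALSE)
  }
  m <- lmerTest::lmer(
    gain ~ baseline_dof * group + session + (1 | subject_id),
    data = records, REML = TRUE)
  tr <- emmeans::emtrends(m, "group", var = "baseline_dof",
                          lmer.df = "satterthwaite")
  trs <- summary(tr)
  slopes <- data.frame(group = as.character(trs$group),
                       slope = trs$baseline_dof.trend,
                       se = trs$SE,
                       lower = trs$lower.CL,
                       upper = trs$upper.CL)
  an <- stats::anova(m)
  inter_row <- grep(":", rownames(an))
  sess_row <- grep("^session$", rownames(an))
  list(slopes = slopes,
       interaction_p = if (length(inter_row)) an[inter_row, "Pr(>F)"] else NA_real_,
       session_p = if (length(sess_row)) an[sess_row, "Pr(>F)"] else NA_real_,
       model = m)
}

#' Repeated-measures omnibus test with post hoc comparisons
#'
#' Compares a per-subject metric (e.g. visual benefit at one distance)
#' across the lenses of one session. Residuals after removing subject and
#' lens means are tested for normality (Shapiro-Wilk, alpha = 0.05):
#' normally distributed data get a repeated-measures ANOVA with
#' Bonferroni-corrected paired t tests; otherwise a Friedman test
#' \deqn{\chi^2_F = \frac{12}{n k (k+1)} \sum_j R_j^2 - 3 n (k+1)}
#' (mid-ranks on ties) with Tukey-Kramer post hoc on the mean ranks using
#' the studentized-range distribution.
#'
#' Subjects missing any lens (incomplete blocks) are dropped with a
#' warning; fewer than 5 complete subjects is an error.
#'
#' @param records data frame with columns `subject_id`, `lens`, and the
#'   metric named by `value`.
#' @param value name of the metric column (default `"value"`).
#' @param alpha significance level for the normality gate and for
#'   reporting significant pairwise effects.
#' @return List with `branch` (`"rm_anova"` or `"friedman"`),
#'   `normality_p`, `omnibus_p`, `statistic`, and `pairwise` (data frame:
#'   comparison, direction, p; direction names the better lens, i.e. the
#'   one with the higher metric).
#' @export
omnibus_and_posthoc <- function(records, value = "value", alpha = 0.05) {
  stopifnot(all(c("subject_id", "lens", value) %in% names(records)))
  wide <- stats::reshape(
    records[, c("subject_id", "lens", value)],
    idvar = "subject_id", timevar = "lens", direction = "wide")
  lens_names <- sub(paste0("^", value, "\\."), "",
                    setdiff(names(wide), "subject_id"))
  mat <- as.matrix(wide[, -1, drop = FALSE])
  colnames(mat) <- lens_names
  complete <- stats::complete.cases(mat)
  if (!all(complete)) {
    warning(sprintf("dropping %d subject(s) with incomplete blocks",
                    sum(!complete)), call. = FALSE)
    mat <- mat[complete, , drop = FALSE]
  }
  n <- nrow(mat); k <- ncol(mat)
  if (n < 5L) stop("fewer than 5 complete subjects", call. = FALSE)

  resid <- mat - rowMeans(mat) -
    matrix(colMeans(mat), n, k, byrow = TRUE) + mean(mat)
  norm_p <- tryCatch(stats::shapiro.test(as.vector(resid))$p.value,
                     error = function(e) 0)
  pairs_idx <- utils::combn(k, 2)
  n_comp <- ncol(pairs_idx)

  if (norm_p >= alpha) {
    branch <- "rm_anova"
    long <- data.frame(
      y = as.vector(mat),
      lens = factor(rep(colnames(mat), each = n)),
      subject = factor(rep(seq_len(n), k)))
    fit <- stats::aov(y ~ lens + Error(subject), data = long)
    tab <- summary(fit)[["Error: Within"]][[1]]
    omnibus_p <- tab["lens", "Pr(>F)"]
    statistic <- tab["lens", "F value"]
    pw <- apply(pairs_idx, 2, function(ij) {
      tt <- stats::t.test(mat[, ij[1]], mat[, ij[2]], paired = TRUE)
      c(p = tt$p.value, diff = mean(mat[, ij[1]] - mat[, ij[2]]))
    })
    p_adj <- pmin(pw["p", ] * n_comp, 1)
    diffs <- pw["diff", ]
  } else {
    branch <- "friedman"
    fr <- stats::friedman.test(mat)
    omnibus_p <- fr$p.value
    statistic <- unname(fr$statistic)
    if (is.nan(statistic)) {
      # fully tied data: the uncorrected statistic is 0 (mid-ranks)
      statistic <- 0
      omnibus_p <- 1
    }
    ranks <- t(apply(mat, 1, rank))
    rbar <- colMeans(ranks)
    se_rank <- sqrt(k * (k + 1) / (12 * n))
    p_adj <- apply(pairs_idx, 2, function(ij) {
      q <- abs(rbar[ij[1]] - rbar[ij[2]]) / se_rank
      stats::ptukey(q, nmeans = k, df = Inf, lower.tail = FALSE)
    })
    diffs <- apply(pairs_idx, 2, function(ij) rbar[ij[1]] - rbar[ij[2]])
  }
  pairwise <- data.frame(
    comparison = apply(pairs_idx, 2, function(ij) {
      paste(colnames(mat)[ij[1]], "vs", colnames(mat)[ij[2]])
    }),
    direction = apply(rbind(pairs_idx, diffs), 2, function(z) {
      if (z[3] > 0) paste(colnames(mat)[z[1]], "better")
      else if (z[3] < 0) paste(colnames(mat)[z[2]], "better")
      else "none"
    }),
    p = as.numeric(p_adj))
  pairwise$significant <- pairwise$p < alpha
  list(branch = branch, normality_p = norm_p, omnibus_p = omnibus_p,
       statistic = statistic, pairwise = pairwise, n = n, k = k)
}
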