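#' Synthetic IOL optical design specification
#'
#' Parameters of a synthetic through-focus MTF profile: a monofocal has a
#' single far peak, a trifocal has far, intermediate and near peaks at its
#' add powers, and an EDOF has a smoothed plateau extending from far
#' toward its intermediate add.
#'
#' @param design `"monofocal"`, `"trifocal"` or `"edof"`.
#' @param add_powers additions in diopters: length 2 (intermediate, near)
#'   for a trifocal, length 1 for an EDOF, empty/0 for a monofocal.
#' @param peak_widths Gaussian sigma of the focal peaks in diopters.
#' @param relative_peak_heights relative heights of the far/intermediate/
#'   near peaks (trifocal) or far peak (others).
#' @param plateau_extent plateau length in diopters (EDOF only; defaults
#'   to the intermediate add).
#' @param peak_mtf raw MTF value at the strongest peak (default 0.5,
#'   a plausible bench value at 15 cycles/degree for a 3-mm pupil).
#' @param name label carried through plots and reports.
#' @return Object of class `"iol_design"`.
#' @export
iol_design_spec <- function(design = c("monofocal", "trifocal", "edof"),
                            add_powers = numeric(0), peak_widths = 0.32,
                            relative_peak_heights = NULL,
                            plateau_extent = NULL, peak_mtf = 0.5,
                            name = design) {
  design <- match.arg(design)
  add_powers <- as.numeric(add_powers)
  if (any(add_powers < 0)) stop("additions must be >= 0", call. = FALSE)
  if (design == "trifocal" && length(add_powers) != 2L) {
    stop("a trifocal needs exactly 2 additions (intermediate, near)",
         call. = FALSE)
  }
  if (design == "edof" && length(add_powers) != 1L && is.null(plateau_extent)) {
    stop("an EDOF needs 1 intermediate addition or a plateau extent",
         call. = FALSE)
  }
  if (design == "monofocal") add_powers <- numeric(0)
  if (is.null(relative_peak_heights)) {
    relative_peak_heights <- switch(design,
      monofocal = 1,
      trifocal = c(1, 0.8, 0.9),
      edof = 1)
  }
  if (design == "edof" && is.null(plateau_extent)) {
    plateau_extent <- add_powers[1]
  }
  if (design == "trifocal" && min(diff(sort(c(0, add_powers)))) < peak_widths[1]) {
    warning("additions closer than one peak width: peaks will overlap",
            call. = FALSE)
  }
  structure(list(design = design, add_powers = add_powers,
                 peak_widths = peak_widths,
                 relative_peak_heights = relative_peak_heights,
                 plateau_extent = plateau_extent, peak_mtf = peak_mtf,
                 name = name),
            class = "iol_design")
}

#' Packaged synthetic lens designs
#'
#' Six synthetic design specifications named after the design classes of
#' commercial presbyopia-correcting IOLs, with the published intermediate
#' and near add powers, plus a monofocal reference. These are the fixtures
#' exercised by the end-to-end pipeline tests.
#'
#' @return Named list of `"iol_design"` objects: `monofocal`,
#'   `trifocal_217_325` (adds +2.17/+3.25 D), `trifocal_175_350`
#'   (+1.75/+3.5 D), `trifocal_166_333` (+1.66/+3.33 D), `edof_175`
#'   (+1.75 D), `edof_153` (+1.53 D), `edof_190` (+1.9 D).
#' @export
iol_fixtures <- function() {
  list(
    monofocal = iol_design_spec("monofocal", name = "monofocal"),
    trifocal_217_325 = iol_design_spec("trifocal", c(2.17, 3.25),
                                       relative_peak_heights = c(1, 0.75, 0.85),
                                       name = "trifocal_217_325"),
    trifocal_175_350 = iol_design_spec("trifocal", c(1.75, 3.5),
                                       relative_peak_heights = c(1, 0.8, 0.9),
                                       name = "trifocal_175_350"),
    trifocal_166_333 = iol_design_spec("trifocal", c(1.66, 3.33),
                                       relative_peak_heights = c(1, 0.8, 0.85),
                                       name = "trifocal_166_333"),
    edof_175 = iol_design_spec("edof", 1.75, peak_widths = 0.35,
                               name = "edof_175"),
    edof_153 = iol_design_spec("edof", 1.53, peak_widths = 0.35,
                               name = "edof_153"),
    edof_190 = iol_design_spec("edof", 1.9, peak_widths = 0.35,
                               name = "edof_190")
  )
}

#' Generate a synthetic through-focus MTF curve from a design spec
#'
#' Deterministic profile on the IOL-plane defocus axis (0 at the far
#' focus, additions appearing at negative defocus): a sum of Gaussian
#' focal peaks for monofocal/trifocal designs, or a unit plateau with
#' Gaussian shoulders for EDOFs, scaled so the maximum equals the spec's
#' `peak_mtf`. The monofocal profile uses the diffraction-limited defocus
#' MTF shape itself rather than a Gaussian.
#'
#' @param spec an `"iol_design"`.
#' @param grid defocus grid in diopters (default -6 to +2.5 D, 0.05 D
#'   step: wide enough for the smoothing filter's support requirement).
#' @param nu,pupil_mm spatial frequency and pupil of the simulated bench
#'   measurement.
#' @return A `"tfmtf"` object (`wavelength = "white"`).
#' @export
make_synthetic_tfmtf <- function(spec, grid = seq(-6, 2.5, by = 0.05),
                                 nu = 15, pupil_mm = 3) {
  stopifnot(inherits(spec, "iol_design"))
  gauss <- function(x, mu, s) exp(-0.5 * ((x - mu) / s)^2)
  s <- spec$peak_widths[1]
  vals <- switch(spec$design,
    monofocal = pmax(defocus_otf(grid, nu, pupil_mm, 555), 0),
    trifocal = {
      mu <- c(0, -spec$add_powers)
      h <- rep_len(spec$relative_peak_heights, length(mu))
      Reduce(`+`, Map(function(m, hh) hh * gauss(grid, m, s), mu, h))
    },
    edof = {
      ext <- spec$plateau_extent
      ifelse(grid <= 0 & grid >= -ext, 1,
             ifelse(grid > 0, gauss(grid, 0, s), gauss(grid, -ext, s)))
    })
  vals <- vals / max(vals) * spec$peak_mtf
  tfmtf_curve(grid, vals, nu = nu, pupil_mm = pupil_mm, wavelength = "white")
}

#' Synthetic cohort specification
#'
#' @param n_subjects number of subjects (default 15, one session's worth).
#' @param vergence_grid vergence levels in diopters (default +1.00 to
#'   -4.00 D in 0.50 D steps).
#' @param residual_sd independent measurement noise per point, logMAR
#'   (default 0.11, the intersubject variability scale of simulated-lens
#'   acuity).
#' @param intercept_sd per-subject additive intercept SD in logMAR.
#' @param seed mandatory integer seed.
#' @return Object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_subjects = 15,
                        vergence_grid = seq(1, -4, by = -0.5),
                        residual_sd = 0.11, intercept_sd = 0.05, seed) {
  if (missing(seed)) stop("`seed` is mandatory for reproducibility",
                          call. = FALSE)
  stopifnot(n_subjects >= 1, residual_sd >= 0, intercept_sd >= 0)
  structure(list(n_subjects = n_subjects, vergence_grid = vergence_grid,
                 residual_sd = residual_sd, intercept_sd = intercept_sd,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Affine map of a TFVS curve onto a plausible logMAR template:
# peak visual Strehl -> -0.1 logMAR, zero -> +0.8 logMAR.
tfvs_to_logmar_template <- function(tfvs, vergence_grid,
                                    logmar_range = c(-0.1, 0.8)) {
  vs <- resample_curve(tfvs$defocus, tfvs$value, vergence_grid, fill = 0)
  vs <- vs / max(tfvs$value)
  logmar_range[2] - (logmar_range[2] - logmar_range[1]) * vs
}

#' Generate a synthetic subject cohort of defocus curves
#'
#' Each subject's curve for a lens is the lens's deterministic template (a
#' monotone affine map of its TFVS onto the logMAR range -0.1 to 0.8) plus
#' a subject-specific random intercept and independent Gaussian
#' measurement noise. Regeneration with the same spec is bit-identical.
#'
#' @param spec a [cohort_spec()].
#' @param lens_profiles named list of `"tfvs"` objects, one per lens.
#' @param groups optional named character vector mapping lens name to
#'   design group (`"trifocal"`, `"EDOF"`, `"monofocal"`).
#' @param sessions optional named vector mapping lens name to session.
#' @return Data frame with columns `subject_id`, `lens`, `group`,
#'   `session`, `vergence_D`, `logmar`.
#' @export
make_synthetic_cohort <- function(spec, lens_profiles, groups = NULL,
                                  sessions = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), length(lens_profiles) > 0)
  lens_names <- names(lens_profiles)
  if (is.null(lens_names)) stop("`lens_profiles` must be named", call. = FALSE)
  set.seed(spec$seed)
  templates <- lapply(lens_profiles, tfvs_to_logmar_template,
                      vergence_grid = spec$vergence_grid)
  intercepts <- stats::rnorm(spec$n_subjects, 0, spec$intercept_sd)
  out <- list()
  for (si in seq_len(spec$n_subjects)) {
    for (ln in lens_names) {
      noise <- stats::rnorm(length(spec$vergence_grid), 0, spec$residual_sd)
      out[[length(out) + 1L]] <- data.frame(
        subject_id = sprintf("S%02d", si),
        lens = ln,
        group = if (!is.null(groups)) unname(groups[ln]) else NA_character_,
        session = if (!is.null(sessions)) unname(sessions[ln]) else "I",
        vergence_D = spec$vergence_grid,
        logmar = templates[[ln]] + intercepts[si] + noise)
    }
  }
  df <- do.call(rbind, out)
  attr(df, "seed") <- spec$seed
  df
}

#' Generate a synthetic depth-of-focus gain table
#'
#' Metrics-level generator for exercising the gain-on-baseline mixed
#' model: each subject receives a baseline monofocal depth of focus and,
#' for each lens, a gain constructed from planted per-group slopes plus a
#' subject random intercept and residual noise:
#' `gain = intercept_g + slope_g * baseline + u_subject + session_shift + noise`.
#' Group intercepts are chosen so mean gains at the central baseline are
#' about +1.5 D (trifocal) and +0.7 D (EDOF).
#'
#' @param n_subjects number of subjects (default 15).
#' @param slopes named numeric: planted baseline slope per group.
#' @param baseline_range uniform range of baseline monofocal DOF in
#'   diopters.
#' @param mean_gains named numeric: mean gain per group at the central
#'   baseline.
#' @param subject_sd random-intercept SD (D).
#' @param residual_sd residual SD (D).
#' @param session_shift additive session-II effect (D, default 0).
#' @param seed mandatory integer seed.
#' @return Data frame suitable for [dof_gain_regression()].
#' @export
make_synthetic_dof_gains <- function(n_subjects = 15,
                                     slopes = c(trifocal = -0.96, EDOF = -0.57),
                                     baseline_range = c(1.0, 2.0),
                                     mean_gains = c(trifocal = 1.5, EDOF = 0.7),
                                     subject_sd = 0.15, residual_sd = 0.2,
                                     session_shift = 0, seed) {
  if (missing(seed)) stop("`seed` is mandatory", call. = FALSE)
  set.seed(as.integer(seed))
  lenses <- data.frame(
    lens = c("tri_a", "tri_b", "tri_c", "edof_a", "edof_b", "edof_c"),
    group = rep(c("trifocal", "EDOF"), each = 3),
    session = c("I", "I", "II", "I", "II", "II"))
  base_mid <- mean(baseline_range)
  intercepts <- mean_gains - slopes * base_mid
  baseline <- stats::runif(n_subjects, baseline_range[1], baseline_range[2])
  u <- stats::rnorm(n_subjects, 0, subject_sd)
  out <- list()
  for (si in seq_len(n_subjects)) {
    for (li in seq_len(nrow(lenses))) {
      g <- lenses$group[li]
      gain <- intercepts[[g]] + slopes[[g]] * baseline[si] + u[si] +
        session_shift * (lenses$session[li] == "II") +
        stats::rnorm(1, 0, residual_sd)
      out[[length(out) + 1L]] <- data.frame(
        subject_id = sprintf("S%02d", si), lens = lenses$lens[li],
        group = g, session = lenses$session[li],
        baseline_dof = baseline[si], dof = baseline[si] + gain, gain = gain)
    }
  }
  do.call(rbind, out)
}
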