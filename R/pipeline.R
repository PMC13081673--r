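#' Program a simulated lens from through-focus MTF data
#'
#' The full lens-programming workflow: per-wavelength normalization by the
#' diffraction limit, polychromatic weighting, zero-phase smoothing to the
#' estimated TFVS, plane conversion, temporal-coefficient solving,
#' reconstruction of the multiplexed TFVS, and simulated high-speed
#' focimetry validation. Validation metrics are computed on
#' peak-normalized curves over the defocus window spanned by the addition
#' grid.
#'
#' @param curves list of `"tfmtf"` objects (one per wavelength, or a
#'   single broadband curve).
#' @param kernel monofocal kernel (default [monofocal_vs_kernel()]).
#' @param spec filter specification (default [filter_spec()]).
#' @param addition_grid candidate additions in diopters.
#' @param plane_factor defocus scale factor for the entrance-pupil
#'   conversion (default 1).
#' @param resample_step uniform grid step in diopters.
#' @param prune_fraction,rmse_tol_frac solver tuning, see
#'   [solve_temporal_coefficients()].
#' @param time_constant_ms lens time constant for the focimetry
#'   simulation.
#' @param thresholds validation bounds: list with `min_correlation`,
#'   `max_rmse`, `max_peak_shift_D`, `max_focimeter_rmse`.
#' @return List of class `"lens_program"`: `tfvs` (estimated), `profile`,
#'   `reconstruction`, `focimetry`, `agreement` (estimated vs
#'   reconstructed, peak-normalized), `focimetry_agreement` (nominal vs
#'   dynamics-affected), `valid` (logical), `window` (defocus window used).
#' @export
program_lens <- function(curves, kernel = monofocal_vs_kernel(),
                         spec = filter_spec(),
                         addition_grid = seq(-0.5, 4.5, by = 0.05),
                         plane_factor = 1, resample_step = 0.05,
                         prune_fraction = 0.01, rmse_tol_frac = 0.01,
                         time_constant_ms = 1,
                         thresholds = validation_thresholds()) {
  if (inherits(curves, "tfmtf")) curves <- list(curves)
  normed <- lapply(curves, normalize_tfmtf)
  poly <- polychromatic_average(normed, step = resample_step)
  tfvs <- smooth_to_tfvs(poly, spec = spec, resample_step = resample_step)
  tfvs <- convert_plane(tfvs, plane_factor)
  window <- c(-(max(addition_grid) + 0.25), -(min(addition_grid) - 0.25))
  sel <- tfvs$defocus >= window[1] & tfvs$defocus <= window[2]
  target <- tfvs_curve(tfvs$defocus[sel], tfvs$value[sel], plane = tfvs$plane)
  profile <- solve_temporal_coefficients(
    target, kernel, addition_grid = addition_grid,
    prune_fraction = prune_fraction, rmse_tol_frac = rmse_tol_frac)
  recon <- reconstruct_tfvs(profile, kernel, target$defocus, scale = "dwell")
  agr <- compare_curves(peak_normalize(target), peak_normalize(recon))
  foci <- simulate_focimeter(profile, kernel, target$defocus,
                             time_constant_ms = time_constant_ms)
  foci_agr <- compare_curves(peak_normalize(recon), peak_normalize(foci))
  valid <- agr$cross_correlation >= thresholds$min_correlation &&
    agr$rmse <= thresholds$max_rmse &&
    (is.na(foci_agr$peak_shift) ||
       foci_agr$peak_shift < thresholds$max_peak_shift_D) &&
    foci_agr$rmse < thresholds$max_focimeter_rmse
  structure(list(tfvs = target, profile = profile, reconstruction = recon,
                 focimetry = foci, agreement = agr,
                 focimetry_agreement = foci_agr, valid = valid,
                 window = window),
            class = "lens_program")
}

#' Default validation thresholds for programmed lenses
#'
#' Reconstruction must reach cross-correlation 0.982 and RMSE 0.040
#' against the estimated TFVS; the focimetry validation must keep peaks
#' within 0.2 D and RMSE below 0.05.
#'
#' @param min_correlation,max_rmse,max_peak_shift_D,max_focimeter_rmse
#'   numeric bounds.
#' @return Named list.
#' @export
validation_thresholds <- function(min_correlation = 0.982, max_rmse = 0.040,
                                  max_peak_shift_D = 0.2,
                                  max_focimeter_rmse = 0.05) {
  list(min_correlation = min_correlation, max_rmse = max_rmse,
       max_peak_shift_D = max_peak_shift_D,
       max_focimeter_rmse = max_focimeter_rmse)
}

#' @export
print.lens_program <- function(x, ...) {
  cat(sprintf("<lens_program> %d temporal coefficients, %s\n",
              length(x$profile$additions),
              if (x$valid) "validation PASSED" else "validation FAILED"))
  cat(sprintf("  reconstruction: r = %.4f, RMSE = %.4f\n",
              x$agreement$cross_correlation, x$agreement$rmse))
  cat(sprintf("  focimetry:      RMSE = %.4f, peak shift = %s D\n",
              x$focimetry_agreement$rmse,
              ifelse(is.na(x$focimetry_agreement$peak_shift), "NA",
                     sprintf("%.3f", x$focimetry_agreement$peak_shift))))
  invisible(x)
}

#' Run the lens-programming workflow from a configuration
#'
#' Thin orchestration over [program_lens()]: reads TF-MTF CSVs, writes the
#' profile JSON, an agreement report, a TFVS overlay plot and a run
#' manifest to `out_dir`.
#'
#' @param config named list (or path to a YAML file) with at least
#'   `tfmtf_csv`; optional keys `pupil_mm`, `nu_cpd`, `resample_step_D`,
#'   `plane_factor`, `addition_min_D`, `addition_max_D`, `prune_fraction`,
#'   `rmse_tol_frac`, `time_constant_ms`, and the threshold names of
#'   [validation_thresholds()].
#' @param out_dir output directory (created if missing).
#' @return The `"lens_program"` result, invisibly.
#' @export
run_program_lens <- function(config, out_dir = "iolsim_out") {
  cfg <- load_config(config)
  if (is.null(cfg$tfmtf_csv)) stop("config needs `tfmtf_csv`", call. = FALSE)
  if (!file.exists(cfg$tfmtf_csv)) {
    stop("TF-MTF CSV not found: ", cfg$tfmtf_csv, call. = FALSE)
  }
  get <- function(key, default) if (is.null(cfg[[key]])) default else cfg[[key]]
  curves <- read_tfmtf_csv(cfg$tfmtf_csv, nu = get("nu_cpd", 15),
                           pupil_mm = get("pupil_mm", 3))
  th <- validation_thresholds(
    min_correlation = get("min_correlation", 0.982),
    max_rmse = get("max_rmse", 0.040),
    max_peak_shift_D = get("max_peak_shift_D", 0.2),
    max_focimeter_rmse = get("max_focimeter_rmse", 0.05))
  res <- program_lens(
    curves,
    spec = filter_spec(),
    addition_grid = seq(get("addition_min_D", -0.5),
                        get("addition_max_D", 4.5), by = 0.05),
    plane_factor = get("plane_factor", 1),
    resample_step = get("resample_step_D", 0.05),
    prune_fraction = get("prune_fraction", 0.01),
    rmse_tol_frac = get("rmse_tol_frac", 0.01),
    time_constant_ms = get("time_constant_ms", 1),
    thresholds = th)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_profile_json(res$profile, file.path(out_dir, "profile.json"),
                     meta = list(source = cfg$tfmtf_csv))
  jsonlite::write_json(
    list(agreement = unclass(res$agreement),
         focimetry = unclass(res$focimetry_agreement),
         n_coefficients = length(res$profile$additions),
         valid = res$valid),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(cfg, out_dir)
  p <- plot_lens_program(res)
  ggplot2::ggsave(file.path(out_dir, "tfvs_overlay.pdf"), p,
                  width = 7, height = 4.5)
  if (!res$valid) {
    warning("lens validation thresholds not met", call. = FALSE)
  }
  invisible(res)
}

#' Analyze defocus visual acuity curves
#'
#' Per-lens analysis of measured (or simulated-subject) DFVA curves
#' against reference curves: RMSE-minimizing offset, agreement metrics,
#' depth of focus and benefit triples, plus cohort statistics when
#' subject-level data are present.
#'
#' @param config named list or YAML path with `dfva_csv` (subject-level
#'   curves; subject `"mean"` entries are treated as group averages),
#'   optional `reference_csv` (same format, one curve per lens),
#'   `monofocal_lens` (label of the monofocal reference condition), and
#'   `dof_range_trifocal` / `dof_range_edof` window bounds.
#' @param out_dir output directory.
#' @return List with per-lens metrics and, when available, cohort
#'   statistics; invisibly.
#' @export
run_analyze_dfva <- function(config, out_dir = "iolsim_out") {
  cfg <- load_config(config)
  if (is.null(cfg$dfva_csv)) stop("config needs `dfva_csv`", call. = FALSE)
  curves <- read_dfva_csv(cfg$dfva_csv)
  labels <- vapply(curves, `[[`, character(1), "label")
  subjects <- vapply(curves, `[[`, character(1), "subject_id")
  mono_label <- if (is.null(cfg$monofocal_lens)) "monofocal" else cfg$monofocal_lens
  refs <- if (!is.null(cfg$reference_csv)) read_dfva_csv(cfg$reference_csv)
  per_lens <- list()
  for (ln in unique(labels)) {
    sel <- which(labels == ln)
    mean_curve <- average_dfva(curves[sel], label = ln)
    entry <- list(lens = ln, n_subjects = length(sel))
    rng <- if (grepl("tri", ln, ignore.case = TRUE)) {
      c(if (is.null(cfg$dof_range_trifocal)) -4 else cfg$dof_range_trifocal, 0)
    } else {
      c(if (is.null(cfg$dof_range_edof)) -3 else cfg$dof_range_edof, 0)
    }
    entry$dof <- compute_dof(mean_curve, range_limits = sort(rng))
    if (!is.null(refs)) {
      ref_labels <- vapply(refs, `[[`, character(1), "label")
      ri <- which(ref_labels == ln)
      if (length(ri) == 1L) {
        cmp <- compare_to_reference(mean_curve, refs[[ri]])
        entry$offset <- cmp$offset
        entry$agreement <- unclass(cmp$agreement)
        entry$differences <- cmp$differences
      }
    }
    if (ln != mono_label && mono_label %in% labels) {
      mono_curve <- average_dfva(curves[labels == mono_label],
                                 label = mono_label)
      has <- all(vapply(c(0, -1.5, -2.5), function(v) {
        any(abs(mean_curve$vergence - v) < 1e-6) &&
          any(abs(mono_curve$vergence - v) < 1e-6)
      }, logical(1)))
      if (has) {
        entry$benefit <- unclass(visual_benefit(mono_curve, mean_curve))
      } else {
        warning(sprintf("lens '%s': benefit vergences missing, skipped", ln),
                call. = FALSE)
      }
    }
    per_lens[[ln]] <- entry
  }
  out <- list(per_lens = per_lens)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(out, file.path(out_dir, "dfva_metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(cfg, out_dir)
  invisible(out)
}

# Pointwise mean of several DFVA curves on their common grid.
average_dfva <- function(curves, label) {
  if (length(curves) == 1L) return(curves[[1]])
  grids <- lapply(curves, function(cv) round(cv$vergence, 6))
  common <- Reduce(intersect, grids)
  common <- sort(common, decreasing = TRUE)
  mat <- vapply(curves, function(cv) {
    cv$logmar[match(common, round(cv$vergence, 6))]
  }, numeric(length(common)))
  dfva_curve(common, rowMeans(mat), label = label, subject_id = "mean")
}

#' Overlay plot of estimated, reconstructed and focimetry TFVS
#'
#' @param program a `"lens_program"` result.
#' @return A ggplot object (peak-normalized curves vs defocus).
#' @export
plot_lens_program <- function(program) {
  pn <- function(cv, what) {
    data.frame(defocus_D = cv$defocus, tfvs = cv$value / max(cv$value),
               curve = what)
  }
  df <- rbind(pn(program$tfvs, "estimated"),
              pn(program$reconstruction, "multiplexed"),
              pn(program$focimetry, "focimetry"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$defocus_D, y = .data$tfvs,
                                   color = .data$curve,
                                   linetype = .data$curve)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::labs(x = "Defocus (D)", y = "TFVS (peak-normalized)",
                  color = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config,
                                   call. = FALSE)
    cfg <- yaml::read_yaml(config)
    cfg$`__config_path` <- config
    cfg
  } else if (is.list(config)) {
    config
  } else {
    stop("`config` must be a list or a YAML path", call. = FALSE)
  }
}

write_manifest <- function(cfg, out_dir) {
  inputs <- unlist(cfg[vapply(cfg, function(x)
    is.character(x) && length(x) == 1L && file.exists(x), logical(1))])
  manifest <- list(
    package_version = as.character(utils::packageVersion("iolsim")),
    r_version = R.version.string,
    config = cfg[setdiff(names(cfg), "__config_path")],
    input_md5 = as.list(tools::md5sum(inputs)),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
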