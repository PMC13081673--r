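#' Read through-focus MTF curves from CSV
#'
#' Expected header: `defocus_D,value[,wavelength_nm]`. Without a
#' wavelength column one `"white"` curve is returned; with it, one curve
#' per wavelength.
#'
#' @param path CSV file path.
#' @param nu,pupil_mm measurement parameters attached to the curves.
#' @return List of `"tfmtf"` objects.
#' @export
read_tfmtf_csv <- function(path, nu = 15, pupil_mm = 3) {
  df <- utils::read.csv(path)
  if (!all(c("defocus_D", "value") %in% names(df))) {
    stop("TF-MTF CSV needs columns `defocus_D,value[,wavelength_nm]`",
         call. = FALSE)
  }
  if ("wavelength_nm" %in% names(df)) {
    lapply(split(df, df$wavelength_nm), function(d) {
      d <- d[order(d$defocus_D), ]
      tfmtf_curve(d$defocus_D, d$value, nu = nu, pupil_mm = pupil_mm,
                  wavelength = d$wavelength_nm[1])
    })
  } else {
    df <- df[order(df$defocus_D), ]
    list(tfmtf_curve(df$defocus_D, df$value, nu = nu, pupil_mm = pupil_mm,
                     wavelength = "white"))
  }
}

#' Write a TFVS curve to CSV (`defocus_D,vs`)
#'
#' @param curve a `"tfvs"` object.
#' @param path output path.
#' @export
write_tfvs_csv <- function(curve, path) {
  utils::write.csv(data.frame(defocus_D = curve$defocus, vs = curve$value),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read defocus visual acuity curves from CSV
#'
#' Expected header: `subject_id,lens,vergence_D,logmar`. Returns one
#' `"dfva"` curve per subject-lens combination (use subject_id `"mean"`
#' or similar for group averages).
#'
#' @param path CSV file path.
#' @return List of `"dfva"` objects.
#' @export
read_dfva_csv <- function(path) {
  df <- utils::read.csv(path)
  req <- c("subject_id", "lens", "vergence_D", "logmar")
  if (!all(req %in% names(df))) {
    stop("DFVA CSV needs columns `subject_id,lens,vergence_D,logmar`",
         call. = FALSE)
  }
  parts <- split(df, interaction(df$subject_id, df$lens, drop = TRUE))
  lapply(parts, function(d) {
    dfva_curve(d$vergence_D, d$logmar, label = d$lens[1],
               subject_id = d$subject_id[1])
  })
}

#' Write a temporal profile to JSON
#'
#' Serializes the profile in the interchange form
#' `{"cycle_ms": 20, "rate_hz": 50, "states": [{"addition_D": ...,
#' "dwell_fraction": ...}, ...], "meta": {...}}`.
#'
#' @param profile a `"temporal_profile"`.
#' @param path output path.
#' @param meta optional named list stored under `"meta"`.
#' @export
write_profile_json <- function(profile, path, meta = list()) {
  obj <- list(
    cycle_ms = profile$cycle_ms,
    rate_hz = profile$rate_hz,
    states = lapply(seq_along(profile$additions), function(i) {
      list(addition_D = profile$additions[i],
           dwell_fraction = profile$dwell_fractions[i])
    }),
    meta = c(meta, list(fitted_scale = profile$fitted_scale)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a temporal profile from JSON
#'
#' @param path JSON path written by [write_profile_json()].
#' @return A `"temporal_profile"`.
#' @export
read_profile_json <- function(path) {
  obj <- jsonlite::read_json(path)
  adds <- vapply(obj$states, function(s) s$addition_D, numeric(1))
  dw <- vapply(obj$states, function(s) s$dwell_fraction, numeric(1))
  fs <- obj$meta$fitted_scale
  temporal_profile(adds, dw / sum(dw), cycle_ms = obj$cycle_ms,
                   rate_hz = obj$rate_hz,
                   fitted_scale = if (is.null(fs)) 1 else fs)
}
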