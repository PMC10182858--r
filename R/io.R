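#' Write / read spectra in the long CSV dialect
#'
#' Columns: `distance_mm`, `wavelength_nm`, then either `od` or the raw
#' triple (`intensity`, `background`, `reference`).
#'
#' @param spectra list of [od_spectrum()] or [raw_measurement()] objects.
#' @param path CSV path.
#' @export
write_spectra_csv <- function(spectra, path) {
  if (!is.list(spectra) || inherits(spectra, c("od_spectrum",
                                               "raw_measurement")))
    spectra <- list(spectra)
  rows <- lapply(spectra, function(s) {
    if (inherits(s, "od_spectrum")) {
      data.frame(distance_mm = s$distance, wavelength_nm = s$wavelengths,
                 od = s$od)
    } else if (inherits(s, "raw_measurement")) {
      data.frame(distance_mm = s$distance, wavelength_nm = s$wavelengths,
                 intensity = s$intensity, background = s$background,
                 reference = s$reference)
    } else stop("unsupported spectrum object")
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectra_csv
#' @return `read_spectra_csv`: a list of [od_spectrum()]s (raw triples are
#'   converted through [compute_od()]).
#' @export
read_spectra_csv <- function(path) {
  tab <- read.csv(path)
  if (!all(c("distance_mm", "wavelength_nm") %in% names(tab)))
    stop("spectra CSV needs distance_mm and wavelength_nm columns")
  by_d <- split(tab, tab$distance_mm)
  lapply(unname(by_d), function(d) {
    d <- d[order(d$wavelength_nm), ]
    if ("od" %in% names(d)) {
      od_spectrum(d$wavelength_nm, d$od, d$distance_mm[1])
    } else if (all(c("intensity", "background", "reference") %in% names(d))) {
      compute_od(raw_measurement(d$wavelength_nm, d$intensity,
                                 d$background, d$reference,
                                 d$distance_mm[1]))
    } else stop("spectra CSV needs an od column or the raw intensity triple")
  })
}

#' Write amplitude fits to CSV
#'
#' Columns: `distance_mm`, `c0`, `c1`, `a_water`, `a_lipid`, `residual`.
#'
#' @param profile an `amplitude_profile` (see [profile_over_distances()]).
#' @param path CSV path.
#' @export
write_fits_csv <- function(profile, path) {
  out <- data.frame(distance_mm = profile$distance, c0 = profile$c0,
                    c1 = profile$c1, a_water = profile$a_water,
                    a_lipid = profile$a_lipid,
                    residual = profile$residual_norm)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write an evaluation report as JSON
#'
#' @param report an `evaluation_report` (or a list containing one plus
#'   provenance fields).
#' @param path JSON path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
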