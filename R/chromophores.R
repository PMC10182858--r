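#' Bundled pure-substance absorption spectrum
#'
#' Loads the bundled near-infrared absorption coefficient table for pure
#' water or pure lipid. The tables are smooth synthetic compilations
#' consistent with the standard literature values (see the provenance header
#' of each file under `inst/extdata`); the water band peaks at 975 nm and
#' the lipid band at 930 nm.
#'
#' @param name `"water"` or `"lipid"`.
#' @return An object of class `chromophore_spectrum` with fields `name`,
#'   `wavelengths` (nm, strictly increasing) and `mua_pure` (cm^-1).
#' @export
chromophore_spectrum <- function(name = c("water", "lipid")) {
  name <- match.arg(name)
  key <- paste0("chrom_", name)
  cached <- .dermaspec_cache[[key]]
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", paste0(name, "_mua_synthetic.tsv"),
                      package = "dermaspec", mustWork = TRUE)
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    col.names = c("wavelength_nm", "mua"))
  obj <- structure(
    list(name = name, wavelengths = tab$wavelength_nm, mua_pure = tab$mua),
    class = "chromophore_spectrum")
  validate_chromophore(obj)
  .dermaspec_cache[[key]] <- obj
  obj
}

validate_chromophore <- function(x) {
  stopifnot(inherits(x, "chromophore_spectrum"))
  if (any(diff(x$wavelengths) <= 0))
    stop("chromophore wavelength grid must be strictly increasing")
  if (any(!is.finite(x$mua_pure)) || any(x$mua_pure < 0))
    stop("chromophore absorption must be finite and non-negative")
  invisible(x)
}

#' Interpolated absorption coefficient of a pure substance
#'
#' Linear interpolation of the bundled table; exact at table nodes.
#'
#' @param spectrum a [chromophore_spectrum()].
#' @param wavelength wavelengths in nm, inside the table range.
#' @return absorption coefficient(s) in cm^-1.
#' @export
mua_at <- function(spectrum, wavelength) {
  validate_chromophore(spectrum)
  rng <- range(spectrum$wavelengths)
  if (any(wavelength < rng[1] | wavelength > rng[2]))
    stop(sprintf("wavelength outside table range [%g, %g] nm",
                 rng[1], rng[2]))
  approx(spectrum$wavelengths, spectrum$mua_pure, xout = wavelength,
         method = "linear")$y
}

#' Layer composition
#'
#' Volume fractions of the two NIR absorbers in a tissue layer.
#'
#' @param water_fraction,lipid_fraction volume fractions in \[0, 1\].
#' @export
layer_composition <- function(water_fraction = 0, lipid_fraction = 0) {
  if (water_fraction < 0 || water_fraction > 1 ||
      lipid_fraction < 0 || lipid_fraction > 1)
    stop("volume fractions must lie in [0, 1]")
  structure(list(water_fraction = water_fraction,
                 lipid_fraction = lipid_fraction),
            class = "layer_composition")
}

#' Absorption spectrum of a composed layer
#'
#' Linear volume-fraction mixing of the pure water and lipid absorption:
#' `mua(lambda) = W * mua_water(lambda) + F * mua_lipid(lambda)`. No other
#' chromophore contributes in the 900--1075 nm synthesis window (background
#' absorption enters only through the linear baseline at fit time).
#'
#' @param composition a [layer_composition()].
#' @param wavelengths nm, non-empty, inside both table ranges.
#' @return absorption coefficients, cm^-1.
#' @export
layer_mua_spectrum <- function(composition, wavelengths) {
  stopifnot(inherits(composition, "layer_composition"))
  if (length(wavelengths) == 0) stop("empty wavelength list")
  w <- composition$water_fraction
  f <- composition$lipid_fraction
  out <- numeric(length(wavelengths))
  if (w > 0) out <- out + w * mua_at(chromophore_spectrum("water"), wavelengths)
  if (f > 0) out <- out + f * mua_at(chromophore_spectrum("lipid"), wavelengths)
  out
}

#' Peak-normalized absorption shape
#'
#' The pure-substance absorption divided by its maximum over a wavelength
#' window, so that the returned shape has maximum 1 there. These are the
#' normalized spectra used as regressors in the spectral decomposition;
#' with this convention the fitted amplitudes are interpretable as the OD
#' contribution at the band peak.
#'
#' @param spectrum a [chromophore_spectrum()].
#' @param window length-2 numeric, nm; must intersect the table range.
#' @return object of class `chromophore_shape`; evaluate with [shape_at()].
#' @export
normalized_shape <- function(spectrum, window = c(900, 1075)) {
  validate_chromophore(spectrum)
  sel <- spectrum$wavelengths >= window[1] & spectrum$wavelengths <= window[2]
  if (!any(sel)) stop("window does not intersect the table range")
  peak <- max(spectrum$mua_pure[sel])
  if (peak <= 0) stop("spectrum is zero everywhere in the window")
  structure(
    list(name = spectrum$name,
         wavelengths = spectrum$wavelengths,
         shape = spectrum$mua_pure / peak,
         window = window,
         peak_mua = peak,
         normalization = "peak-normalized to 1 over the window"),
    class = "chromophore_shape")
}

#' Evaluate a normalized shape at arbitrary wavelengths
#'
#' @param shape a [normalized_shape()] object.
#' @param wavelength nm, within the underlying table range.
#' @export
shape_at <- function(shape, wavelength) {
  stopifnot(inherits(shape, "chromophore_shape"))
  rng <- range(shape$wavelengths)
  if (any(wavelength < rng[1] | wavelength > rng[2]))
    stop("wavelength outside table range")
  approx(shape$wavelengths, shape$shape, xout = wavelength)$y
}

# default fit shapes over the standard window, cached
default_shapes <- function(window = c(900, 1075)) {
  key <- paste0("shapes_", window[1], "_", window[2])
  cached <- .dermaspec_cache[[key]]
  if (!is.null(cached)) return(cached)
  sh <- list(water = normalized_shape(chromophore_spectrum("water"), window),
             lipid = normalized_shape(chromophore_spectrum("lipid"), window))
  .dermaspec_cache[[key]] <- sh
  sh
}
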