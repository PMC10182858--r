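#' Optical-density spectrum
#'
#' @param wavelengths nm, increasing.
#' @param od optical density values (dimensionless), finite or NA (masked).
#' @param distance source-detector separation, mm.
#' @param origin `"simulated"` or `"measured"`.
#' @export
od_spectrum <- function(wavelengths, od, distance, origin = "measured") {
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (length(od) != length(wavelengths)) stop("length mismatch")
  structure(list(wavelengths = wavelengths, od = od,
                 distance = distance, origin = origin),
            class = "od_spectrum")
}

#' Raw intensity measurement
#'
#' One acquisition at one source-detector distance: sample, background and
#' reference intensities on a shared wavelength grid.
#'
#' @param wavelengths nm.
#' @param intensity,background,reference counts.
#' @param distance mm.
#' @export
raw_measurement <- function(wavelengths, intensity, background, reference,
                            distance) {
  n <- length(wavelengths)
  if (length(intensity) != n || length(background) != n ||
      length(reference) != n)
    stop("intensity, background and reference must match the wavelength grid")
  structure(list(wavelengths = wavelengths, intensity = intensity,
                 background = background, reference = reference,
                 distance = distance),
            class = "raw_measurement")
}

#' Optical density from raw intensities
#'
#' `OD(lambda) = -ln((I - Ibg) / (Iref - Ibg))`. Wavelengths where the net
#' sample intensity is non-positive are masked (NA) with a warning rather
#' than crashing; a non-positive net reference is an error.
#'
#' @param m a [raw_measurement()].
#' @return an [od_spectrum()].
#' @export
compute_od <- function(m) {
  stopifnot(inherits(m, "raw_measurement"))
  ref <- m$reference - m$background
  if (any(ref <= 0))
    stop("reference minus background must be positive everywhere")
  net <- m$intensity - m$background
  bad <- net <= 0
  od <- rep(NA_real_, length(net))
  od[!bad] <- -log(net[!bad] / ref[!bad])
  if (any(bad))
    warning(sprintf("%d wavelength(s) with non-positive net intensity masked",
                    sum(bad)))
  od_spectrum(m$wavelengths, od, m$distance, origin = "measured")
}

# build the (1, lambda, eps_water, eps_lipid) design over a window
fit_design <- function(wavelengths, shapes, window) {
  sel <- wavelengths >= window[1] & wavelengths <= window[2]
  wl <- wavelengths[sel]
  X <- cbind(intercept = 1, lambda = wl,
             eps_water = shape_at(shapes$water, wl),
             eps_lipid = shape_at(shapes$lipid, wl))
  list(X = X, sel = sel, wl = wl)
}

#' Decompose an OD spectrum into baseline + water + lipid
#'
#' Ordinary (unconstrained) least squares of OD on the design
#' `(1, lambda, eps_water(lambda), eps_lipid(lambda))` over the fit window.
#' The linear baseline absorbs residual background absorption and the
#' wavelength dependence of scattering; `a_water` and `a_lipid` are the OD
#' contributions at the respective band peaks (the shapes are
#' peak-normalized). Negative amplitudes are reported, not clipped. Masked
#' (NA) wavelengths are dropped from the design.
#'
#' @param od an [od_spectrum()].
#' @param shapes list with `water` and `lipid` [normalized_shape()]s;
#'   defaults to the bundled chromophores over the window.
#' @param window fit window, nm.
#' @return object of class `component_fit` with `c0`, `c1`, `a_water`,
#'   `a_lipid`, `residual_norm`, `window`, `distance`.
#' @export
fit_components <- function(od, shapes = NULL, window = c(900, 1075)) {
  stopifnot(inherits(od, "od_spectrum"))
  if (is.null(shapes)) shapes <- default_shapes(window)
  d <- fit_design(od$wavelengths, shapes, window)
  y <- od$od[d$sel]
  keep <- is.finite(y)
  X <- d$X[keep, , drop = FALSE]
  y <- y[keep]
  if (length(y) < 4)
    stop("need at least 4 usable wavelengths in the fit window")
  qrX <- qr(X)
  if (qrX$rank < 4) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):4]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qrX, y)
  res <- y - X %*% beta
  structure(list(c0 = unname(beta[1]), c1 = unname(beta[2]),
                 a_water = unname(beta[3]), a_lipid = unname(beta[4]),
                 residual_norm = sqrt(sum(res^2)),
                 n_points = length(y),
                 window = window, distance = od$distance),
            class = "component_fit")
}

#' @export
print.component_fit <- function(x, ...) {
  cat(sprintf(
    "<component_fit> r=%.2g mm | c0=%.4g c1=%.4g a_water=%.4g a_lipid=%.4g (resid %.3g)\n",
    x$distance, x$c0, x$c1, x$a_water, x$a_lipid, x$residual_norm))
  invisible(x)
}

#' Amplitude profile over source-detector distances
#'
#' Fits every spectrum and assembles the water/lipid amplitudes as functions
#' of distance -- the feature set for all inversions.
#'
#' @param spectra list of [od_spectrum()]s with distinct distances.
#' @inheritParams fit_components
#' @return data.frame of class `amplitude_profile`: columns `distance`,
#'   `c0`, `c1`, `a_water`, `a_lipid`, `residual_norm`, ordered by distance.
#' @export
profile_over_distances <- function(spectra, shapes = NULL,
                                   window = c(900, 1075)) {
  if (inherits(spectra, "od_spectrum")) spectra <- list(spectra)
  dists <- vapply(spectra, function(s) s$distance, 1)
  if (anyDuplicated(dists)) stop("duplicate distances in spectra")
  ord <- order(dists)
  rows <- lapply(spectra[ord], function(s) {
    f <- fit_components(s, shapes, window)
    data.frame(distance = f$distance, c0 = f$c0, c1 = f$c1,
               a_water = f$a_water, a_lipid = f$a_lipid,
               residual_norm = f$residual_norm)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("amplitude_profile", "data.frame")
  out
}

# Vectorized decomposition of an OD array (model x wavelength x distance)
# sharing one wavelength grid: returns list(a_water, a_lipid, c0, c1,
# residual_norm) each (model x distance). Used by the fixture generators.
fit_components_array <- function(od_array, wavelengths, shapes = NULL,
                                 window = c(900, 1075)) {
  if (is.null(shapes)) shapes <- default_shapes(window)
  d <- fit_design(wavelengths, shapes, window)
  nm <- dim(od_array)[1]; nd <- dim(od_array)[3]
  Y <- matrix(aperm(od_array[, d$sel, , drop = FALSE], c(2, 1, 3)),
              nrow = sum(d$sel))
  qrX <- qr(d$X)
  if (qrX$rank < 4) stop("rank-deficient design")
  B <- qr.coef(qrX, Y)                     # 4 x (nm*nd)
  res <- sqrt(colSums((Y - d$X %*% B)^2))
  shape_out <- function(v) matrix(v, nm, nd)
  list(c0 = shape_out(B[1, ]), c1 = shape_out(B[2, ]),
       a_water = shape_out(B[3, ]), a_lipid = shape_out(B[4, ]),
       residual_norm = shape_out(res))
}
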