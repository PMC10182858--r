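#' Optical layer
#'
#' One plane-parallel tissue layer. Public units: thickness in mm, optical
#' coefficients in cm^-1 (the engine converts internally).
#'
#' @param thickness mm, finite and positive.
#' @param mua absorption coefficient, cm^-1, >= 0.
#' @param mus scattering coefficient, cm^-1, > 0.
#' @param g scattering anisotropy, in (-1, 1).
#' @param n refractive index, >= 1. Typical soft tissue: 1.4.
#' @export
optical_layer <- function(thickness, mua, mus, g = 0.9, n = 1.4) {
  if (!is.finite(thickness) || thickness <= 0) stop("thickness must be > 0")
  if (!is.finite(mua) || mua < 0) stop("mua must be >= 0")
  if (!is.finite(mus) || mus <= 0) stop("mus must be > 0")
  if (g <= -1 || g >= 1) stop("g must lie in (-1, 1)")
  if (n < 1) stop("n must be >= 1")
  structure(list(thickness = thickness, mua = mua, mus = mus, g = g, n = n),
            class = "optical_layer")
}

#' Layered medium
#'
#' Ordered stack of [optical_layer()]s, top to bottom, with ambient
#' refractive indices. The default ambient indices (1.0 above, matched to
#' the bottom layer below) reflect skin measured in air over deep tissue.
#'
#' @param layers list of [optical_layer()].
#' @param ambient_n_above,ambient_n_below ambient refractive indices.
#' @export
layer_stack <- function(layers, ambient_n_above = 1.0,
                        ambient_n_below = NULL) {
  if (length(layers) < 1) stop("at least one layer required")
  lapply(layers, function(l) stopifnot(inherits(l, "optical_layer")))
  if (is.null(ambient_n_below))
    ambient_n_below <- layers[[length(layers)]]$n
  structure(list(layers = layers,
                 ambient_n_above = ambient_n_above,
                 ambient_n_below = ambient_n_below),
            class = "layer_stack")
}

#' Three-layer skin stack with the standard scattering parameters
#'
#' Dermis (mus = 200 cm^-1), hypodermis (100 cm^-1) and muscle (90 cm^-1,
#' 5 mm thick), g = 0.9 and n = 1.4 everywhere; absorption per layer is
#' supplied by the caller (typically from [layer_mua_spectrum()] at one
#' wavelength).
#'
#' @param mua length-3 absorption triple (dermis, hypodermis, muscle), cm^-1.
#' @param d_dermis,d_hypodermis,d_muscle layer thicknesses, mm.
#' @param mus,g,n per-layer scattering parameters (recycled if scalar).
#' @export
skin_stack <- function(mua, d_dermis, d_hypodermis, d_muscle = 5,
                       mus = c(200, 100, 90), g = 0.9, n = 1.4) {
  stopifnot(length(mua) == 3)
  g <- rep_len(g, 3); n <- rep_len(n, 3); mus <- rep_len(mus, 3)
  th <- c(d_dermis, d_hypodermis, d_muscle)
  layer_stack(lapply(1:3, function(i)
    optical_layer(th[i], mua[i], mus[i], g[i], n[i])))
}

#' Transport configuration
#'
#' @param n_photons number of photon packets (>= 1).
#' @param radial_bin_width annulus width for radial scoring, mm.
#' @param max_radius outer scoring radius, mm; weight escaping beyond it is
#'   tracked in an overflow bucket so the energy budget still closes.
#' @param roulette_threshold,roulette_survival Russian-roulette parameters.
#' @param seed RNG seed (integer); every run is reproducible given the seed.
#' @export
transport_config <- function(n_photons = 2e5, radial_bin_width = 0.05,
                             max_radius = 15, roulette_threshold = 1e-4,
                             roulette_survival = 0.1, seed = 1) {
  if (n_photons < 1) stop("n_photons must be >= 1")
  if (radial_bin_width <= 0) stop("radial_bin_width must be > 0")
  if (roulette_survival <= 0 || roulette_survival >= 1)
    stop("roulette_survival must lie in (0, 1)")
  structure(list(n_photons = as.integer(n_photons),
                 radial_bin_width = radial_bin_width,
                 max_radius = max_radius,
                 roulette_threshold = roulette_threshold,
                 roulette_survival = roulette_survival,
                 seed = as.integer(seed)),
            class = "transport_config")
}

stack_params <- function(stack) {
  list(thickness_cm = vapply(stack$layers, function(l) l$thickness, 1) / 10,
       mua = vapply(stack$layers, function(l) l$mua, 1),
       mus = vapply(stack$layers, function(l) l$mus, 1),
       g = vapply(stack$layers, function(l) l$g, 1),
       n = vapply(stack$layers, function(l) l$n, 1))
}

run_engine <- function(stack, config, record_paths = FALSE,
                       vis = FALSE, det_dist = 0, det_radius = 0,
                       vis_dr = 0.1, vis_dz = 0.05) {
  stopifnot(inherits(stack, "layer_stack"),
            inherits(config, "transport_config"))
  p <- stack_params(stack)
  withr::with_seed(config$seed,
    cpp_transport(p$thickness_cm, p$mua, p$mus, p$g, p$n,
                  stack$ambient_n_above, stack$ambient_n_below,
                  config$n_photons,
                  config$radial_bin_width / 10, config$max_radius / 10,
                  config$roulette_threshold, config$roulette_survival,
                  record_paths, vis,
                  det_dist / 10, det_radius / 10, vis_dr / 10, vis_dz / 10))
}

as_radial_reflectance <- function(raw, config, seed) {
  nb <- length(raw$bins)
  structure(list(
    annulus_edges = seq(0, by = config$radial_bin_width, length.out = nb + 1),
    diffuse_per_annulus = raw$bins,
    overflow = raw$overflow,
    specular = raw$specular,
    diffuse_total = raw$diffuse_total,
    absorbed = raw$absorbed,
    transmitted = raw$transmitted,
    n_photons = config$n_photons,
    seed = seed), class = "radial_reflectance")
}

#' Simulate radially resolved diffuse reflectance
#'
#' Standard layered-media photon-packet walk: pencil beam normally incident
#' at the origin, specular split at entry, Henyey-Greenstein scattering,
#' implicit-capture weight deposition, Fresnel reflection/refraction at
#' every index-mismatched interface, Russian roulette, and scoring of the
#' escaping top-hemisphere weight by exit annulus over all exit angles
#' (2 pi collection).
#'
#' @param stack a [layer_stack()].
#' @param config a [transport_config()].
#' @return object of class `radial_reflectance`: per-annulus escaped weight
#'   fraction plus the full energy budget (specular, diffuse, absorbed,
#'   transmitted, all as fractions of launched weight).
#' @export
simulate_transport <- function(stack, config = transport_config()) {
  raw <- run_engine(stack, config)
  as_radial_reflectance(raw, config, config$seed)
}

#' Scattering-only transport with per-photon pathlength records
#'
#' White Monte Carlo: runs the stack with all absorption forced to zero and
#' records, per escaping photon, the exit radius, exit hemisphere and the
#' pathlength traveled in every layer. [rescale_absorption()] then gives the
#' reflectance for any absorption triple by Beer-Lambert reweighting --
#' exact when the scattering coefficients are fixed.
#'
#' @inheritParams simulate_transport
#' @return object of class `pathlength_records`.
#' @export
simulate_pathlengths <- function(stack, config = transport_config()) {
  p <- stack_params(stack)
  if (any(p$mua != 0)) {
    stack$layers <- lapply(stack$layers, function(l) { l$mua <- 0; l })
    p <- stack_params(stack)
  }
  raw <- run_engine(stack, config, record_paths = TRUE)
  structure(list(
    exit_radius = raw$path_radius * 10,          # mm
    hemisphere = ifelse(raw$path_hemisphere == 0, "top", "bottom"),
    weight = raw$path_weight,
    pathlengths = raw$path_lengths,              # cm, one column per layer
    specular = raw$specular,
    n_photons = config$n_photons,
    config = config,
    geometry = list(thickness = vapply(stack$layers,
                                       function(l) l$thickness, 1),
                    mus = p$mus, g = p$g, n = p$n,
                    ambient_n_above = stack$ambient_n_above,
                    ambient_n_below = stack$ambient_n_below)),
    class = "pathlength_records")
}

#' Beer-Lambert reweighting of pathlength records
#'
#' Reweights every recorded photon by `exp(-sum_i mua_i * L_i)` and rebins,
#' reproducing a direct simulation at the given absorption triple on the
#' same geometry (same thicknesses, scattering and boundaries).
#'
#' @param records a [simulate_pathlengths()] result.
#' @param mua one absorption value per layer, cm^-1.
#' @param geometry optional geometry list to check against the records
#'   (thicknesses in mm, mus, g, n); mismatch is an error.
#' @return a `radial_reflectance` like [simulate_transport()].
#' @export
rescale_absorption <- function(records, mua, geometry = NULL) {
  stopifnot(inherits(records, "pathlength_records"))
  k <- ncol(records$pathlengths)
  if (length(mua) != k) stop("need one mua per layer")
  if (any(mua < 0)) stop("mua must be >= 0")
  if (!is.null(geometry)) {
    g0 <- records$geometry
    same <- isTRUE(all.equal(geometry$thickness, g0$thickness)) &&
      isTRUE(all.equal(geometry$mus, g0$mus)) &&
      isTRUE(all.equal(geometry$g, g0$g)) &&
      isTRUE(all.equal(geometry$n, g0$n))
    if (!same) stop("geometry mismatch between records and request")
  }
  config <- records$config
  top <- records$hemisphere == "top"
  nb <- round(config$max_radius / config$radial_bin_width)
  bin <- pmin(floor(records$exit_radius[top] / config$radial_bin_width), nb)
  M <- matrix(mua, nrow = 1)
  binned <- cpp_rescale_bins(records$pathlengths[top, , drop = FALSE],
                             records$weight[top], as.integer(bin), M, nb)
  trans <- cpp_rescale_total(records$pathlengths[!top, , drop = FALSE],
                             records$weight[!top], M)
  n <- records$n_photons
  diffuse <- sum(binned) / n
  transmitted <- trans[1] / n
  structure(list(
    annulus_edges = seq(0, by = config$radial_bin_width, length.out = nb + 1),
    diffuse_per_annulus = binned[1, seq_len(nb)] / n,
    overflow = binned[1, nb + 1] / n,
    specular = records$specular,
    diffuse_total = diffuse,
    absorbed = 1 - records$specular - diffuse - transmitted,
    transmitted = transmitted,
    n_photons = n,
    seed = config$seed), class = "radial_reflectance")
}

# overlap area between a disk of radius rho centred at distance d and a
# concentric disk of radius r around the origin
circle_overlap_area <- function(r, d, rho) {
  if (d == 0) return(pi * pmin(r, rho)^2)
  out <- numeric(length(r))
  full_fiber <- d + rho <= r
  full_disk <- r + d <= rho
  lens <- !full_fiber & !full_disk & (d < r + rho)
  out[full_fiber] <- pi * rho^2
  out[full_disk] <- pi * r[full_disk]^2
  if (any(lens)) {
    rl <- r[lens]
    a1 <- rl^2 * acos(pmin(1, pmax(-1, (d^2 + rl^2 - rho^2) / (2 * d * rl))))
    a2 <- rho^2 * acos(pmin(1, pmax(-1, (d^2 + rho^2 - rl^2) / (2 * d * rho))))
    s <- (-d + rl + rho) * (d + rl - rho) * (d - rl + rho) * (d + rl + rho)
    out[lens] <- a1 + a2 - 0.5 * sqrt(pmax(0, s))
  }
  out
}

# fraction of each annulus' weight collected by an offset fiber circle;
# returns a (n_annuli x n_distances) matrix of coupling fractions
fiber_coupling_matrix <- function(annulus_edges, distances, fiber_diameter) {
  rho <- fiber_diameter / 2
  nb <- length(annulus_edges) - 1
  area <- pi * diff(annulus_edges^2)
  K <- matrix(0, nb, length(distances))
  for (j in seq_along(distances)) {
    A <- circle_overlap_area(annulus_edges, distances[j], rho)
    K[, j] <- diff(A) / area
  }
  K
}

#' Fiber-coupled reflectance at an offset detector
#'
#' Converts the annular exit density to the expected escaped weight landing
#' inside a circle of the given diameter centred at the given distance from
#' the source, by overlap-area weighting of each annulus with the offset
#' circle (valid by azimuthal symmetry of the exit distribution).
#'
#' @param rr a `radial_reflectance`.
#' @param fiber_diameter mm, > 0.
#' @param center_distance mm, >= 0.
#' @return collected weight fraction (scalar if one distance).
#' @export
fiber_coupled_reflectance <- function(rr, fiber_diameter = 0.55,
                                      center_distance) {
  stopifnot(inherits(rr, "radial_reflectance"))
  if (fiber_diameter <= 0) stop("fiber_diameter must be > 0")
  if (any(center_distance < 0)) stop("center_distance must be >= 0")
  K <- fiber_coupling_matrix(rr$annulus_edges, center_distance,
                             fiber_diameter)
  as.vector(crossprod(K, rr$diffuse_per_annulus))
}

#' Depth-resolved visitation of detected photons
#'
#' Runs the transport simulation while accumulating, on an (r, z) grid, the
#' pathlength-weighted visitation of photons that are eventually detected by
#' a fiber of the given diameter centred at the given distance from the
#' source. Every escaping photon contributes with the azimuthal probability
#' of landing inside the detector circle times its detected weight, which
#' keeps the estimator exact under azimuthal symmetry and gives far lower
#' variance than point detection. The map is normalized to total weight 1.
#'
#' @inheritParams simulate_transport
#' @param fiber_diameter detector fiber diameter, mm.
#' @param center_distance source-detector separation, mm.
#' @param dr,dz visitation cell sizes, mm.
#' @return object of class `visitation_map` with fields `z` (cell lower
#'   edges, mm), `r`, `map` (rows = depth, cols = radius, sums to 1) and
#'   `detected_weight`.
#' @export
detected_visitation <- function(stack, config = transport_config(),
                                fiber_diameter = 0.55, center_distance = 1,
                                dr = 0.1, dz = 0.05) {
  if (fiber_diameter <= 0) stop("fiber_diameter must be > 0")
  raw <- run_engine(stack, config, vis = TRUE,
                    det_dist = center_distance,
                    det_radius = fiber_diameter / 2,
                    vis_dr = dr, vis_dz = dz)
  if (raw$detected_weight <= 0 || sum(raw$visitation) <= 0)
    stop("no photons detected; increase n_photons or the fiber size")
  V <- raw$visitation / sum(raw$visitation)
  structure(list(
    z = seq(0, by = dz, length.out = nrow(V)),
    r = seq(0, by = dr, length.out = ncol(V)),
    map = V,
    detected_weight = raw$detected_weight,
    detector = list(fiber_diameter = fiber_diameter,
                    center_distance = center_distance),
    n_photons = config$n_photons, seed = config$seed),
    class = "visitation_map")
}

#' Fraction of detected signal above a depth
#'
#' Cumulative visitation weight shallower than `depth`, in \[0, 1\] and
#' non-decreasing in depth.
#'
#' @param map a [detected_visitation()] result.
#' @param depth mm, >= 0.
#' @export
fraction_above_depth <- function(map, depth) {
  stopifnot(inherits(map, "visitation_map"))
  if (depth < 0) stop("depth must be >= 0")
  rowsum_z <- rowSums(map$map)
  dz <- map$z[2] - map$z[1]
  # include the partial cell containing `depth`
  full <- map$z + dz <= depth
  part <- !full & map$z < depth
  sum(rowsum_z[full]) + sum(rowsum_z[part] * (depth - map$z[part]) / dz)
}

#' @export
print.radial_reflectance <- function(x, ...) {
  cat(sprintf(
    "<radial_reflectance> %d photons | specular %.4f diffuse %.4f absorbed %.4f transmitted %.4f\n",
    x$n_photons, x$specular, x$diffuse_total, x$absorbed, x$transmitted))
  invisible(x)
}
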