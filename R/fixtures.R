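#' Synthetic raw measurement for a skin model
#'
#' Inverts the OD definition: synthesizes the model's OD spectrum from the
#' grid, then produces sample/background/reference counts with a flat
#' reference (`Iref - Ibg = 1e5` counts, `Ibg = 1e3`) and multiplicative
#' Gaussian noise on the sample intensity (a spectrometer shot/flicker
#' proxy). With `noise = 0`, [compute_od()] recovers the synthesized OD to
#' machine precision.
#'
#' @param model a [skin_model()].
#' @param grid a `simulation_grid`.
#' @param distance mm, on the grid's distance axis.
#' @param noise relative intensity noise sigma (>= 0).
#' @param seed RNG seed.
#' @param wavelengths nm.
#' @return a [raw_measurement()].
#' @export
generate_raw_measurement <- function(model, grid, distance, noise = 0.01,
                                     seed = 1,
                                     wavelengths = seq(900, 1075, by = 5)) {
  if (noise < 0) stop("noise must be >= 0")
  od <- synthesize_od(grid, model, wavelengths, distances = distance)[[1]]
  ibg <- 1e3
  ref_net <- 1e5
  net <- ref_net * exp(-od$od)
  if (noise > 0)
    net <- withr::with_seed(seed,
                            net * (1 + rnorm(length(net), 0, noise)))
  raw_measurement(wavelengths, intensity = ibg + net,
                  background = rep(ibg, length(wavelengths)),
                  reference = rep(ibg + ref_net, length(wavelengths)),
                  distance = distance)
}

# internal: labeled profile set from a table of skin-model parameters,
# optionally with intensity noise applied through the raw-measurement layer
profiles_from_models <- function(models, grid, distances, wavelengths,
                                 noise = 0, seed = 1, window = c(900, 1075),
                                 k = 4) {
  od <- synthesize_od_array(grid, models, wavelengths, distances, k)
  if (noise > 0) {
    od <- withr::with_seed(seed, {
      net <- exp(-od) * (1 + rnorm(length(od), 0, noise))
      if (any(net <= 0))
        stop("noise level produced non-positive intensities")
      -log(net)
    })
  }
  fits <- fit_components_array(od, wavelengths, window = window)
  list(a_water = fits$a_water, a_lipid = fits$a_lipid, fits = fits)
}

#' Simulated configuration set over the standard parameter ranges
#'
#' Generates the lattice (or a uniform sample) of three-layer skin
#' configurations spanning dermal water 0.5--1, dermal thickness 1--2.5 mm
#' and hypodermal thickness 0.5--5 mm with hypodermal lipid fraction fixed
#' to 1 and muscle water fixed to 0.8, synthesizes their OD spectra from the
#' grid, fits the water/lipid amplitudes at every distance and returns the
#' labeled profile set used by all inverse models.
#'
#' @param grid a `simulation_grid`.
#' @param sampling `"grid"` (full lattice) or `"uniform"` (random within
#'   ranges).
#' @param W_values dermal water lattice (grid sampling).
#' @param d1_values,d2_values thickness lattices, mm (grid sampling).
#' @param n number of configurations (uniform sampling only).
#' @param W_range,d1_range,d2_range ranges for uniform sampling.
#' @param distances,wavelengths synthesis axes.
#' @param noise relative intensity noise (0 = noiseless spectra).
#' @param seed RNG seed (sampling + noise).
#' @return a [labeled_profile_set()] with targets `dermis_water`,
#'   `dermis_thickness`, `hypodermis_thickness`.
#' @export
generate_configuration_set <- function(grid,
                                       sampling = c("grid", "uniform"),
                                       W_values = seq(0.5, 1, by = 0.05),
                                       d1_values = c(1, 1.5, 2, 2.5),
                                       d2_values = c(0.5, 1, 2, 3, 4, 5),
                                       n = 100,
                                       W_range = c(0.5, 1),
                                       d1_range = c(1, 2.5),
                                       d2_range = c(0.5, 5),
                                       distances = grid$distances,
                                       wavelengths = seq(900, 1075, by = 5),
                                       noise = 0, seed = 1) {
  sampling <- match.arg(sampling)
  if (sampling == "grid") {
    par <- expand.grid(dermis_water = W_values,
                       dermis_thickness = d1_values,
                       hypodermis_thickness = d2_values)
  } else {
    if (n < 1) stop("n must be >= 1")
    if (d1_range[1] < grid$d1_range[1] || d1_range[2] > grid$d1_range[2] ||
        d2_range[1] < grid$d2_range[1] || d2_range[2] > grid$d2_range[2])
      stop("requested thickness range outside grid bounds")
    par <- withr::with_seed(seed, data.frame(
      dermis_water = runif(n, W_range[1], W_range[2]),
      dermis_thickness = runif(n, d1_range[1], d1_range[2]),
      hypodermis_thickness = runif(n, d2_range[1], d2_range[2])))
  }
  if (any(par$dermis_thickness < grid$d1_range[1]) ||
      any(par$dermis_thickness > grid$d1_range[2]) ||
      any(par$hypodermis_thickness < grid$d2_range[1]) ||
      any(par$hypodermis_thickness > grid$d2_range[2]))
    stop("requested thickness range outside grid bounds")
  models <- data.frame(dermis_water = par$dermis_water,
                       dermis_thickness = par$dermis_thickness,
                       hypodermis_lipid = 1,
                       hypodermis_thickness = par$hypodermis_thickness,
                       muscle_water = 0.8,
                       muscle_thickness = grid$spec$muscle_thickness)
  pr <- profiles_from_models(models, grid, distances, wavelengths,
                             noise = noise, seed = seed + 1)
  labeled_profile_set(pr$a_water, pr$a_lipid, par, distances)
}

#' Edema timecourse specification
#'
#' Parameterized monotone rise to a plateau of dermal thickness and dermal
#' water fraction, emulating a histamine-induced cutaneous edema: both
#' parameters follow `baseline + (peak - baseline) * (1 - exp(-t / tau))`.
#'
#' @param times minutes, increasing.
#' @param d_dermis baseline and peak dermal thickness, mm.
#' @param dermis_water baseline and peak dermal water fraction.
#' @param tau rise time constant, minutes.
#' @export
edema_spec <- function(times = seq(0, 60, by = 10),
                       d_dermis = c(1.4, 2.2),
                       dermis_water = c(0.70, 0.81),
                       tau = 15) {
  if (any(diff(times) <= 0)) stop("times must be increasing")
  s <- 1 - exp(-(times - times[1]) / tau)
  s <- s / max(s)  # reach the stated peak at the last time point
  structure(list(times = times,
                 dermis_thickness = d_dermis[1] + diff(d_dermis) * s,
                 dermis_water = dermis_water[1] + diff(dermis_water) * s),
            class = "edema_spec")
}

#' Synthetic edema timecourse spectra
#'
#' Synthesizes the OD spectra and amplitude profiles along an edema
#' timecourse (default: dermal thickness 1.4 -> 2.2 mm and dermal water
#' 0.70 -> 0.81 at the plateau).
#'
#' @param spec an [edema_spec()].
#' @param grid a `simulation_grid`.
#' @param distances mm.
#' @param noise relative intensity noise.
#' @param seed RNG seed.
#' @param wavelengths nm.
#' @return a [labeled_profile_set()] whose targets carry `time`,
#'   `dermis_water` and `dermis_thickness`.
#' @export
generate_edema_timecourse <- function(spec = edema_spec(), grid,
                                      distances = grid$distances,
                                      noise = 0, seed = 1,
                                      wavelengths = seq(900, 1075, by = 5)) {
  stopifnot(inherits(spec, "edema_spec"))
  models <- data.frame(dermis_water = spec$dermis_water,
                       dermis_thickness = spec$dermis_thickness,
                       hypodermis_lipid = 1,
                       hypodermis_thickness = 2,
                       muscle_water = 0.8,
                       muscle_thickness = grid$spec$muscle_thickness)
  pr <- profiles_from_models(models, grid, distances, wavelengths,
                             noise = noise, seed = seed)
  targets <- data.frame(time = spec$times,
                        dermis_water = spec$dermis_water,
                        dermis_thickness = spec$dermis_thickness,
                        hypodermis_thickness = 2)
  labeled_profile_set(pr$a_water, pr$a_lipid, targets, distances)
}

#' Volunteer-like cohort specification
#'
#' Defaults emulate a 7-subject, 3-sites-per-subject forearm protocol:
#' hypodermal thickness uniform on 0.5--4 mm (wrist to antecubital fossa),
#' dermal thickness with low variability (normal, mean 1.5 mm, sd 0.15 mm,
#' truncated to 1--2.5 mm) and dermal water near 0.70. Entirely synthetic --
#' the parameter distributions are declared, not estimated from any real
#' cohort.
#'
#' @param n_subjects,sites_per_subject cohort layout.
#' @param d2_range hypodermal thickness range, mm.
#' @param d1_mean,d1_sd,d1_bounds dermal thickness distribution, mm.
#' @param W_mean,W_sd dermal water distribution (truncated to \[0.5, 1\]).
#' @param noise relative intensity noise sigma.
#' @param seed mandatory RNG seed.
#' @export
cohort_spec <- function(n_subjects = 7, sites_per_subject = 3,
                        d2_range = c(0.5, 4),
                        d1_mean = 1.5, d1_sd = 0.15, d1_bounds = c(1, 2.5),
                        W_mean = 0.70, W_sd = 0.03,
                        noise = 0.01, seed = 1) {
  structure(list(n_subjects = n_subjects,
                 sites_per_subject = sites_per_subject,
                 d2_range = d2_range, d1_mean = d1_mean, d1_sd = d1_sd,
                 d1_bounds = d1_bounds, W_mean = W_mean, W_sd = W_sd,
                 noise = noise, seed = seed),
            class = "cohort_spec")
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

#' Synthetic volunteer cohort
#'
#' Draws per-site skin parameters from the cohort specification, synthesizes
#' noisy spectra through the raw-measurement layer and returns the labeled
#' amplitude profiles (one record per site).
#'
#' @param spec a [cohort_spec()].
#' @param grid a `simulation_grid`.
#' @param distances,wavelengths synthesis axes.
#' @return a [labeled_profile_set()]; targets carry `subject`, `site`,
#'   `dermis_water`, `dermis_thickness`, `hypodermis_thickness`.
#' @export
generate_cohort <- function(spec = cohort_spec(), grid,
                            distances = grid$distances,
                            wavelengths = seq(900, 1075, by = 5)) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects * spec$sites_per_subject
  par <- withr::with_seed(spec$seed, data.frame(
    subject = rep(seq_len(spec$n_subjects), each = spec$sites_per_subject),
    site = rep(seq_len(spec$sites_per_subject), spec$n_subjects),
    dermis_water = rtrunc_norm(n, spec$W_mean, spec$W_sd, 0.5, 1),
    dermis_thickness = rtrunc_norm(n, spec$d1_mean, spec$d1_sd,
                                   spec$d1_bounds[1], spec$d1_bounds[2]),
    hypodermis_thickness = runif(n, spec$d2_range[1], spec$d2_range[2])))
  models <- data.frame(dermis_water = par$dermis_water,
                       dermis_thickness = par$dermis_thickness,
                       hypodermis_lipid = 1,
                       hypodermis_thickness = par$hypodermis_thickness,
                       muscle_water = 0.8,
                       muscle_thickness = grid$spec$muscle_thickness)
  pr <- profiles_from_models(models, grid, distances, wavelengths,
                             noise = spec$noise, seed = spec$seed + 7)
  labeled_profile_set(pr$a_water, pr$a_lipid, par, distances)
}
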