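# dermaspec

Forward modeling and inversion of **spatially resolved diffuse reflectance
spectroscopy (SR DRS)** of human skin in the 900–1075 nm window.

Skin edema, hydration changes and fat-layer thickness all alter how
near-infrared light diffuses through the dermis (water-dominated, 970 nm
band), the hypodermis (lipid-dominated, 930 nm band) and the muscle
beneath. Measuring diffuse reflectance at several source–detector
separations r (here 0.5–10 mm) probes different depths, and the spectra
can be inverted for the physiological parameters a dermatologist or
physiologist actually wants: **dermal water content W, dermal thickness,
and hypodermal thickness**. The package is for biophotonics researchers
building or evaluating such probes.

## What it implements

* **Monte Carlo photon transport** (`simulate_transport()`): photon-packet
  walk in a plane-parallel layered medium — Henyey–Greenstein scattering,
  Fresnel boundaries, implicit capture, Russian roulette — with radially
  resolved scoring and an energy budget (specular + diffuse + absorbed +
  transmitted = 1) that closes to 1e-10. Validated against an
  adding-doubling radiative-transfer oracle.
* **White Monte Carlo** (`simulate_pathlengths()` /
  `rescale_absorption()`): one scattering-only run per geometry plus
  Beer–Lambert reweighting covers every absorption combination exactly —
  the key trick that makes grid construction desk-scale.
* **Reflectance lookup table + KNN** (`build_grid()`,
  `knn_interpolate()`, `synthesize_od()`): fiber-coupled reflectance
  R(r) on a log-absorption × thickness lattice, interpolated by
  inverse-distance KNN on normalized features
  (μ̃ₐ = (ln μₐ − min)/(max − min)); optical density OD = −ln R.
* **Spectral decomposition** (`fit_components()`): least squares of
  OD(λ) = C₀ + C₁λ + A_water ε_water(λ) + A_lipid ε_lipid(λ)
  over 900–1075 nm, giving amplitude profiles A_water(r), A_lipid(r).
* **Inversion** (`error_vs_distance()`, `fit_ridge_all_distances()`,
  `leave_one_out()`): single-distance linear models scored by the mean
  relative error δ = mean(|ŷ − y|/y), and an all-distance ridge
  regression (CV-selected L2 penalty, seeded 95/5 train/test split).
* **Synthetic study generators** (`generate_configuration_set()`,
  `generate_edema_timecourse()`, `generate_cohort()`,
  `generate_raw_measurement()`): seeded, fully reproducible inputs
  spanning the standard parameter ranges, an edema timecourse
  (dermis 1.4→2.2 mm, water 0.70→0.81) and a 7-subject × 3-site cohort.

A thin CLI (`inst/exec/dermaspec`) exposes `simulate`, `build-grid`,
`synthesize`, `fit`, `invert` and `make-fixtures` for shell pipelines.

## Worked example

```r
library(dermaspec)

# 1. desk-scale lookup table: 8 log mua nodes/layer, 24 thickness
#    geometries, 2e5 photons each via white-MC rescaling (~3-4 min)
grid <- build_grid(grid_spec(), seed = 101)

# 2. synthesize a skin spectrum and decompose it
model <- skin_model(dermis_water = 0.7, dermis_thickness = 1.5,
                    hypodermis_thickness = 2)
od <- synthesize_od(grid, model, distances = 1)[[1]]
fit_components(od)
#> <component_fit> r=1 mm | c0=4.486 c1=0.0002625 a_water=0.1529
#>                 a_lipid=0.05452 (resid 0.116)

# 3. inversion study over the standard configuration lattice (264 configs)
configs <- generate_configuration_set(grid, seed = 101)
delta_W <- error_vs_distance(configs, "a_water", "dermis_water")
min(delta_W$delta); attr(delta_W, "argmin")
#> [1] 0.0538  ->  5.4% mean relative error for dermal water, at r = 0.5 mm

configs <- assign_split(configs, 0.05, seed = 101)
ridge <- fit_ridge_all_distances(configs, "dermis_thickness", seed = 101)
ridge$report
#> <evaluation_report> n=13 | RMSE 0.07 | rel. error 2.5% | Pearson R 0.995
```

The numbers mean: with a single short separation the water amplitude alone
recovers dermal water content to ~5% relative error, while combining the
water and lipid amplitudes at *all* separations recovers dermal thickness
to a few percent on held-out configurations. Hypodermal thickness needs
the lipid amplitude at the largest separation (error curve minimized at
r = 10 mm), and predicting it from the water amplitude fails at every
distance (δ > 80%) — the depth ordering one expects from the visitation
analysis: at r = 1 mm over 80% of detected signal originates above 1.1 mm
depth (`detected_visitation()` + `fraction_above_depth()`).

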