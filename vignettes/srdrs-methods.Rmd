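---
title: "Modeling and inverting spatially resolved diffuse reflectance of skin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and inverting spatially resolved diffuse reflectance of skin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The measurement and the inverse problem

Spatially resolved diffuse reflectance spectroscopy (SR DRS) measures the
near-infrared light that re-emerges from the skin at several source-detector
("interfiber") separations. Short separations sample shallow tissue, long
separations sample deep tissue, so a set of spectra at separations between
0.5 and 10 mm carries depth-resolved information. In the 900--1075 nm
window the dominant absorbers are water (band at 970 nm, mostly in the
collagen-rich dermis and in muscle) and lipid (band at 930 nm, mostly in
the subcutaneous fat). `dermaspec` implements the full chain needed to
exploit this:

1. **photon transport** -- a Monte Carlo photon-packet engine for
   plane-parallel layered media (dermis / hypodermis / muscle);
2. **forward model** -- a lookup table of fiber-coupled reflectance
   $R(r)$ over absorption and thickness grids, interpolated with a
   k-nearest-neighbour (KNN) scheme, from which optical-density spectra
   $\mathrm{OD}(\lambda, r) = -\ln R$ are synthesized for any skin
   parameter set;
3. **spectral decomposition** -- least-squares unmixing
   $\mathrm{OD}(\lambda) = C_0 + C_1 \lambda +
   A_\mathrm{water}\,\varepsilon_\mathrm{water}(\lambda) +
   A_\mathrm{lipid}\,\varepsilon_\mathrm{lipid}(\lambda)$
   over 900--1075 nm, giving amplitude-vs-distance profiles
   $A_\mathrm{water}(r), A_\mathrm{lipid}(r)$;
4. **inversion** -- single-distance linear regressions with the mean
   relative error $\delta = \frac1N \sum_i |{\hat y}_i - y_i| / y_i$
   as accuracy metric, and an all-distance ridge regression with
   cross-validated penalty, recovering dermal water content, dermal
   thickness and hypodermal thickness.

## The three-layer skin model

The standard stack fixes scattering (wavelength-independent) and varies
absorption and geometry:

| layer      | $\mu_s$ (cm$^{-1}$) | absorber                  | thickness    |
|------------|--------------------:|---------------------------|--------------|
| dermis     | 200                 | water, fraction $W$       | 1--2.5 mm    |
| hypodermis | 100                 | lipid, fraction $F = 1$   | 0.5--5 mm    |
| muscle     | 90                  | water, fraction $W_3=0.8$ | 5 mm         |

Anisotropy $g = 0.9$ everywhere; layer absorption is linear volume-fraction
mixing of the bundled pure-substance tables
(`layer_mua_spectrum()`). The refractive index is nowhere constrained by
the study design, so the package takes the conventional tissue value
$n = 1.4$ for all layers, air ($n = 1$) above and an index-matched
half-space below the muscle; all of these are overridable through
`optical_layer()` / `layer_stack()`.

The bundled chromophore tables (`inst/extdata/*_mua_synthetic.tsv`) are
*synthetic smooth compilations*: they were written to agree with the widely
published water (Hale & Querry / Segelstein style) and fat (van Veen style)
absorption data to within a few percent over 850--1100 nm, with the water
band maximum at 975 nm and the lipid maximum at 930 nm, but they are not a
verbatim copy of any digital table. For quantitative work against real
spectra, replace them with your laboratory's calibrated tables (same
two-column format).

## Monte Carlo engine

`simulate_transport()` is a standard photon-packet walk: pencil beam at the
origin, analytic specular split at entry, exponential step sampling from
$\mu_t$, implicit capture (deposit $w\,\mu_a/\mu_t$ per interaction),
Henyey--Greenstein scattering, Fresnel reflection/refraction at every
index-mismatched interface, Russian roulette (threshold $10^{-4}$,
survival 0.1). Escaping top-hemisphere weight is scored by exit annulus
(0.05 mm wide out to 15 mm) over all exit angles; weight escaping beyond
the scoring radius goes to an overflow bucket so that

$$\text{specular} + \text{diffuse} + \text{absorbed} + \text{transmitted} = 1$$

closes to $10^{-10}$ in every run. Roulette bookkeeping debits the
survival boost from (and credits killed weight to) the absorbed pool,
which keeps the budget an exact identity rather than a statistical one.

The engine was validated against an independently written adding-doubling
solver: for $\mu_a = 10$, $\mu_s = 90$ cm$^{-1}$, $g = 0.75$, matched
boundaries, the classic slab of optical thickness 2 gives
$R_d = 0.09739$ / $T = 0.66096$ and the semi-infinite medium gives
$0.16556$; the isotropic semi-infinite case reproduces the exact
H-function value $0.414947$. The test suite pins all four numbers.

**White Monte Carlo.** Because the study design fixes all scattering
coefficients, one scattering-only run per thickness geometry suffices:
`simulate_pathlengths()` records per-photon exit radius and per-layer
pathlengths $\ell_i$, and `rescale_absorption()` reweights every photon by
$\exp(-\sum_i \mu_{a,i} \ell_i)$ -- exact in expectation for *any*
absorption triple. Grid construction is therefore dominated by 24
scattering-only runs instead of hundreds of thousands of absorbing runs.
The grid builder uses a common seed for all geometries (common random
numbers), so photon histories coincide until a trajectory first reaches a
depth where the geometries differ; this reduces noise in exactly the
thickness contrasts the lookup table exists to resolve.

**Fiber coupling.** The annular exit density is converted to the weight
collected by a 550 µm fiber at center distance $r$ by overlap-area
weighting of each annulus with the offset circle (exact under azimuthal
symmetry). The depth-visitation estimator (`detected_visitation()`)
weights every escaping photon's trajectory by its azimuthal probability of
landing inside the detector circle, which gives far lower variance than
point detection and underlies the result that at 1 mm separation over 80%
of the detected signal originates above 1.1 mm depth.

## Lookup table and KNN interpolation

The grid axes follow the study design: per-layer absorption on a
logarithmic grid over 0.001--10 cm$^{-1}$, dermal thickness
$\{1, 1.5, 2, 2.5\}$ mm, hypodermal thickness
$\{0.5, 1, 2, 3, 4, 5\}$ mm. Absorption features are normalized as
$\tilde\mu_a = (\ln\mu_a - \min)/(\max - \min)$ so the node lattice is
uniform on $[0,1]$; thickness features are min-max normalized (the source
design prescribes the normalization only for absorption -- extending it to
thicknesses is this package's choice, recorded here, so that one metric
serves all five dimensions). Interpolation is an inverse-distance-weighted
mean of the $k$ nearest nodes, exact at nodes, with no silent
extrapolation. The default is $k = 4$; `validate_grid()` offers node-holdout
cross-validation, but note that predicting *held-out nodes* (one grid
spacing away) is a different regime from interpolating *between* nodes, and
on the desk-scale grid it selects a smaller $k$ than is good for synthesis.
The default is therefore kept unless the user overrides it.

### Problem sizes

The package's default grid is deliberately desk-scale: 8 logarithmic
absorption nodes per layer ($8^3 \times 24$ geometries $= 12{,}288$ nodes)
with $2\times10^5$ photons per scattering-only run, built in a few minutes
on one core. The full-scale design (20 nodes per layer, $10^7$ photons) is
available as `grid_spec(preset = "full")`. The choice matters: a
20-node-per-layer build with the same photon budget reproduces the
full-scale study's single-distance errors essentially exactly, while the
8-node default inflates the thickness errors that rely on small spectral
contrasts (see Limitations).

## Spectral decomposition

`fit_components()` performs *unconstrained* ordinary least squares of OD on
$(1, \lambda, \varepsilon_\mathrm{water}, \varepsilon_\mathrm{lipid})$.
The shapes $\varepsilon$ are the pure-substance spectra peak-normalized to
1 over the fit window (900--1075 nm), so the amplitudes read as the OD
contribution at the band maximum; the convention is recorded in every
shape object. Negative amplitudes are reported, not clipped -- they are a
diagnostic, and clipping would bias the downstream regressions. Wavelengths
with non-positive net intensity are masked and dropped from the design
rather than imputed. The linear baseline $C_0 + C_1\lambda$ absorbs
residual background absorption and the smooth wavelength dependence of
scattering; no scattering-model baseline is attempted.

## Inversion conventions

* **Single-distance error curves** (`error_vs_distance()`) regress the
  target on one amplitude at one distance and report the mean relative
  error per distance. The default evaluation is *in-sample* over the whole
  configuration lattice: the plain single-distance regressions have two
  parameters against hundreds of configurations, so overfitting is not a
  concern, and a 5% held-out subset (~13 points) would make the curve and
  its minimum location statistically unstable. A `"heldout"` mode exists
  for diagnostics.
* **Ridge regression** (`fit_ridge_all_distances()`) uses all 40
  amplitude features (water and lipid at 20 distances), which are highly
  collinear; the L2 penalty is selected on a logarithmic grid
  $10^{-4} \ldots 10^2$ (13 points) by 5-fold cross-validation on the
  seeded 95% training split and the model is scored only on the untouched
  5% test split. A canary test asserts that a feature leaking the target on
  the training rows only does not improve test metrics.
* **Leave-one-out** (`leave_one_out()`) serves small cohorts (e.g., 21
  sites); the penalty is either fixed or re-selected inside every fold.
* Relative error is undefined for true value 0 and the package refuses it
  rather than epsilon-padding.

## Synthetic data generators

`generate_configuration_set()` spans dermal water 0.5--1 (step 0.05 on the
lattice -- the generating design states only the range; 0.05 gives 11
levels, comparable resolution to the thickness axes), dermal thickness
1--2.5 mm, hypodermal thickness 0.5--5 mm. `generate_raw_measurement()`
inverts the OD definition with a flat reference ($I_\mathrm{ref} -
I_\mathrm{bg} = 10^5$ counts, $I_\mathrm{bg} = 10^3$) and multiplicative
Gaussian intensity noise (default 1%, a plain spectrometer shot/flicker
proxy -- no wavelength-correlated structure, no baseline drift).
`generate_edema_timecourse()` drives dermal thickness 1.4 → 2.2 mm and
dermal water 0.70 → 0.81 along a saturating-exponential rise.
`generate_cohort()` draws 7 subjects × 3 forearm sites with hypodermal
thickness uniform on 0.5--4 mm and dermal thickness normal(1.5, 0.15) mm
truncated to 1--2.5 mm -- *declared* distributions, not estimates of any
real cohort. What passing tests on these fixtures shows is that the
pipeline inverts its own forward model under realistic parameter ranges
and mild noise; they cannot certify performance on real skin, where
scattering varies with wavelength and between subjects, additional
chromophores absorb, and probe contact varies.

## Numerical choices and degenerate inputs

* Internal transport units are cm; all public interfaces use mm and
  cm$^{-1}$, converted in exactly one place.
* Roulette threshold $10^{-4}$, survival 0.1 (conventional values; the
  result is insensitive to them and the budget identity holds regardless).
* KNN ties are broken by node order; a query exactly on a node returns
  that node's value regardless of $k$.
* Grid cells that received no photons are flagged `NA` (with a warning) at
  build time and poison any query that touches them, rather than silently
  reading 0 (whose $-\ln$ would be infinite).
* Rank-deficient decomposition designs name the collinear columns;
  duplicate distances, overlapping splits, zero-variance features and
  out-of-range queries are all hard errors.

## Known limitations

* The desk-scale default grid (8 absorption nodes/layer) carries visible
  KNN interpolation bias: spectral structure interpolated *in R* is
  systematically distorted between nodes, which leaks water-band signal
  into the lipid amplitude and inflates the single-distance thickness
  errors (hypodermal thickness from the lipid band at 10 mm: ~29% at 8
  nodes vs ~16% at 20 nodes with the same photon budget) and the
  edema water-amplitude rise (~42% at 8 nodes vs ~33% expected). Use
  20 nodes per layer when accuracy of those quantities matters; the white
  Monte Carlo build makes the extra nodes cheap.
* Scattering is wavelength-independent and fixed per layer by design; the
  lookup table has no scattering axis.
* The transport model is plane-parallel with a pencil-beam source: no
  curvature, no finite source diameter (the detector-side convolution can
  be reused for the source if needed), no polarization, no fluorescence,
  no time resolution.
* Amplitudes at $r = 0$ (probe overlap) are geometrically dubious;
  the default distance axis starts at 0.5 mm.
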