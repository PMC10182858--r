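#' Reflectance grid specification
#'
#' Defines the absorption/thickness node lattice and the simulation settings
#' for a reflectance lookup table. The default is a desk-scale build: 8
#' log-spaced absorption nodes per layer over 0.001--10 cm^-1 and 2e5
#' photons per geometry with white-Monte-Carlo pathlength rescaling. The
#' `"full"` preset mirrors the full-scale study design (20 nodes per layer,
#' 1e7 photons) and is substantially more expensive.
#'
#' @param n_mua_nodes log-grid nodes per layer over `mua_range`.
#' @param mua_range absorption range, cm^-1, both endpoints > 0.
#' @param dermis_thicknesses,hypodermis_thicknesses thickness axes, mm.
#' @param muscle_thickness mm.
#' @param distances fiber center-to-center separations at which the grid
#'   stores fiber-coupled reflectance, mm.
#' @param fiber_diameter collection fiber core diameter, mm.
#' @param n_photons photon packets per transport run.
#' @param radial_bin_width,max_radius radial scoring, mm.
#' @param preset `"desk"` (default) or `"full"`.
#' @export
grid_spec <- function(n_mua_nodes = 8, mua_range = c(0.001, 10),
                      dermis_thicknesses = c(1, 1.5, 2, 2.5),
                      hypodermis_thicknesses = c(0.5, 1, 2, 3, 4, 5),
                      muscle_thickness = 5,
                      distances = seq(0.5, 10, by = 0.5),
                      fiber_diameter = 0.55,
                      n_photons = 2e5,
                      radial_bin_width = 0.05, max_radius = 15,
                      preset = c("desk", "full")) {
  preset <- match.arg(preset)
  if (preset == "full") {
    n_mua_nodes <- 20
    n_photons <- 1e7
  }
  stopifnot(all(mua_range > 0), mua_range[1] < mua_range[2],
            length(dermis_thicknesses) >= 1,
            length(hypodermis_thicknesses) >= 1,
            all(diff(distances) > 0))
  mua_nodes <- exp(seq(log(mua_range[1]), log(mua_range[2]),
                       length.out = n_mua_nodes))
  structure(list(mua_nodes = mua_nodes,
                 dermis_thicknesses = sort(dermis_thicknesses),
                 hypodermis_thicknesses = sort(hypodermis_thicknesses),
                 muscle_thickness = muscle_thickness,
                 distances = distances,
                 fiber_diameter = fiber_diameter,
                 n_photons = as.integer(n_photons),
                 radial_bin_width = radial_bin_width,
                 max_radius = max_radius,
                 mus = c(200, 100, 90), g = 0.9, n_tissue = 1.4,
                 preset = preset),
            class = "grid_spec")
}

#' Normalize an absorption coefficient to the log-uniform grid scale
#'
#' `(ln mua - min) / (max - min)` with ln-space bounds, so that the
#' logarithmic node grid maps to a uniform \[0, 1\] feature.
#'
#' @param mua cm^-1, > 0.
#' @param bounds length-2, ln-space min and max (e.g. `log(c(0.001, 10))`).
#' @export
normalize_mua <- function(mua, bounds) {
  if (any(mua <= 0)) stop("mua must be > 0 for log normalization")
  (log(mua) - bounds[1]) / (bounds[2] - bounds[1])
}

# min-max normalization for a thickness axis; a degenerate axis maps to 0
norm_axis <- function(x, rng) {
  if (diff(rng) <= 0) return(rep(0, length(x)))
  (x - rng[1]) / (rng[2] - rng[1])
}

grid_features <- function(grid, mua1, mua2, mua3, d1, d2) {
  cbind(normalize_mua(mua1, grid$bounds),
        normalize_mua(mua2, grid$bounds),
        normalize_mua(mua3, grid$bounds),
        norm_axis(d1, grid$d1_range),
        norm_axis(d2, grid$d2_range))
}

#' Build a reflectance lookup grid
#'
#' Fills every (mua1, mua2, mua3, d_dermis, d_hypodermis) node with the
#' fiber-coupled reflectance R(r) at the spec's distances. In
#' `"rescaled"` mode (the default) one scattering-only simulation is run per
#' thickness pair and Beer-Lambert reweighting fills all absorption triples
#' -- exact for fixed scattering. `"direct"` mode runs one absorbing
#' simulation per node and is retained as the oracle path.
#'
#' @param spec a [grid_spec()].
#' @param mode `"rescaled"` or `"direct"`.
#' @param seed integer seed; the build is deterministic given the seed.
#' @param verbose print per-geometry progress.
#' @return object of class `simulation_grid`.
#' @export
build_grid <- function(spec, mode = c("rescaled", "direct"), seed = 1,
                       verbose = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "grid_spec"))
  axes <- expand.grid(mua1 = spec$mua_nodes, mua2 = spec$mua_nodes,
                      mua3 = spec$mua_nodes)
  geoms <- expand.grid(d1 = spec$dermis_thicknesses,
                       d2 = spec$hypodermis_thicknesses)
  nb <- round(spec$max_radius / spec$radial_bin_width)
  edges <- seq(0, spec$max_radius, by = spec$radial_bin_width)
  K <- fiber_coupling_matrix(edges, spec$distances, spec$fiber_diameter)
  nodes <- vector("list", nrow(geoms))
  Rblocks <- vector("list", nrow(geoms))
  Mua <- as.matrix(axes)

  for (gi in seq_len(nrow(geoms))) {
    d1 <- geoms$d1[gi]; d2 <- geoms$d2[gi]
    # common random numbers across geometries: photon histories are shared
    # until a trajectory first reaches a depth where the geometries differ,
    # which cancels most of the between-geometry sampling noise in the
    # thickness contrasts the grid exists to resolve
    cfg <- transport_config(n_photons = spec$n_photons,
                            radial_bin_width = spec$radial_bin_width,
                            max_radius = spec$max_radius,
                            seed = seed)
    if (mode == "rescaled") {
      stack <- skin_stack(c(0, 0, 0), d1, d2, spec$muscle_thickness,
                          spec$mus, spec$g, spec$n_tissue)
      rec <- simulate_pathlengths(stack, cfg)
      top <- rec$hemisphere == "top"
      bin <- pmin(floor(rec$exit_radius[top] / spec$radial_bin_width), nb)
      binned <- cpp_rescale_bins(rec$pathlengths[top, , drop = FALSE],
                                 rec$weight[top], as.integer(bin), Mua, nb)
      Rfib <- (binned[, seq_len(nb), drop = FALSE] / spec$n_photons) %*% K
    } else {
      Rfib <- matrix(0, nrow(axes), length(spec$distances))
      for (ti in seq_len(nrow(axes))) {
        stack <- skin_stack(unlist(axes[ti, ]), d1, d2,
                            spec$muscle_thickness,
                            spec$mus, spec$g, spec$n_tissue)
        cfg$seed <- as.integer(seed + gi * 100003L + ti)
        rr <- simulate_transport(stack, cfg)
        Rfib[ti, ] <- fiber_coupled_reflectance(rr, spec$fiber_diameter,
                                                spec$distances)
      }
    }
    nodes[[gi]] <- data.frame(axes, d_dermis = d1, d_hypodermis = d2)
    Rblocks[[gi]] <- Rfib
    if (verbose)
      message(sprintf("geometry %d/%d (d1=%.1f d2=%.1f) done",
                      gi, nrow(geoms), d1, d2))
  }

  nodes <- do.call(rbind, nodes)
  R <- do.call(rbind, Rblocks)
  flagged <- which(R <= 0, arr.ind = TRUE)
  if (nrow(flagged) > 0) {
    warning(sprintf("%d node/distance cells received no photons; flagged NA",
                    nrow(flagged)))
    R[R <= 0] <- NA_real_
  }
  grid <- structure(list(
    nodes = nodes, R = R, distances = spec$distances,
    bounds = log(range(spec$mua_nodes)),
    d1_range = range(spec$dermis_thicknesses),
    d2_range = range(spec$hypodermis_thicknesses),
    spec = spec,
    provenance = list(mode = mode, seed = seed,
                      n_photons = spec$n_photons,
                      n_nodes = nrow(nodes),
                      built = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))),
    class = "simulation_grid")
  grid$features <- grid_features(grid, nodes$mua1, nodes$mua2, nodes$mua3,
                                 nodes$d_dermis, nodes$d_hypodermis)
  grid
}

#' @export
print.simulation_grid <- function(x, ...) {
  cat(sprintf(
    "<simulation_grid> %d nodes x %d distances | mode=%s photons=%g seed=%d\n",
    nrow(x$nodes), length(x$distances), x$provenance$mode,
    x$provenance$n_photons, x$provenance$seed))
  invisible(x)
}

# indices of the k smallest entries of v, ordered by increasing value
k_smallest <- function(v, k) {
  kth <- sort(v, partial = k)[k]
  idx <- which(v <= kth)
  idx[order(v[idx])][seq_len(k)]
}

#' KNN interpolation of grid reflectance
#'
#' Inverse-distance-weighted mean of the k nearest grid nodes in the
#' normalized feature space (log-normalized absorption triple plus
#' min-max-normalized thicknesses). Exact at grid nodes. Queries outside the
#' grid axis ranges raise an extrapolation error.
#'
#' @param grid a [build_grid()] result.
#' @param query data frame with columns `mua1`, `mua2`, `mua3`, `d_dermis`,
#'   `d_hypodermis` (cm^-1 / mm).
#' @param distance separations (mm) to return; default all grid distances.
#'   Must be on the grid's distance axis.
#' @param k number of neighbors.
#' @return numeric matrix, `nrow(query)` x `length(distance)`.
#' @export
knn_interpolate <- function(grid, query, distance = NULL, k = 4) {
  stopifnot(inherits(grid, "simulation_grid"))
  need <- c("mua1", "mua2", "mua3", "d_dermis", "d_hypodermis")
  if (!all(need %in% names(query)))
    stop("query must have columns ", paste(need, collapse = ", "))
  if (is.null(distance)) distance <- grid$distances
  di <- match(distance, grid$distances)
  if (any(is.na(di)))
    stop("requested distance not on the grid's distance axis")
  Q <- grid_features(grid, query$mua1, query$mua2, query$mua3,
                     query$d_dermis, query$d_hypodermis)
  tol <- 1e-9
  if (any(Q < -tol) || any(Q > 1 + tol))
    stop("query outside the grid axis ranges (no extrapolation)")
  FT <- grid$features
  Rm <- grid$R[, di, drop = FALSE]
  nq <- nrow(Q)
  out <- matrix(NA_real_, nq, length(di))
  chunk <- max(1L, floor(2e7 / nrow(FT)))
  for (start in seq(1, nq, by = chunk)) {
    idx <- start:min(nq, start + chunk - 1)
    D2 <- matrix(0, length(idx), nrow(FT))
    for (j in 1:5)
      D2 <- D2 + outer(Q[idx, j], FT[, j], "-")^2
    for (ii in seq_along(idx)) {
      nb <- k_smallest(D2[ii, ], k)
      d2 <- D2[ii, nb]
      if (d2[1] < 1e-18) {
        val <- Rm[nb[1], ]
      } else {
        w <- 1 / sqrt(d2)
        w <- w / sum(w)
        val <- crossprod(Rm[nb, , drop = FALSE], w)
      }
      if (any(is.na(val)))
        stop("query touches a flagged (photon-starved) grid node")
      out[idx[ii], ] <- val
    }
  }
  out
}

#' Hold-out validation of the grid + KNN interpolator
#'
#' Splits the grid nodes into training and test subsets, predicts each test
#' node's R(r) from the training nodes by [knn_interpolate()]'s scheme, and
#' reports relative-error statistics, optionally selecting k by
#' cross-validation on the training split.
#'
#' @param grid a `simulation_grid`.
#' @param test_fraction held-out node fraction (default 0.05).
#' @param k neighbors; if a vector, the value minimizing training
#'   cross-validation error is chosen.
#' @param seed split seed.
#' @return list with `k`, per-cell relative errors and summary quantiles.
#' @export
validate_grid <- function(grid, test_fraction = 0.05, k = 4, seed = 1) {
  n <- nrow(grid$nodes)
  test <- withr::with_seed(seed,
                           sample(n, size = max(1, round(test_fraction * n))))
  train <- setdiff(seq_len(n), test)
  sub <- grid
  sub$nodes <- grid$nodes[train, ]
  sub$R <- grid$R[train, , drop = FALSE]
  sub$features <- grid$features[train, , drop = FALSE]
  if (length(k) > 1) {
    # 5-fold CV on the training nodes
    folds <- withr::with_seed(seed + 1,
                              sample(rep(1:5, length.out = length(train))))
    cv <- sapply(k, function(kk) {
      errs <- unlist(lapply(1:5, function(f) {
        tr <- sub; sel <- folds != f
        tr$nodes <- sub$nodes[sel, ]; tr$R <- sub$R[sel, , drop = FALSE]
        tr$features <- sub$features[sel, , drop = FALSE]
        pred <- knn_interpolate(tr, sub$nodes[!sel, ], k = kk)
        abs(pred - sub$R[!sel, ]) / pmax(sub$R[!sel, ], .Machine$double.eps)
      }))
      mean(errs, na.rm = TRUE)
    })
    k <- k[which.min(cv)]
  }
  pred <- knn_interpolate(sub, grid$nodes[test, ], k = k)
  truth <- grid$R[test, , drop = FALSE]
  rel <- abs(pred - truth) / pmax(truth, .Machine$double.eps)
  list(k = k, rel_error = rel,
       median_rel_error = stats::median(rel, na.rm = TRUE),
       mean_rel_error = mean(rel, na.rm = TRUE),
       q90_rel_error = unname(quantile(rel, 0.9, na.rm = TRUE)),
       n_test = length(test))
}

#' Skin model parameterization
#'
#' Composition and geometry of the three-layer skin model: dermal water
#' volume fraction `W`, hypodermal lipid fraction `F` (fixed to 1 in the
#' standard configuration), muscle water fraction `W3` (fixed to 0.8) and
#' the layer thicknesses.
#'
#' @param dermis_water,hypodermis_lipid,muscle_water volume fractions.
#' @param dermis_thickness,hypodermis_thickness,muscle_thickness mm.
#' @export
skin_model <- function(dermis_water = 0.7, dermis_thickness = 1.5,
                       hypodermis_lipid = 1, hypodermis_thickness = 2,
                       muscle_water = 0.8, muscle_thickness = 5) {
  fr <- c(dermis_water, hypodermis_lipid, muscle_water)
  if (any(fr < 0 | fr > 1)) stop("volume fractions must lie in [0, 1]")
  th <- c(dermis_thickness, hypodermis_thickness, muscle_thickness)
  if (any(th <= 0)) stop("thicknesses must be > 0")
  structure(list(dermis_water = dermis_water,
                 dermis_thickness = dermis_thickness,
                 hypodermis_lipid = hypodermis_lipid,
                 hypodermis_thickness = hypodermis_thickness,
                 muscle_water = muscle_water,
                 muscle_thickness = muscle_thickness),
            class = "skin_model")
}

# absorption triples implied by skin models at given wavelengths;
# returns a (n_models * n_wl) query data frame in grid column order
model_queries <- function(models, wavelengths) {
  muaw <- mua_at(chromophore_spectrum("water"), wavelengths)
  mual <- mua_at(chromophore_spectrum("lipid"), wavelengths)
  nw <- length(wavelengths)
  do.call(rbind, lapply(seq_len(nrow(models)), function(i) {
    data.frame(mua1 = models$dermis_water[i] * muaw,
               mua2 = models$hypodermis_lipid[i] * mual,
               mua3 = models$muscle_water[i] * muaw,
               d_dermis = models$dermis_thickness[i],
               d_hypodermis = models$hypodermis_thickness[i],
               model = i, wavelength = wavelengths)
  }))
}

# OD array for many models at once: dims (model, wavelength, distance)
synthesize_od_array <- function(grid, models, wavelengths,
                                distances = grid$distances, k = 4) {
  q <- model_queries(models, wavelengths)
  R <- knn_interpolate(grid, q, distance = distances, k = k)
  if (any(R <= 0, na.rm = TRUE))
    stop("non-positive interpolated reflectance; OD undefined")
  od <- -log(R)
  # rows of q vary wavelength fastest within model
  aperm(array(od, dim = c(length(wavelengths), nrow(models),
                          length(distances))), c(2, 1, 3))
}

#' Synthesize optical-density spectra for a skin model
#'
#' For each wavelength the model's absorption triple is computed from the
#' chromophore tables, normalized, interpolated on the grid by KNN, and
#' converted to optical density `OD = -ln R`.
#'
#' @param grid a `simulation_grid`.
#' @param model a [skin_model()].
#' @param wavelengths nm (default 900--1075 nm in 5 nm steps).
#' @param distances mm, subset of the grid distance axis.
#' @param k KNN neighbors.
#' @return list of `od_spectrum` objects, one per distance.
#' @export
synthesize_od <- function(grid, model, wavelengths = seq(900, 1075, by = 5),
                          distances = grid$distances, k = 4) {
  stopifnot(inherits(model, "skin_model"))
  models <- as.data.frame(unclass(model))
  od <- synthesize_od_array(grid, models, wavelengths, distances, k)
  lapply(seq_along(distances), function(j)
    od_spectrum(wavelengths, od[1, , j], distance = distances[j],
                origin = "simulated"))
}

#' Persist / load a simulation grid
#'
#' The grid is stored as an RDS file with a JSON provenance sidecar
#' (`<path>.json`). Round trip is lossless.
#'
#' @param grid a `simulation_grid`.
#' @param path file path (conventionally `.rds`).
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "simulation_grid"))
  saveRDS(grid, path)
  jsonlite::write_json(grid$provenance, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) {
  grid <- readRDS(path)
  stopifnot(inherits(grid, "simulation_grid"))
  grid
}
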