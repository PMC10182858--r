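# Shared fixtures, built lazily and cached for the whole test run.

.test_cache <- new.env(parent = emptyenv())

# small grid for unit tests: coarse mua axis, two thicknesses per axis,
# distances kept short so a 3e4-photon budget populates every cell
tiny_grid <- function() {
  if (is.null(.test_cache$tiny_grid)) {
    sp <- grid_spec(n_mua_nodes = 4,
                    dermis_thicknesses = c(1, 1.75, 2.5),
                    hypodermis_thicknesses = c(0.5, 2, 5),
                    n_photons = 3e4,
                    distances = seq(0.5, 6, by = 0.5),
                    max_radius = 8)
    .test_cache$tiny_grid <- build_grid(sp, seed = 5)
  }
  .test_cache$tiny_grid
}

# analytic pseudo-grid with a smooth known response, for testing the KNN
# machinery itself (interpolation + hold-out validation) free of MC noise
analytic_grid <- function() {
  if (is.null(.test_cache$analytic_grid)) {
    sp <- grid_spec(n_mua_nodes = 8,
                    dermis_thicknesses = c(1, 1.5, 2, 2.5),
                    hypodermis_thicknesses = c(0.5, 1, 2, 3, 4, 5),
                    distances = seq(0.5, 10, by = 0.5))
    nodes <- expand.grid(mua1 = sp$mua_nodes, mua2 = sp$mua_nodes,
                         mua3 = sp$mua_nodes)
    geoms <- expand.grid(d1 = sp$dermis_thicknesses,
                         d2 = sp$hypodermis_thicknesses)
    nodes <- do.call(rbind, lapply(seq_len(nrow(geoms)), function(gi)
      data.frame(nodes, d_dermis = geoms$d1[gi],
                 d_hypodermis = geoms$d2[gi])))
    # smooth positive response decreasing in absorption and distance
    f <- function(n, r) exp(-0.5 * log1p(n$mua1) - 0.3 * log1p(n$mua2) -
                              0.1 * log1p(n$mua3) - 0.25 * r -
                              0.1 * n$d_dermis + 0.02 * n$d_hypodermis)
    R <- sapply(sp$distances, function(r) f(nodes, r))
    g <- structure(list(nodes = nodes, R = R, distances = sp$distances,
                        bounds = log(range(sp$mua_nodes)),
                        d1_range = range(sp$dermis_thicknesses),
                        d2_range = range(sp$hypodermis_thicknesses),
                        spec = sp,
                        provenance = list(mode = "analytic", seed = 0,
                                          n_photons = 0)),
                   class = "simulation_grid")
    g$features <- dermaspec:::grid_features(
      g, nodes$mua1, nodes$mua2, nodes$mua3,
      nodes$d_dermis, nodes$d_hypodermis)
    .test_cache$analytic_grid <- g
  }
  .test_cache$analytic_grid
}

# noiseless profile set with an exact affine link to a synthetic target,
# for inversion unit tests that need controllable structure
affine_profile_set <- function(n = 30, nd = 6, seed = 3) {
  withr::with_seed(seed, {
    distances <- seq(0.5, by = 0.5, length.out = nd)
    aw <- matrix(runif(n * nd, 0.1, 1), n, nd)
    al <- matrix(runif(n * nd, 0.05, 0.5), n, nd)
    targets <- data.frame(
      dermis_water = 0.2 + 0.6 * aw[, 2],
      dermis_thickness = 1 + 2 * al[, 3],
      hypodermis_thickness = runif(n, 0.5, 5))
    labeled_profile_set(aw, al, targets, distances)
  })
}
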