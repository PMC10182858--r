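test_that("normalize_mua maps the log grid to [0, 1]", {
  b <- log(c(0.001, 10))
  expect_equal(normalize_mua(0.001, b), 0)
  expect_equal(normalize_mua(10, b), 1)
  # geometric midpoint of the bounds
  expect_equal(normalize_mua(0.1, b), 0.5)
  expect_error(normalize_mua(0, b), "> 0")
  expect_error(normalize_mua(-1, b), "> 0")
})

test_that("grid spec validates and the minimal grid is complete and finite", {
  expect_error(grid_spec(mua_range = c(0, 1)), "mua_range")
  sp <- grid_spec(n_mua_nodes = 2, dermis_thicknesses = 1.5,
                  hypodermis_thicknesses = 2, n_photons = 5e3,
                  distances = c(1, 2), max_radius = 5)
  g <- suppressWarnings(build_grid(sp, seed = 2))
  expect_equal(nrow(g$nodes), 8)  # 2^3 mua triples x 1 geometry
  expect_true(all(is.finite(g$R) | is.na(g$R)))
  expect_true(all(g$R >= 0 & g$R <= 1, na.rm = TRUE))
  expect_identical(g$provenance$mode, "rescaled")
})

test_that("rescaled and direct builds agree within Monte Carlo error", {
  sp <- grid_spec(n_mua_nodes = 3, mua_range = c(0.05, 2),
                  dermis_thicknesses = 1.5, hypodermis_thicknesses = 2,
                  n_photons = 2e4, distances = c(0.5, 1, 2), max_radius = 5)
  gr <- build_grid(sp, mode = "rescaled", seed = 41)
  gd <- build_grid(sp, mode = "direct", seed = 42)
  # conservative 3 sigma bound from the binomial count at each cell
  se <- sqrt(pmax(gr$R, gd$R) / sp$n_photons)
  expect_true(all(abs(gr$R - gd$R) < 3 * sqrt(2) * se + 1e-12))
})

test_that("grid build is deterministic given the seed and round-trips", {
  sp <- grid_spec(n_mua_nodes = 2, dermis_thicknesses = 1,
                  hypodermis_thicknesses = 1, n_photons = 5e3,
                  distances = c(1, 2), max_radius = 5)
  g1 <- suppressWarnings(build_grid(sp, seed = 9))
  g2 <- suppressWarnings(build_grid(sp, seed = 9))
  expect_identical(g1$R, g2$R)
  path <- tempfile(fileext = ".rds")
  write_grid(g1, path)
  g3 <- read_grid(path)
  expect_identical(g1$R, g3$R)
  expect_identical(g1$nodes, g3$nodes)
  expect_true(file.exists(paste0(path, ".json")))
})

test_that("KNN is exact at nodes and convex between them", {
  g <- analytic_grid()
  idx <- c(1, 777, 4040, nrow(g$nodes))
  for (i in idx) {
    v <- knn_interpolate(g, g$nodes[i, ], k = 4)
    expect_equal(as.vector(v), unname(g$R[i, ]), tolerance = 1e-12)
  }
  # midway between two nodes differing only in mua1: convex combination
  n1 <- g$nodes[1, ]
  stopifnot(g$nodes$mua1[2] > g$nodes$mua1[1])
  # with k = 2 the two bracketing nodes are the nearest neighbors
  q <- n1
  q$mua1 <- exp(mean(log(c(g$nodes$mua1[1], g$nodes$mua1[2]))))
  v <- knn_interpolate(g, q, distance = 1, k = 2)
  lo <- min(g$R[1:2, 2]); hi <- max(g$R[1:2, 2])
  expect_gte(v[1], lo - 1e-12)
  expect_lte(v[1], hi + 1e-12)
})

test_that("KNN prediction stays within the neighbor range (random queries)", {
  g <- analytic_grid()
  qs <- withr::with_seed(77, data.frame(
    mua1 = exp(runif(25, log(0.001), log(10))),
    mua2 = exp(runif(25, log(0.001), log(10))),
    mua3 = exp(runif(25, log(0.001), log(10))),
    d_dermis = runif(25, 1, 2.5),
    d_hypodermis = runif(25, 0.5, 5)))
  v <- knn_interpolate(g, qs, distance = 1, k = 4)
  expect_true(all(v >= min(g$R[, 2]) & v <= max(g$R[, 2])))
})

test_that("queries outside the axis ranges raise an extrapolation error", {
  g <- analytic_grid()
  q <- g$nodes[1, ]
  q$mua1 <- 20
  expect_error(knn_interpolate(g, q), "outside")
  q <- g$nodes[1, ]
  q$d_dermis <- 0.5
  expect_error(knn_interpolate(g, q), "outside")
  expect_error(knn_interpolate(g, g$nodes[1, ], distance = 0.77),
               "distance axis")
})

test_that("hold-out validation machinery reports small error on a smooth grid", {
  g <- analytic_grid()
  v <- validate_grid(g, test_fraction = 0.05, k = 4, seed = 3)
  expect_lt(v$median_rel_error, 0.05)
  expect_equal(v$n_test, round(0.05 * nrow(g$nodes)))
  # CV k selection returns one of the candidates
  v2 <- validate_grid(g, test_fraction = 0.05, k = c(2, 4), seed = 3)
  expect_true(v2$k %in% c(2, 4))
})

test_that("synthesized OD is finite, positive and wetter skin absorbs more", {
  g <- tiny_grid()
  dry <- skin_model(dermis_water = 0.55, dermis_thickness = 1.75,
                    hypodermis_thickness = 2)
  wet <- skin_model(dermis_water = 0.95, dermis_thickness = 1.75,
                    hypodermis_thickness = 2)
  od_d <- synthesize_od(g, dry, distances = 1)[[1]]
  od_w <- synthesize_od(g, wet, distances = 1)[[1]]
  expect_true(all(is.finite(od_d$od)))
  expect_true(all(od_d$od > 0))
  i970 <- which(od_d$wavelengths == 970)
  expect_gt(od_w$od[i970], od_d$od[i970])
})

test_that("synthesis at an exact node equals -ln of the stored value", {
  g <- analytic_grid()
  # choose a model whose mua triple lands exactly on grid nodes: pick node
  # values and invert the chromophore scaling at one wavelength
  node <- g$nodes[123, ]
  q <- node
  R <- knn_interpolate(g, q, k = 4)
  expect_equal(-log(as.vector(R)), -log(unname(g$R[123, ])),
               tolerance = 1e-12)
})

test_that("reflectance decreases with dermal absorption at short distance", {
  g <- tiny_grid()
  # R at mua nodes is non-increasing in mua1 at fixed small r
  nodes <- g$nodes
  base <- nodes$mua2 == nodes$mua2[1] & nodes$mua3 == nodes$mua3[1] &
    nodes$d_dermis == 1.75 & nodes$d_hypodermis == 2
  sub <- which(base)
  ord <- order(nodes$mua1[sub])
  r1 <- g$R[sub[ord], 2]  # r = 1 mm
  expect_true(all(diff(r1) <= 1e-12))
})
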