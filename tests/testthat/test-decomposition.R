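test_that("compute_od matches the closed forms", {
  wl <- seq(900, 1000, by = 10)
  n <- length(wl)
  # I = Iref -> OD = 0
  m <- raw_measurement(wl, rep(1010, n), rep(10, n), rep(1010, n), 1)
  expect_equal(compute_od(m)$od, rep(0, n))
  # (I - Ibg) = (Iref - Ibg)/e -> OD = 1
  m <- raw_measurement(wl, rep(10 + 1000 / exp(1), n), rep(10, n),
                       rep(1010, n), 1)
  expect_equal(compute_od(m)$od, rep(1, n))
  # I=110, Ibg=10, Iref=1010 -> OD = ln 10
  m <- raw_measurement(wl, rep(110, n), rep(10, n), rep(1010, n), 1)
  expect_equal(compute_od(m)$od, rep(log(10), n))
})

test_that("non-positive net intensities are masked with a warning", {
  wl <- c(900, 910, 920, 930, 940)
  I <- c(110, 5, 110, 110, 110)  # second point below background
  m <- raw_measurement(wl, I, rep(10, 5), rep(1010, 5), 1)
  expect_warning(od <- compute_od(m), "masked")
  expect_true(is.na(od$od[2]))
  expect_false(anyNA(od$od[-2]))
  # non-positive reference is an error
  m2 <- raw_measurement(wl, I, rep(10, 5), rep(10, 5), 1)
  expect_error(compute_od(m2), "reference")
})

test_that("an exactly linear spectrum is recovered to 1e-10", {
  wl <- seq(900, 1075, by = 5)
  shapes <- list(water = normalized_shape(chromophore_spectrum("water")),
                 lipid = normalized_shape(chromophore_spectrum("lipid")))
  truth <- c(c0 = 0.2, c1 = 1e-4, a_water = 0.3, a_lipid = 0.1)
  od_v <- truth["c0"] + truth["c1"] * wl +
    truth["a_water"] * shape_at(shapes$water, wl) +
    truth["a_lipid"] * shape_at(shapes$lipid, wl)
  f <- fit_components(od_spectrum(wl, od_v, 1), shapes)
  expect_equal(f$c0, unname(truth["c0"]), tolerance = 1e-10)
  expect_equal(f$c1, unname(truth["c1"]), tolerance = 1e-10)
  expect_equal(f$a_water, unname(truth["a_water"]), tolerance = 1e-10)
  expect_equal(f$a_lipid, unname(truth["a_lipid"]), tolerance = 1e-10)
  expect_lt(f$residual_norm, 1e-10)
})

test_that("noisy amplitude estimates are unbiased with the analytic spread", {
  wl <- seq(900, 1075, by = 5)
  shapes <- default_shapes()
  X <- cbind(1, wl, shape_at(shapes$water, wl), shape_at(shapes$lipid, wl))
  beta <- c(0.2, 1e-4, 0.3, 0.1)
  mu <- drop(X %*% beta)
  sigma <- 0.01
  # closed-form OLS covariance oracle
  cov_beta <- sigma^2 * solve(crossprod(X))
  nrep <- 400
  est <- withr::with_seed(42, t(vapply(seq_len(nrep), function(i) {
    f <- fit_components(od_spectrum(wl, mu + rnorm(length(wl), 0, sigma), 1),
                        shapes)
    c(f$a_water, f$a_lipid)
  }, c(0, 0))))
  # unbiasedness within 4 standard errors of the replicate mean
  se_mean <- sqrt(diag(cov_beta)[3:4] / nrep)
  expect_lt(abs(mean(est[, 1]) - beta[3]), 4 * se_mean[1])
  expect_lt(abs(mean(est[, 2]) - beta[4]), 4 * se_mean[2])
  # spread matches the analytic covariance (chi-squared-ish window)
  expect_gt(sd(est[, 1]) / sqrt(cov_beta[3, 3]), 0.85)
  expect_lt(sd(est[, 1]) / sqrt(cov_beta[3, 3]), 1.15)
  expect_gt(sd(est[, 2]) / sqrt(cov_beta[4, 4]), 0.85)
  expect_lt(sd(est[, 2]) / sqrt(cov_beta[4, 4]), 1.15)
})

test_that("fit is scale-equivariant and noise strictly increases residual", {
  wl <- seq(900, 1075, by = 5)
  shapes <- default_shapes()
  od_v <- 0.1 + 2e-4 * wl + 0.25 * shape_at(shapes$water, wl) +
    0.15 * shape_at(shapes$lipid, wl)
  f1 <- fit_components(od_spectrum(wl, od_v, 1), shapes)
  f3 <- fit_components(od_spectrum(wl, 3 * od_v, 1), shapes)
  expect_equal(c(f3$c0, f3$c1, f3$a_water, f3$a_lipid),
               3 * c(f1$c0, f1$c1, f1$a_water, f1$a_lipid), tolerance = 1e-9)
  noisy <- withr::with_seed(1, od_v + rnorm(length(wl), 0, 0.01))
  fn <- fit_components(od_spectrum(wl, noisy, 1), shapes)
  expect_gt(fn$residual_norm, f1$residual_norm)
})

test_that("degenerate designs fail loudly, masked points are dropped", {
  wl <- seq(900, 1075, by = 5)
  shapes <- default_shapes()
  # collinear shapes: lipid replaced by water
  bad <- list(water = shapes$water, lipid = shapes$water)
  od <- od_spectrum(wl, rep(1, length(wl)), 1)
  expect_error(fit_components(od, bad), "collinear")
  # too few usable points
  od2 <- od_spectrum(wl, c(1, 1, 1, rep(NA, length(wl) - 3)), 1)
  expect_error(fit_components(od2, shapes), "at least 4")
  # masked points are dropped, not imputed
  odv <- 0.2 + 1e-4 * wl + 0.3 * shape_at(shapes$water, wl)
  odv_masked <- odv
  odv_masked[5:8] <- NA
  f <- fit_components(od_spectrum(wl, odv_masked, 1), shapes)
  expect_equal(f$a_water, 0.3, tolerance = 1e-9)
  expect_equal(f$n_points, length(wl) - 4)
})

test_that("profiles assemble per distance, rejecting duplicates", {
  wl <- seq(900, 1075, by = 5)
  shapes <- default_shapes()
  mk <- function(r, aw) od_spectrum(
    wl, 0.1 + aw * shape_at(shapes$water, wl), r)
  prof <- profile_over_distances(list(mk(2, 0.4), mk(1, 0.2)), shapes)
  expect_equal(prof$distance, c(1, 2))
  expect_equal(prof$a_water, c(0.2, 0.4), tolerance = 1e-9)
  single <- profile_over_distances(mk(1, 0.2), shapes)
  f <- fit_components(mk(1, 0.2), shapes)
  expect_equal(single$a_water, f$a_water)
  expect_error(profile_over_distances(list(mk(1, 0.1), mk(1, 0.2)), shapes),
               "duplicate")
})

test_that("batch decomposition matches per-spectrum fits", {
  wl <- seq(900, 1075, by = 5)
  shapes <- default_shapes()
  sw <- shape_at(shapes$water, wl)
  sl <- shape_at(shapes$lipid, wl)
  od <- array(0, dim = c(2, length(wl), 3))
  pars <- expand.grid(m = 1:2, d = 1:3)
  for (i in 1:2) for (j in 1:3)
    od[i, , j] <- 0.1 * i + 1e-4 * j * wl + (0.1 * i + 0.05 * j) * sw +
      0.02 * j * sl
  fits <- dermaspec:::fit_components_array(od, wl, shapes)
  for (i in 1:2) for (j in 1:3) {
    f <- fit_components(od_spectrum(wl, od[i, , j], j), shapes)
    expect_equal(fits$a_water[i, j], f$a_water, tolerance = 1e-10)
    expect_equal(fits$a_lipid[i, j], f$a_lipid, tolerance = 1e-10)
    expect_equal(fits$c0[i, j], f$c0, tolerance = 1e-10)
  }
})
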