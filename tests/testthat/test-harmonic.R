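test_that("design matrix rows evaluate the harmonics", {
  X <- build_design_matrix(c(0, 0.25, 0.4), m = 1)
  expect_equal(X[1, ], c(a0 = 1, a1 = 1, b1 = 0), tolerance = 1e-12)
  expect_equal(X[2, ], c(a0 = 1, a1 = 0, b1 = 1), tolerance = 1e-12)
  X2 <- build_design_matrix(c(0.5, 0.1, 0.2, 0.3, 0.7), m = 2)
  expect_equal(unname(X2[1, ]), c(1, -1, 0, 1, 0), tolerance = 1e-12)
  expect_error(build_design_matrix(c(0, 0.1, 0.2, 0.2), m = 2), "at least 5")
})

test_that("OLS recovers noise-free harmonic signals exactly", {
  t23 <- (0:22) * 16 / 365
  # constant series
  fit0 <- fit_harmonic(t23, rep(0.37, 23), m = 2)
  expect_equal(fit0$a0, 0.37, tolerance = 1e-10)
  expect_equal(c(fit0$a, fit0$b), rep(0, 4), tolerance = 1e-10)
  # single harmonic
  y1 <- 0.3 + 0.2 * cos(2 * pi * t23)
  fit1 <- fit_harmonic(t23, y1, m = 1)
  expect_equal(c(fit1$a0, fit1$a, fit1$b), c(0.3, 0.2, 0), tolerance = 1e-8)
  # two harmonics, all five coefficients
  y2 <- 0.25 + 0.15 * cos(2 * pi * t23) - 0.05 * sin(2 * pi * t23) +
    0.04 * cos(4 * pi * t23) + 0.02 * sin(4 * pi * t23)
  fit2 <- fit_harmonic(t23, y2, m = 2)
  expect_equal(c(fit2$a0, fit2$a[1], fit2$b[1], fit2$a[2], fit2$b[2]),
               c(0.25, 0.15, -0.05, 0.04, 0.02), tolerance = 1e-8)
  expect_equal(fit2$rmse, 0, tolerance = 1e-8)
})

test_that("coefficients agree with a normal-equations oracle on noisy data", {
  set.seed(7)
  for (m in 1:2) {
    t <- sort(runif(20))
    y <- 0.2 + 0.3 * cos(2 * pi * t) + rnorm(20, 0, 0.1)
    fit <- fit_harmonic(t, y, m = m)
    X <- build_design_matrix(t, m)
    oracle <- solve(t(X) %*% X, t(X) %*% y)[, 1]
    expect_equal(unname(c(fit$a0, rbind(fit$a, fit$b))), unname(oracle),
                 tolerance = 1e-8)
    # residual orthogonality to the design columns
    resid <- y - reconstruct(fit, t)
    expect_lt(max(abs(t(X) %*% resid)), 1e-8)
  }
})

test_that("degenerate designs are rejected", {
  # times aliasing the annual sine to zero: full count, deficient rank
  expect_error(fit_harmonic(c(0, 0.5, 1, 1.5), c(1, 2, 1, 2), m = 1), "rank")
  expect_error(fit_harmonic(rep(0.3, 10), rnorm(10), m = 1), "distinct")
})

test_that("reconstruction inverts the fit and smooths noise", {
  fit <- structure(list(a0 = 0.3, a = 0.2, b = 0, m = 1L, omega = 1,
                        n_obs_used = 23L, rmse = 0), class = "harmonic_fit")
  expect_equal(reconstruct(fit, 0), 0.5)
  expect_equal(reconstruct(fit, 0.5), 0.1)
  # smoothing: reconstruction variance below raw variance, 100 seeded pixels
  set.seed(11)
  t <- (0:22) * 16 / 365
  worse <- 0
  for (i in 1:100) {
    y <- 0.4 + 0.25 * cos(2 * pi * (t - runif(1))) + rnorm(23, 0, 0.08)
    f <- fit_harmonic(t, y, m = 2)
    if (var(reconstruct(f, t)) > var(y)) worse <- worse + 1
  }
  expect_equal(worse, 0)
})

test_that("phenology features match analytic extrema of the fitted curve", {
  const <- fit_harmonic((0:22) / 23, rep(0.42, 23), m = 1)
  feats <- extract_phenology_features(list(NDVI = const), wf = 0.1)
  expect_equal(unname(feats[c("ndvi_max", "ndvi_min", "ndvi_range")]),
               c(0.42, 0.42, 0), tolerance = 1e-10)
  expect_equal(unname(feats["wf"]), 0.1)
  fit <- structure(list(a0 = 0.3, a = 0.2, b = 0, m = 1L, omega = 1,
                        n_obs_used = 23L, rmse = 0), class = "harmonic_fit")
  f2 <- extract_phenology_features(list(NDVI = fit),
                                   wf = list(wf = 0.2, n_water = 2,
                                             n_observation = 10))
  expect_equal(unname(f2["ndvi_max"]), 0.5, tolerance = 1e-4)
  expect_equal(unname(f2["ndvi_min"]), 0.1, tolerance = 1e-4)
  expect_equal(unname(f2["ndvi_range"]), 0.4, tolerance = 1e-4)
  # daily-sampled maximum vs a0 + amplitude for a random m=1 fit
  set.seed(3)
  for (i in 1:10) {
    a1 <- rnorm(1, 0, 0.3); b1 <- rnorm(1, 0, 0.3)
    f <- structure(list(a0 = 0.2, a = a1, b = b1, m = 1L, omega = 1,
                        n_obs_used = 23L, rmse = 0), class = "harmonic_fit")
    mx <- max(reconstruct(f, (0:364) / 365))
    expect_equal(mx, 0.2 + sqrt(a1^2 + b1^2), tolerance = 1e-4)
  }
})

test_that("amplitude and phase recover from sparse noisy series", {
  set.seed(21)
  amp_err <- phase_err <- numeric(50)
  for (i in 1:50) {
    t <- sort(sample((0:22) * 16 / 365, 20))
    phase <- runif(1, 0, 1)
    y <- 0.4 + 0.3 * cos(2 * pi * (t - phase)) + rnorm(20, 0, 0.05)
    f <- fit_harmonic(t, y, m = 1)
    amp_err[i] <- abs(sqrt(f$a[1]^2 + f$b[1]^2) - 0.3) / 0.3
    est_phase <- (atan2(f$b[1], f$a[1]) / (2 * pi)) %% 1
    d <- abs(est_phase - phase)
    phase_err[i] <- min(d, 1 - d)
  }
  expect_lt(mean(amp_err), 0.05)
  expect_lt(mean(phase_err), 0.02)
})

test_that("fitted cordgrass pixels peak in early summer, bottom in winter", {
  sc <- generate_scene(noise_free_config())
  cls <- as.integer(sc$class_raster$values)
  ser <- scene_index_series(sc, "NDVI")
  pix <- which(cls == 1)[1:5]
  for (i in pix) {
    fit <- fit_harmonic(ser$times, ser$values[i, ], ser$valid[i, ], m = 2)
    pk <- peak_doy(fit)
    # May-July
    expect_true(pk >= 121 && pk <= 212)
    trough <- which.min(reconstruct(fit, (0:364) / 365))
    # November-January
    expect_true(trough >= 305 || trough <= 31)
  }
})

test_that("scene features flag under-observed pixels as no-data", {
  cfg <- scene_config(width = 8, height = 8, cloud_gap_fraction = 0.9,
                      cloud_spatial_sd = 0, seed = 5)
  sc <- generate_scene(cfg)
  feat <- scene_features(sc, m = 2)
  ok <- attr(feat, "ok")
  few <- rowSums(sc$valid) < 5
  expect_true(all(!ok[few]))
})
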