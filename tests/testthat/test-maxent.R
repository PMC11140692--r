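test_that("occurrence de-duplication keeps the first point per cell", {
  grid <- cg_raster(matrix(0, 10, 10))
  pts <- data.frame(x = 0, y = 0, cell = c(5, 9, 5, 22, 81))
  occ <- dedupe_occurrences(pts, grid)
  expect_equal(occ$cell, c(5, 9, 22, 81))
  expect_equal(attr(occ, "n_raw"), 5)
  # all-distinct input is the identity
  pts2 <- data.frame(x = 0, y = 0, cell = c(3, 7, 11))
  expect_equal(dedupe_occurrences(pts2, grid)$cell, pts2$cell)
  expect_error(dedupe_occurrences(pts2[0, ], grid), "empty")
  # coordinates are binned to cells when no cell index is given
  xy <- cell_xy(grid, c(14, 14, 60))
  occ3 <- dedupe_occurrences(data.frame(x = xy$x, y = xy$y), grid)
  expect_equal(occ3$cell, c(14, 60))
})

test_that("correlation pruning drops the right layers", {
  set.seed(13)
  z <- matrix(rnorm(400), 20, 20)
  stack <- manual_stack(a = z, b = z, c = matrix(rnorm(400), 20, 20))
  pruned <- prune_variables(stack)
  ret <- vapply(pruned$layers, function(l) l$retained, logical(1))
  expect_equal(sum(ret[c("a", "b")]), 1)   # exactly one of the twins
  expect_true(ret[["c"]])
  # independent layers all survive
  ind <- manual_stack(a = matrix(rnorm(10000), 100, 100),
                      b = matrix(rnorm(10000), 100, 100),
                      c = matrix(rnorm(10000), 100, 100))
  ret2 <- vapply(prune_variables(ind)$layers, function(l) l$retained,
                 logical(1))
  expect_true(all(ret2))
  # constant layers are dropped with a warning
  expect_warning(
    pc <- prune_variables(manual_stack(a = matrix(1, 5, 5),
                                       b = matrix(rnorm(25), 5, 5))),
    "constant")
  expect_false(pc$layers$a$retained)
})

test_that("pruning a 16-variable candidate set retains 12", {
  set.seed(17)
  n <- 2500
  parents <- c("sst1", "sst2", "sst5", "climt1", "climt3", "climt4",
               "climp1", "sali", "sali_mean", "dem", "slope")
  vals <- lapply(parents, function(nm) rnorm(n))
  names(vals) <- parents
  derive <- function(p1, p2) {
    0.9 * vals[[p1]] + 0.3 * vals[[p2]] + sqrt(1 - 0.81 - 0.09) * rnorm(n)
  }
  vals$sst3 <- derive("sst2", "sst5")
  vals$sst4 <- derive("sst5", "sst1")
  vals$climt2 <- derive("climt4", "climt1")
  vals$climp2 <- derive("climp1", "sali")
  args <- lapply(vals, function(v) matrix(v, 50, 50))
  args$soiltype <- matrix(sample(1:3, n, replace = TRUE), 50, 50)
  stack <- do.call(manual_stack,
                   c(args, list(types = c(rep("continuous", 15), "categorical"))))
  pruned <- prune_variables(stack, r_threshold = 0.75)
  ret <- names(Filter(function(l) l$retained, pruned$layers))
  expect_length(ret, 12)
  expect_setequal(setdiff(names(stack$layers), ret),
                  c("sst3", "sst4", "climt2", "climp2"))
})

test_that("one-binary-feature fit matches the closed form", {
  f1 <- matrix(rep(c(0, 1), each = 50), 10, 10)
  stack <- manual_stack(env1 = f1)
  occ <- manual_occurrences(which(as.vector(f1) == 1)[1:10], cg_raster(f1))
  for (beta in c(0.02, 0.05, 0.1, 0.2)) {
    m <- fit_maxent(occ, stack, beta = beta, tol = 1e-12)
    lam_true <- log((1 - beta) * 50 / (beta * 50))
    expect_equal(unname(m$lambda), lam_true, tolerance = 1e-6)
  }
  # heavier regularisation shrinks the weight monotonically
  lams <- vapply(c(0.02, 0.05, 0.1, 0.2), function(b) {
    unname(fit_maxent(occ, stack, beta = b, tol = 1e-12)$lambda)
  }, numeric(1))
  expect_true(all(diff(lams) < 0))
})

test_that("coordinate descent matches a convex-optimizer oracle", {
  for (seed in c(5, 6)) {
    sdm <- simulate_sdm_scene(width = 20, height = 20, n_presences = 80,
                              seed = seed)
    mod <- fit_maxent(sdm$occurrences, sdm$stack, tol = 1e-12)
    Fb <- mod$feature_matrix[mod$bg_cells, , drop = FALSE]
    fbar <- colMeans(mod$feature_matrix[sdm$occurrences$cell, , drop = FALSE])
    oracle <- maxent_oracle(Fb, fbar, mod$beta)
    expect_equal(unname(mod$lambda), oracle, tolerance = 1e-4)
    # raw distribution normalises over the background
    raw <- exp(as.vector(Fb %*% mod$lambda) - mod$logZ)
    expect_lt(abs(sum(raw) - 1), 1e-9)
  }
})

test_that("with no penalty the fitted expectations match presence means", {
  sdm <- simulate_sdm_scene(width = 15, height = 15, n_presences = 120,
                            intercept = -1, seed = 9)
  mod <- fit_maxent(sdm$occurrences, sdm$stack, beta = 0, tol = 1e-14,
                    max_iter = 5000)
  Fb <- mod$feature_matrix[mod$bg_cells, , drop = FALSE]
  p <- exp(as.vector(Fb %*% mod$lambda) - mod$logZ)
  fitted_mean <- as.vector(t(Fb) %*% p)
  fbar <- colMeans(mod$feature_matrix[sdm$occurrences$cell, , drop = FALSE])
  expect_equal(fitted_mean, unname(fbar), tolerance = 1e-6)
})

test_that("featureless landscapes give the uniform distribution", {
  stack <- manual_stack(env1 = matrix(0.7, 10, 10))
  occ <- manual_occurrences(c(1, 5, 9, 22, 33), cg_raster(matrix(0, 10, 10)))
  expect_warning(mod <- fit_maxent(occ, stack), NA)
  raw <- exp(as.vector(mod$feature_matrix[mod$bg_cells, , drop = FALSE] %*%
                         mod$lambda) - mod$logZ)
  expect_true(all(abs(raw - 1 / 100) < 1e-12))
  # raw * exp(H) = 1 everywhere, so the logistic output is 1/3 at tau = 0.5
  expect_equal(unname(logistic_output(mod)), rep(1 / 3, 100), tolerance = 1e-12)
})

test_that("logistic output is a strictly increasing transform of raw", {
  sdm <- simulate_sdm_scene(width = 15, height = 15, n_presences = 60, seed = 2)
  mod <- fit_maxent(sdm$occurrences, sdm$stack)
  raw <- exp(as.vector(mod$feature_matrix %*% mod$lambda) - mod$logZ)
  lo <- logistic_output(mod, cells = seq_along(raw))
  expect_equal(order(raw), order(lo))
  expect_true(all(lo > 0 & lo < 1))
  # direct algebra of the transform
  expect_equal(logistic_output(mod, raw = exp(-mod$entropy)), 1 / 3)
  expect_equal(logistic_output(mod, raw = 2 * exp(-mod$entropy)), 0.5)
})

test_that("rank AUC enumerates concordant pairs with half ties", {
  expect_equal(roc_auc(c(0.9, 0.8), c(0.1, 0.2)), 1)
  expect_equal(roc_auc(c(0.5, 0.5), c(0.5, 0.5, 0.5)), 0.5)
  expect_equal(roc_auc(c(0.8, 0.4), c(0.6, 0.5, 0.2)), 4 / 6)
  expect_error(roc_auc(numeric(0), 1), "non-empty")
  # invariance under strictly increasing transforms
  set.seed(3)
  p <- runif(20); b <- runif(30)
  expect_equal(roc_auc(p, b), roc_auc(exp(3 * p), exp(3 * b)))
  expect_equal(roc_auc(p, b), roc_auc(qlogis(p), qlogis(b)))
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  p <- rnorm(40, 1); b <- rnorm(60)
  ours <- roc_auc(p, b)
  theirs <- as.numeric(pROC::auc(
    pROC::roc(response = rep(c(1, 0), c(40, 60)), predictor = c(p, b),
              quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("replicated evaluation is seeded and separable data give AUC 1", {
  sdm <- simulate_sdm_scene(width = 20, height = 20, n_presences = 150, seed = 4)
  e1 <- evaluate_replicates(sdm$occurrences, sdm$stack, n_replicates = 3,
                            seed = 7)
  e2 <- evaluate_replicates(sdm$occurrences, sdm$stack, n_replicates = 3,
                            seed = 7)
  expect_identical(e1$auc, e2$auc)
  expect_identical(raster_values(e1$mean_map), raster_values(e2$mean_map))
  # perfectly informative feature, presences at the very top of the gradient,
  # background drawn outside the occupied cells: separable, test AUC 1
  u <- matrix(seq(0, 1, length.out = 400), 20, 20)
  stack <- manual_stack(env1 = u)
  pres_cells <- order(as.vector(u), decreasing = TRUE)[1:20]
  occ <- manual_occurrences(pres_cells, cg_raster(u))
  ev <- evaluate_replicates(occ, stack, n_replicates = 1, seed = 1,
                            background = setdiff(seq_len(400), pres_cells))
  expect_equal(ev$auc, 1)
  expect_error(evaluate_replicates(occ[1:4, ], stack), "few presences")
})

test_that("percent contribution attributes gain to the driving variable", {
  sdm1 <- simulate_sdm_scene(width = 20, height = 20, n_continuous = 1,
                             suitability_weights = 3, n_presences = 100,
                             seed = 3)
  pc1 <- percent_contribution(fit_maxent(sdm1$occurrences, sdm1$stack))
  expect_equal(unname(pc1), 100)
  # two symmetric, equally informative, independent variables: near-even
  # split on average over seeded fixtures
  pcs <- sapply(1:6, function(s) {
    cfg <- scene_config(width = 40, height = 40, seed = 100 + s)
    env <- generate_env_layers(cfg, n_continuous = 2,
                               suitability_weights = c(2, 2), intercept = -4,
                               seed = 100 + s)
    occ <- dedupe_occurrences(
      sample_presences(env$suitability, 300, seed = 200 + s), env$suitability)
    percent_contribution(fit_maxent(occ, env$stack))["env1"]
  })
  expect_equal(mean(pcs), 50, tolerance = 5)
})

test_that("permutation importance isolates single-variable effects", {
  sdm <- simulate_sdm_scene(width = 25, height = 25, n_presences = 150, seed = 6)
  mod <- fit_maxent(sdm$occurrences, sdm$stack)
  imp <- permutation_importance(mod, n_perm = 20, seed = 1)
  expect_equal(sum(imp), 100)
  expect_lt(imp[["env2"]], 2)      # zero-weight variable
  expect_gt(imp[["env1"]], 98)     # sole informative variable
})

test_that("the driving variable wins the importance race across scenes", {
  wins <- 0
  for (s in 1:100) {
    sdm <- simulate_sdm_scene(width = 15, height = 15, n_presences = 60,
                              seed = 1000 + s)
    mod <- fit_maxent(sdm$occurrences, sdm$stack)
    imp <- permutation_importance(mod, n_perm = 3, seed = s)
    if (imp[["env1"]] > imp[["env2"]]) wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("response curves reflect the fitted feature weights", {
  sdm <- simulate_sdm_scene(width = 20, height = 20, n_presences = 120, seed = 8)
  mod <- fit_maxent(sdm$occurrences, sdm$stack)
  rc1 <- response_curve(mod, "env1")
  rc2 <- response_curve(mod, "env2")
  expect_true(all(diff(rc1$suitability) > 0))          # positive weight
  expect_lt(diff(range(rc2$suitability)), 1e-6)        # zero weight: flat
  expect_error(response_curve(mod, "nope"), "unknown variable")
})

test_that("opposing linear and quadratic features recover a unimodal optimum", {
  set.seed(19)
  u <- matrix(runif(900), 30, 30)
  stack <- manual_stack(lin = u, quad = u^2)
  suit <- cg_raster(stats::plogis(-3 + 10 * u - 10 * u^2))
  occ <- dedupe_occurrences(sample_presences(suit, 400, seed = 20), suit)
  # light regularisation: the two features are strongly collinear and the
  # default penalty flattens the curvature the check is about
  mod <- fit_maxent(occ, stack, beta_scale = 0.1, tol = 1e-12)
  grid <- data.frame(lin = seq(0, 1, length.out = 1001))
  grid$quad <- grid$lin^2
  curve <- predict(mod, grid, type = "exponent")
  est <- grid$lin[which.max(curve)]
  # analytic optimum of the truth law at u = 0.5
  expect_equal(est, 0.5, tolerance = 0.05)
  # and the grid maximum matches the calculus optimum of the fitted exponent
  sc_l <- mod$scales[["lin"]]; sc_q <- mod$scales[["quad"]]
  a <- mod$lambda[["lin"]] / sc_l[["range"]]
  b <- mod$lambda[["quad"]] / sc_q[["range"]]
  expect_equal(est, unname(-a / (2 * b)), tolerance = 0.01)
})

test_that("threshold selection maximises sensitivity plus specificity", {
  expect_equal(threshold_max_ss(c(0.8, 0.6, 0.3), c(0.7, 0.2, 0.1)), 0.3)
  # perfectly separated: lowest observed presence score
  expect_equal(threshold_max_ss(c(0.9, 0.8, 0.7), c(0.3, 0.2)), 0.7)
  expect_error(threshold_max_ss(numeric(0), 1), "non-empty")
  # brute-force cross-check over random score sets
  set.seed(23)
  for (i in 1:20) {
    p <- round(runif(8), 2); b <- round(runif(12), 2)
    cand <- sort(unique(c(p, b)))
    ss <- vapply(cand, function(t) mean(p >= t) + mean(b < t), numeric(1))
    expect_equal(threshold_max_ss(p, b), cand[which.max(ss)])
  }
})

test_that("tier classification partitions the potential region", {
  suit <- cg_raster(matrix(c(0.9, 0.8, 0.7, 0.6, 0.5, 0.1, 0.1, 0.1, 0.1),
                           3, 3), pixel_size = 100)
  sa <- cg_raster(matrix(c(1, 0, 0, 0, 0, 0, 0, 0, 0), 3, 3))
  mg <- cg_raster(matrix(c(0, 1, 1, 0, 0, 0, 0, 0, 0), 3, 3))
  tf <- cg_raster(matrix(c(0, 0, 0, 1, 1, 0, 0, 0, 0), 3, 3))
  tm <- classify_tiers(suit, 0.4, sa, mg, tf)
  tiers <- raster_values(tm$tiers)
  expect_equal(sum(tiers == 3), 1)   # high
  expect_equal(sum(tiers == 1), 2)   # least
  expect_equal(sum(tiers == 2), 2)   # moderate
  expect_equal(sum(tiers == 0), 4)
  row <- tm$table[tm$table$region == "whole zone", ]
  expect_equal(c(row$high_pct, row$least_pct, row$moderate_pct), c(20, 40, 40))
  expect_equal(row$total_hm2, 5 * 1)   # 100 m pixels: 1 hm^2 each
  # tier areas sum to the regional potential exactly
  expect_equal(row$high_hm2 + row$moderate_hm2 + row$least_hm2, row$total_hm2)
  # threshold above all suitabilities empties every tier
  tm0 <- classify_tiers(suit, 0.95, sa, mg, tf)
  expect_true(all(raster_values(tm0$tiers) == 0))
  expect_equal(tm0$table$total_hm2, 0)
})

test_that("mask precedence is high over least over moderate", {
  suit <- cg_raster(matrix(1, 2, 2), pixel_size = 100)
  both <- cg_raster(matrix(1, 2, 2))
  tm <- classify_tiers(suit, 0.5, sa_mask = both, mangrove_mask = both,
                       tidalflat_mask = both)
  expect_true(all(raster_values(tm$tiers) == 3))
  tm2 <- classify_tiers(suit, 0.5, sa_mask = NULL, mangrove_mask = both,
                        tidalflat_mask = both)
  expect_true(all(raster_values(tm2$tiers) == 1))
})
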