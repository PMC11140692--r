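# Shared fixtures, built in code. Expensive ones are memoised per session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# fully deterministic scene: no gaps, no noise, no outliers, no pixel effects
noise_free_config <- function(width = 12, height = 12, ...) {
  scene_config(width = width, height = height, cloud_gap_fraction = 0,
               cloud_spatial_sd = 0, outlier_fraction = 0, noise_sd = 0,
               pixel_level_sd = 0, pixel_amp_sd = 0, ...)
}

# small default-noise scene reused across classification tests
small_default_scene <- function() {
  cached("small_default_scene", generate_scene(scene_config(width = 24, height = 24)))
}

# clean, well-separated scene for ensemble sanity checks
separable_scene <- function() {
  cached("separable_scene", {
    generate_scene(scene_config(width = 40, height = 40, noise_sd = 0.01,
                                outlier_fraction = 0, cloud_spatial_sd = 0,
                                pixel_level_sd = 0.005, pixel_amp_sd = 0.05,
                                seed = 3))
  })
}

# expected index values computed directly from a phenology profile (an
# independent re-derivation of the generator's arithmetic)
profile_index <- function(profile, doy, index) {
  band <- function(b) {
    profile[b, "mean"] +
      profile[b, "amp"] * cos(2 * pi * (doy - profile[b, "peak_doy"]) / 365)
  }
  switch(index,
    NDVI = (band("nir") - band("red")) / (band("nir") + band("red")),
    NDWI = (band("green") - band("nir")) / (band("green") + band("nir"))
  )
}

# hand-rolled env stack from plain matrices
manual_stack <- function(..., types = NULL) {
  mats <- list(...)
  nms <- names(mats)
  if (is.null(types)) types <- rep("continuous", length(mats))
  layers <- lapply(seq_along(mats), function(i) {
    list(name = nms[i], type = types[i],
         raster = cg_raster(mats[[i]]), retained = TRUE)
  })
  names(layers) <- nms
  structure(list(layers = layers), class = "env_stack")
}

manual_occurrences <- function(cells, grid) {
  xy <- cell_xy(grid, cells)
  out <- data.frame(x = xy$x, y = xy$y, cell = cells)
  class(out) <- c("occurrence_set", "data.frame")
  out
}

# independent L-BFGS-B oracle for the penalized maxent objective, using a
# positive/negative split of the weights to handle the L1 term smoothly
maxent_oracle <- function(Fb, fbar, beta) {
  J <- ncol(Fb)
  nll <- function(ab) {
    lam <- ab[1:J] - ab[(J + 1):(2 * J)]
    -(sum(lam * fbar) - log(sum(exp(Fb %*% lam))) -
        sum(beta * (ab[1:J] + ab[(J + 1):(2 * J)])))
  }
  o <- stats::optim(rep(0, 2 * J), nll, method = "L-BFGS-B", lower = 0,
                    control = list(maxit = 5000, factr = 1e3))
  o$par[1:J] - o$par[(J + 1):(2 * J)]
}
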