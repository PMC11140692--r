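#' Land-cover classes used throughout the package
#'
#' Six coastal-zone cover types: invasive cordgrass (*Spartina alterniflora*),
#' mangrove, bare mudflat, aquaculture raft, seawater and artificial surface.
#' The integer coding (1..6, in this order) is the tie-break order for
#' classifier votes.
#' @export
scene_classes <- function() {
  c("spartina", "mangrove", "mudflat", "raft", "seawater", "artificial")
}

#' Bands simulated by the scene generator
#' @export
scene_bands <- function() c("blue", "green", "red", "nir", "swir1")

#' Configuration for a synthetic reflectance scene
#'
#' Describes a Landsat-like acquisition: 30 m pixels on a 16-day revisit
#' grid, with per-observation cloud gaps, additive Gaussian band noise and
#' occasional undetected cloud/shadow spikes.
#'
#' @param width,height scene size in pixels.
#' @param pixel_size pixel edge, metres.
#' @param start_date,end_date observation window (coercible to `Date`).
#' @param revisit_days days between observations.
#' @param cloud_gap_fraction mean probability in `[0,1)` that an
#'   observation is masked out (detected cloud). Gaps are seasonally
#'   modulated (see `cloud_season_strength`) but average to this fraction
#'   over the date grid.
#' @param cloud_season_strength concentration of the seasonal cloud cycle
#'   (von Mises-style, peaking in late July as in a subtropical monsoon
#'   climate). 0 gives uniform gaps; the default 1 makes wet-season
#'   observations roughly seven times more likely to be masked than
#'   winter ones.
#' @param cloud_spatial_sd log-scale standard deviation of a smooth
#'   per-pixel cloudiness factor: cloud cover is spatially correlated, so
#'   some pixels retain most of their observations while others keep only
#'   a handful. 0 gives identically distributed gaps at every pixel.
#' @param outlier_fraction probability that a *valid* observation carries an
#'   undetected spike.
#' @param outlier_magnitude spike size, reflectance units; sign is random
#'   (bright cloud vs. dark shadow) and shared across bands of an
#'   observation.
#' @param noise_sd additive Gaussian noise per band-observation,
#'   reflectance units.
#' @param pixel_level_sd per-pixel, per-band baseline reflectance shift
#'   (standard deviation, reflectance units): substrate and canopy-cover
#'   heterogeneity within a class.
#' @param pixel_amp_sd log-scale standard deviation of a per-pixel
#'   multiplicative factor on the seasonal amplitude (biomass / cover
#'   fraction variability).
#' @param class_map_spec `"blocks"` (contiguous class blocks plus a mixed
#'   border strip) or an integer matrix of class codes 1..6 of the scene's
#'   dimensions.
#' @param seed integer RNG seed; scenes are bit-identical for a fixed seed.
#' @return a `scene_config` list.
#' @export
scene_config <- function(width = 64, height = 64, pixel_size = 30,
                         start_date = "2019-01-01", end_date = "2019-12-31",
                         revisit_days = 16,
                         cloud_gap_fraction = 0.2,
                         cloud_season_strength = 1,
                         cloud_spatial_sd = 0.2,
                         outlier_fraction = 0.05,
                         outlier_magnitude = 0.2,
                         noise_sd = 0.05,
                         pixel_level_sd = 0.02,
                         pixel_amp_sd = 0.1,
                         class_map_spec = "blocks",
                         seed = 1L) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  if (!(end_date > start_date)) stop("end_date must be after start_date")
  if (cloud_gap_fraction < 0 || cloud_gap_fraction >= 1) {
    stop("cloud_gap_fraction must be in [0, 1)")
  }
  if (outlier_fraction < 0 || outlier_fraction > 1) {
    stop("outlier_fraction must be in [0, 1]")
  }
  stopifnot(pixel_size > 0, width >= 1, height >= 1, revisit_days >= 1)
  structure(
    list(width = as.integer(width), height = as.integer(height),
         pixel_size = pixel_size, start_date = start_date,
         end_date = end_date, revisit_days = as.integer(revisit_days),
         cloud_gap_fraction = cloud_gap_fraction,
         cloud_season_strength = cloud_season_strength,
         cloud_spatial_sd = cloud_spatial_sd,
         outlier_fraction = outlier_fraction,
         outlier_magnitude = outlier_magnitude,
         noise_sd = noise_sd, pixel_level_sd = pixel_level_sd,
         pixel_amp_sd = pixel_amp_sd, class_map_spec = class_map_spec,
         seed = as.integer(seed)),
    class = "scene_config"
  )
}

scene_dates <- function(config) {
  d <- seq(config$start_date, config$end_date, by = config$revisit_days)
  if (length(d) < 3) {
    stop("date range yields fewer than 3 observations; ",
         "time series too short for fitting", call. = FALSE)
  }
  d
}

# fractional years since Jan 1 of the start year
date_to_fyear <- function(dates, origin_year) {
  origin <- as.Date(sprintf("%d-01-01", origin_year))
  as.numeric(dates - origin) / 365
}

#' Seasonal reflectance profiles per cover class
#'
#' Each class carries, per band, a mean reflectance, an annual-harmonic
#' amplitude and a peak day-of-year:
#' `rho(t) = mean + amp * cos(2*pi*(doy - peak)/365)`.
#' The profiles are calibrated qualitatively: cordgrass NDVI peaks in early
#' summer (May-July) and bottoms out in winter (Nov-Jan) with a large annual
#' range; mangrove stays densely green year-round (NDVI > 0.6, small range);
#' seawater is permanent water (NDWI > 0 at every clean observation);
#' mudflat floods seasonally; rafts sit on water with a weak structural
#' signal; artificial surfaces are bright and aseasonal.
#'
#' @return named list of 5x3 matrices (band x mean/amp/peak_doy).
#' @export
default_phenology_profiles <- function() {
  p <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE,
                dimnames = list(scene_bands(), c("mean", "amp", "peak_doy")))
    m
  }
  list(
    spartina = p(
      0.040, 0.010, 350,   # blue
      0.080, 0.030, 350,   # green: turbid tidal water over senesced marsh
      0.070, 0.030, 350,   # red: brighter in winter senescence
      0.250, 0.170, 166,   # nir: peaks mid June
      0.120, 0.040, 350    # swir1: drier canopy in winter
    ),
    mangrove = p(
      0.030, 0.005, 166,
      0.050, 0.010, 166,
      0.035, 0.005, 350,
      0.350, 0.030, 166,
      0.100, 0.020, 350
    ),
    mudflat = p(
      0.080, 0.005, 30,
      0.100, 0.020, 30,    # wetter, greener-looking in winter floods
      0.100, 0.005, 200,
      0.110, 0.020, 200,
      0.100, 0.010, 200
    ),
    raft = p(
      0.060, 0.005, 100,
      0.070, 0.010, 100,
      0.050, 0.005, 100,
      0.050, 0.010, 280,
      0.030, 0.005, 100
    ),
    seawater = p(
      0.050, 0.005, 100,
      0.060, 0.005, 100,
      0.040, 0.005, 100,
      0.020, 0.003, 100,
      0.010, 0.002, 100
    ),
    artificial = p(
      0.220, 0.005, 100,
      0.240, 0.005, 100,
      0.260, 0.005, 100,
      0.280, 0.005, 100,
      0.300, 0.005, 100
    )
  )
}

# class raster for a config: 2x3 contiguous blocks + mixed border strip on
# the right (classes interleaved in 3-row chunks), or a user matrix.
scene_class_map <- function(config) {
  h <- config$height; w <- config$width
  spec <- config$class_map_spec
  if (is.matrix(spec)) {
    stopifnot(nrow(spec) == h, ncol(spec) == w,
              all(spec %in% seq_along(scene_classes())))
    m <- spec
  } else if (identical(spec, "blocks")) {
    strip <- max(2L, round(0.06 * w))
    core_w <- w - strip
    m <- matrix(0L, h, w)
    row_split <- ceiling(h / 2)
    col_edges <- round(seq(0, core_w, length.out = 4))
    k <- 0L
    for (i in 1:2) {
      rows <- if (i == 1) 1:row_split else (row_split + 1):h
      for (j in 1:3) {
        k <- k + 1L
        cols <- (col_edges[j] + 1):col_edges[j + 1]
        m[rows, cols] <- k
      }
    }
    # mixed border: cycle classes down the strip in 3-row chunks
    chunk <- ((seq_len(h) - 1L) %/% 3L) %% 6L + 1L
    m[, (core_w + 1):w] <- matrix(chunk, h, strip)
  } else {
    stop("unknown class_map_spec: ", spec)
  }
  cg_raster(m, config$pixel_size)
}

profile_band_values <- function(profile, doy) {
  # matrix: time x band
  sapply(rownames(profile), function(b) {
    profile[b, "mean"] +
      profile[b, "amp"] * cos(2 * pi * (doy - profile[b, "peak_doy"]) / 365)
  })
}

#' Generate a synthetic reflectance scene
#'
#' Builds a fully labelled scene: a reflectance stack (pixel x time x band)
#' with a validity mask marking injected cloud gaps, plus the true class
#' raster. Deterministic for a fixed seed. Reflectance is clipped to
#' `[1e-4, 1]` after noise so index denominators stay positive.
#'
#' @param config a [scene_config()].
#' @param profiles class phenology profiles, as
#'   [default_phenology_profiles()].
#' @return a `synthetic_scene`: list with `config`, `dates`, `times`
#'   (fractional years), `doy`, `class_raster`, `reflectance` (array
#'   `[pixel, time, band]`), `valid` (matrix `[pixel, time]`).
#' @export
generate_scene <- function(config, profiles = default_phenology_profiles()) {
  stopifnot(inherits(config, "scene_config"))
  dates <- scene_dates(config)
  doy <- as.numeric(format(dates, "%j"))
  times <- date_to_fyear(dates, as.integer(format(config$start_date, "%Y")))
  cls <- scene_class_map(config)
  clsv <- as.integer(cls$values)
  npix <- config$width * config$height
  nt <- length(dates)
  nb <- length(scene_bands())

  # class signal split into band means and seasonal components so that
  # per-pixel heterogeneity can rescale the seasonal part
  class_means <- lapply(scene_classes(), function(cl) profiles[[cl]][, "mean"])
  class_seasonal <- lapply(scene_classes(), function(cl) {
    pr <- profiles[[cl]]
    sapply(rownames(pr), function(b) {
      pr[b, "amp"] * cos(2 * pi * (doy - pr[b, "peak_doy"]) / 365)
    })
  })
  refl <- array(NA_real_, c(npix, nt, nb),
                dimnames = list(NULL, NULL, scene_bands()))

  # seasonal cloud cycle (wet-season maximum near late July)
  kc <- config$cloud_season_strength
  w <- exp(kc * cos(2 * pi * (doy - 207) / 365))
  with_seed(config$seed, {
    # spatially correlated cloudiness: smooth log-normal pixel factor;
    # the pixel x date gap probability is rescaled (after clamping at
    # 0.95) so its overall mean equals cloud_gap_fraction exactly
    s_pix <- if (config$cloud_spatial_sd > 0) {
      exp(config$cloud_spatial_sd * smooth_field(config$height, config$width))
    } else matrix(1, config$height, config$width)
    gap_p <- outer(as.vector(s_pix), w)
    if (config$cloud_gap_fraction > 0) {
      sc <- config$cloud_gap_fraction / mean(gap_p)
      for (i in 1:6) {
        sc <- sc * config$cloud_gap_fraction / mean(pmin(gap_p * sc, 0.95))
      }
      gap_p <- pmin(gap_p * sc, 0.95)
    } else {
      gap_p <- gap_p * 0
    }
    level_shift <- if (config$pixel_level_sd > 0) {
      matrix(stats::rnorm(npix * nb, 0, config$pixel_level_sd), npix, nb)
    } else matrix(0, npix, nb)
    amp_scale <- if (config$pixel_amp_sd > 0) {
      exp(stats::rnorm(npix, 0, config$pixel_amp_sd))
    } else rep(1, npix)
    for (k in seq_along(class_means)) {
      rows <- which(clsv == k)
      if (!length(rows)) next
      for (b in seq_len(nb)) {
        refl[rows, , b] <-
          class_means[[k]][b] + level_shift[rows, b] +
          outer(amp_scale[rows], class_seasonal[[k]][, b])
      }
    }
    valid <- matrix(stats::runif(npix * nt), npix, nt) >= gap_p
    if (config$noise_sd > 0) {
      refl <- refl + array(stats::rnorm(npix * nt * nb, 0, config$noise_sd),
                           c(npix, nt, nb))
    }
    if (config$outlier_fraction > 0 && config$outlier_magnitude != 0) {
      hit <- valid & matrix(stats::runif(npix * nt) < config$outlier_fraction,
                            npix, nt)
      sgn <- matrix(sample(c(-1, 1), npix * nt, replace = TRUE), npix, nt)
      spike <- ifelse(hit, sgn * config$outlier_magnitude, 0)
      for (b in seq_len(nb)) refl[, , b] <- refl[, , b] + spike
    }
  })
  refl[refl < 1e-4] <- 1e-4
  refl[refl > 1] <- 1

  structure(
    list(config = config, dates = dates, times = times, doy = doy,
         class_raster = cls, classes = scene_classes(),
         reflectance = refl, valid = valid),
    class = "synthetic_scene"
  )
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d pixels, %d dates (%s .. %s)\n",
              x$config$height, x$config$width, length(x$dates),
              format(min(x$dates)), format(max(x$dates))))
  cat(sprintf("  valid observations: %.1f%%\n", 100 * mean(x$valid)))
  invisible(x)
}

# smooth standardized spatial field: sum of low-frequency random cosines
smooth_field <- function(nrow, ncol, n_waves = 12) {
  xs <- (seq_len(ncol) - 0.5) / ncol
  ys <- (seq_len(nrow) - 0.5) / nrow
  gx <- matrix(xs, nrow, ncol, byrow = TRUE)
  gy <- matrix(ys, nrow, ncol)
  f <- matrix(0, nrow, ncol)
  for (k in seq_len(n_waves)) {
    fx <- stats::runif(1, 0.3, 2.5)
    fy <- stats::runif(1, 0.3, 2.5)
    ph <- stats::runif(1, 0, 2 * pi)
    a <- stats::rnorm(1)
    f <- f + a * cos(2 * pi * (fx * gx + fy * gy) + ph)
  }
  (f - mean(f)) / stats::sd(f)
}

#' Generate environmental layers with a known suitability law
#'
#' Continuous layers are smooth standardized spatial fields (optionally
#' rescaled to stated ranges); true suitability is
#' `plogis(intercept + sum(w_l * z_l))` over the continuous layers, so a
#' zero weight makes a layer irrelevant by construction. Optionally adds a
#' categorical soil-type layer (not part of the truth law).
#'
#' @param config a [scene_config()] (grid dimensions and seed).
#' @param n_continuous number of continuous layers (>= 1).
#' @param suitability_weights numeric weights, one per continuous layer.
#' @param intercept intercept of the logistic truth law. 0 gives
#'   suitability 0.5 where the weighted sum vanishes; strongly negative
#'   values give realistic low-prevalence landscapes.
#' @param ranges optional list of `c(lo, hi)` per continuous layer; layers
#'   are linearly rescaled from their standardized values.
#' @param pair_correlation optional target Pearson correlation between
#'   layers 1 and 2 (achieved exactly in-sample by Gram-Schmidt mixing).
#' @param include_soil add a categorical `soiltype` layer with 3 classes.
#' @param seed RNG seed; defaults to `config$seed + 1`.
#' @return list with `stack` (an `env_stack`) and `suitability`
#'   (a [cg_raster] in `[0,1]`).
#' @export
generate_env_layers <- function(config, n_continuous = 2,
                                suitability_weights = c(3, 0),
                                intercept = 0, ranges = NULL,
                                pair_correlation = NULL,
                                include_soil = FALSE,
                                seed = config$seed + 1L) {
  stopifnot(n_continuous >= 1,
            length(suitability_weights) == n_continuous)
  h <- config$height; w <- config$width
  with_seed(seed, {
    fields <- lapply(seq_len(n_continuous), function(i) smooth_field(h, w))
    if (!is.null(pair_correlation)) {
      stopifnot(n_continuous >= 2, abs(pair_correlation) <= 1)
      z1 <- as.vector(fields[[1]])
      z2 <- as.vector(fields[[2]])
      resid <- stats::residuals(stats::lm(z2 ~ z1))
      resid <- resid / stats::sd(resid)
      z1s <- (z1 - mean(z1)) / stats::sd(z1)
      mixed <- pair_correlation * z1s +
        sqrt(1 - pair_correlation^2) * resid
      fields[[2]] <- matrix((mixed - mean(mixed)) / stats::sd(mixed), h, w)
    }
    soil_field <- if (include_soil) smooth_field(h, w) else NULL
  })
  lin <- matrix(intercept, h, w)
  layers <- list()
  for (i in seq_len(n_continuous)) {
    z <- fields[[i]]
    lin <- lin + suitability_weights[i] * z
    vals <- z
    if (!is.null(ranges) && !is.null(ranges[[i]])) {
      lo <- ranges[[i]][1]; hi <- ranges[[i]][2]
      zmin <- min(z); zmax <- max(z)
      vals <- lo + (z - zmin) / (zmax - zmin) * (hi - lo)
    }
    layers[[sprintf("env%d", i)]] <- list(
      name = sprintf("env%d", i), type = "continuous",
      raster = cg_raster(vals, config$pixel_size), retained = TRUE
    )
  }
  if (include_soil) {
    codes <- cut(soil_field, breaks = stats::quantile(soil_field, c(0, 1/3, 2/3, 1)),
                 labels = FALSE, include.lowest = TRUE)
    layers[["soiltype"]] <- list(
      name = "soiltype", type = "categorical",
      raster = cg_raster(matrix(codes, h, w), config$pixel_size),
      retained = TRUE
    )
  }
  stack <- structure(list(layers = layers), class = "env_stack")
  suit <- cg_raster(stats::plogis(lin), config$pixel_size)
  list(stack = stack, suitability = suit)
}

#' @export
print.env_stack <- function(x, ...) {
  cat(sprintf("<env_stack> %d layers:\n", length(x$layers)))
  for (l in x$layers) {
    cat(sprintf("  %-12s %-11s retained=%s\n", l$name, l$type, l$retained))
  }
  invisible(x)
}

#' Sample presence points proportionally to suitability
#'
#' Cells are drawn with replacement with probability proportional to the
#' suitability surface; points sit at cell centres and carry the cell index
#' for later grid de-duplication.
#'
#' @param suitability a [cg_raster] of non-negative weights.
#' @param n_points number of draws (>= 1).
#' @param seed RNG seed.
#' @return data.frame `(x, y, cell)`.
#' @export
sample_presences <- function(suitability, n_points, seed = 1L) {
  stopifnot(n_points >= 1)
  wts <- raster_values(suitability)
  wts[is.na(wts)] <- 0
  if (all(wts <= 0)) stop("suitability is zero everywhere; cannot sample")
  cells <- with_seed(seed, {
    sample.int(length(wts), n_points, replace = TRUE, prob = wts)
  })
  xy <- cell_xy(suitability, cells)
  data.frame(x = xy$x, y = xy$y, cell = cells)
}

#' Packaged study conditions for the distribution-model experiments
#'
#' One call that reproduces the package's canonical species-distribution
#' fixture: a 50 x 50 grid with two standardized continuous layers, truth
#' suitability driven by the first layer only (weights `(3, 0)`) through a
#' logistic law with intercept -4 (landscape prevalence roughly 10-15%, as
#' expected for an invasive species occupying a small fraction of a coastal
#' zone), and presences sampled proportionally to suitability.
#'
#' @param width,height grid size.
#' @param n_continuous number of continuous layers.
#' @param suitability_weights truth weights.
#' @param intercept logistic intercept of the truth law.
#' @param n_presences presence draws before de-duplication.
#' @param include_soil include a categorical soil layer.
#' @param seed RNG seed.
#' @return list with `stack`, `suitability`, `presences`, `occurrences`
#'   (de-duplicated, one per cell).
#' @export
simulate_sdm_scene <- function(width = 50, height = 50, n_continuous = 2,
                               suitability_weights = c(3, 0),
                               intercept = -4, n_presences = 200,
                               include_soil = FALSE, seed = 1L) {
  cfg <- scene_config(width = width, height = height, seed = seed)
  env <- generate_env_layers(cfg, n_continuous = n_continuous,
                             suitability_weights = suitability_weights,
                             intercept = intercept,
                             include_soil = include_soil, seed = seed)
  pres <- sample_presences(env$suitability, n_presences, seed = seed + 1L)
  occ <- dedupe_occurrences(pres, env$suitability)
  c(env, list(presences = pres, occurrences = occ))
}
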