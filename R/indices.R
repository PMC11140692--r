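#' Spectral index names supported
#' @export
index_names <- function() c("NDVI", "EVI", "LSWI", "NDWI")

#' Compute a spectral index from band reflectances
#'
#' Formulas (surface reflectance on a 0-1 scale):
#' \deqn{NDVI = (NIR - Red) / (NIR + Red)}
#' \deqn{EVI  = 2.5 (NIR - Red) / (NIR + 6 Red - 7.5 Blue + 1)}
#' \deqn{LSWI = (NIR - SWIR1) / (NIR + SWIR1)}
#' \deqn{NDWI = (Green - NIR) / (Green + NIR)}
#'
#' Vectorised over observations. A zero denominator yields `NA` (flagged
#' invalid) rather than an infinity, so downstream fitting can skip it.
#' Observations flagged invalid are rejected with an error: indices are
#' defined for clear-sky observations only.
#'
#' @param obs data.frame or named list with reflectance columns `blue`,
#'   `green`, `red`, `nir`, `swir1` (subset needed by the index suffices)
#'   and optional logical `valid`.
#' @param index_name one of `"NDVI"`, `"EVI"`, `"LSWI"`, `"NDWI"`.
#' @return numeric vector of index values; `NA` where the denominator is 0.
#' @export
compute_index <- function(obs, index_name = index_names()) {
  index_name <- match.arg(index_name)
  if (!is.null(obs$valid) && !all(obs$valid)) {
    stop("compute_index requires valid observations; filter by the validity ",
         "flag first", call. = FALSE)
  }
  num_den <- switch(index_name,
    NDVI = list(obs$nir - obs$red, obs$nir + obs$red),
    EVI  = list(2.5 * (obs$nir - obs$red),
                obs$nir + 6 * obs$red - 7.5 * obs$blue + 1),
    LSWI = list(obs$nir - obs$swir1, obs$nir + obs$swir1),
    NDWI = list(obs$green - obs$nir, obs$green + obs$nir)
  )
  out <- num_den[[1]] / num_den[[2]]
  out[num_den[[2]] == 0] <- NA_real_
  out
}

#' Per-pixel index series for a whole synthetic scene
#'
#' @param scene a [generate_scene()] result.
#' @param index_name index to compute.
#' @return list with `index`, `times` (fractional years), `doy`, `values`
#'   (matrix pixel x time; computed at all dates), `valid` (matrix, FALSE
#'   where cloud gaps were injected or the denominator vanished).
#' @export
scene_index_series <- function(scene, index_name = index_names()) {
  index_name <- match.arg(index_name)
  b <- function(nm) scene$reflectance[, , nm]
  obs <- list(blue = b("blue"), green = b("green"), red = b("red"),
              nir = b("nir"), swir1 = b("swir1"))
  vals <- compute_index(obs, index_name)
  vals <- matrix(vals, nrow = dim(scene$reflectance)[1])
  valid <- scene$valid & is.finite(vals)
  list(index = index_name, times = scene$times, doy = scene$doy,
       values = vals, valid = valid)
}

#' Water frequency of an NDWI series
#'
#' Fraction of valid observations classified as water; an observation is
#' water iff NDWI > 0 (strictly — NDWI = 0 counts as non-water).
#'
#' @param values NDWI values (vector, one pixel).
#' @param valid logical validity flags (default all valid).
#' @return list with `wf` in `[0,1]`, `n_water`, `n_observation`.
#' @export
water_frequency <- function(values, valid = rep(TRUE, length(values))) {
  stopifnot(length(values) == length(valid))
  valid <- valid & !is.na(values)
  n_obs <- sum(valid)
  if (n_obs < 1) stop("no valid observations in NDWI series", call. = FALSE)
  n_water <- sum(values[valid] > 0)
  list(wf = n_water / n_obs, n_water = n_water, n_observation = n_obs)
}

#' Vectorised water frequency over a pixel x time matrix
#' @param values NDWI matrix (pixels x observations).
#' @param valid logical matrix of the same shape.
#' @return list of per-pixel vectors `wf`, `n_water`, `n_observation`
#'   (`wf` is `NA` for pixels with no valid observations).
#' @export
water_frequency_matrix <- function(values, valid) {
  valid <- valid & !is.na(values)
  n_obs <- rowSums(valid)
  n_water <- rowSums(valid & values > 0)
  wf <- ifelse(n_obs > 0, n_water / n_obs, NA_real_)
  list(wf = wf, n_water = n_water, n_observation = n_obs)
}
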