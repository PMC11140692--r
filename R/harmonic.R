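#' Harmonic design matrix
#'
#' Columns `[1, cos(2*pi*1*t), sin(2*pi*1*t), ..., cos(2*pi*m*t),
#' sin(2*pi*m*t)]` with `t` in fractional years, so harmonic `j` has
#' frequency `j` cycles per year.
#'
#' @param times fractional years.
#' @param m number of harmonics (>= 1).
#' @return numeric matrix, `length(times)` rows and `2m + 1` columns.
#' @export
build_design_matrix <- function(times, m = 2) {
  stopifnot(m >= 1)
  if (length(unique(times)) < 2 * m + 1) {
    stop(sprintf(
      "harmonic fit with m = %d needs at least %d distinct observation times, got %d",
      m, 2 * m + 1, length(unique(times))), call. = FALSE)
  }
  cols <- list(rep(1, length(times)))
  for (j in seq_len(m)) {
    cols[[2 * j]] <- cos(2 * pi * j * times)
    cols[[2 * j + 1]] <- sin(2 * pi * j * times)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- c("a0", as.vector(rbind(paste0("a", 1:m), paste0("b", 1:m))))
  X
}

#' Fit a harmonic regression to one index series
#'
#' Ordinary least squares of
#' `y(t) = a0 + sum_j a_j cos(2*pi*j*t) + b_j sin(2*pi*j*t)` on the valid
#' observations. The low-order harmonics carry the seasonal signal; noise
#' and undetected outliers fall into the residual.
#'
#' @param times fractional years.
#' @param values index values, same length.
#' @param valid logical flags; only valid, finite observations are used.
#' @param m number of harmonics (default 2: annual + semi-annual).
#' @return a `harmonic_fit`: `a0`, `a`, `b`, `m`, `omega` (cycles/year),
#'   `n_obs_used`, `rmse`.
#' @export
fit_harmonic <- function(times, values, valid = rep(TRUE, length(values)),
                         m = 2) {
  keep <- valid & is.finite(values)
  t_use <- times[keep]
  y <- values[keep]
  X <- build_design_matrix(t_use, m)
  sv <- svd(X, nu = 0, nv = 0)$d
  if (min(sv) < max(sv) * 1e-8) {
    stop("rank-deficient harmonic design (aliased or degenerate times)",
         call. = FALSE)
  }
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  structure(
    list(a0 = unname(cf[1]),
         a = unname(cf[seq(2, 2 * m, by = 2)]),
         b = unname(cf[seq(3, 2 * m + 1, by = 2)]),
         m = m, omega = seq_len(m), n_obs_used = length(y),
         rmse = sqrt(mean(fit$residuals^2))),
    class = "harmonic_fit"
  )
}

#' @export
print.harmonic_fit <- function(x, ...) {
  cat(sprintf("<harmonic_fit> m = %d, n = %d, rmse = %.4g\n",
              x$m, x$n_obs_used, x$rmse))
  cat(sprintf("  a0 = %.4g; amplitude(j=1) = %.4g\n", x$a0,
              sqrt(x$a[1]^2 + x$b[1]^2)))
  invisible(x)
}

#' Evaluate a harmonic fit at given times
#'
#' @param fit a [fit_harmonic()] result.
#' @param times fractional years.
#' @return fitted index values.
#' @export
reconstruct <- function(fit, times) {
  out <- rep(fit$a0, length(times))
  for (j in seq_len(fit$m)) {
    out <- out + fit$a[j] * cos(2 * pi * j * times) +
      fit$b[j] * sin(2 * pi * j * times)
  }
  out
}

# daily grid over one canonical year (365 samples)
daily_grid <- function() (0:364) / 365

#' Phenological features from harmonic fits
#'
#' For each index, the maximum, minimum and range of the reconstructed
#' annual curve sampled at daily resolution, plus the raw water frequency.
#' These 13 values are the classifier's input features.
#'
#' @param fits named list of `harmonic_fit`s, one per index
#'   (`NDVI`, `EVI`, `LSWI`, `NDWI`).
#' @param wf a [water_frequency()] result (or a plain number in `[0,1]`).
#' @return named numeric vector
#'   `(<index>_max, <index>_min, <index>_range) x 4, wf`.
#' @export
extract_phenology_features <- function(fits, wf) {
  wf_val <- if (is.list(wf)) wf$wf else wf
  tg <- daily_grid()
  out <- c()
  for (idx in names(fits)) {
    curve <- reconstruct(fits[[idx]], tg)
    mx <- max(curve); mn <- min(curve)
    v <- c(mx, mn, mx - mn)
    names(v) <- paste0(tolower(idx), c("_max", "_min", "_range"))
    out <- c(out, v)
  }
  c(out, wf = wf_val)
}

#' Day-of-year of the annual maximum of a fitted curve
#' @param fit a `harmonic_fit`.
#' @return integer day of year (1..365) where the reconstruction peaks.
#' @export
peak_doy <- function(fit) {
  tg <- daily_grid()
  which.max(reconstruct(fit, tg))
}

#' Feature matrix for a whole scene
#'
#' Fits all four index series per pixel and assembles the 13-band feature
#' matrix (4 indices x max/min/range, plus water frequency). With
#' `fitted = FALSE` the extrema are taken directly from the raw valid
#' observations instead of the reconstructed curves — the degraded baseline
#' that motivates harmonic smoothing. Pixels with fewer than `2m + 1` valid
#' observations for some index get an all-`NA` row (excluded from maps).
#'
#' @param scene a [generate_scene()] result.
#' @param m harmonics (default 2).
#' @param fitted use harmonic-fit extrema (TRUE) or raw-series extrema.
#' @return matrix `pixels x 13` with feature column names; attribute
#'   `"ok"` flags rows with complete features.
#' @export
scene_features <- function(scene, m = 2, fitted = TRUE) {
  series <- lapply(index_names(), function(idx) scene_index_series(scene, idx))
  names(series) <- index_names()
  npix <- nrow(series[[1]]$values)
  tg <- daily_grid()
  feat <- NULL
  for (idx in index_names()) {
    s <- series[[idx]]
    if (fitted) {
      p <- 2 * m + 1
      coefs <- matrix(NA_real_, npix, p)
      for (i in seq_len(npix)) {
        keep <- s$valid[i, ]
        if (sum(keep) < p) next
        X <- build_design_matrix(s$times[keep], m)
        f <- stats::lm.fit(X, s$values[i, keep])
        if (f$rank == p) coefs[i, ] <- f$coefficients
      }
      Xd <- build_design_matrix(tg, m)
      curves <- coefs %*% t(Xd)
      mx <- apply(curves, 1, max)
      mn <- apply(curves, 1, min)
    } else {
      vals <- s$values
      vals[!s$valid] <- NA
      mx <- suppressWarnings(apply(vals, 1, max, na.rm = TRUE))
      mn <- suppressWarnings(apply(vals, 1, min, na.rm = TRUE))
      mx[!is.finite(mx)] <- NA
      mn[!is.finite(mn)] <- NA
    }
    block <- cbind(mx, mn, mx - mn)
    colnames(block) <- paste0(tolower(idx), c("_max", "_min", "_range"))
    feat <- cbind(feat, block)
  }
  ndwi <- series[["NDWI"]]
  wf <- water_frequency_matrix(ndwi$values, ndwi$valid)$wf
  feat <- cbind(feat, wf = wf)
  ok <- stats::complete.cases(feat)
  attr(feat, "ok") <- ok
  feat
}
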