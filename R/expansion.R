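#' Connected-component labelling of a binary matrix
#'
#' Breadth-first flood fill under 8- (default) or 4-connectivity.
#'
#' @param mask logical matrix (TRUE = foreground).
#' @param connectivity 8 (edges + diagonals) or 4 (edges only).
#' @return integer matrix of patch labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8) {
    cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
          dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    cbind(dr = c(-1, 0, 0, 1), dc = c(0, -1, 1, 0))
  }
  fg <- which(mask)
  cur <- 0L
  for (start in fg) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    lab[start] <- cur
    frontier <- start
    while (length(frontier)) {
      r <- (frontier - 1L) %% nr + 1L
      cc <- (frontier - 1L) %/% nr + 1L
      nxt <- integer(0)
      for (k in seq_len(nrow(offs))) {
        rr <- r + offs[k, 1]; ccc <- cc + offs[k, 2]
        okk <- rr >= 1 & rr <= nr & ccc >= 1 & ccc <= nc
        cand <- (ccc[okk] - 1L) * nr + rr[okk]
        cand <- cand[mask[cand] & lab[cand] == 0L]
        if (length(cand)) {
          lab[cand] <- cur
          nxt <- c(nxt, cand)
        }
      }
      frontier <- unique(nxt)
    }
  }
  lab
}

#' Extract cordgrass patches from a binary map
#'
#' Connected components of the foreground, with per-patch pixel count,
#' area in hm^2 (`count * pixel_size^2 / 10,000`) and centroid (mean of
#' pixel centres, projected metres).
#'
#' @param binary a [cg_raster] with values 1/0/`NA`; must be projected.
#' @param connectivity 8 (default) or 4.
#' @return a `patch_set` data.frame
#'   `(patch_id, n_pixels, area_hm2, x, y)` with attributes `pixel_size`
#'   and `connectivity`.
#' @export
extract_patches <- function(binary, connectivity = 8) {
  if (binary$crs != "projected") {
    stop("patch metrics require a projected (metric) CRS", call. = FALSE)
  }
  mask <- !is.na(binary$values) & binary$values == 1
  lab <- label_components(mask, connectivity)
  ids <- sort(unique(lab[lab > 0]))
  area1 <- cell_area_hm2(binary)
  rows <- lapply(ids, function(id) {
    cells <- which(lab == id)
    xy <- cell_xy(binary, cells)
    data.frame(patch_id = id, n_pixels = length(cells),
               area_hm2 = length(cells) * area1,
               x = mean(xy$x), y = mean(xy$y))
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(patch_id = integer(0), n_pixels = integer(0),
               area_hm2 = numeric(0), x = numeric(0), y = numeric(0))
  }
  attr(out, "pixel_size") <- binary$pixel_size
  attr(out, "connectivity") <- connectivity
  class(out) <- c("patch_set", "data.frame")
  out
}

#' Area-weighted centroid of a patch set
#'
#' `X = sum(S_i x_i) / sum(S_i)` (and likewise for Y), with `S_i` the patch
#' areas: the integral centroid whose year-to-year displacement tracks the
#' direction of expansion.
#'
#' @param patches a [extract_patches()] result (>= 1 patch).
#' @param epoch optional label (e.g. the mapping year).
#' @return a `centroid_record`: `epoch`, `x`, `y`, `total_area_hm2`,
#'   `n_patches`.
#' @export
weighted_centroid <- function(patches, epoch = NA) {
  if (!nrow(patches)) stop("empty patch set has no centroid", call. = FALSE)
  s <- patches$area_hm2
  structure(
    list(epoch = epoch,
         x = sum(s * patches$x) / sum(s),
         y = sum(s * patches$y) / sum(s),
         total_area_hm2 = sum(s), n_patches = nrow(patches)),
    class = "centroid_record"
  )
}

#' @export
print.centroid_record <- function(x, ...) {
  cat(sprintf("<centroid_record> epoch %s: (%.1f, %.1f), %.2f hm^2 in %d patches\n",
              x$epoch, x$x, x$y, x$total_area_hm2, x$n_patches))
  invisible(x)
}

#' Centroid migration between two epochs
#'
#' Euclidean displacement in projected metres plus a compass-octant
#' bearing (N, NE, E, SE, S, SW, W, NW) of the move from `rec_a` to
#' `rec_b`.
#'
#' @param rec_a,rec_b [weighted_centroid()] records on the same CRS.
#' @return list `distance_m`, `bearing` (octant, `NA` for zero move),
#'   `dx`, `dy`.
#' @export
centroid_migration <- function(rec_a, rec_b) {
  dx <- rec_b$x - rec_a$x
  dy <- rec_b$y - rec_a$y
  dist <- sqrt(dx^2 + dy^2)
  bearing <- NA_character_
  if (dist > 0) {
    ang <- (atan2(dx, dy) * 180 / pi) %% 360   # 0 = north, clockwise
    oct <- c("N", "NE", "E", "SE", "S", "SW", "W", "NW")
    bearing <- oct[(floor((ang + 22.5) / 45) %% 8) + 1]
  }
  list(distance_m = dist, bearing = bearing, dx = dx, dy = dy)
}

#' Yearly growth statistics of an area series
#'
#' Rates are `(A_t - A_{t-1}) / A_{t-1} * 100`; a zero prior-year area
#' leaves that step's rate `NA` (flagged). The mean over a window is the
#' arithmetic mean of the yearly percentage rates by default; a geometric
#' alternative (`(A_end/A_start)^(1/k) - 1`) is also reported.
#'
#' @param areas named numeric vector, names = years, values = hm^2.
#' @return list with `rates` (data.frame `year`, `rate_pct`),
#'   `mean_rate_pct`, `geometric_mean_rate_pct`.
#' @export
growth_statistics <- function(areas) {
  if (length(areas) < 2) stop("need at least 2 epochs", call. = FALSE)
  yrs <- names(areas)
  if (is.null(yrs)) yrs <- as.character(seq_along(areas))
  prev <- areas[-length(areas)]
  cur <- areas[-1]
  rate <- ifelse(prev > 0, (cur - prev) / prev * 100, NA_real_)
  k <- length(areas) - 1
  geo <- if (areas[[1]] > 0) ((areas[[length(areas)]] / areas[[1]])^(1 / k) - 1) * 100
         else NA_real_
  list(
    rates = data.frame(year = yrs[-1], rate_pct = unname(rate)),
    mean_rate_pct = mean(rate, na.rm = TRUE),
    geometric_mean_rate_pct = unname(geo)
  )
}

#' Area ratio between two named years
#' @param areas named numeric vector of areas.
#' @param year_num,year_den numerator and denominator years (names).
#' @return `areas[year_num] / areas[year_den]`.
#' @export
area_ratio <- function(areas, year_num, year_den) {
  unname(areas[[as.character(year_num)]] / areas[[as.character(year_den)]])
}

#' Percent deviation of a mapped area from a reference estimate
#'
#' `|area - reference| / reference * 100`, reported to one decimal — the
#' convention used when comparing mapped areas against independent
#' higher-resolution estimates.
#'
#' @param area mapped area (hm^2).
#' @param reference independent reference area (> 0, hm^2).
#' @return percent deviation, 1 decimal.
#' @export
deviation_vs_reference <- function(area, reference) {
  if (!is.finite(reference) || reference <= 0) {
    stop("reference area must be positive", call. = FALSE)
  }
  round(abs(area - reference) / reference * 100, 1)
}
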