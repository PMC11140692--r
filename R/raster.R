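#' Lightweight projected grid raster
#'
#' A minimal single-band raster: a numeric matrix plus grid metadata. Row 1 is
#' the northernmost row; cells are addressed either as `[row, col]` or by a
#' single column-major cell index (the native R matrix index). Coordinates are
#' metres for a projected grid; expansion metrics refuse geographic grids.
#'
#' @param values numeric matrix (row 1 = top/north).
#' @param pixel_size cell edge length, metres (projected) or degrees
#'   (geographic).
#' @param xmin,ymin coordinates of the lower-left corner of the grid.
#' @param crs `"projected"` (default) or `"geographic"`.
#' @return An object of class `cg_raster`.
#' @export
cg_raster <- function(values, pixel_size = 30, xmin = 0, ymin = 0,
                      crs = c("projected", "geographic")) {
  crs <- match.arg(crs)
  if (!is.matrix(values)) values <- as.matrix(values)
  stopifnot(pixel_size > 0)
  structure(
    list(values = values, pixel_size = pixel_size,
         xmin = xmin, ymin = ymin, crs = crs),
    class = "cg_raster"
  )
}

#' @export
dim.cg_raster <- function(x) dim(x$values)

#' Number of cells in a raster
#' @param r a [cg_raster].
#' @return integer cell count.
#' @export
ncell <- function(r) length(r$values)

#' Raster cell values
#' @param r a [cg_raster].
#' @return numeric vector in column-major (native matrix) order.
#' @export
raster_values <- function(r) as.vector(r$values)

#' @export
print.cg_raster <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<cg_raster> %d x %d cells, pixel %g, %s CRS\n",
              d[1], d[2], x$pixel_size, x$crs))
  cat(sprintf("  origin (%g, %g); value range [%g, %g]\n", x$xmin, x$ymin,
              suppressWarnings(min(x$values, na.rm = TRUE)),
              suppressWarnings(max(x$values, na.rm = TRUE))))
  invisible(x)
}

#' Coordinates of cell centres
#'
#' @param r a [cg_raster].
#' @param cell column-major cell indices (default all cells).
#' @return data.frame with columns `cell`, `row`, `col`, `x`, `y`.
#' @export
cell_xy <- function(r, cell = seq_len(ncell(r))) {
  nr <- nrow(r$values)
  row <- (cell - 1L) %% nr + 1L
  col <- (cell - 1L) %/% nr + 1L
  data.frame(
    cell = cell, row = row, col = col,
    x = r$xmin + (col - 0.5) * r$pixel_size,
    y = r$ymin + (nr - row + 0.5) * r$pixel_size
  )
}

#' Area of one cell in hectares (hm^2)
#' @param r a projected [cg_raster].
#' @return cell area in hm^2 (10,000 m^2 per hm^2).
#' @export
cell_area_hm2 <- function(r) {
  if (r$crs != "projected") {
    stop("cell areas require a projected (metric) CRS", call. = FALSE)
  }
  r$pixel_size^2 / 1e4
}

raster_like <- function(r, values) {
  cg_raster(matrix(values, nrow = nrow(r$values)), r$pixel_size,
            r$xmin, r$ymin, r$crs)
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by standard GIS software.
#'
#' @param r a [cg_raster].
#' @param path output file path.
#' @param nodata value written for `NA` cells.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path, nodata = -9999) {
  v <- r$values
  v[is.na(v)] <- nodata
  hdr <- c(
    sprintf("ncols %d", ncol(v)),
    sprintf("nrows %d", nrow(v)),
    sprintf("xllcorner %.10g", r$xmin),
    sprintf("yllcorner %.10g", r$ymin),
    sprintf("cellsize %.10g", r$pixel_size),
    sprintf("NODATA_value %.10g", nodata)
  )
  body <- apply(v, 1, function(row) paste(format(row, trim = TRUE), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path file written by [write_ascii_grid()] or any GIS export.
#' @param crs CRS kind to attach (`"projected"` or `"geographic"`).
#' @return a [cg_raster].
#' @export
read_ascii_grid <- function(path, crs = "projected") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- lapply(lines[i:length(lines)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])
  })
  m <- do.call(rbind, vals)
  stopifnot(nrow(m) == hdr$nrows, ncol(m) == hdr$ncols)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  cg_raster(m, hdr$cellsize, hdr$xllcorner, hdr$yllcorner, crs)
}

#' Write point records as GeoJSON
#'
#' @param df data.frame with `x` and `y` columns; remaining columns become
#'   feature properties.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_points_geojson <- function(df, path) {
  props <- setdiff(names(df), c("x", "y"))
  feats <- lapply(seq_len(nrow(df)), function(i) {
    list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(df$x[i], df$y[i])),
      properties = as.list(df[i, props, drop = FALSE])
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Seed scoping: run code under a given seed, then restore the caller's RNG
# state so library functions do not perturb user scripts.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
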