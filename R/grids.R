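#' A regular latitude/longitude grid of cell values
#'
#' Lightweight in-memory raster: a matrix of cell values plus the latitudes
#' and longitudes of cell centers. Rows run north to south (row 1 is the
#' northernmost band), columns west to east — the layout of ASCII-grid files.
#'
#' @param values numeric or logical matrix, `length(lat)` rows by
#'   `length(lon)` columns.
#' @param lat cell-center latitudes, strictly decreasing, equal spacing.
#' @param lon cell-center longitudes, strictly increasing, equal spacing.
#' @return Object of class `pheno_grid`.
#' @export
pheno_grid <- function(values, lat, lon) {
  values <- as.matrix(values)
  if (nrow(values) != length(lat) || ncol(values) != length(lon)) {
    stop("values must be length(lat) x length(lon)")
  }
  if (length(lat) > 1) {
    dlat <- diff(lat)
    if (any(dlat >= 0) || max(abs(dlat - dlat[1])) > 1e-8) {
      stop("lat must be strictly decreasing and evenly spaced")
    }
  }
  if (length(lon) > 1) {
    dlon <- diff(lon)
    if (any(dlon <= 0) || max(abs(dlon - dlon[1])) > 1e-8) {
      stop("lon must be strictly increasing and evenly spaced")
    }
  }
  structure(list(values = values, lat = as.numeric(lat), lon = as.numeric(lon)),
            class = "pheno_grid")
}

#' @export
print.pheno_grid <- function(x, ...) {
  cat(sprintf("pheno_grid: %d x %d cells, lat [%.3f, %.3f], lon [%.3f, %.3f]\n",
              nrow(x$values), ncol(x$values),
              min(x$lat), max(x$lat), min(x$lon), max(x$lon)))
  v <- x$values[is.finite(x$values)]
  if (length(v) > 0) cat(sprintf("  values: [%.3g, %.3g], %d missing\n",
                                 min(v), max(v), sum(!is.finite(x$values))))
  invisible(x)
}

grid_res <- function(grid) {
  dy <- if (length(grid$lat) > 1) abs(grid$lat[1] - grid$lat[2]) else NA_real_
  dx <- if (length(grid$lon) > 1) grid$lon[2] - grid$lon[1] else NA_real_
  c(dx = dx, dy = dy)
}

same_georef <- function(a, b) {
  isTRUE(all.equal(a$lat, b$lat)) && isTRUE(all.equal(a$lon, b$lon))
}

#' Locate the grid cell containing a point
#'
#' @param grid a `pheno_grid`.
#' @param lat,lon point coordinates (vectorised).
#' @return `data.frame` with `row`, `col` (`NA` when the point falls outside
#'   the grid extent).
#' @export
cell_of_point <- function(grid, lat, lon) {
  res <- grid_res(grid)
  row <- round((grid$lat[1] - lat) / res["dy"]) + 1
  col <- round((lon - grid$lon[1]) / res["dx"]) + 1
  row[row < 1 | row > length(grid$lat)] <- NA
  col[col < 1 | col > length(grid$lon)] <- NA
  bad <- is.na(row) | is.na(col)
  row[bad] <- NA
  col[bad] <- NA
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Write a grid as an ESRI ASCII raster
#'
#' Plain-text interchange format: header (`ncols`, `nrows`, `xllcorner`,
#' `yllcorner`, `cellsize`, `NODATA_value`) followed by rows north to south.
#' Requires square cells. Logical grids are written as 0/1.
#'
#' @param grid a `pheno_grid`.
#' @param path output path.
#' @param nodata value standing for missing cells (default -9999).
#' @export
write_ascii_grid <- function(grid, path, nodata = -9999) {
  stopifnot(inherits(grid, "pheno_grid"))
  res <- grid_res(grid)
  if (is.finite(res["dx"]) && is.finite(res["dy"]) &&
      abs(res["dx"] - res["dy"]) > 1e-6) {
    stop("ASCII grids require square cells (dx == dy)")
  }
  cs <- if (is.finite(res["dx"])) res["dx"] else res["dy"]
  v <- grid$values
  storage.mode(v) <- "double"
  v[!is.finite(v)] <- nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("ncols", ncol(v)),
               paste("nrows", nrow(v)),
               paste("xllcorner", format(min(grid$lon) - cs / 2, digits = 12)),
               paste("yllcorner", format(min(grid$lat) - cs / 2, digits = 12)),
               paste("cellsize", format(cs, digits = 12)),
               paste("NODATA_value", nodata)), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ESRI ASCII raster
#'
#' @param path path to an ASCII-grid file.
#' @return A `pheno_grid`; NODATA cells become `NA`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path, n = 6)
  hdr <- lapply(strsplit(trimws(lines), "\\s+"), function(x) x)
  keys <- tolower(vapply(hdr, `[`, character(1), 1))
  vals <- as.numeric(vapply(hdr, `[`, character(1), 2))
  names(vals) <- keys
  needed <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(needed %in% keys)) stop("not an ESRI ASCII grid: ", path)
  nodata <- if ("nodata_value" %in% keys) vals["nodata_value"] else -9999
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  if (nrow(m) != vals["nrows"] || ncol(m) != vals["ncols"]) {
    stop("ASCII grid body does not match its header dimensions")
  }
  m[m == nodata] <- NA
  cs <- vals["cellsize"]
  lon <- vals["xllcorner"] + cs / 2 + (seq_len(vals["ncols"]) - 1) * cs
  lat <- vals["yllcorner"] + cs / 2 + (vals["nrows"] - seq_len(vals["nrows"])) * cs
  pheno_grid(m, lat, lon)
}

#' Read a range polygon from GeoJSON
#'
#' Accepts a Polygon or MultiPolygon geometry (plain coordinates, WGS84),
#' either bare or as the first feature of a FeatureCollection. Only exterior
#' rings are used.
#'
#' @param path GeoJSON path.
#' @return A list of rings, each a two-column matrix (lon, lat).
#' @export
read_range_geojson <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!is.null(g$type) && g$type == "FeatureCollection") g <- g$features[[1]]
  if (!is.null(g$type) && g$type == "Feature") g <- g$geometry
  ring_mat <- function(ring) {
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    colnames(m) <- c("lon", "lat")
    m
  }
  if (g$type == "Polygon") {
    list(ring_mat(g$coordinates[[1]]))
  } else if (g$type == "MultiPolygon") {
    lapply(g$coordinates, function(poly) ring_mat(poly[[1]]))
  } else {
    stop("unsupported GeoJSON geometry: ", g$type)
  }
}

#' Write a polygon as GeoJSON
#'
#' @param rings list of two-column (lon, lat) matrices, exterior rings.
#' @param path output path.
#' @param species optional species name stored as a feature property.
#' @export
write_range_geojson <- function(rings, path, species = NULL) {
  close_ring <- function(m) {
    if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])
    lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
  }
  geom <- if (length(rings) == 1) {
    list(type = "Polygon", coordinates = list(close_ring(rings[[1]])))
  } else {
    list(type = "MultiPolygon",
         coordinates = lapply(rings, function(r) list(close_ring(r))))
  }
  feature <- list(type = "Feature",
                  properties = if (is.null(species)) stats::setNames(list(), character(0)) else list(species = species),
                  geometry = geom)
  fc <- list(type = "FeatureCollection", features = list(feature))
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# even-odd ray casting; points on an edge count as inside often enough for
# cell-center membership at fixture scale
point_in_ring <- function(px, py, ring) {
  x <- ring[, 1]; y <- ring[, 2]
  n <- nrow(ring)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- ((y[i] > py) != (y[j] > py)) &
      (px < (x[j] - x[i]) * (py - y[i]) / (y[j] - y[i]) + x[i])
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

#' Rasterize a range polygon onto a grid
#'
#' Cell membership is by cell center: a cell is in range when its center
#' lies inside any exterior ring (even-odd rule).
#'
#' @param rings polygon rings from [read_range_geojson()].
#' @param grid the `pheno_grid` defining the target georeferencing.
#' @param species optional species tag stored on the mask.
#' @return A `range_mask`: a logical `pheno_grid` with a `species` attribute.
#' @export
rasterize_range <- function(rings, grid, species = NULL) {
  pts <- expand.grid(row = seq_along(grid$lat), col = seq_along(grid$lon))
  px <- grid$lon[pts$col]
  py <- grid$lat[pts$row]
  inside <- rep(FALSE, length(px))
  for (ring in rings) inside <- inside | point_in_ring(px, py, ring)
  m <- matrix(FALSE, nrow = length(grid$lat), ncol = length(grid$lon))
  m[cbind(pts$row, pts$col)] <- inside
  range_mask(m, grid, species)
}

#' Construct a species range mask aligned to a grid
#'
#' @param values logical matrix, same shape as `grid$values`.
#' @param grid the `pheno_grid` supplying the georeferencing.
#' @param species optional species tag.
#' @return A logical `pheno_grid` of class `c("range_mask", "pheno_grid")`.
#' @export
range_mask <- function(values, grid, species = NULL) {
  g <- pheno_grid(values, grid$lat, grid$lon)
  storage.mode(g$values) <- "logical"
  attr(g, "species") <- species
  class(g) <- c("range_mask", "pheno_grid")
  g
}
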