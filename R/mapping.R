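#' A gridded daily temperature stack for one calendar year
#'
#' @param tmin,tmax 3-d arrays `[lat, lon, day]` of daily temperatures,
#'   deg C; third dimension matches the year's calendar.
#' @param lat,lon cell-center coordinates (lat decreasing, lon increasing).
#' @param year calendar year.
#' @return Object of class `temp_stack`.
#' @export
temp_stack <- function(tmin, tmax, lat, lon, year) {
  stopifnot(length(dim(tmin)) == 3, identical(dim(tmin), dim(tmax)))
  if (dim(tmin)[1] != length(lat) || dim(tmin)[2] != length(lon)) {
    stop("stack dimensions do not match lat/lon")
  }
  if (dim(tmin)[3] != year_length(year)) {
    stop("stack must have ", year_length(year), " daily layers for ", year)
  }
  if (any(tmax < tmin, na.rm = TRUE)) stop("tmax < tmin in stack")
  structure(list(tmin = tmin, tmax = tmax, lat = as.numeric(lat),
                 lon = as.numeric(lon), year = as.integer(year)),
            class = "temp_stack")
}

#' Extract one cell's daily series from a stack
#'
#' @param stack a `temp_stack`.
#' @param row,col cell indices.
#' @param site_id identifier given to the extracted series.
#' @return A `temp_series`.
#' @export
stack_cell_series <- function(stack, row, col, site_id = sprintf("cell_%d_%d", row, col)) {
  temp_series(site_id, stack$year, stack$tmin[row, col, ], stack$tmax[row, col, ])
}

#' Not-met sentinel used in DOY maps
#'
#' Cells whose AGDD never reaches the threshold during the year carry this
#' value; it is distinct from `NA`, which marks missing temperature data.
#' @export
DOY_NOT_MET <- -1L

#' Map the day of year a model's threshold is met
#'
#' Applies [doy_threshold_met()] to every grid cell of a daily temperature
#' stack. Cells with any missing temperature are missing in the output;
#' cells whose accumulation ends the year below the threshold carry the
#' [DOY_NOT_MET] sentinel.
#'
#' @param stack a `temp_stack`.
#' @param model a `thermal_time_model`, or a bare numeric threshold
#'   (deg C day, base 0).
#' @return A `doy_map`: an integer `pheno_grid` with attributes `year` and
#'   `model_id`.
#' @export
threshold_doy_map <- function(stack, model) {
  stopifnot(inherits(stack, "temp_stack"))
  if (inherits(model, "thermal_time_model")) {
    threshold <- model$threshold_agdd
    base <- model$base_temp
    model_id <- paste(model$species, model$phenophase, sep = ":")
  } else {
    threshold <- model
    base <- 0
    model_id <- sprintf("threshold_%g", threshold)
  }
  nlat <- length(stack$lat); nlon <- length(stack$lon)
  nd <- dim(stack$tmin)[3]
  gdd <- (stack$tmin + stack$tmax) / 2 - base
  gdd[!is.na(gdd) & gdd < 0] <- 0
  m <- matrix(aperm(gdd, c(3, 1, 2)), nrow = nd)  # days x cells (col-major lat,lon)
  cum <- apply(m, 2, cumsum)
  doy <- vapply(seq_len(ncol(cum)), function(j) {
    col <- cum[, j]
    if (anyNA(col)) return(NA_integer_)
    if (threshold <= 0) return(1L)
    i <- which(col >= threshold)
    if (length(i) == 0) DOY_NOT_MET else i[1]
  }, integer(1))
  g <- pheno_grid(matrix(doy, nrow = nlat, ncol = nlon), stack$lat, stack$lon)
  storage.mode(g$values) <- "integer"
  attr(g, "year") <- stack$year
  attr(g, "model_id") <- model_id
  class(g) <- c("doy_map", "pheno_grid")
  g
}

#' Clip a DOY map to a range mask
#'
#' Cells outside the mask become missing. In the standard workflow this is
#' applied twice: first with the full species range, then with the
#' envelope-clipped range.
#'
#' @param map a `doy_map`.
#' @param mask a `range_mask` aligned with the map.
#' @return The clipped `doy_map`.
#' @export
clip_map <- function(map, mask) {
  stopifnot(inherits(map, "doy_map"), inherits(mask, "range_mask"))
  if (!same_georef(map, mask)) stop("map and mask are not aligned")
  out <- map
  out$values[!mask$values] <- NA_integer_
  out
}

#' Summary statistics of a DOY map
#'
#' Minimum and maximum crossing DOY over cells where the threshold was met,
#' plus met / not-met / missing cell counts. Each successive clip of a map
#' can only narrow (or preserve) the [min, max] interval.
#'
#' @param map a `doy_map`.
#' @return Named list: `min_doy`, `max_doy`, `n_met`, `n_not_met`,
#'   `n_missing`.
#' @export
doy_map_stats <- function(map) {
  stopifnot(inherits(map, "doy_map"))
  v <- map$values
  met <- v[!is.na(v) & v != DOY_NOT_MET]
  list(min_doy = if (length(met) > 0) min(met) else NA_integer_,
       max_doy = if (length(met) > 0) max(met) else NA_integer_,
       n_met = length(met),
       n_not_met = sum(!is.na(v) & v == DOY_NOT_MET),
       n_missing = sum(is.na(v)))
}

#' Write a DOY map as an ASCII grid
#'
#' Missing cells take the NODATA value; not-met cells keep the [DOY_NOT_MET]
#' sentinel, which is documented in a sidecar-free way by being distinct
#' from NODATA.
#'
#' @param map a `doy_map`.
#' @param path output path.
#' @export
write_doy_map <- function(map, path) {
  stopifnot(inherits(map, "doy_map"))
  write_ascii_grid(map, path, nodata = -9999)
}
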