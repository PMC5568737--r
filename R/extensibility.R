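#' Long-term mean spring (JFMA) temperature grid
#'
#' Per cell: the mean of the January, February, March and April monthly mean
#' temperatures (each monthly mean the average of daily `(tmin + tmax)/2`),
#' averaged across the supplied climatology years. Spring temperature is a
#' strong proxy for the continuously accumulating AGDD signal, which is why
#' it anchors the extensibility envelope.
#'
#' @param stacks list of `temp_stack` objects, one per climatology year,
#'   each covering at least January-April.
#' @return A `pheno_grid` of mean JFMA temperature, deg C; cells missing in
#'   any input are missing in the output.
#' @export
spring_climatology <- function(stacks) {
  if (inherits(stacks, "temp_stack")) stacks <- list(stacks)
  stopifnot(length(stacks) > 0)
  g0 <- stacks[[1]]
  per_year <- lapply(stacks, function(st) {
    stopifnot(inherits(st, "temp_stack"))
    if (!isTRUE(all.equal(st$lat, g0$lat)) || !isTRUE(all.equal(st$lon, g0$lon))) {
      stop("temperature stacks are not aligned")
    }
    ml <- month_day_index(st$year)
    if (dim(st$tmin)[3] < max(ml$last[1:4])) {
      stop("stack for ", st$year, " does not cover January-April")
    }
    tmean <- (st$tmin + st$tmax) / 2
    monthly <- lapply(1:4, function(m) {
      days <- ml$first[m]:ml$last[m]
      apply(tmean[, , days, drop = FALSE], c(1, 2), mean)
    })
    Reduce(`+`, monthly) / 4
  })
  avg <- Reduce(`+`, per_year) / length(per_year)
  pheno_grid(avg, g0$lat, g0$lon)
}

# first/last day-of-year index of each month for a calendar year
month_day_index <- function(year) {
  lens <- c(31, if (year_length(year) == 366) 29 else 28,
            31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  last <- cumsum(lens)
  list(first = c(1, utils::head(last, -1) + 1), last = last)
}

#' Climate envelope of the calibration points
#'
#' Extracts the spring-temperature value of the grid cell containing each
#' calibration site and takes the closed [min, max] interval. Sites outside
#' the grid extent or on missing cells are listed in `rejects`, not fatal.
#'
#' @param grid a spring-temperature `pheno_grid`.
#' @param sites site table with `site_id`, `latitude`, `longitude` (the
#'   calibration sites for one model).
#' @return Object of class `climate_envelope`: `t_min`, `t_max`, `n_points`,
#'   `values` (per-site extractions), `rejects` (site ids not usable).
#' @export
envelope_from_points <- function(grid, sites) {
  stopifnot(inherits(grid, "pheno_grid"), nrow(sites) > 0)
  cells <- cell_of_point(grid, sites$latitude, sites$longitude)
  vals <- rep(NA_real_, nrow(sites))
  ok <- !is.na(cells$row)
  vals[ok] <- grid$values[cbind(cells$row[ok], cells$col[ok])]
  usable <- is.finite(vals)
  if (!any(usable)) stop("no calibration site falls on a usable grid cell")
  structure(list(t_min = min(vals[usable]), t_max = max(vals[usable]),
                 n_points = sum(usable),
                 values = stats::setNames(vals, sites$site_id),
                 rejects = sites$site_id[!usable]),
            class = "climate_envelope")
}

#' @export
print.climate_envelope <- function(x, ...) {
  cat(sprintf("Climate envelope: spring temperature [%.2f, %.2f] degC from %d points",
              x$t_min, x$t_max, x$n_points))
  if (length(x$rejects) > 0) cat(sprintf(" (%d rejected)", length(x$rejects)))
  cat("\n")
  invisible(x)
}

#' Clip a species range to a climate envelope
#'
#' A cell stays in range only if its spring temperature lies inside the
#' closed envelope interval; cells with missing spring temperature drop out.
#'
#' @param mask a `range_mask`.
#' @param grid the spring-temperature `pheno_grid`, aligned with `mask`.
#' @param envelope a `climate_envelope`.
#' @return The clipped `range_mask`.
#' @export
clip_range_to_envelope <- function(mask, grid, envelope) {
  stopifnot(inherits(mask, "range_mask"), inherits(grid, "pheno_grid"),
            inherits(envelope, "climate_envelope"))
  if (!same_georef(mask, grid)) stop("range mask and grid are not aligned")
  inside <- is.finite(grid$values) &
    grid$values >= envelope$t_min & grid$values <= envelope$t_max
  range_mask(mask$values & inside, grid, attr(mask, "species"))
}

#' Fraction of a species range covered by a clipped mask
#'
#' Ratio of clipped to full range area as a percentage. Cell areas are
#' weighted by the cosine of cell-center latitude (cells shrink toward the
#' poles); set `area_weighted = FALSE` for a raw cell count, used by exact
#' brute-force checks.
#'
#' @param clipped,full `range_mask`s on the same grid; `clipped` must be a
#'   subset of `full`.
#' @param area_weighted weight cells by cos(latitude)? Default `TRUE`.
#' @return Percentage in [0, 100].
#' @export
percent_range_covered <- function(clipped, full, area_weighted = TRUE) {
  stopifnot(inherits(clipped, "range_mask"), inherits(full, "range_mask"))
  if (!same_georef(clipped, full)) stop("masks are not aligned")
  if (any(clipped$values & !full$values)) {
    stop("clipped mask is not a subset of the full range")
  }
  w <- if (area_weighted) cos(clipped$lat * pi / 180) else rep(1, length(clipped$lat))
  wm <- matrix(w, nrow = length(clipped$lat), ncol = length(clipped$lon))
  denom <- sum(wm[full$values])
  if (denom == 0) stop("full range mask is empty")
  100 * sum(wm[clipped$values]) / denom
}
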