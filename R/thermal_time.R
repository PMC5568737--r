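#' Daily growing degree days
#'
#' Simple-average GDD: `max(0, (tmin + tmax)/2 - base)`. The daily mean is
#' formed first and then truncated at the base temperature, the convention
#' used by continental GDD map products.
#'
#' @param tmin,tmax daily minimum/maximum temperature, deg C (vectorised).
#' @param base base temperature, deg C (default 0).
#' @return Non-negative heat units, deg C day.
#' @export
daily_gdd <- function(tmin, tmax, base = 0) {
  if (any(tmax < tmin, na.rm = TRUE)) stop("tmax < tmin")
  pmax(0, (tmin + tmax) / 2 - base)
}

#' Construct a daily temperature series for one site and year
#'
#' @param site_id site identifier.
#' @param year calendar year.
#' @param tmin,tmax numeric vectors of daily temperatures, length 365 or 366
#'   matching the year.
#' @return An object of class `temp_series`.
#' @export
temp_series <- function(site_id, year, tmin, tmax) {
  n <- year_length(year)
  if (length(tmin) != n || length(tmax) != n) {
    stop("temperature series for ", year, " must have length ", n)
  }
  if (any(tmax < tmin, na.rm = TRUE)) stop("tmax < tmin in series ", site_id, " ", year)
  structure(list(site_id = as.character(site_id), year = as.integer(year),
                 tmin = as.numeric(tmin), tmax = as.numeric(tmax)),
            class = "temp_series")
}

#' Read a per-site daily temperature CSV
#'
#' Columns: `doy`, `tmin`, `tmax`, sorted or not; one calendar year.
#'
#' @param path CSV path.
#' @param site_id,year series identity.
#' @return A `temp_series`.
#' @export
read_temp_csv <- function(path, site_id, year) {
  df <- utils::read.csv(path)
  required <- c("doy", "tmin", "tmax")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) stop("temperature CSV missing column(s): ",
                                paste(missing, collapse = ", "))
  df <- df[order(df$doy), ]
  if (!identical(as.integer(df$doy), seq_len(year_length(year)))) {
    stop("temperature CSV must cover DOY 1..", year_length(year), " exactly")
  }
  temp_series(site_id, year, df$tmin, df$tmax)
}

#' Accumulated growing degree days by day of year
#'
#' Cumulative sum of [daily_gdd()] from January 1; element `d` is the AGDD
#' accumulated through day `d`.
#'
#' @param series a `temp_series`.
#' @param base base temperature, deg C.
#' @return Non-decreasing numeric vector, one element per calendar day.
#' @export
agdd_series <- function(series, base = 0) {
  stopifnot(inherits(series, "temp_series"))
  cumsum(daily_gdd(series$tmin, series$tmax, base))
}

# round half away from zero; DOYs are positive so this is round-half-up
round_half_up <- function(x) floor(x + 0.5)

#' AGDD accumulated at a phenophase onset
#'
#' Heat units accumulated from Jan 1 through the onset day. Fractional onset
#' DOYs (site means across individuals) are rounded half-up to a calendar
#' day, since accumulation is a daily step function.
#'
#' @param series a `temp_series`.
#' @param first_yes_doy onset day of year, possibly fractional.
#' @param base base temperature, deg C.
#' @return AGDD in deg C day.
#' @export
agdd_at_onset <- function(series, first_yes_doy, base = 0) {
  stopifnot(inherits(series, "temp_series"))
  n <- length(series$tmin)
  if (first_yes_doy < 1 || first_yes_doy > n) {
    stop("first_yes_doy ", first_yes_doy, " outside [1, ", n, "]")
  }
  d <- round_half_up(first_yes_doy)
  agdd_series(series, base)[d]
}

#' Day of year an AGDD threshold is met
#'
#' Smallest day `d` whose accumulated GDD reaches the threshold;
#' `NA_integer_` when the year ends below it. A threshold of zero or less is
#' met on day 1 by convention.
#'
#' @param series a `temp_series` (or a precomputed AGDD vector).
#' @param threshold AGDD threshold, deg C day.
#' @param base base temperature, deg C.
#' @return Integer DOY, or `NA_integer_` if never met.
#' @export
doy_threshold_met <- function(series, threshold, base = 0) {
  stopifnot(is.finite(threshold))
  if (threshold <= 0) return(1L)
  agdd <- if (inherits(series, "temp_series")) agdd_series(series, base) else series
  idx <- which(agdd >= threshold)
  if (length(idx) == 0) NA_integer_ else idx[1]
}

# canonical key into the site x year temperature list
temp_key <- function(site_id, year) paste(site_id, year, sep = "::")

lookup_series <- function(temps, site_id, year) {
  temps[[temp_key(site_id, year)]]
}

#' Fit a universal AGDD threshold for one species x phenophase
#'
#' Computes the AGDD at onset for every calibration site x year and averages
#' them: the universal threshold is the mean AGDD associated with onset,
#' independent of site and year.
#'
#' @param calibration calibration phenometrics for a single species x
#'   phenophase.
#' @param temps named list of `temp_series`, keyed `"<site_id>::<year>"`.
#' @param base base temperature, deg C (0 for these models).
#' @param min_n minimum calibration site x years required (default 30).
#' @return An object of class `thermal_time_model` with fields `species`,
#'   `phenophase`, `threshold_agdd`, `base_temp`, `start_doy`,
#'   `n_calibration`, `per_record_agdd`.
#' @export
estimate_threshold <- function(calibration, temps, base = 0, min_n = 30) {
  sp <- unique(calibration$species)
  ph <- unique(calibration$phenophase)
  if (length(sp) != 1 || length(ph) != 1) {
    stop("estimate_threshold expects one species x phenophase")
  }
  if (!check_min_sample(calibration, min_n)) {
    stop("insufficient calibration data: ",
         nrow(unique(calibration[, c("site_id", "year")])),
         " site x years < ", min_n)
  }
  keys <- temp_key(calibration$site_id, calibration$year)
  absent <- !(keys %in% names(temps))
  if (any(absent)) {
    stop("missing temperature series for: ",
         paste(utils::head(unique(keys[absent]), 10), collapse = "; "))
  }
  agdd <- vapply(seq_len(nrow(calibration)), function(i) {
    agdd_at_onset(temps[[keys[i]]], calibration$first_yes_doy[i], base)
  }, numeric(1))
  structure(list(species = sp, phenophase = ph,
                 threshold_agdd = mean(agdd), base_temp = base,
                 start_doy = 1L, n_calibration = nrow(calibration),
                 per_record_agdd = agdd),
            class = "thermal_time_model")
}

#' @export
print.thermal_time_model <- function(x, ...) {
  cat("Thermal-time model:", x$species, "-", x$phenophase, "\n")
  cat(sprintf("  universal AGDD threshold: %.1f degC day (base %g degC, from DOY %d)\n",
              x$threshold_agdd, x$base_temp, x$start_doy))
  cat(sprintf("  calibration site x years: %d\n", x$n_calibration))
  invisible(x)
}

#' Predict onset days by threshold inversion
#'
#' For each phenometric, returns the DOY the model's universal threshold is
#' met in that site x year's temperature series, alongside the observed
#' first-"yes" DOY. Rows whose threshold is never met during the year are
#' flagged (`met = FALSE`, `predicted_doy = NA`) rather than dropped
#' silently; metric code excludes and counts them.
#'
#' @param model a `thermal_time_model`.
#' @param phens phenometrics to predict for.
#' @param temps named list of `temp_series` keyed `"<site_id>::<year>"`.
#' @return `data.frame` with `site_id`, `year`, `observed_doy`,
#'   `predicted_doy`, `met`.
#' @export
predict_onsets <- function(model, phens, temps) {
  stopifnot(inherits(model, "thermal_time_model"))
  if (nrow(phens) == 0) {
    return(data.frame(site_id = character(), year = integer(),
                      observed_doy = numeric(), predicted_doy = integer(),
                      met = logical(), stringsAsFactors = FALSE))
  }
  keys <- temp_key(phens$site_id, phens$year)
  absent <- !(keys %in% names(temps))
  if (any(absent)) {
    stop("missing temperature series for: ",
         paste(utils::head(unique(keys[absent]), 10), collapse = "; "))
  }
  pred <- vapply(keys, function(k) {
    doy_threshold_met(temps[[k]], model$threshold_agdd, model$base_temp)
  }, integer(1), USE.NAMES = FALSE)
  data.frame(site_id = phens$site_id, year = phens$year,
             observed_doy = phens$first_yes_doy, predicted_doy = pred,
             met = !is.na(pred), stringsAsFactors = FALSE)
}

#' Serialise a thermal-time model to JSON
#'
#' @param model a `thermal_time_model`.
#' @param path output path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "thermal_time_model"))
  x <- model[c("species", "phenophase", "threshold_agdd", "base_temp",
               "start_doy", "n_calibration")]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a thermal-time model from JSON
#'
#' @param path JSON path written by [write_model_json()].
#' @return A `thermal_time_model` (without per-record AGDD values).
#' @export
read_model_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(species = x$species, phenophase = x$phenophase,
                 threshold_agdd = x$threshold_agdd, base_temp = x$base_temp,
                 start_doy = as.integer(x$start_doy),
                 n_calibration = as.integer(x$n_calibration),
                 per_record_agdd = NULL),
            class = "thermal_time_model")
}
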