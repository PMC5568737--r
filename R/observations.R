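#' Recognised phenophases
#'
#' The four phenophase classes handled by the package: the vegetative and
#' reproductive stages that best represent the full expression of a state in
#' a plant and are carried by nearly all status-monitoring protocols.
#'
#' @format Character vector of length four.
#' @export
PHENOPHASES <- c("breaking_leaf_buds", "leaves", "open_flowers", "ripe_fruits")

#' Day of year of a Date
#'
#' DOY 1 is January 1 of the date's own calendar year; leap years run to 366.
#'
#' @param date a `Date` vector.
#' @return Integer day-of-year vector.
#' @export
doy_of_date <- function(date) {
  as.POSIXlt(date)$yday + 1L
}

#' Number of days in a calendar year
#'
#' @param year integer year(s).
#' @return 365L or 366L per element.
#' @export
year_length <- function(year) {
  ifelse(year %% 4 == 0 & (year %% 100 != 0 | year %% 400 == 0), 366L, 365L)
}

#' Read status-format phenology observations
#'
#' Reads a CSV of per-visit status reports: on each visit to an individual
#' plant the observer records whether a phenophase is occurring ("yes") or
#' not ("no"). Required columns: `site_id`, `individual_id`, `species`,
#' `phenophase`, `date` (ISO 8601), `status` (yes/no).
#'
#' @param path path to the status CSV.
#' @return A `data.frame` with one row per report; `date` is a `Date`,
#'   `year` and `doy` are derived columns.
#' @export
read_status_csv <- function(path) {
  if (!file.exists(path)) stop("status file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("site_id", "individual_id", "species", "phenophase", "date", "status")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("status CSV is missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) {
    return(data.frame(site_id = character(), individual_id = character(),
                      species = character(), phenophase = character(),
                      date = as.Date(character()), status = character(),
                      year = integer(), doy = integer(),
                      stringsAsFactors = FALSE))
  }
  bad_phen <- !(df$phenophase %in% PHENOPHASES)
  if (any(bad_phen)) {
    stop("unknown phenophase value(s) at data row(s) ",
         paste(utils::head(which(bad_phen), 5), collapse = ", "),
         ": ", paste(unique(df$phenophase[bad_phen]), collapse = ", "))
  }
  status <- tolower(trimws(df$status))
  bad_status <- !(status %in% c("yes", "no"))
  if (any(bad_status)) {
    stop("status must be 'yes' or 'no'; offending data row(s): ",
         paste(utils::head(which(bad_status), 5), collapse = ", "))
  }
  date <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(date)) {
    stop("unparseable date(s) at data row(s): ",
         paste(utils::head(which(is.na(date)), 5), collapse = ", "))
  }
  data.frame(site_id = df$site_id, individual_id = df$individual_id,
             species = df$species, phenophase = df$phenophase,
             date = date, status = status,
             year = as.integer(format(date, "%Y")),
             doy = doy_of_date(date),
             stringsAsFactors = FALSE)
}

#' Read a site table
#'
#' Columns: `site_id`, `latitude`, `longitude`, optionally `region` (a free
#' tag used by the region-exclusion filter, e.g. a state code).
#'
#' @param path path to the sites CSV.
#' @return `data.frame` with one row per unique site.
#' @export
read_sites_csv <- function(path) {
  if (!file.exists(path)) stop("sites file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("site_id", "latitude", "longitude")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("sites CSV is missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (!("region" %in% names(df))) df$region <- NA_character_
  df$site_id <- as.character(df$site_id)
  df <- df[!duplicated(df$site_id), c("site_id", "latitude", "longitude", "region")]
  if (nrow(df) > 0) {
    if (any(df$latitude < -90 | df$latitude > 90, na.rm = TRUE))
      stop("latitude out of [-90, 90]")
    if (any(df$longitude < -180 | df$longitude > 180, na.rm = TRUE))
      stop("longitude out of [-180, 180]")
  }
  df
}

#' Reduce status records to site phenometrics
#'
#' For each individual plant and year, finds the first "yes" on or after
#' Jan 1 (later yeses the same year are ignored) and that individual's latest
#' "no" strictly before it within the same year. The site phenometric for a
#' site x species x phenophase x year is the mean first-"yes" DOY across
#' individuals with a first yes, and the mean prior-"no" DOY across the
#' subset of those individuals that have one (NA when none does). No
#' cross-year look-back is performed: heat accumulation restarts every Jan 1,
#' so a "yes" with no same-year prior "no" simply has no gap.
#'
#' Conflicting same-day yes/no reports for one individual are resolved with
#' yes-precedence; the number of such conflicts is recorded in the
#' `"conflicts"` attribute of the result.
#'
#' @param records status records as returned by [read_status_csv()] (or the
#'   synthetic generator).
#' @return `data.frame` with columns `site_id`, `species`, `phenophase`,
#'   `year`, `first_yes_doy`, `prior_no_doy`, `n_individuals`.
#' @export
compute_site_phenometrics <- function(records) {
  empty <- data.frame(site_id = character(), species = character(),
                      phenophase = character(), year = integer(),
                      first_yes_doy = numeric(), prior_no_doy = numeric(),
                      n_individuals = integer(), stringsAsFactors = FALSE)
  if (nrow(records) == 0) {
    attr(empty, "conflicts") <- 0L
    return(empty)
  }
  r <- records
  if (!("year" %in% names(r))) r$year <- as.integer(format(r$date, "%Y"))
  if (!("doy" %in% names(r))) r$doy <- doy_of_date(r$date)

  # yes-precedence for contradictory same-day reports on one individual
  day_key <- paste(r$site_id, r$species, r$phenophase, r$individual_id,
                   r$year, r$doy, sep = "\r")
  yes_days <- unique(day_key[r$status == "yes"])
  conflict <- r$status == "no" & day_key %in% yes_days
  n_conflicts <- length(unique(day_key[conflict]))
  r <- r[!conflict, , drop = FALSE]

  ind_key <- paste(r$site_id, r$species, r$phenophase, r$year,
                   r$individual_id, sep = "\r")
  yes <- r[r$status == "yes", , drop = FALSE]
  yes_key <- ind_key[r$status == "yes"]
  if (nrow(yes) == 0) {
    attr(empty, "conflicts") <- n_conflicts
    return(empty)
  }
  first_yes <- tapply(yes$doy, yes_key, min)

  no <- r[r$status == "no", , drop = FALSE]
  no_key <- ind_key[r$status == "no"]
  fy_for_no <- first_yes[no_key]
  keep <- !is.na(fy_for_no) & no$doy < fy_for_no
  prior_no <- if (any(keep)) tapply(no$doy[keep], no_key[keep], max) else numeric(0)

  ind <- data.frame(key = names(first_yes), first_yes = as.numeric(first_yes),
                    stringsAsFactors = FALSE)
  ind$prior_no <- as.numeric(prior_no[ind$key])
  parts <- do.call(rbind, strsplit(ind$key, "\r", fixed = TRUE))
  ind$site_key <- paste(parts[, 1], parts[, 2], parts[, 3], parts[, 4], sep = "\r")

  agg_fy <- tapply(ind$first_yes, ind$site_key, mean)
  agg_pn <- tapply(ind$prior_no, ind$site_key, function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) NA_real_ else mean(x)
  })
  agg_n <- tapply(ind$first_yes, ind$site_key, length)

  keys <- names(agg_fy)
  kp <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
  out <- data.frame(site_id = kp[, 1], species = kp[, 2], phenophase = kp[, 3],
                    year = as.integer(kp[, 4]),
                    first_yes_doy = as.numeric(agg_fy),
                    prior_no_doy = as.numeric(agg_pn[keys]),
                    n_individuals = as.integer(agg_n[keys]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$species, out$phenophase, out$site_id, out$year), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "conflicts") <- n_conflicts
  out
}

#' Filtering configuration
#'
#' Defaults follow the standard status-data trimming rules: the prior-"no"
#' must fall strictly within `max_gap_days` (15) of the first "yes"; onsets
#' after the first day of summer (DOY 172) are discarded for the vegetative
#' phenophases and after Aug 1 (DOY 213) for the reproductive ones; and sites
#' tagged with an excluded region (Alaska by default, where gridded climate
#' coverage is lacking) are dropped.
#'
#' @param max_gap_days strict upper bound (days) on first-yes minus prior-no.
#' @param doy_cutoffs named numeric vector of inclusive DOY cutoffs, one per
#'   phenophase.
#' @param excluded_regions character vector of region tags to drop.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(max_gap_days = 15,
                          doy_cutoffs = c(breaking_leaf_buds = 172, leaves = 172,
                                          open_flowers = 213, ripe_fruits = 213),
                          excluded_regions = "AK") {
  stopifnot(max_gap_days > 0)
  structure(list(max_gap_days = max_gap_days, doy_cutoffs = doy_cutoffs,
                 excluded_regions = excluded_regions),
            class = "filter_config")
}

#' Filter site phenometrics
#'
#' Applies, in order: (a) the prior-"no" gap rule — retained only if a prior
#' "no" exists and `first_yes_doy - prior_no_doy < max_gap_days`; (b) the
#' phenophase DOY cutoff (inclusive); (c) region exclusion. Each removed
#' record is attributed to the first rule it fails, so the audit counts sum
#' to input minus output.
#'
#' @param phens phenometrics from [compute_site_phenometrics()].
#' @param sites site table (needed for region exclusion; may be `NULL` if no
#'   regions are excluded).
#' @param config a [filter_config()].
#' @return A list with `phenometrics` (the retained rows) and `audit`
#'   (named counts: `n_input`, `removed_gap`, `removed_cutoff`,
#'   `removed_region`, `n_retained`).
#' @export
filter_phenometrics <- function(phens, sites = NULL, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  unknown <- setdiff(unique(phens$phenophase), names(config$doy_cutoffs))
  if (length(unknown) > 0) {
    stop("no DOY cutoff configured for phenophase(s): ",
         paste(unknown, collapse = ", "))
  }
  n_input <- nrow(phens)
  gap <- phens$first_yes_doy - phens$prior_no_doy
  pass_gap <- !is.na(phens$prior_no_doy) & gap < config$max_gap_days
  cutoff <- config$doy_cutoffs[phens$phenophase]
  pass_cut <- phens$first_yes_doy <= cutoff
  if (length(config$excluded_regions) > 0 && !is.null(sites)) {
    region <- sites$region[match(phens$site_id, sites$site_id)]
    pass_region <- is.na(region) | !(region %in% config$excluded_regions)
  } else {
    pass_region <- rep(TRUE, n_input)
  }
  removed_gap <- sum(!pass_gap)
  removed_cutoff <- sum(pass_gap & !pass_cut)
  removed_region <- sum(pass_gap & pass_cut & !pass_region)
  keep <- pass_gap & pass_cut & pass_region
  out <- phens[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(phenometrics = out,
       audit = c(n_input = n_input, removed_gap = removed_gap,
                 removed_cutoff = removed_cutoff, removed_region = removed_region,
                 n_retained = nrow(out)))
}

#' Split phenometrics into calibration and validation pools
#'
#' Validation is the hold-out year; calibration is every earlier year. Years
#' after the hold-out are dropped with a count (they postdate the analysis
#' window).
#'
#' @param phens phenometrics.
#' @param holdout_year the validation year.
#' @return list with `calibration`, `validation`, and `n_later_dropped`.
#' @export
split_calibration_validation <- function(phens, holdout_year) {
  stopifnot(is.numeric(holdout_year), length(holdout_year) == 1)
  later <- phens$year > holdout_year
  if (any(later)) {
    warning(sum(later), " phenometric(s) later than the hold-out year dropped")
  }
  list(calibration = phens[phens$year < holdout_year, , drop = FALSE],
       validation = phens[phens$year == holdout_year, , drop = FALSE],
       n_later_dropped = sum(later))
}

#' Minimum-sample check for model construction
#'
#' A species x phenophase is modelled only when its calibration pool holds at
#' least `minimum` distinct site x year combinations.
#'
#' @param calibration calibration phenometrics for one species x phenophase.
#' @param minimum inclusive minimum count (default 30).
#' @return `TRUE` or `FALSE`.
#' @export
check_min_sample <- function(calibration, minimum = 30) {
  n <- nrow(unique(calibration[, c("site_id", "year")]))
  n >= minimum
}
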