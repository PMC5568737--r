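#' Default synthetic species table
#'
#' Three species spanning the realistic range of universal AGDD thresholds
#' (roughly 450-1300 deg C day for temperate woody onsets), one per
#' phenophase class so both DOY cutoffs are exercised.
#'
#' @return `data.frame` with `species`, `phenophase`, `true_threshold_agdd`.
#' @export
default_species_table <- function() {
  data.frame(species = c("spp_early", "spp_mid", "spp_late"),
             phenophase = c("breaking_leaf_buds", "leaves", "open_flowers"),
             true_threshold_agdd = c(450, 700, 1300),
             stringsAsFactors = FALSE)
}

#' Configuration of the synthetic phenology world
#'
#' The generator emulates a network of monitoring sites spread along a
#' latitudinal climate gradient. Each site x year gets a daily temperature
#' series `Tmean(d) = a(lat) - amplitude * cos(2 pi d / 365.25) + AR(1)
#' noise`, with `a(lat) = mean_temp_intercept - mean_temp_lat_slope * lat`
#' and `tmin/tmax = Tmean -/+ diurnal_half_range`. Phenophase onset at a site
#' is the day its true AGDD threshold is crossed; individuals jitter around
#' the site onset; observers visit on a fixed cadence and report yes/no
#' status, producing prior-"no"/first-"yes" intervals whose width is
#' controlled by `visit_interval`.
#'
#' @param n_sites number of monitoring sites (default 50).
#' @param lat_range site latitude range, degrees (default 30-48).
#' @param lon_range site longitude range, degrees (default -96 to -70).
#' @param mean_temp_intercept,mean_temp_lat_slope annual-mean temperature
#'   model `a(lat)`, deg C and deg C per degree latitude (defaults 33, 0.6:
#'   15 deg C at 30 N falling to 4.2 deg C at 48 N).
#' @param seasonal_amplitude half peak-to-trough seasonal swing, deg C
#'   (default 12).
#' @param noise_sd marginal standard deviation of day-to-day temperature
#'   noise, deg C (default 3; 0 gives a pure sinusoid).
#' @param noise_ar1 lag-1 autocorrelation of the noise (default 0.7), so
#'   warm and cold spells persist as in real weather.
#' @param diurnal_half_range half the daily tmax-tmin spread, deg C
#'   (default 5).
#' @param species species table as in [default_species_table()].
#' @param individuals_per_site monitored individuals per species per site
#'   (default 3).
#' @param onset_jitter_sd SD of individual onset jitter, days (default 2).
#' @param visit_interval days between observer visits (default 7).
#' @param visit_phase `"random"` (each individual-year starts its schedule
#'   on a uniformly drawn day within the first interval) or `"fixed"`
#'   (day 1).
#' @param years calendar years simulated (default 2011-2016; the last year
#'   is the conventional hold-out).
#' @param grid_nlat,grid_nlon gridded-stack dimensions (default 20 x 20).
#' @param grid_lat_pad degrees the grid extends beyond the site latitude
#'   range on each side (default 4), so the species range can reach climates
#'   unsampled by any site.
#' @param seed RNG seed applied once at the start of a simulation run;
#'   `NULL` uses the current RNG state.
#' @return A list of class `world_config`.
#' @export
world_config <- function(n_sites = 50,
                         lat_range = c(30, 48),
                         lon_range = c(-96, -70),
                         mean_temp_intercept = 33,
                         mean_temp_lat_slope = 0.6,
                         seasonal_amplitude = 12,
                         noise_sd = 3,
                         noise_ar1 = 0.7,
                         diurnal_half_range = 5,
                         species = default_species_table(),
                         individuals_per_site = 3,
                         onset_jitter_sd = 2,
                         visit_interval = 7,
                         visit_phase = c("random", "fixed"),
                         years = 2011:2016,
                         grid_nlat = 20, grid_nlon = 20,
                         grid_lat_pad = 4,
                         seed = NULL) {
  visit_phase <- match.arg(visit_phase)
  stopifnot(n_sites >= 1, diff(lat_range) >= 0, noise_sd >= 0,
            noise_ar1 >= 0, noise_ar1 < 1, diurnal_half_range >= 0,
            onset_jitter_sd >= 0, visit_interval >= 1,
            all(species$true_threshold_agdd > 0),
            all(species$phenophase %in% PHENOPHASES))
  structure(as.list(environment()), class = "world_config")
}

# annual-mean temperature at a latitude
site_mean_temp <- function(config, lat) {
  config$mean_temp_intercept - config$mean_temp_lat_slope * lat
}

# deterministic seasonal daily-mean cycle for a year
seasonal_cycle <- function(config, lat, year) {
  d <- seq_len(year_length(year))
  site_mean_temp(config, lat) -
    config$seasonal_amplitude * cos(2 * pi * d / 365.25)
}

# AR(1) noise with given marginal sd, drawn from the global RNG
ar1_noise <- function(n, sd, phi) {
  if (sd == 0) return(numeric(n))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

#' Generate the synthetic world
#'
#' Builds the site table, per-site x year daily temperature series, the
#' gridded daily stack for the final simulated year, its JFMA spring
#' climatology, and a rectangular species range mask that extends poleward
#' of the coldest site (so envelope clipping has something to exclude).
#' Grid-cell temperatures are the deterministic climatological sinusoid;
#' site series add AR(1) weather noise on top of it.
#'
#' @param config a [world_config()].
#' @return A list of class `pheno_world`: `config`, `sites`, `temps` (named
#'   list keyed `"<site_id>::<year>"`), `stack`, `spring_grid`,
#'   `range_rings`, `range_mask`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_sites
  lat <- if (n == 1) mean(config$lat_range) else
    seq(config$lat_range[1], config$lat_range[2], length.out = n)
  lon <- stats::runif(n, config$lon_range[1] + 0.5, config$lon_range[2] - 0.5)
  sites <- data.frame(site_id = sprintf("S%03d", seq_len(n)),
                      latitude = lat, longitude = lon,
                      region = NA_character_, stringsAsFactors = FALSE)

  temps <- list()
  for (i in seq_len(n)) {
    for (yr in config$years) {
      ylen <- year_length(yr)
      tmean <- seasonal_cycle(config, lat[i], yr) +
        ar1_noise(ylen, config$noise_sd, config$noise_ar1)
      temps[[temp_key(sites$site_id[i], yr)]] <-
        temp_series(sites$site_id[i], yr,
                    tmean - config$diurnal_half_range,
                    tmean + config$diurnal_half_range)
    }
  }

  map_year <- max(config$years)
  glat_span <- c(config$lat_range[1] - config$grid_lat_pad,
                 config$lat_range[2] + config$grid_lat_pad)
  glat <- seq(glat_span[2], glat_span[1], length.out = config$grid_nlat)
  glon <- seq(config$lon_range[1], config$lon_range[2],
              length.out = config$grid_nlon)
  nd <- year_length(map_year)
  tmean_mat <- vapply(seq_len(nd), function(d) {
    matrix(site_mean_temp(config, glat) -
             config$seasonal_amplitude * cos(2 * pi * d / 365.25),
           nrow = config$grid_nlat, ncol = config$grid_nlon)
  }, matrix(0, config$grid_nlat, config$grid_nlon))
  stack <- temp_stack(tmean_mat - config$diurnal_half_range,
                      tmean_mat + config$diurnal_half_range,
                      glat, glon, map_year)
  spring <- spring_climatology(stack)

  # rectangular range reaching poleward of the coldest site
  rlat <- c(config$lat_range[1] - config$grid_lat_pad / 2,
            config$lat_range[2] + config$grid_lat_pad * 0.75)
  rlon <- c(config$lon_range[1] + 1, config$lon_range[2] - 1)
  ring <- cbind(lon = c(rlon[1], rlon[2], rlon[2], rlon[1]),
                lat = c(rlat[1], rlat[1], rlat[2], rlat[2]))
  mask <- rasterize_range(list(ring), spring)

  structure(list(config = config, sites = sites, temps = temps,
                 stack = stack, spring_grid = spring,
                 range_rings = list(ring), range_mask = mask),
            class = "pheno_world")
}

#' Ground-truth onset days
#'
#' Site-level true onset is the day the species' true AGDD threshold is
#' crossed in that site x year's temperature series; individual onsets add
#' rounded Gaussian jitter (SD `onset_jitter_sd`), clamped to the year.
#' Sites where the threshold is never crossed yield `NA` onsets (the
#' phenophase never occurs that year).
#'
#' @param world a `pheno_world`.
#' @param species species table (default: the world's configured species).
#' @return `data.frame` of truth records: `site_id`, `species`,
#'   `phenophase`, `year`, `individual_id`, `true_onset_doy`,
#'   `site_onset_doy`, `true_threshold_agdd`.
#' @export
generate_true_onsets <- function(world, species = NULL) {
  stopifnot(inherits(world, "pheno_world"))
  config <- world$config
  if (is.null(species)) species <- config$species
  rows <- list()
  for (s in seq_len(nrow(species))) {
    thr <- species$true_threshold_agdd[s]
    for (i in seq_len(nrow(world$sites))) {
      sid <- world$sites$site_id[i]
      for (yr in config$years) {
        series <- world$temps[[temp_key(sid, yr)]]
        onset <- doy_threshold_met(series, thr)
        ylen <- year_length(yr)
        nind <- config$individuals_per_site
        ind_onset <- if (is.na(onset)) rep(NA_integer_, nind) else {
          jit <- round(stats::rnorm(nind, 0, config$onset_jitter_sd))
          pmin(pmax(onset + jit, 1L), ylen)
        }
        rows[[length(rows) + 1]] <- data.frame(
          site_id = sid, species = species$species[s],
          phenophase = species$phenophase[s], year = yr,
          individual_id = sprintf("%s_%s_I%02d", sid, species$species[s],
                                  seq_len(nind)),
          true_onset_doy = as.integer(ind_onset),
          site_onset_doy = as.integer(onset),
          true_threshold_agdd = thr, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Generate status observations from ground truth
#'
#' Each individual x year is visited every `visit_interval` days starting at
#' a per-individual phase (random within the first interval, or day 1 when
#' `visit_phase = "fixed"`); the observer reports "yes" when the visit day
#' is on or after the individual's onset, "no" before it (and all "no" when
#' the phenophase never occurs). With phase <= onset this guarantees a prior
#' "no" within `visit_interval` days of the first "yes".
#'
#' @param truth truth records from [generate_true_onsets()].
#' @param config the [world_config()].
#' @return Status records `data.frame` in the shape of [read_status_csv()]
#'   output.
#' @export
generate_observations <- function(truth, config) {
  stopifnot(inherits(config, "world_config"))
  n <- nrow(truth)
  phase <- if (config$visit_phase == "random") {
    sample.int(config$visit_interval, n, replace = TRUE)
  } else {
    rep(1L, n)
  }
  ylen <- year_length(truth$year)
  visits <- lapply(seq_len(n), function(i) seq.int(phase[i], ylen[i],
                                                   by = config$visit_interval))
  nv <- lengths(visits)
  idx <- rep(seq_len(n), nv)
  doy <- unlist(visits)
  onset <- truth$true_onset_doy[idx]
  status <- ifelse(!is.na(onset) & doy >= onset, "yes", "no")
  date <- as.Date(paste0(truth$year[idx], "-01-01")) + (doy - 1)
  data.frame(site_id = truth$site_id[idx],
             individual_id = truth$individual_id[idx],
             species = truth$species[idx],
             phenophase = truth$phenophase[idx],
             date = date, status = status,
             year = truth$year[idx], doy = doy,
             stringsAsFactors = FALSE)
}

#' Run the full synthetic generator
#'
#' Seeds the global RNG once (when the config carries a seed) and produces
#' the world, the ground-truth onsets and the observer records in one call.
#'
#' @param config a [world_config()].
#' @return A list of class `pheno_sim`: `world`, `truth`, `records`.
#' @export
simulate_dataset <- function(config = world_config()) {
  if (!is.null(config$seed)) set.seed(config$seed)
  cfg <- config
  cfg$seed <- NULL  # world must not re-seed mid-stream
  world <- generate_world(cfg)
  world$config <- config
  truth <- generate_true_onsets(world)
  records <- generate_observations(truth, config)
  structure(list(world = world, truth = truth, records = records),
            class = "pheno_sim")
}

#' Write a simulated dataset to disk in the package's interchange formats
#'
#' Emits `sites.csv`, `status.csv`, per-site temperature CSVs under
#' `temps/`, `spring.asc`, `range.geojson`, `truth.csv` and a JSON echo of
#' the configuration — the same dialects the readers consume.
#'
#' @param sim a `pheno_sim`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "pheno_sim"))
  dir.create(file.path(dir, "temps"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$world$sites, file.path(dir, "sites.csv"), row.names = FALSE)
  rec <- sim$records[, c("site_id", "individual_id", "species", "phenophase",
                         "date", "status")]
  utils::write.csv(rec, file.path(dir, "status.csv"), row.names = FALSE)
  for (key in names(sim$world$temps)) {
    ts <- sim$world$temps[[key]]
    utils::write.csv(data.frame(doy = seq_along(ts$tmin), tmin = ts$tmin,
                                tmax = ts$tmax),
                     file.path(dir, "temps", paste0(gsub("::", "_", key), ".csv")),
                     row.names = FALSE)
  }
  write_ascii_grid(sim$world$spring_grid, file.path(dir, "spring.asc"))
  write_range_geojson(sim$world$range_rings, file.path(dir, "range.geojson"))
  utils::write.csv(sim$truth, file.path(dir, "truth.csv"), row.names = FALSE)
  cfg <- sim$world$config
  cfg$species <- as.list(cfg$species)
  jsonlite::write_json(cfg[setdiff(names(cfg), "visit_phase_choices")],
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}
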