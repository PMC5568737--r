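small_config <- function(...) {
  args <- list(n_sites = 6, years = 2014:2016, individuals_per_site = 2,
               grid_nlat = 10, grid_nlon = 10, seed = 99)
  args[names(list(...))] <- list(...)
  do.call(world_config, args)
}

test_that("the synthetic world realises its configured climate gradient", {
  cfg <- world_config(n_sites = 2, lat_range = c(30, 45), years = 2015,
                      noise_sd = 0, seed = 1)
  w <- generate_world(cfg)
  jfma <- function(ts) mean((ts$tmin[1:120] + ts$tmax[1:120]) / 2)
  s30 <- w$temps[[phenothermal:::temp_key("S001", 2015)]]
  s45 <- w$temps[[phenothermal:::temp_key("S002", 2015)]]
  expect_gt(jfma(s30), jfma(s45))

  # zero noise + zero amplitude + flat gradient: constant temperatures
  flat <- world_config(n_sites = 2, noise_sd = 0, seasonal_amplitude = 0,
                       mean_temp_intercept = 10, mean_temp_lat_slope = 0,
                       diurnal_half_range = 0, years = 2015, seed = 1)
  wf <- generate_world(flat)
  ts <- wf$temps[[phenothermal:::temp_key("S001", 2015)]]
  expect_equal(ts$tmin, rep(10, 365))
  expect_equal(ts$tmax, rep(10, 365))
})

test_that("simulation is deterministic under a fixed seed", {
  a <- simulate_dataset(small_config())
  b <- simulate_dataset(small_config())
  expect_equal(a$records, b$records)
  expect_equal(a$truth, b$truth)
  expect_equal(a$world$sites, b$world$sites)
  expect_equal(a$world$temps, b$world$temps)
})

test_that("ground-truth onsets follow the threshold crossing plus jitter", {
  cfg <- world_config(n_sites = 1, lat_range = c(35, 35), noise_sd = 0,
                      seasonal_amplitude = 0, mean_temp_intercept = 10,
                      mean_temp_lat_slope = 0, diurnal_half_range = 0,
                      species = data.frame(species = "x", phenophase = "leaves",
                                           true_threshold_agdd = 500),
                      onset_jitter_sd = 0, individuals_per_site = 4,
                      years = 2015, seed = 2)
  w <- generate_world(cfg)
  truth <- generate_true_onsets(w)
  # constant 10 degC mean: threshold 500 crosses on day 50, no jitter
  expect_true(all(truth$true_onset_doy == 50L))
  expect_true(all(truth$site_onset_doy == 50L))

  # jittered onsets scatter around the site onset with roughly the configured sd
  cfg$onset_jitter_sd <- 2
  cfg$individuals_per_site <- 400
  set.seed(3)
  truth_j <- generate_true_onsets(generate_world(cfg))
  expect_equal(mean(truth_j$true_onset_doy), 50, tolerance = 0.01)
  expect_equal(sd(truth_j$true_onset_doy), 2, tolerance = 0.15)
})

test_that("daily observation reproduces the true onset with gap 1", {
  cfg <- small_config(visit_interval = 1, onset_jitter_sd = 0, noise_sd = 0)
  sim <- simulate_dataset(cfg)
  phens <- compute_site_phenometrics(sim$records)
  site_truth <- unique(sim$truth[, c("site_id", "species", "phenophase",
                                     "year", "site_onset_doy")])
  m <- merge(phens, site_truth)
  expect_true(all(m$first_yes_doy == m$site_onset_doy))
  expect_true(all(ifelse(is.na(m$prior_no_doy), m$first_yes_doy == 1,
                         m$first_yes_doy - m$prior_no_doy == 1)))
})

test_that("sparse visit schedules bound the prior-no gap at the visit interval", {
  sim <- simulate_dataset(small_config(visit_interval = 7))
  phens <- compute_site_phenometrics(sim$records)
  gaps <- phens$first_yes_doy - phens$prior_no_doy
  expect_true(all(gaps[!is.na(gaps)] <= 7))

  # a 20-day cadence leaves nothing inside the strict 15-day window
  sim20 <- simulate_dataset(small_config(visit_interval = 20))
  phens20 <- compute_site_phenometrics(sim20$records)
  out <- filter_phenometrics(phens20, sim20$world$sites)
  expect_equal(nrow(out$phenometrics), 0)
  expect_equal(unname(out$audit["removed_gap"]), nrow(phens20))
})

test_that("the exact regime recovers each true threshold within one day's maximum GDD", {
  cfg <- small_config(visit_interval = 1, onset_jitter_sd = 0, noise_sd = 0,
                      n_sites = 12)
  sim <- simulate_dataset(cfg)
  phens <- compute_site_phenometrics(sim$records)
  split <- split_calibration_validation(phens, 2016)
  max_gdd <- max(vapply(sim$world$temps, function(ts) {
    max(daily_gdd(ts$tmin, ts$tmax))
  }, numeric(1)))
  for (i in seq_len(nrow(cfg$species))) {
    sp <- cfg$species$species[i]
    cal <- split$calibration[split$calibration$species == sp, , drop = FALSE]
    model <- estimate_threshold(cal, sim$world$temps, min_n = 1)
    expect_lt(abs(model$threshold_agdd - cfg$species$true_threshold_agdd[i]),
              max_gdd)
  }
})

test_that("the synthetic range reaches climates beyond the calibration envelope", {
  # default grid resolution: cells are fine enough to resolve latitudes
  # poleward of the coldest site
  sim <- simulate_dataset(small_config(grid_nlat = 20, grid_nlon = 20))
  env <- envelope_from_points(sim$world$spring_grid, sim$world$sites)
  clipped <- clip_range_to_envelope(sim$world$range_mask, sim$world$spring_grid, env)
  pct <- percent_range_covered(clipped, sim$world$range_mask)
  expect_lt(pct, 100)
  expect_gt(pct, 0)
})

test_that("a written dataset reads back through the package's own readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(small_config(years = 2015:2016, n_sites = 3))
  write_simulated_dataset(sim, dir)

  rec <- read_status_csv(file.path(dir, "status.csv"))
  expect_equal(nrow(rec), nrow(sim$records))
  expect_equal(compute_site_phenometrics(rec),
               compute_site_phenometrics(sim$records))

  sites <- read_sites_csv(file.path(dir, "sites.csv"))
  expect_equal(sites$site_id, sim$world$sites$site_id)

  ts <- read_temp_csv(file.path(dir, "temps", "S001_2015.csv"), "S001", 2015)
  expect_equal(ts$tmin, sim$world$temps[["S001::2015"]]$tmin, tolerance = 1e-9)

  spring <- read_ascii_grid(file.path(dir, "spring.asc"))
  expect_equal(spring$values, sim$world$spring_grid$values, tolerance = 1e-6)

  mask <- rasterize_range(read_range_geojson(file.path(dir, "range.geojson")),
                          spring)
  expect_equal(mask$values, sim$world$range_mask$values)
})
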