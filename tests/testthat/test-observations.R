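test_that("status CSV reader parses well-formed files and rejects bad ones", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_id,individual_id,species,phenophase,date,status",
               "A,I1,oak,leaves,2015-03-01,no",
               "A,I1,oak,leaves,2015-03-08,yes",
               "A,I2,oak,leaves,2015-03-10,yes"), path)
  rec <- read_status_csv(path)
  expect_equal(nrow(rec), 3)
  expect_s3_class(rec$date, "Date")
  expect_equal(rec$doy[1], 60)  # 2015-03-01
  expect_equal(length(unique(rec$site_id)), 1)

  # header-only file: empty collections, no error
  writeLines("site_id,individual_id,species,phenophase,date,status", path)
  expect_equal(nrow(read_status_csv(path)), 0)

  # enum violation in status
  writeLines(c("site_id,individual_id,species,phenophase,date,status",
               "A,I1,oak,leaves,2015-03-01,maybe"), path)
  expect_error(read_status_csv(path), "status.*row")

  # unknown phenophase
  writeLines(c("site_id,individual_id,species,phenophase,date,status",
               "A,I1,oak,budburst,2015-03-01,yes"), path)
  expect_error(read_status_csv(path), "phenophase")

  # missing column named in the error
  writeLines(c("site_id,individual_id,species,phenophase,date",
               "A,I1,oak,leaves,2015-03-01"), path)
  expect_error(read_status_csv(path), "status")

  # unparseable date carries the row number
  writeLines(c("site_id,individual_id,species,phenophase,date,status",
               "A,I1,oak,leaves,2015-03-01,yes",
               "A,I1,oak,leaves,not-a-date,yes"), path)
  expect_error(read_status_csv(path), "date.*2")
})

test_that("site reader deduplicates and validates coordinates", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("site_id,latitude,longitude,region",
               "A,40.1,-75.2,PA", "A,40.1,-75.2,PA", "B,64.8,-147.7,AK"), path)
  sites <- read_sites_csv(path)
  expect_equal(nrow(sites), 2)
  expect_equal(sites$region, c("PA", "AK"))

  writeLines(c("site_id,latitude,longitude", "A,95,-75.2"), path)
  expect_error(read_sites_csv(path), "latitude")
  writeLines(c("site_id,latitude", "A,40"), path)
  expect_error(read_sites_csv(path), "longitude")
})

test_that("site phenometrics average individual first-yes and prior-no days", {
  # two individuals, first-yes DOYs 100 and 104 -> site mean 102
  rec <- status_df("A", c("I1", "I1", "I2", "I2"), "oak", "leaves",
                   as.Date("2015-01-01") + c(94, 99, 98, 103),
                   c("no", "yes", "no", "yes"))
  p <- compute_site_phenometrics(rec)
  expect_equal(nrow(p), 1)
  expect_equal(p$first_yes_doy, 102)
  expect_equal(p$prior_no_doy, 97)   # mean of 95 and 99
  expect_equal(p$n_individuals, 2L)

  # a single monitored individual: its values are used directly
  rec <- status_df("A", "I1", "oak", "leaves",
                   as.Date("2015-01-01") + c(84, 89), c("no", "yes"))
  p <- compute_site_phenometrics(rec)
  expect_equal(p$first_yes_doy, 90)
  expect_equal(p$prior_no_doy, 85)

  # later yeses in the same year are ignored
  rec <- status_df("A", "I1", "oak", "leaves",
                   as.Date("2015-01-01") + c(49, 199), c("yes", "yes"))
  p <- compute_site_phenometrics(rec)
  expect_equal(p$first_yes_doy, 50)
  expect_true(is.na(p$prior_no_doy))

  # prior-no mean runs only over individuals that have one
  rec <- rbind(
    status_df("A", "I1", "oak", "leaves",
              as.Date("2015-01-01") + c(94, 99), c("no", "yes")),
    status_df("A", "I2", "oak", "leaves",
              as.Date("2015-01-01") + 103, "yes"))
  p <- compute_site_phenometrics(rec)
  expect_equal(p$first_yes_doy, 102)
  expect_equal(p$prior_no_doy, 95)
})

test_that("same-day yes/no conflicts resolve to yes and are counted", {
  rec <- status_df("A", c("I1", "I1", "I1"), "oak", "leaves",
                   as.Date("2015-01-01") + c(90, 90, 80),
                   c("yes", "no", "no"))
  p <- compute_site_phenometrics(rec)
  expect_equal(p$first_yes_doy, 91)
  expect_equal(p$prior_no_doy, 81)
  expect_equal(attr(p, "conflicts"), 1L)
})

test_that("phenometrics are invariant to record order and track years separately", {
  set.seed(42)
  rec <- status_df("A", rep(c("I1", "I2"), each = 6), "oak", "leaves",
                   rep(as.Date("2015-01-01") + seq(60, 110, by = 10), 2),
                   c("no", "no", "no", "yes", "yes", "yes",
                     "no", "no", "yes", "yes", "yes", "yes"))
  rec2 <- rbind(rec, status_df("A", "I1", "oak", "leaves",
                               as.Date("2014-03-15"), "yes"))
  for (i in 1:5) {
    shuffled <- rec2[sample(nrow(rec2)), ]
    expect_equal(compute_site_phenometrics(shuffled),
                 compute_site_phenometrics(rec2), ignore_attr = TRUE)
  }
  p <- compute_site_phenometrics(rec2)
  expect_equal(sort(p$year), c(2014, 2015))
  # no cross-year prior-no look-back: the 2014 yes has no gap
  expect_true(is.na(p$prior_no_doy[p$year == 2014]))
})

test_that("the gap rule is strict and the DOY cutoffs inclusive", {
  phens <- phen_df("S1", "oak", "leaves", 2015,
                   first_yes_doy = c(100, 100, 100, 100, 100),
                   prior_no_doy = c(97, 86, 85, 80, NA))  # gaps 3,14,15,20,absent
  out <- filter_phenometrics(phens, config = filter_config())
  expect_equal(nrow(out$phenometrics), 2)
  expect_equal(out$phenometrics$prior_no_doy, c(97, 86))
  expect_equal(unname(out$audit["removed_gap"]), 3)

  # vegetative cutoff at 172, inclusive
  phens <- phen_df("S1", "oak", "leaves", 2015, c(172, 173, 180), c(170, 171, 178))
  out <- filter_phenometrics(phens, config = filter_config())
  expect_equal(out$phenometrics$first_yes_doy, 172)
  expect_equal(unname(out$audit["removed_cutoff"]), 2)

  # reproductive cutoff at 213
  phens <- phen_df("S1", "oak", "open_flowers", 2015, c(200, 213, 214),
                   c(190, 204, 205))
  out <- filter_phenometrics(phens, config = filter_config())
  expect_equal(out$phenometrics$first_yes_doy, c(200, 213))
})

test_that("region exclusion drops tagged sites and audits reconcile", {
  sites <- data.frame(site_id = c("S1", "S2"), latitude = c(40, 64),
                      longitude = c(-75, -147), region = c("PA", "AK"),
                      stringsAsFactors = FALSE)
  phens <- phen_df(c("S1", "S2", "S2"), "oak", "leaves", 2015,
                   c(100, 110, 300), c(95, 105, 290))
  out <- filter_phenometrics(phens, sites, filter_config())
  expect_equal(out$phenometrics$site_id, "S1")
  # the DOY-300 row fails both cutoff and region; it is attributed to cutoff
  expect_equal(unname(out$audit["removed_cutoff"]), 1)
  expect_equal(unname(out$audit["removed_region"]), 1)
  expect_equal(unname(out$audit["n_input"] - out$audit["n_retained"]),
               unname(sum(out$audit[c("removed_gap", "removed_cutoff",
                                      "removed_region")])))

  expect_error(filter_phenometrics(phen_df("S1", "oak", "weird", 2015, 100, 95)),
               "weird")
})

test_that("filtering is idempotent and every survivor satisfies all rules", {
  set.seed(7)
  n <- 60
  phens <- phen_df(sprintf("S%02d", sample(1:20, n, TRUE)), "oak",
                   sample(PHENOPHASES, n, TRUE), sample(2012:2016, n, TRUE),
                   first_yes_doy = runif(n, 1, 300),
                   prior_no_doy = NA_real_)
  has_no <- runif(n) < 0.8
  phens$prior_no_doy[has_no] <- phens$first_yes_doy[has_no] - runif(sum(has_no), 1, 30)
  cfg <- filter_config()
  once <- filter_phenometrics(phens, config = cfg)
  twice <- filter_phenometrics(once$phenometrics, config = cfg)
  expect_equal(twice$phenometrics, once$phenometrics)
  expect_equal(unname(twice$audit[c("removed_gap", "removed_cutoff", "removed_region")]),
               c(0, 0, 0))
  kept <- once$phenometrics
  expect_true(all(kept$first_yes_doy - kept$prior_no_doy < cfg$max_gap_days))
  expect_true(all(kept$first_yes_doy <= cfg$doy_cutoffs[kept$phenophase]))
})

test_that("calibration/validation split honours the hold-out year", {
  phens <- phen_df("S1", "oak", "leaves", c(2012, 2015, 2016), c(90, 95, 100),
                   c(85, 90, 95))
  s <- split_calibration_validation(phens, 2016)
  expect_equal(sort(s$calibration$year), c(2012, 2015))
  expect_equal(s$validation$year, 2016)
  expect_equal(s$n_later_dropped, 0)

  s <- split_calibration_validation(phens[phens$year == 2016, , drop = FALSE], 2016)
  expect_equal(nrow(s$calibration), 0)
  expect_false(check_min_sample(s$calibration))

  expect_warning(s <- split_calibration_validation(phens, 2015), "later")
  expect_equal(s$n_later_dropped, 1)

  s <- split_calibration_validation(phens[0, ], 2016)
  expect_equal(nrow(s$calibration), 0)
  expect_equal(nrow(s$validation), 0)
})

test_that("minimum-sample rule counts distinct site x years inclusively", {
  mk <- function(n) phen_df(sprintf("S%03d", seq_len(n)), "oak", "leaves",
                            2015, rep(100, n), rep(95, n))
  expect_true(check_min_sample(mk(33)))
  expect_false(check_min_sample(mk(29)))
  expect_true(check_min_sample(mk(30)))
  # duplicated site x year rows do not inflate the count
  dup <- rbind(mk(29), mk(29)[1, ])
  expect_false(check_min_sample(dup))
})
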