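# shared builders for tiny in-code fixtures

# constant-mean temperature series: tmin = mean - hr, tmax = mean + hr
const_series <- function(mean_temp, year = 2015, site_id = "S1", half_range = 0) {
  n <- phenothermal::year_length(year)
  phenothermal::temp_series(site_id, year,
                            rep(mean_temp - half_range, n),
                            rep(mean_temp + half_range, n))
}

# a phenometric row set with free-form fields
phen_df <- function(site_id, species, phenophase, year, first_yes_doy,
                    prior_no_doy = NA_real_, n_individuals = 1L) {
  data.frame(site_id = site_id, species = species, phenophase = phenophase,
             year = year, first_yes_doy = first_yes_doy,
             prior_no_doy = prior_no_doy, n_individuals = n_individuals,
             stringsAsFactors = FALSE)
}

# status record rows
status_df <- function(site_id, individual_id, species, phenophase, date, status) {
  data.frame(site_id = site_id, individual_id = individual_id,
             species = species, phenophase = phenophase,
             date = as.Date(date), status = status, stringsAsFactors = FALSE)
}

# independent brute-force oracle: day-by-day accumulation scan
naive_doy_scan <- function(tmin, tmax, threshold, base = 0) {
  if (threshold <= 0) return(1L)
  acc <- 0
  for (d in seq_along(tmin)) {
    g <- (tmin[d] + tmax[d]) / 2 - base
    if (g > 0) acc <- acc + g
    if (acc >= threshold) return(as.integer(d))
  }
  NA_integer_
}

# small random temperature series for property tests
random_series <- function(n_days = 60, year = 2015, site_id = "R1") {
  tmean <- stats::runif(n_days, -10, 20)
  hr <- stats::runif(n_days, 0, 8)
  s <- phenothermal::temp_series(site_id, year,
                                 c(tmean - hr, rep(-20, phenothermal::year_length(year) - n_days)),
                                 c(tmean + hr, rep(-20, phenothermal::year_length(year) - n_days)))
  s
}
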