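#' Full-run configuration
#'
#' Collects every tunable of the end-to-end analysis. Defaults mirror the
#' standard protocol: 15-day prior-"no" window, DOY cutoffs 172/213, 2016
#' hold-out, candidate criteria NSME >= 0.4, R^2 >= 0.5, MAE <= 10 days, and
#' a 30 site x year minimum per model.
#'
#' @param filter a [filter_config()].
#' @param holdout_year validation year (default 2016).
#' @param criteria a [candidate_criteria()].
#' @param min_n minimum calibration site x years per model (default 30).
#' @param area_weighted cosine-latitude weighting for range coverage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(filter = filter_config(), holdout_year = 2016,
                       criteria = candidate_criteria(), min_n = 30,
                       area_weighted = TRUE) {
  structure(list(filter = filter, holdout_year = holdout_year,
                 criteria = criteria, min_n = min_n,
                 area_weighted = area_weighted),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Recognised keys (all optional): `max_gap_days`, `doy_cutoffs` (named
#' map), `excluded_regions`, `holdout_year`, `nsme_min`, `r2_min`,
#' `mae_max`, `min_n`, `area_weighted`.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  fc_args <- list()
  if (!is.null(y$max_gap_days)) fc_args$max_gap_days <- y$max_gap_days
  if (!is.null(y$doy_cutoffs)) fc_args$doy_cutoffs <- unlist(y$doy_cutoffs)
  if (!is.null(y$excluded_regions)) fc_args$excluded_regions <- unlist(y$excluded_regions)
  cc_args <- list()
  for (k in c("nsme_min", "r2_min", "mae_max")) {
    if (!is.null(y[[k]])) cc_args[[k]] <- y[[k]]
  }
  run_config(filter = do.call(filter_config, fc_args),
             holdout_year = if (is.null(y$holdout_year)) 2016 else y$holdout_year,
             criteria = do.call(candidate_criteria, cc_args),
             min_n = if (is.null(y$min_n)) 30 else y$min_n,
             area_weighted = if (is.null(y$area_weighted)) TRUE else y$area_weighted)
}

#' Run the complete analysis over every species x phenophase
#'
#' Pipeline: status records are reduced to site phenometrics, filtered,
#' split into calibration and validation pools; each species x phenophase
#' with at least `min_n` calibration site x years gets a universal AGDD
#' threshold, a null model, calibration and validation evaluation reports
#' and a candidate flag; the rest are listed as insufficient-data. When a
#' spring-temperature grid and range mask are supplied, the calibration
#' climate envelope and the percentage of the range the model extends to
#' are computed as well. A stage failure in one combination is recorded for
#' that combination without aborting the run.
#'
#' @param records status records ([read_status_csv()] shape).
#' @param sites site table.
#' @param temps named list of `temp_series` keyed `"<site_id>::<year>"`.
#' @param config a [run_config()].
#' @param spring_grid optional spring-temperature `pheno_grid`.
#' @param range_masks optional: a single `range_mask` shared by all species,
#'   or a named list keyed by species.
#' @param out_dir optional directory; when given, a Table-1-shaped summary
#'   CSV (`model_summary.csv`), the full report (`run_report.json`) and the
#'   filter audit (`filter_audit.json`) are written there.
#' @return A list of class `run_report`: `summary` (one row per combination),
#'   `models`, `null_models`, `reports`, `audit`, `conflicts`.
#' @export
run_all <- function(records, sites, temps, config = run_config(),
                    spring_grid = NULL, range_masks = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  phens <- compute_site_phenometrics(records)
  filt <- filter_phenometrics(phens, sites, config$filter)
  split <- split_calibration_validation(filt$phenometrics, config$holdout_year)

  combos <- unique(filt$phenometrics[, c("species", "phenophase")])
  combos <- combos[order(combos$species, combos$phenophase), , drop = FALSE]
  models <- list(); nulls <- list(); reports <- list()
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    sp <- combos$species[i]; ph <- combos$phenophase[i]
    key <- paste(sp, ph, sep = ":")
    cal <- split$calibration[split$calibration$species == sp &
                               split$calibration$phenophase == ph, , drop = FALSE]
    val <- split$validation[split$validation$species == sp &
                              split$validation$phenophase == ph, , drop = FALSE]
    row <- data.frame(species = sp, phenophase = ph,
                      n_calibration = nrow(unique(cal[, c("site_id", "year")])),
                      status = "ok", threshold_agdd = NA_real_,
                      null_mae = NA_real_, null_rmse = NA_real_,
                      calib_mae = NA_real_, calib_rmse = NA_real_,
                      calib_r2 = NA_real_, calib_nsme = NA_real_,
                      n_validation = nrow(val), valid_mae = NA_real_,
                      valid_rmse = NA_real_, valid_r2 = NA_real_,
                      valid_nsme = NA_real_, n_not_met = NA_integer_,
                      candidate = FALSE, pct_range = NA_real_,
                      envelope_t_min = NA_real_, envelope_t_max = NA_real_,
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      if (!check_min_sample(cal, config$min_n)) {
        row$status <- "insufficient_data"
      } else {
        model <- estimate_threshold(cal, temps, min_n = config$min_n)
        null <- fit_null(cal)
        cal_rep <- evaluate_model(model, null, cal, temps, "calibration")
        val_rep <- if (nrow(val) > 0) {
          evaluate_model(model, null, val, temps, "validation")
        } else NULL
        models[[key]] <- model
        nulls[[key]] <- null
        reports[[key]] <- list(calibration = cal_rep, validation = val_rep)
        row$threshold_agdd <- model$threshold_agdd
        null_res <- null$mean_doy - cal$first_yes_doy
        row$null_mae <- mae(null_res)
        row$null_rmse <- rmse(null_res)
        row$calib_mae <- cal_rep$mae; row$calib_rmse <- cal_rep$rmse
        row$calib_r2 <- cal_rep$r2; row$calib_nsme <- cal_rep$nsme
        row$n_not_met <- cal_rep$n_not_met
        if (!is.null(val_rep) && val_rep$n > 0) {
          row$valid_mae <- val_rep$mae; row$valid_rmse <- val_rep$rmse
          row$valid_r2 <- val_rep$r2; row$valid_nsme <- val_rep$nsme
        }
        row$candidate <- is_candidate(cal_rep, config$criteria)
        if (anyNA(c(cal_rep$r2, cal_rep$nsme))) row$status <- "metric_undefined"
        if (!is.null(spring_grid)) {
          mask <- if (inherits(range_masks, "range_mask")) range_masks
                  else range_masks[[sp]]
          if (!is.null(mask)) {
            cal_sites <- sites[sites$site_id %in% unique(cal$site_id), , drop = FALSE]
            env <- envelope_from_points(spring_grid, cal_sites)
            clipped <- clip_range_to_envelope(mask, spring_grid, env)
            row$pct_range <- percent_range_covered(clipped, mask,
                                                   config$area_weighted)
            row$envelope_t_min <- env$t_min
            row$envelope_t_max <- env$t_max
          }
        }
      }
      row
    }, error = function(e) {
      row$status <- paste("error:", conditionMessage(e))
      row
    })
    rows[[i]] <- res
  }
  summary <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(species = character(0))
  rownames(summary) <- NULL
  report <- structure(list(summary = summary, models = models,
                           null_models = nulls, reports = reports,
                           audit = filt$audit,
                           n_later_dropped = split$n_later_dropped,
                           conflicts = attr(phens, "conflicts")),
                      class = "run_report")
  if (!is.null(out_dir)) write_run_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Run report: %d species x phenophase combination(s), %d modelled, %d candidate(s)\n",
              nrow(s), sum(!is.na(s$threshold_agdd)), sum(s$candidate)))
  cat(sprintf("  filter audit: %d in, %d retained (gap %d, cutoff %d, region %d removed)\n",
              x$audit["n_input"], x$audit["n_retained"], x$audit["removed_gap"],
              x$audit["removed_cutoff"], x$audit["removed_region"]))
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits `model_summary.csv` (one Table-1-shaped row per combination),
#' `run_report.json` (summary + audit, full precision) and
#' `filter_audit.json`. Output is deterministic for a given report, so
#' reruns under the same seed are byte-identical.
#'
#' @param report a `run_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$summary, file.path(dir, "model_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(summary = report$summary,
                            audit = as.list(report$audit),
                            n_later_dropped = report$n_later_dropped,
                            conflicts = report$conflicts),
                       file.path(dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  jsonlite::write_json(as.list(report$audit), file.path(dir, "filter_audit.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Run the pipeline on a simulated dataset
#'
#' Convenience wrapper: [simulate_dataset()] then [run_all()], wiring the
#' synthetic world's temperatures, spring grid and range mask through.
#'
#' @param config a [world_config()].
#' @param run a [run_config()]; its hold-out defaults to the last simulated
#'   year.
#' @param out_dir optional output directory, passed to [run_all()].
#' @return A list: `sim` (the `pheno_sim`) and `report` (the `run_report`).
#' @export
run_all_synthetic <- function(config = world_config(),
                              run = run_config(holdout_year = max(config$years)),
                              out_dir = NULL) {
  sim <- simulate_dataset(config)
  report <- run_all(sim$records, sim$world$sites, sim$world$temps, run,
                    spring_grid = sim$world$spring_grid,
                    range_masks = sim$world$range_mask, out_dir = out_dir)
  list(sim = sim, report = report)
}
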