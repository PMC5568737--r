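#' Fit the null model for a species x phenophase
#'
#' The null predictor is the calibration-period mean of the site-level mean
#' first-"yes" DOYs: every site x year is predicted to transition on the same
#' constant day. Thermal-time models must beat this to be of interest.
#'
#' @param calibration calibration phenometrics for one species x phenophase.
#' @return Object of class `null_model` with `species`, `phenophase`,
#'   `mean_doy`.
#' @export
fit_null <- function(calibration) {
  if (nrow(calibration) == 0) stop("cannot fit a null model to an empty calibration set")
  sp <- unique(calibration$species)
  ph <- unique(calibration$phenophase)
  if (length(sp) != 1 || length(ph) != 1) stop("fit_null expects one species x phenophase")
  structure(list(species = sp, phenophase = ph,
                 mean_doy = mean(calibration$first_yes_doy)),
            class = "null_model")
}

#' Mean absolute error
#' @param residuals predicted-minus-observed differences, days.
#' @return MAE in days.
#' @export
mae <- function(residuals) {
  if (length(residuals) == 0) stop("MAE of an empty residual vector is undefined")
  mean(abs(residuals))
}

#' Root mean squared error
#' @param residuals predicted-minus-observed differences, days.
#' @return RMSE in days.
#' @export
rmse <- function(residuals) {
  if (length(residuals) == 0) stop("RMSE of an empty residual vector is undefined")
  sqrt(mean(residuals^2))
}

#' Nash-Sutcliffe model efficiency
#'
#' `1 - sum((pred - obs)^2) / sum((null - obs)^2)`: 1 is a perfect match,
#' 0 means no better than the null predictor, negative means worse; the
#' range is (-Inf, 1].
#'
#' @param predicted,observed,null_predicted equal-length numeric vectors.
#' @return Dimensionless efficiency.
#' @export
nsme <- function(predicted, observed, null_predicted) {
  n <- length(observed)
  if (n == 0 || length(predicted) != n || length(null_predicted) != n) {
    stop("nsme requires equal-length, non-empty vectors")
  }
  ss_null <- sum((null_predicted - observed)^2)
  if (ss_null == 0) {
    stop("null sum of squares is zero; model efficiency is undefined")
  }
  1 - sum((predicted - observed)^2) / ss_null
}

#' Squared Pearson correlation of predicted vs observed
#'
#' Note R^2 is direction-blind (a perfectly anti-correlated predictor also
#' scores 1); MAE and NSME catch that case.
#'
#' @param predicted,observed equal-length numeric vectors, n >= 2.
#' @return R^2 in [0, 1].
#' @export
r_squared <- function(predicted, observed) {
  n <- length(observed)
  if (n < 2 || length(predicted) != n) stop("r_squared requires n >= 2 paired values")
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    stop("zero variance; R^2 is undefined")
  }
  stats::cor(predicted, observed)^2
}

#' Evaluate a thermal-time model against observations
#'
#' Runs [predict_onsets()] and computes MAE, RMSE, R^2 and NSME on the rows
#' whose threshold was met during the year; never-met rows are excluded and
#' counted in `n_not_met`. Residuals are predicted minus observed, so a
#' negative residual means the model predicted the phenophase earlier than
#' observers reported it. The null constant comes from the calibration-fit
#' null model regardless of which dataset is being evaluated.
#'
#' @param model a `thermal_time_model`.
#' @param null a `null_model` fit on the calibration pool.
#' @param phens phenometrics to evaluate on.
#' @param temps named list of `temp_series` keyed `"<site_id>::<year>"`.
#' @param label `"calibration"` or `"validation"`.
#' @return Object of class `evaluation_report`: `dataset_label`, `n`,
#'   `n_not_met`, `mae`, `rmse`, `r2`, `nsme`, `residuals`, and the
#'   prediction table in `predictions`. Metrics are `NA` when `n` is 0 (and
#'   `r2`/`nsme` when their preconditions fail, with the reason in
#'   `metric_notes`).
#' @export
evaluate_model <- function(model, null, phens, temps,
                           label = c("calibration", "validation")) {
  label <- match.arg(label)
  stopifnot(inherits(null, "null_model"))
  pred <- predict_onsets(model, phens, temps)
  ok <- pred[pred$met, , drop = FALSE]
  n <- nrow(ok)
  report <- list(dataset_label = label, n = n,
                 n_not_met = sum(!pred$met),
                 mae = NA_real_, rmse = NA_real_, r2 = NA_real_,
                 nsme = NA_real_, residuals = numeric(0),
                 predictions = pred, metric_notes = character(0))
  if (n > 0) {
    res <- ok$predicted_doy - ok$observed_doy
    report$residuals <- res
    report$mae <- mae(res)
    report$rmse <- rmse(res)
    null_pred <- rep(null$mean_doy, n)
    report$r2 <- tryCatch(r_squared(ok$predicted_doy, ok$observed_doy),
                          error = function(e) {
                            report$metric_notes <<- c(report$metric_notes, conditionMessage(e))
                            NA_real_
                          })
    report$nsme <- tryCatch(nsme(ok$predicted_doy, ok$observed_doy, null_pred),
                            error = function(e) {
                              report$metric_notes <<- c(report$metric_notes, conditionMessage(e))
                              NA_real_
                            })
  }
  structure(report, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation (%s): n = %d (+%d threshold never met)\n",
              x$dataset_label, x$n, x$n_not_met))
  if (x$n > 0) {
    cat(sprintf("  MAE %.1f d  RMSE %.1f d  R2 %.2f  NSME %.2f\n",
                x$mae, x$rmse, x$r2, x$nsme))
  }
  invisible(x)
}

#' Serialise an evaluation report to JSON
#'
#' Metrics at full precision plus the per-point residuals and the not-met
#' count.
#'
#' @param report an `evaluation_report`.
#' @param path output path.
#' @export
write_evaluation_json <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  x <- report[c("dataset_label", "n", "n_not_met", "mae", "rmse", "r2",
                "nsme", "residuals")]
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}

#' Candidate-model criteria
#'
#' Minimum calibration-period performance for a model to be considered a
#' candidate: model efficiency at least `nsme_min`, R^2 at least `r2_min`,
#' MAE at most `mae_max` days — all inclusive.
#'
#' @param nsme_min,r2_min,mae_max criterion values (defaults 0.4, 0.5, 10).
#' @return A list of class `candidate_criteria`.
#' @export
candidate_criteria <- function(nsme_min = 0.4, r2_min = 0.5, mae_max = 10) {
  structure(list(nsme_min = nsme_min, r2_min = r2_min, mae_max = mae_max),
            class = "candidate_criteria")
}

#' Does a calibration report meet the candidate criteria?
#'
#' @param report an `evaluation_report` on the calibration dataset.
#' @param criteria a [candidate_criteria()].
#' @return `TRUE`/`FALSE`; `FALSE` when any metric is unavailable.
#' @export
is_candidate <- function(report, criteria = candidate_criteria()) {
  stopifnot(inherits(report, "evaluation_report"),
            inherits(criteria, "candidate_criteria"))
  if (is.na(report$nsme) || is.na(report$r2) || is.na(report$mae)) return(FALSE)
  report$nsme >= criteria$nsme_min &&
    report$r2 >= criteria$r2_min &&
    report$mae <= criteria$mae_max
}
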