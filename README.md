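# phenothermal

Thermal-time models of plant phenophase onset from status-format phenology
observations.

Continental phenology networks collect "status" data: on each visit to an
individual plant, a volunteer records whether a phenophase — breaking leaf
buds, leaves, open flowers, ripe fruits — is occurring ("yes") or not
("no"). `phenothermal` turns those reports, together with daily
minimum/maximum temperature series, into simple predictive models of onset
timing, and provides everything needed to test the whole pipeline against
synthetic data with known ground truth. It is aimed at phenology-network
analysts and ecologists who want a reproducible, fully tested version of the
standard accumulated-growing-degree-day workflow.

## The model

Daily heat units above a 0 °C base are accumulated from January 1:

    GDD(d)  = max(0, (Tmin(d) + Tmax(d)) / 2)
    AGDD(d) = Σ_{i=1..d} GDD(i)

For each species × phenophase, the observed onset at a site in a year is the
mean first-"yes" day of year (DOY) across monitored individuals. The
**universal AGDD threshold** is the mean of AGDD-at-onset across all
calibration site × years — a single forcing requirement assumed independent
of site and year. Predictions invert the threshold: the predicted onset at
any location is the first DOY whose AGDD reaches it.

Before fitting, records are trimmed: the last prior "no" must fall strictly
within 15 days of the first "yes" (bounding onset-date imprecision), onsets
after DOY 172 (vegetative phases) or DOY 213 (reproductive phases) are
dropped as outliers, excluded regions are removed, and a model is only fit
when ≥ 30 calibration site × years remain. The final year of data is held
out for validation.

Models are judged against a **null model** (the calibration mean onset DOY)
via the Nash–Sutcliffe model efficiency

    NSME = 1 − Σ(pred − obs)² / Σ(null − obs)²

(1 = perfect, 0 = no better than the null), alongside MAE, RMSE and R².
Candidate models require NSME ≥ 0.4, R² ≥ 0.5 and MAE ≤ 10 days on the
calibration set. A candidate model's **geographic extensibility** is the
fraction of the species' range whose long-term mean January–April (spring)
temperature falls inside the [min, max] envelope of the calibration sites;
threshold-crossing DOY maps computed on gridded temperature stacks are
clipped first to the range, then to that envelope.

## Worked example

Simulate a 40-site observation network over 2012–2016 (three species with
true thresholds 450, 700 and 1300 °C·day, weekly visits, 2-day onset
jitter), fit and evaluate all models, and map one of them:

```r
library(phenothermal)

cfg <- world_config(n_sites = 40, years = 2012:2016, seed = 42)
res <- run_all_synthetic(cfg, run_config(holdout_year = 2016))
print(res$report)
#> Run report: 3 species x phenophase combination(s), 3 modelled, 3 candidate(s)
#>   filter audit: 600 in, 600 retained (gap 0, cutoff 0, region 0 removed)

res$report$summary[, c("species", "phenophase", "threshold_agdd",
                       "calib_mae", "calib_nsme", "valid_mae", "pct_range")]
#>     species         phenophase threshold_agdd calib_mae calib_nsme valid_mae pct_range
#> 1 spp_early breaking_leaf_buds            499      1.55      0.990      1.74      83.3
#> 2  spp_late       open_flowers           1367      1.46      0.992      1.68      83.3
#> 3   spp_mid             leaves            760      1.58      0.990      1.52      83.3
```

The recovered thresholds sit close to the generator's true values (the
upward offset reflects the one-day discretisation of threshold crossing plus
the late-detection bias of weekly visits); calibration MAE is ~1.5 days
against a null-model MAE of ~12–25 days, so every model clears the candidate
bar, and each extends to 83 % of the synthetic species range — the poleward
and equatorward extremes fall outside the calibration climate envelope.

```r
model <- res$report$models[["spp_mid:leaves"]]
print(model)
#> Thermal-time model: spp_mid - leaves
#>   universal AGDD threshold: 759.6 degC day (base 0 degC, from DOY 1)
#>   calibration site x years: 160

doy_map <- threshold_doy_map(res$sim$world$stack, model)
doy_map <- clip_map(doy_map, res$sim$world$range_mask)
doy_map_stats(doy_map)
#> $min_doy 93 ... $max_doy 169 ... (onset sweeps ~2.5 months from the warm
#> to the cold edge of the range)
write_doy_map(doy_map, "spp_mid_leaves_2016.asc")
```

Real data enter the same way through `read_status_csv()`,
`read_sites_csv()`, `read_temp_csv()` / `temp_stack()`,
`read_ascii_grid()` and `read_range_geojson()`, then `run_all()`.

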