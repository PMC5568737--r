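---
title: "Thermal-time phenology models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermal-time phenology models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenothermal)
```

## The modelling problem

Status-format phenology data record, for each visit to an individual plant,
whether a phenophase is occurring. The quantity being modelled is the *site
phenometric*: for one species, phenophase, site and year, the mean
first-"yes" day of year (DOY) across the individuals monitored there. The
model class is the classic thermal-time (growing degree day) model: a
phenophase begins when heat accumulation since January 1 reaches a
threshold. `phenothermal` fits the simplest member of that class — a single
*universal* threshold per species × phenophase, assumed independent of site
and year — because status networks are still temporally shallow and a
one-parameter model is the most that can be asked of them while remaining
operationally useful (it can be inverted on any gridded temperature product
to make a forecast map).

### Heat accumulation

Daily heat units use the simple-average convention,
`GDD(d) = max(0, (Tmin + Tmax)/2 - base)` with `base = 0` °C: the daily
mean is formed *first* and then truncated. The alternative (truncating tmin
and tmax separately before averaging) gives slightly higher totals in
oscillating weather; the simple-average form is the one used by
continental-scale GDD map products, which these models are meant to feed.
Accumulation always restarts on January 1, so DOY is the calendar day index
of its own year — day 61 is March 1 in leap years and March 2 otherwise. No
normalisation is applied; accumulation is physical, not calendrical.

### Fitting and inversion

The universal threshold is the arithmetic mean of AGDD-at-onset over all
calibration site × years. Inversion returns the *smallest integer day*
whose AGDD reaches the threshold. Two numerical consequences follow and are
worth stating precisely:

* **Fractional onsets.** A site phenometric can be fractional (a mean over
  individuals). AGDD is a daily step function, so fractional onsets are
  rounded half-up to a calendar day before lookup.
* **The one-day discretisation slack.** Because onset is observed on a day
  grid, the AGDD recorded at a crossing overshoots the underlying threshold
  by up to one day's GDD. The mean of such overshooting values therefore
  recovers a true threshold only to within one day's maximum GDD, and a
  fitted threshold sits above roughly half the per-record crossing values —
  so even with perfect daily observation and no biological noise, inverted
  predictions land one day late at below-average sites. Parameter-recovery
  tests on exactly observed synthetic data accordingly bound the mean
  absolute error by one day (observed ≈ 0.5 days) rather than expecting
  literal zero; efficiency and correlation reach 1 at their two-decimal
  reporting precision.

### Filtering rules

Three trims precede fitting, in this order, with removals attributed to the
first failing rule so the audit counts always reconcile:

1. *Prior-"no" window*: a record is kept only when a prior "no" exists in
   the same year and `first_yes - prior_no < 15` days (strict). The gap
   bounds how wrong the onset date can be.
2. *DOY cutoffs* (inclusive): onsets after DOY 172 (first day of summer)
   are discarded for breaking leaf buds and leaves, after DOY 213 (Aug 1)
   for open flowers and ripe fruits — late-season "first yes" reports are
   overwhelmingly observer artefacts.
3. *Region exclusion*: a string-tag filter (default tag `"AK"`), used where
   gridded climate products do not cover the sites. A tag filter rather
   than a geometry test keeps the rule auditable and configuration-driven.

The site-level prior "no" is the mean over individuals that have one, among
the individuals contributing a first yes — symmetric with the first-"yes"
definition, which is a mean by construction. No cross-year look-back is
performed: accumulation restarts each January 1, so a "yes" with no
same-year prior "no" has no gap and fails rule 1. Contradictory same-day
reports for one individual resolve to "yes" (a positive observation is more
likely deliberate than a stale negative), and the number of such conflicts
is reported.

### Evaluation

The null model predicts every site × year at the calibration-period mean
onset DOY. Model efficiency is Nash–Sutcliffe,
`NSME = 1 - SS_model / SS_null`; because the null constant *is* the
calibration mean, NSME on calibration data coincides with the classic
efficiency about the observed mean (asserted numerically in the tests). On
the validation year the null constant is still the calibration mean — the
null is a fitted model and must not peek at the hold-out. R² is the squared
Pearson correlation of predicted and observed onset, which is
direction-blind; MAE and NSME catch anti-correlated predictors. Residuals
are predicted − observed, so negative means the model called the phenophase
too early. Site × years whose threshold is never met during the year are
excluded from metrics and counted (`n_not_met`) rather than imputed —
silent dropping would bias MAE, and imputation would invent a date.

Candidate selection (NSME ≥ 0.4, R² ≥ 0.5, MAE ≤ 10 days, all inclusive)
uses calibration metrics only; validation metrics are reported but never
select.

### Geographic extensibility

Mean spring (January–April) temperature is the envelope variable: it is a
strong proxy for the accumulating forcing signal itself. The climatology is
the mean of the four monthly means of daily `(Tmin+Tmax)/2`, averaged
across climatology years. The envelope is the closed `[min, max]` interval
of the values extracted at the calibration sites (value of the containing
cell). Min/max is the most literal reading of a "climate envelope" for a
one-variable criterion; percentile or density envelopes are deliberately
out of scope. Range coverage is cosine-latitude area-weighted by default
(cells shrink poleward); a raw-cell-count mode exists so brute-force scans
can check the arithmetic exactly.

### Maps

`threshold_doy_map()` applies the scalar inversion to every cell of a daily
temperature stack and is property-tested against a per-cell day-by-day
scan, so the vectorised path cannot drift from the scalar one. Never-met
cells carry a sentinel (`DOY_NOT_MET`, −1) distinct from missing data
(`NA`/NODATA): "the threshold was not reached this year" is a model output,
"we had no temperatures" is not. The standard workflow clips a map twice —
species range, then envelope-clipped range — and each clip can only narrow
the map's DOY span, which the tests assert.

Grids are an in-memory matrix class with ESRI ASCII text I/O, and range
polygons are GeoJSON exterior rings rasterized by cell-center membership
(even-odd rule). These plain-text formats keep every fixture generatable
and diffable; production-scale binary rasters can be converted to ASCII
grids with any GIS tool.

## The synthetic world

The generator is first-class, tested code: it is the only way to know the
right answer exactly, hence the only honest way to validate the pipeline.

Per site and year, daily mean temperature is
`a(lat) − A·cos(2πd/365.25) + ε(d)`, with annual mean `a(lat)` declining
linearly with latitude (defaults: 15 °C at 30° N to 4.2 °C at 48° N),
seasonal amplitude `A = 12` °C, and AR(1) noise (marginal SD 3 °C, lag-1
correlation 0.7). Autocorrelated rather than white noise matters: warm
spells move the AGDD crossing by several days at once, which is what makes
the prior-"no"/first-"yes" imprecision interact with realistic AGDD
variance. `tmin`/`tmax` sit a fixed half-range (5 °C) below/above the mean.
The defaults put the three species' onsets (true thresholds 450, 700 and
1300 °C·day, spanning the realistic range for temperate woody phenophases)
comfortably inside their DOY cutoffs at every simulated latitude.

A site's true onset is the day its series crosses the species' true
threshold — the generator uses the same crossing definition the estimator
inverts, so recovery error isolates estimation, not definitional mismatch.
Individuals jitter around the site onset (rounded Gaussian, default SD
2 days); observers visit every `visit_interval` days from a random phase,
reporting yes iff the visit is on or after the individual's onset. Daily
visits with zero jitter reproduce the truth exactly; weekly visits bound
the prior-"no" gap at 7 days and bias detection late by about half the
interval — a bias that partially cancels in prediction because the fitted
threshold absorbs it.

The gridded stack uses the *deterministic* climatological sinusoid (no
weather noise): it plays the role of a smooth normals surface for the
spring climatology, envelope and maps. The synthetic species range is a
rectangle extending poleward of the coldest calibration site, so envelope
clipping always has extreme-latitude bands to exclude — the qualitative
pattern expected when calibration sites under-sample a range's climatic
extremes.

What the generator does **not** emulate: observer error (false yeses/nos),
clustered site placement, missing temperature days, multi-year individual
turnover, chilling or photoperiod controls on onset. Passing tests
therefore demonstrate that the pipeline's arithmetic and bookkeeping are
correct and that estimation degrades gracefully with sampling interval —
not that a universal threshold is an adequate biological model for any
particular real species.

## Problem sizes and determinism

The test suite and the acceptance script use worlds of 15–50 sites over 4–6
years (hundreds of site × years per model), 20-seed ensembles for the
degraded-observation regime, 1,000 random series and a 20 × 20 × 365 stack
for the oracle-equivalence checks; the full suite runs in about a minute on
one core. All randomness flows from a single global RNG seeded once per
run, so any run is exactly reproducible from its configuration — reruns of
the orchestrated pipeline are byte-identical, which the tests assert on the
emitted CSV/JSON.

## Known limitations

* One forcing variable, one fixed base (0 °C) and start date (Jan 1):
  alternative bases, chilling and photoperiod terms are out of scope by
  design.
* The universal threshold ignores systematic site effects; on real data,
  geographic residual structure (too late in the north, too early in the
  south, or vice versa) should be expected and inspected.
* The climate envelope is a one-dimensional interval; it cannot express
  precipitation limits or interactions.
* `check_min_sample`'s 30 site × year floor is a pragmatic stability rule,
  not a statistical guarantee; metrics from models near the floor are
  noisy.
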