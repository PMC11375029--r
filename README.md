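# edattrib

Exposure attribution for cause-specific emergency department (ED)
admissions: from raw environmental measurements to lagged
exposure–response curves and population attributable fractions.

Weekly ED admission counts respond to rainfall, temperature, wind speed
and ambient air pollutants (PM10, SO2, CO) non-linearly and with delays
of one to three weeks.  `edattrib` implements the full analysis chain a
health-systems modeller needs to quantify those effects:

* **Exposure assembly** — daily station weather records are
  interpolated to national rasters by inverse distance weighting, with
  the distance power chosen by leave-one-out cross-validation, then
  aggregated to epidemiological weeks; zone-level air quality index
  (AQI) values are averaged nationally and converted to concentration
  units by piecewise-linear EPA breakpoint inversion.
* **Count modelling** — for each admission category, weekly counts
  `Y_t` follow a generalized additive model

  ```
  log E[Y_t] = β0 + Σₙ f_n(Y_{t−n}) + Σᵢ Σₙ f_{i,n}(X_{i,t−n})
             + s(Week_t) + s(Year_t),     n = 1..l,  l ≤ 3
  ```

  with penalized thin plate regression spline smooths fitted by REML
  under Poisson, quasi-Poisson or negative binomial families, and
  candidate models (family × lag × immediate effects) compared by
  AIC/RMSE/MAPE with overdispersion triage via the Pearson dispersion.
* **Effects** — incidence rate ratio (IRR) curves
  `IRR(x) = E[Ŷ | X_i = x, rest at means] / E[Ŷ | X_i = X̄_i, rest at means]`
  over the observed exposure range, with pointwise Wald intervals on
  the log scale.
* **Attribution** — population attributable fractions
  `PAF_t = (observed_t − expected_t)/observed_t × 100%`, where the
  expected count removes one exposure's fitted contribution, plus
  locally-weighted PAF-versus-exposure trend curves.
* **Synthetic ground truth** — a calibrated generator (261
  epi-weeks, 12 admission categories, exposure marginals matching a
  tropical urban setting, haze-spike process, autoregressive feedback,
  seasonality) with closed-form oracle IRR/PAF, used to validate every
  stage.

## Worked example

Simulate a 261-week study in which rainfall above 10 mm raises next
week's admissions (a hockey-stick effect on the log scale, slope 0.04
per mm), fit the model, and read off the effect:

```r
library(edattrib)

cfg <- default_exposure_config()
truth <- truth_model(
  beta0 = log(500),
  effects = list(rain_mm = list(
    "1" = effect_threshold(10, 0.04, cfg$rain_mm$mean))))

exposures  <- generate_exposures(cfg, n_weeks = 261, seed = 1)
admissions <- generate_admissions(exposures, truth, seed = 2)
design <- build_lag_design(admissions, exposures, max_lag = 1)
model  <- fit_admission_gam(design, "poisson", terms = "rain_mm_lag1",
                            include_seasonal = FALSE)

score_model(model)
#>   family max_lag include_immediate  aic  rmse mape   edf mape_excluded
#>  poisson       1             FALSE 2422 24.61 3.94 6.533             0

curve <- irr_curve(model, "rain_mm", 1, n_grid = 100)
curve[which.min(abs(curve$grid_value - 15)),
      c("grid_value", "irr", "lo", "hi")]
#>  grid_value   irr    lo    hi
#>      14.716 1.204 1.176 1.231

oracle_irr(truth, "rain_mm", 1, 14.716)
#> [1] 1.208
```

At 14.7 mm of rainfall the fitted IRR is 1.204 (95% CI 1.176–1.231):
admissions are predicted to be about 20% above what the mean rainfall
week would produce, and the interval covers the true value 1.208
implied by the generating model.  The attributable fraction in wet
weeks follows the same machinery:

```r
ps <- paf_series(model, "rain_mm", 1)
xv <- design$data$rain_mm_lag1[match(ps$week_index,
                                     design$data$week_index)]
mean(ps$paf_pct[xv > 15])
#> [1] 19.1
```

i.e. roughly 19% of admissions in weeks following >15 mm rainfall are
attributable to the rainfall effect.

The full per-category protocol — candidate grid, selection, IRR and
PAF products, CSV outputs — runs through `run_all()`:

```r
bundle <- run_all(default_config(), out_dir = "study_out")
```

A thin command-line wrapper with `simulate` and `run` subcommands is
installed at `inst/scripts/edattrib`.

## Package layout

| Area | Functions |
|---|---|
| Synthetic data | `generate_exposures`, `generate_admissions`, `truth_model`, `effect_*`, `oracle_irr`, `oracle_paf`, `generate_station_daily` |
| Spatial | `idw_interpolate`, `fit_idw_power`, `aggregate_weekly` |
| AQI | `average_zones`, `aqi_to_concentration`, `concentration_to_aqi`, `zones_to_concentration` |
| Design | `build_lag_design`, `epiweek_calendar`, `pacf_dl` |
| Models | `fit_admission_gam`, `predict_ed`, `score_model`, `dispersion_stat`, `build_basis` |
| Effects | `irr_curve`, `irr_interval`, `significance_mask` |
| Attribution | `paf_series`, `paf_percent`, `remove_exposure`, `smooth_paf`, `group_categories` |
| Pipeline | `run_category`, `run_all`, `candidate_grid`, `default_config`, `summarize_shares` |

See the vignette (`vignettes/exposure-attribution.Rmd`) for the model,
its assumptions, and the design decisions behind the defaults.
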