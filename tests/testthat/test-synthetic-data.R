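test_that("exposure generation is deterministic and range-respecting", {
  cfg <- default_exposure_config()
  a <- generate_exposures(cfg, n_weeks = 120, seed = 7)
  b <- generate_exposures(cfg, n_weeks = 120, seed = 7)
  expect_identical(a, b)
  for (nm in exposure_names()) {
    expect_true(all(a[[nm]] >= cfg[[nm]]$min - 1e-12))
    expect_true(all(a[[nm]] <= cfg[[nm]]$max + 1e-12))
  }
  expect_false(identical(a, generate_exposures(cfg, 120, seed = 8)))
})

test_that("generated exposures reproduce the configured marginals", {
  cfg <- default_exposure_config()
  x <- generate_exposures(cfg, n_weeks = 261, seed = 1)
  expect_equal(nrow(x), 261)
  for (nm in exposure_names())
    expect_lt(abs(mean(x[[nm]]) - cfg[[nm]]$mean), 0.15 * cfg[[nm]]$mean)
  expect_gt(mean(x$temp_c), 27.6)
  expect_lt(mean(x$temp_c), 28.4)
  # at a longer horizon the sd calibration is identifiable too (a 261-week
  # PM10 sd is dominated by a handful of haze spikes)
  xl <- generate_exposures(cfg, n_weeks = 2088, seed = 2)
  for (nm in exposure_names()) {
    expect_lt(abs(mean(xl[[nm]]) - cfg[[nm]]$mean), 0.15 * cfg[[nm]]$mean)
    expect_lt(abs(sd(xl[[nm]]) - cfg[[nm]]$sd), 0.15 * cfg[[nm]]$sd)
  }
})

test_that("degenerate variance yields a constant series", {
  cfg <- default_exposure_config()
  cfg$temp_c$sd <- 0
  x <- generate_exposures(cfg, n_weeks = 60, seed = 2)
  expect_true(all(x$temp_c == cfg$temp_c$mean))
})

test_that("invalid exposure configs and sizes are rejected", {
  cfg <- default_exposure_config()
  expect_error(generate_exposures(cfg, n_weeks = 5, seed = 1), "at least 8")
  cfg$wind_kmh$min <- cfg$wind_kmh$max + 1
  expect_error(generate_exposures(cfg, n_weeks = 60, seed = 1),
               "min must be <")
  expect_error(default_exposure_config(rho = 1), "rho")
})

test_that("null truth model draws i.i.d. counts at the baseline rate", {
  cfg <- default_exposure_config()
  truth <- truth_model(beta0 = log(100))
  x <- generate_exposures(cfg, n_weeks = 261, seed = 3)
  adm <- generate_admissions(x, truth, seed = 4)
  expect_true(all(adm$count >= 0))
  expect_true(all(adm$count == round(adm$count)))
  expect_gt(mean(adm$count), 90)
  expect_lt(mean(adm$count), 110)
  expect_identical(adm, generate_admissions(x, truth, seed = 4))
})

test_that("a rainfall step effect raises counts after wet weeks", {
  cfg <- default_exposure_config()
  truth <- truth_model(
    beta0 = log(100),
    effects = list(rain_mm = list("1" = effect_threshold(15, 0.1,
                                                         cfg$rain_mm$mean))))
  x <- generate_exposures(cfg, n_weeks = 3000, seed = 5)
  adm <- generate_admissions(x, truth, seed = 6)
  rain_prev <- x$rain_mm[1:2999]
  cnt <- adm$count[2:3000]
  expect_gt(mean(cnt[rain_prev > 15]), mean(cnt[rain_prev < 5]))
})

test_that("IRR oracle matches closed forms and direct evaluation", {
  ctr <- 28
  truth <- truth_model(beta0 = log(50), effects = list(
    temp_c = list("1" = effect_linear(0.1, ctr))))
  expect_identical(oracle_irr(truth, "temp_c", 1, ctr), 1)
  expect_equal(oracle_irr(truth, "temp_c", 1, ctr + 1), exp(0.1))
  # piecewise truth against direct evaluation of exp(delta f)
  ef <- effect_threshold(10, 0.05, 6)
  truth2 <- truth_model(beta0 = 0,
                        effects = list(rain_mm = list("2" = ef)))
  grid <- c(0, 6, 10, 15, 20)
  expect_equal(oracle_irr(truth2, "rain_mm", 2, grid),
               exp(eval_effect(ef, grid)))
  # absent effect: IRR identically 1
  expect_equal(oracle_irr(truth2, "so2_ppb", 1, c(1, 5)), c(1, 1))
})

test_that("PAF oracle honors the counterfactual-removal identities", {
  cfg <- default_exposure_config()
  x <- generate_exposures(cfg, n_weeks = 30, seed = 8)
  null_truth <- truth_model(beta0 = log(10))
  expect_true(all(oracle_paf(null_truth, x, "rain_mm", 1)$paf_pct == 0))
  # a +log 2 contribution gives PAF 50%, -log 2 gives -100%
  up <- truth_model(beta0 = log(10), effects = list(
    rain_mm = list("1" = effect_threshold(-1, log(2), 0))))
  x_const <- x
  x_const$rain_mm <- 1   # f(x) = log 2 * (1 - 0) ... evaluate directly
  p <- oracle_paf(up, x_const, "rain_mm", 1)
  expect_equal(unique(round(p$paf_pct, 10)), 50)
  down <- truth_model(beta0 = log(10), effects = list(
    rain_mm = list("1" = effect_threshold(-1, -log(2), 0))))
  p2 <- oracle_paf(down, x_const, "rain_mm", 1)
  expect_equal(unique(round(p2$paf_pct, 10)), -100)
})

test_that("station generator returns consistent records and surface", {
  st <- generate_station_daily(n_stations = 21, n_days = 7, seed = 3)
  expect_equal(nrow(st$records), 147)
  expect_identical(st$records,
                   generate_station_daily(n_stations = 21, n_days = 7,
                                          seed = 3)$records)
  # zero noise: records equal the surface at station coordinates
  st0 <- generate_station_daily(n_stations = 5, n_days = 3, seed = 4,
                                noise_sd = 0)
  expect_equal(st0$records$value,
               st0$surface(st0$records$x, st0$records$y,
                           st0$records$date))
  expect_error(generate_station_daily(n_stations = 1, n_days = 3,
                                      seed = 1), ">= 2")
})
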