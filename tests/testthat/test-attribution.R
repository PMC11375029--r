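test_that("PAF arithmetic matches the counterfactual-removal formula", {
  expect_equal(paf_percent(c(100, 100, 80), c(100, 50, 100)),
               c(0, 50, -25))
  expect_error(paf_percent(c(0, 10), c(1, 1)), "zero observed")
})

test_that("drop-term removal equals manual subtraction of the smooth
           contribution", {
  fx <- hockey_fixture(seed = 61, n_weeks = 150)
  m <- fx$model
  d <- fx$design
  expected <- edattrib:::counterfactual_expected(m, "rain_mm", 1,
                                                 mode = "drop-term")
  # independent route: per-term contributions from predict(type = "terms")
  terms_mat <- predict(m$fit, newdata = d$data, type = "terms")
  lp_full <- predict_ed(m, d$data)$lp
  lp_manual <- lp_full - terms_mat[, "s(rain_mm_lag1)"]
  expect_equal(expected, unname(exp(lp_manual)), tolerance = 1e-12)
})

test_that("removing a null smooth leaves predictions unchanged", {
  fx <- hockey_fixture(seed = 62, n_weeks = 120)
  m <- fx$model
  idx <- edattrib:::smooth_coef_index(m, "rain_mm_lag1")
  m$fit$coefficients[idx] <- 0
  expected <- edattrib:::counterfactual_expected(m, "rain_mm", 1,
                                                 mode = "drop-term")
  expect_equal(expected, predict_ed(m)$expected, tolerance = 1e-12)
  ps <- paf_series(m, "rain_mm", 1)
  expect_lt(max(abs(ps$expected - predict_ed(m)$expected)), 1e-10)
})

test_that("set-zero mode zeroes the column and warns about
           extrapolation", {
  fx <- hockey_fixture(seed = 63, n_weeks = 100)
  d <- fx$design
  # rainfall can be zero, so no warning when 0 is inside the range
  expect_silent(cf <- remove_exposure(d, "rain_mm", 1,
                                      mode = "set-zero"))
  expect_true(all(cf$data$rain_mm_lag1 == 0))
  # a column already all zero stays unchanged
  d0 <- d
  d0$data$rain_mm_lag1 <- 0
  cf0 <- remove_exposure(d0, "rain_mm", 1, mode = "set-zero")
  expect_identical(cf0$data, d0$data)
  # temperature never reaches zero: extrapolation is flagged
  cfg <- default_exposure_config()
  x <- generate_exposures(cfg, n_weeks = 100, seed = 64)
  adm <- generate_admissions(x, truth_model(log(100)), seed = 65)
  dt <- build_lag_design(adm, x, max_lag = 1)
  expect_warning(remove_exposure(dt, "temp_c", 1, mode = "set-zero"),
                 "outside its observed range")
})

test_that("PAF series stays below 100% and excludes zero-count weeks", {
  fx <- hockey_fixture(seed = 66, n_weeks = 200)
  ps <- paf_series(fx$model, "rain_mm", 1)
  expect_true(all(ps$paf_pct < 100))
  expect_true(all(ps$observed > 0))
  expect_s3_class(ps, "paf_series")
})

test_that("the PAF smoother reproduces flat and linear trends", {
  fx <- hockey_fixture(seed = 67, n_weeks = 120)
  ps <- paf_series(fx$model, "rain_mm", 1)
  xv <- fx$design$data$rain_mm_lag1[
    match(ps$week_index, fx$design$data$week_index)]
  flat <- ps
  flat$paf_pct <- 5
  fc <- smooth_paf(flat, xv)
  expect_equal(fc$paf_trend, rep(5, 100), tolerance = 1e-6)
  lin <- ps
  lin$paf_pct <- 2 + 3 * xv
  lc <- smooth_paf(lin, xv, span = 0.9)
  expect_equal(lc$paf_trend, 2 + 3 * lc$grid_value, tolerance = 1e-6)
  expect_error(smooth_paf(ps[1:10, ], xv[1:10]), "at least 20")
})

test_that("the PAF band shrinks roughly as one over root n", {
  set.seed(68)
  make_band <- function(n) {
    x <- runif(n, 0, 10)
    y <- 2 + 0.5 * x + rnorm(n, 0, 2)
    ps <- structure(data.frame(week_index = seq_len(n), observed = 1,
                               expected = 1, paf_pct = y),
                    class = c("paf_series", "data.frame"))
    pc <- smooth_paf(ps, x)
    mean(pc$hi - pc$lo)
  }
  ratio <- make_band(1600) / make_band(400)
  expect_gt(ratio, 0.3)
  expect_lt(ratio, 0.7)
})

test_that("category grouping matches the fixed vocabulary", {
  expect_equal(group_categories("Cardiovascular disease"),
               "Cardiorespiratory system disorders")
  expect_equal(group_categories("Diabetes mellitus"),
               "Metabolic and digestive system disorders")
  expect_equal(group_categories("Oral diseases"), "Others")
  expect_equal(sum(group_categories(ed_category_stats()$category) ==
                     "Others"), 4)
  expect_error(group_categories("Dental"), "unknown admission category")
})

test_that("strong harmful exposures give positive smoothed PAF where the
           IRR is significantly raised", {
  fx <- hockey_fixture(seed = 69, slope = 0.08)
  cv <- irr_curve(fx$model, "rain_mm", 1, n_grid = 50)
  ps <- paf_series(fx$model, "rain_mm", 1)
  xv <- fx$design$data$rain_mm_lag1[
    match(ps$week_index, fx$design$data$week_index)]
  pc <- smooth_paf(ps, xv)
  harmful <- cv$grid_value[cv$significant & cv$irr > 1]
  if (length(harmful)) {
    sel <- pc$grid_value >= min(harmful)
    expect_true(mean(pc$paf_trend[sel] > 0) > 0.9)
  }
})
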