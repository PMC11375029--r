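test_that("IRR is exactly 1 with a degenerate interval at the reference
           mean", {
  fx <- hockey_fixture(seed = 51)
  cv <- irr_curve(fx$model, "rain_mm", 1, n_grid = 40)
  ref_row <- cv[cv$is_reference, ]
  expect_equal(nrow(ref_row), 1)
  expect_identical(ref_row$irr, 1)
  expect_identical(ref_row$lo, 1)
  expect_identical(ref_row$hi, 1)
  pt <- irr_interval(fx$model, "rain_mm", 1,
                     mean(fx$design$data$rain_mm_lag1))
  expect_identical(unname(pt), c(1, 1, 1))
})

test_that("ratio-of-predictions and linear-predictor-difference routes
           agree", {
  for (s in c(52, 53)) {
    fx <- hockey_fixture(seed = s, n_weeks = 150)
    cv <- irr_curve(fx$model, "rain_mm", 1, n_grid = 30)
    expect_lt(max(abs(cv$irr - attr(cv, "ratio_route"))), 1e-10)
  }
})

test_that("a forced linear smooth with slope 0.1 yields IRR exp(0.1) one
           unit above the mean", {
  fx <- hockey_fixture(seed = 54, n_weeks = 120)
  d <- fx$design
  m <- fit_admission_gam(d, "poisson", linear_terms = TRUE,
                         include_seasonal = FALSE,
                         terms = "rain_mm_lag1")
  m$fit$coefficients["rain_mm_lag1"] <- 0.1
  ref <- mean(d$data$rain_mm_lag1)
  pt <- irr_interval(m, "rain_mm", 1, ref + 1)
  expect_equal(unname(pt["irr"]), exp(0.1), tolerance = 1e-10)
})

test_that("interval width scales with the coefficient covariance", {
  fx <- hockey_fixture(seed = 55, n_weeks = 150)
  x0 <- quantile(fx$design$data$rain_mm_lag1, 0.9)
  base <- irr_interval(fx$model, "rain_mm", 1, x0)
  m2 <- fx$model
  m2$vp <- m2$vp * 2
  wide <- irr_interval(m2, "rain_mm", 1, x0)
  ratio <- log(wide["hi"] / wide["lo"]) / log(base["hi"] / base["lo"])
  expect_equal(unname(ratio), sqrt(2), tolerance = 1e-10)
})

test_that("null-effect intervals cover 1 at near-nominal rates", {
  cfg <- default_exposure_config()
  truth <- truth_model(log(200))    # rainfall truly has no effect
  covered <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    x <- generate_exposures(cfg, n_weeks = 120,
                            seed = child_seed(s, 11L))
    adm <- generate_admissions(x, truth, seed = child_seed(s, 12L))
    d <- build_lag_design(adm, x, max_lag = 1)
    m <- fit_admission_gam(d, "poisson", terms = "rain_mm_lag1",
                           include_seasonal = FALSE)
    x0 <- quantile(d$data$rain_mm_lag1, 0.85)
    pt <- irr_interval(m, "rain_mm", 1, x0)
    if (pt["lo"] <= 1 && pt["hi"] >= 1) covered <- covered + 1L
  }
  expect_gte(covered / n_seeds, 0.9)
})

test_that("the targeted IRR curve is invariant to shifting another
           covariate", {
  cfg <- default_exposure_config()
  truth <- truth_model(log(300), effects = list(
    rain_mm = list("1" = effect_threshold(10, 0.04, cfg$rain_mm$mean)),
    temp_c = list("1" = effect_linear(0.05, cfg$temp_c$mean))))
  x <- generate_exposures(cfg, n_weeks = 200, seed = 57)
  adm <- generate_admissions(x, truth, seed = 58)
  fit2 <- function(expos) {
    d <- build_lag_design(adm, expos, max_lag = 1)
    fit_admission_gam(d, "poisson",
                      terms = c("rain_mm_lag1", "temp_c_lag1"),
                      include_seasonal = FALSE)
  }
  x_shift <- x
  x_shift$temp_c <- x_shift$temp_c + 5
  cv1 <- irr_curve(fit2(x), "rain_mm", 1, n_grid = 25)
  cv2 <- irr_curve(fit2(x_shift), "rain_mm", 1, n_grid = 25)
  expect_equal(cv1$irr, cv2$irr, tolerance = 1e-6)
})

test_that("significance flags follow the interval-versus-1 convention", {
  fake <- data.frame(exposure = "x", lag = 1, grid_value = 1:3,
                     irr = c(1.05, 1.0, 0.9),
                     lo = c(1.01, 0.95, 0.80),
                     hi = c(1.11, 1.05, 0.99))
  class(fake) <- c("irr_curve", "data.frame")
  expect_identical(significance_mask(fake), c(TRUE, FALSE, TRUE))
})

test_that("requesting a missing term or degenerate grid errors", {
  fx <- hockey_fixture(seed = 59, n_weeks = 100)
  expect_error(irr_curve(fx$model, "so2_ppb", 1), "not in the model")
  expect_error(irr_curve(fx$model, "rain_mm", 1, n_grid = 1),
               "at least 2")
})
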