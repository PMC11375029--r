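quick_design <- function(seed = 21, n = 120, max_lag = 1) {
  cfg <- default_exposure_config()
  truth <- truth_model(log(200), effects = list(
    temp_c = list("1" = effect_linear(0.08, cfg$temp_c$mean))))
  x <- generate_exposures(cfg, n_weeks = n, seed = seed)
  adm <- generate_admissions(x, truth, seed = seed + 1)
  build_lag_design(adm, x, max_lag = max_lag)
}

test_that("basis construction enforces constraints and penalty
           structure", {
  set.seed(31)
  v <- runif(80, 0, 10)
  b <- build_basis(v, smooth_spec(k = 8))
  # sum-to-zero constraint absorbed: every fitted smooth is centered
  expect_lt(max(abs(colSums(b$X))), 1e-8)
  # penalty is PSD with a polynomial null space
  ev <- eigen(b$S, symmetric = TRUE)
  expect_true(all(ev$values > -1e-8))
  null_vec <- ev$vectors[, which(abs(ev$values) < 1e-8)[1]]
  expect_lt(abs(drop(t(null_vec) %*% b$S %*% null_vec)), 1e-10)
  expect_error(build_basis(rep(2, 50)), "constant")
  expect_error(smooth_spec(k = 2), ">= 3")
  expect_warning(build_basis(c(1, 2, 3, 4), smooth_spec(k = 8)),
                 "reducing k")
})

test_that("the cyclic weekly basis is continuous across the year
           boundary", {
  b <- build_basis(rep(1:53, 3), smooth_spec(role = "week", bs = "cc",
                                             k = 10))
  ends <- mgcv::PredictMat(b$smooth, data.frame(x = c(0.5, 53.5)))
  expect_equal(ends[1, ], ends[2, ], tolerance = 1e-10)
})

test_that("intercept-only fit recovers a constant response exactly", {
  adm <- data.frame(week_index = 1:40, count = 17)
  expo <- data.frame(week_index = 1:40, year = 2014, epiweek = 1:40,
                     rain_mm = runif(40))
  d <- build_lag_design(adm, expo, max_lag = 1)
  m <- fit_admission_gam(d, "poisson", terms = character(0),
                         include_seasonal = FALSE)
  expect_equal(unname(coef(m$fit)[1]), log(17), tolerance = 1e-8)
  expect_equal(unique(round(predict_ed(m)$expected, 8)), 17)
})

test_that("the zero-penalty linear-basis limit matches stats::glm", {
  d <- quick_design(seed = 23)
  m <- fit_admission_gam(d, "poisson", linear_terms = TRUE,
                         include_seasonal = FALSE)
  ref <- glm(y ~ y_lag1 + rain_mm_lag1 + temp_c_lag1 + wind_kmh_lag1 +
               pm10_ugm3_lag1 + so2_ppb_lag1 + co_ppm_lag1,
             family = poisson(), data = d$data)
  expect_equal(unname(coef(m$fit)), unname(coef(ref)), tolerance = 1e-6)
})

test_that("an infinite penalty collapses a smooth onto its null space", {
  d <- quick_design(seed = 24)
  m <- fit_admission_gam(d, "poisson", terms = "temp_c_lag1",
                         include_seasonal = FALSE, sp = 1e9)
  # EDF of the penalized smooth falls to its null-space dimension (1)
  sm_edf <- sum(m$fit$edf[edattrib:::smooth_coef_index(m, "temp_c_lag1")])
  expect_lt(sm_edf, 1.05)
  # the fitted smooth is a straight line in the covariate
  nd <- d$data[rep(1, 50), ]
  nd$temp_c_lag1 <- seq(min(d$data$temp_c_lag1), max(d$data$temp_c_lag1),
                        length.out = 50)
  lp <- predict_ed(m, nd)$lp
  expect_lt(max(abs(diff(diff(lp)))), 1e-6)
})

test_that("EDF decreases monotonically along an increasing lambda grid", {
  d <- quick_design(seed = 25)
  edfs <- vapply(c(1e-4, 1e-2, 1, 100, 1e4), function(lam)
    total_edf(fit_admission_gam(d, "poisson", terms = "temp_c_lag1",
                                include_seasonal = FALSE, sp = lam)),
    numeric(1))
  expect_true(all(diff(edfs) < 1e-8))
})

test_that("REML-selected smoothing is finite and positive on smooth
           truths", {
  d <- quick_design(seed = 26, n = 200)
  m <- fit_admission_gam(d, "poisson", terms = "temp_c_lag1",
                         include_seasonal = FALSE)
  expect_true(all(is.finite(m$fit$sp)))
  expect_true(all(m$fit$sp > 0))
})

test_that("quasi-Poisson equals Poisson point estimates with scaled
           covariance", {
  d <- quick_design(seed = 27)
  mp <- fit_admission_gam(d, "poisson", terms = "temp_c_lag1",
                          include_seasonal = FALSE)
  mq <- fit_admission_gam(d, "quasipoisson", terms = "temp_c_lag1",
                          include_seasonal = FALSE)
  expect_identical(coef(mp$fit), coef(mq$fit))
  expect_equal(mq$vp, mp$vp * mq$dispersion, tolerance = 1e-12)
  expect_true(is.na(score_model(mq)$aic))
  expect_false(is.na(score_model(mp)$aic))
})

test_that("negative binomial fits estimate a dispersion parameter", {
  cfg <- default_exposure_config()
  truth <- truth_model(log(150), family = "negbin", theta = 2)
  x <- generate_exposures(cfg, n_weeks = 200, seed = 31)
  adm <- generate_admissions(x, truth, seed = 32)
  d <- build_lag_design(adm, x, max_lag = 1)
  m <- fit_admission_gam(d, "negbin", terms = "temp_c_lag1",
                         include_seasonal = FALSE)
  theta_hat <- m$fit$family$getTheta(TRUE)
  expect_gt(theta_hat, 0.5)
  expect_lt(theta_hat, 8)
  # the extra size parameter costs one EDF in the AIC
  expect_equal(total_edf(m), sum(m$fit$edf) + 1)
})

test_that("prediction reproduces training fits and inflates variance off
           support", {
  d <- quick_design(seed = 28)
  m <- fit_admission_gam(d, "poisson", terms = "temp_c_lag1",
                         include_seasonal = FALSE)
  pr <- predict_ed(m, d$data)
  expect_equal(pr$expected, unname(fitted(m$fit)), tolerance = 1e-10)
  inside <- d$data[1, ]
  inside$temp_c_lag1 <- mean(d$data$temp_c_lag1)
  outside <- inside
  rng <- range(d$data$temp_c_lag1)
  outside$temp_c_lag1 <- rng[2] + 2 * diff(rng)
  v_in <- predict_ed(m, inside, se = TRUE)$lp_se
  v_out <- predict_ed(m, outside, se = TRUE)$lp_se
  expect_gt(v_out, v_in)
})

test_that("score arithmetic follows the definitions", {
  s1 <- model_score(-100, 5, 1:10, 1:10)
  s2 <- model_score(-100, 7, 1:10, 1:10)
  expect_equal(s2$aic - s1$aic, 4)
  expect_equal(s1$rmse, 0)
  expect_equal(s1$mape, 0)
  s3 <- model_score(-100, 5, c(10, 20, 40), c(11, 22, 44))
  expect_equal(s3$mape, 10)
  expect_equal(s3$rmse, sqrt(mean(c(1, 4, 16))))
  # zero counts excluded from MAPE and counted
  m <- edattrib:::mape(c(0, 10), c(5, 11))
  expect_equal(m$mape, 10)
  expect_equal(m$excluded, 1)
})

test_that("Pearson dispersion separates Poisson from overdispersed
           truths", {
  cfg <- default_exposure_config()
  x <- generate_exposures(cfg, n_weeks = 261, seed = 33)
  tp <- truth_model(log(150), effects = list(
    temp_c = list("1" = effect_linear(0.05, cfg$temp_c$mean))))
  tn <- truth_model(log(150), effects = tp$effects, family = "negbin",
                    theta = 2)
  fit1 <- function(adm) {
    d <- build_lag_design(adm, x, max_lag = 1)
    fit_admission_gam(d, "poisson", terms = "temp_c_lag1",
                      include_seasonal = FALSE)
  }
  disp_p <- dispersion_stat(fit1(generate_admissions(x, tp, seed = 34)))
  disp_n <- dispersion_stat(fit1(generate_admissions(x, tn, seed = 35)))
  expect_gt(disp_p, 0.7)
  expect_lt(disp_p, 1.3)
  expect_gt(disp_n, 1.5)
})

test_that("model archives round-trip to identical predictions", {
  d <- quick_design(seed = 29)
  m <- fit_admission_gam(d, "poisson", terms = "temp_c_lag1",
                         include_seasonal = FALSE)
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict_ed(m)$expected, predict_ed(m2)$expected)
  unlink(path)
})
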