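# Shared fixtures and independent oracles for the test suite.  Oracles are
# written from first principles so they never share code with the
# implementation paths they check.

# Unpenalized Poisson IRLS, written directly from the scoring equations.
irls_poisson <- function(X, y, tol = 1e-12, maxit = 100) {
  beta <- c(log(mean(y) + 0.5), rep(0, ncol(X) - 1))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    W <- mu
    XtWX <- crossprod(X, X * W)
    XtWz <- crossprod(X, W * z)
    beta_new <- drop(solve(XtWX, XtWz))
    if (max(abs(beta_new - beta)) < tol) return(beta_new)
    beta <- beta_new
  }
  beta
}

# Brute-force leave-one-out IDW RMSE, loop-written independently of
# fit_idw_power.
brute_loo_rmse <- function(obs, power) {
  errs <- numeric(nrow(obs))
  for (i in seq_len(nrow(obs))) {
    num <- 0
    den <- 0
    exact <- NA
    for (j in seq_len(nrow(obs))[-i]) {
      d <- sqrt((obs$x[j] - obs$x[i])^2 + (obs$y[j] - obs$y[i])^2)
      if (d < 1e-9) { exact <- obs$value[j]; break }
      w <- d^(-power)
      num <- num + w * obs$value[j]
      den <- den + w
    }
    pred <- if (!is.na(exact)) exact else num / den
    errs[i] <- pred - obs$value[i]
  }
  sqrt(mean(errs^2))
}

# Piecewise-linear AQI-to-concentration oracle straight from the band
# formula, one band at a time.
aqi_oracle <- function(aqi, bands) {
  out <- numeric(length(aqi))
  for (i in seq_along(aqi)) {
    b <- bands[bands$aqi_low <= aqi[i] & aqi[i] <= bands$aqi_high, ]
    b <- b[1, ]
    out[i] <- b$conc_low + (aqi[i] - b$aqi_low) /
      (b$aqi_high - b$aqi_low) * (b$conc_high - b$conc_low)
  }
  out
}

# Synthetic stations sampled from a field that is itself an IDW (power 2)
# surface over hidden source points.
idw2_surface_stations <- function(n_stations, seed, noise_sd = 0.05) {
  set.seed(seed)
  ns <- 6
  sx <- runif(ns, 0, 50); sy <- runif(ns, 0, 50)
  sv <- rnorm(ns, 20, 5)
  px <- runif(n_stations, 0, 50); py <- runif(n_stations, 0, 50)
  val <- vapply(seq_len(n_stations), function(i) {
    d <- sqrt((sx - px[i])^2 + (sy - py[i])^2)
    if (any(d < 1e-9)) sv[which(d < 1e-9)[1]]
    else { w <- d^-2; sum(w * sv) / sum(w) }
  }, numeric(1))
  data.frame(x = px, y = py, value = val + rnorm(n_stations, 0, noise_sd))
}

# One-exposure hockey-stick study: the standard recovery fixture.
# Returns the truth, exposures, admissions and a fitted single-smooth
# Poisson model.
hockey_fixture <- function(seed, n_weeks = 261, beta0 = log(500),
                           threshold = 10, slope = 0.04,
                           family = "poisson", theta = NULL,
                           fit = TRUE) {
  cfg <- default_exposure_config()
  truth <- truth_model(
    beta0 = beta0,
    effects = list(rain_mm = list(
      "1" = effect_threshold(threshold, slope, cfg$rain_mm$mean))),
    family = family, theta = theta)
  exposures <- generate_exposures(cfg, n_weeks = n_weeks,
                                  seed = child_seed(seed, 1L))
  admissions <- generate_admissions(exposures, truth,
                                    seed = child_seed(seed, 2L))
  out <- list(truth = truth, exposures = exposures,
              admissions = admissions, config = cfg)
  if (fit) {
    design <- build_lag_design(admissions, exposures, max_lag = 1)
    out$design <- design
    out$model <- fit_admission_gam(design, "poisson",
                                   terms = "rain_mm_lag1",
                                   include_seasonal = FALSE)
  }
  out
}

# Small arbitrary fitted model for randomized identity checks.
random_small_model <- function(seed, n_weeks = 80) {
  set.seed(seed)
  cfg <- default_exposure_config()
  expo <- sample(exposure_names(), 1)
  shape <- sample(c("linear", "threshold", "invu"), 1)
  ctr <- cfg[[expo]]$mean
  ef <- switch(shape,
    linear = effect_linear(runif(1, -0.5, 0.5) * cfg[[expo]]$sd /
                             cfg[[expo]]$sd^2, ctr),
    threshold = effect_threshold(ctr, runif(1, 0.1, 0.5) / cfg[[expo]]$sd,
                                 ctr),
    invu = effect_inverted_u(ctr + cfg[[expo]]$sd, cfg[[expo]]$sd,
                             runif(1, 0.05, 0.3), ctr))
  truth <- truth_model(beta0 = log(200),
                       effects = setNames(list(list("1" = ef)), expo))
  exposures <- generate_exposures(cfg, n_weeks = n_weeks,
                                  seed = child_seed(seed, 3L))
  admissions <- generate_admissions(exposures, truth,
                                    seed = child_seed(seed, 4L))
  design <- build_lag_design(admissions, exposures, max_lag = 1)
  model <- fit_admission_gam(design, "poisson",
                             terms = paste0(expo, "_lag1"),
                             include_seasonal = FALSE, k_exposure = 6)
  list(model = model, exposure = expo, truth = truth)
}
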