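# Synthetic study generator: station weather, zone AQI, and weekly admission
# counts drawn from a fully known additive count model, so that every
# downstream stage (interpolation, lag design, GAM fit, IRR, PAF) can be
# validated against ground truth.

#' Exposure vocabulary
#'
#' The six national weekly exposures used throughout the package, in fixed
#' column order: total daily rainfall (mm), mean temperature (deg C), mean
#' wind speed (km/hr), PM10 (ug/m3), SO2 (ppb) and CO (ppm).
#'
#' @return Character vector of the six exposure column names.
#' @export
exposure_names <- function() {
  c("rain_mm", "temp_c", "wind_kmh", "pm10_ugm3", "so2_ppb", "co_ppm")
}

#' Default exposure marginal configuration
#'
#' Marginal mean, standard deviation and observed range for each exposure,
#' calibrated to the summary statistics of the 2014--2018 Singapore study
#' period (weekly national values).  Each exposure is generated as a
#' stationary AR(1) Gaussian series with the configured marginal moments,
#' truncated to the observed range; rainfall is additionally floored at zero
#' before range truncation.  PM10 carries a Bernoulli haze-spike process
#' (default probability 0.02 per week, multiplier drawn uniformly from
#' [2, 4]) reproducing the heavy right tail of the observed series
#' (mean 29.06, max 117.01 ug/m3).
#'
#' @param rho Temporal autocorrelation coefficient shared by all exposures,
#'   in `[0, 1)`.  Default 0.5.
#' @param cor_matrix Optional 6 x 6 cross-correlation matrix for the AR(1)
#'   innovations (row/column order of [exposure_names()]).  `NULL` (the
#'   default) generates independent exposures; no observed target values
#'   exist for these cross-correlations.
#' @return A list of class `exposure_config`: one element per exposure with
#'   fields `mean`, `sd`, `min`, `max`, `rho`, `zero_floor` and optional
#'   `spike = list(prob, mult)`, plus the `cor_matrix` attribute.
#' @export
default_exposure_config <- function(rho = 0.5, cor_matrix = NULL) {
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho >= 1)
    stop("`rho` must be in [0, 1)", call. = FALSE)
  spec <- function(mean, sd, min, max, zero_floor = FALSE, spike = NULL)
    list(mean = mean, sd = sd, min = min, max = max, rho = rho,
         zero_floor = zero_floor, spike = spike)
  cfg <- list(
    rain_mm   = spec(6.04, 4.52, 0.00, 21.72, zero_floor = TRUE),
    temp_c    = spec(28.01, 0.86, 25.01, 29.99),
    wind_kmh  = spec(8.24, 1.81, 5.43, 15.24),
    pm10_ugm3 = spec(29.06, 12.37, 16.03, 117.01,
                     spike = list(prob = 0.02, mult = c(2, 4))),
    so2_ppb   = spec(3.81, 1.83, 0.78, 8.57),
    co_ppm    = spec(0.36, 0.11, 0.19, 1.10)
  )
  validate_exposure_config(cfg)
  if (!is.null(cor_matrix)) {
    cor_matrix <- as.matrix(cor_matrix)
    if (!identical(dim(cor_matrix), c(6L, 6L)))
      stop("`cor_matrix` must be 6 x 6", call. = FALSE)
  }
  attr(cfg, "cor_matrix") <- cor_matrix
  class(cfg) <- "exposure_config"
  cfg
}

# Mean and sd of a normal clamped (censored) to [a, b].
censored_normal_moments <- function(mu, s, a, b) {
  al <- (a - mu) / s
  be <- (b - mu) / s
  p_lo <- pnorm(al)
  p_hi <- 1 - pnorm(be)
  pm <- pnorm(be) - pnorm(al)
  m1 <- a * p_lo + b * p_hi + mu * pm - s * (dnorm(be) - dnorm(al))
  m2 <- a^2 * p_lo + b^2 * p_hi + (mu^2 + s^2) * pm -
    s * ((b + mu) * dnorm(be) - (a + mu) * dnorm(al))
  c(mean = unname(m1), sd = sqrt(max(unname(m2 - m1^2), 0)))
}

# Base Gaussian parameters that deliver the configured marginal mean/sd
# AFTER the spike and range-clamp transforms.  The clamp is inverted by a
# fixed-point iteration on the censored-normal moments; the spike process
# (multiplier m with prob p) is inverted in closed form from its first two
# moments.
calibrate_base <- function(sp) {
  mu_t <- sp$mean
  sd_t <- sp$sd
  if (sd_t == 0) return(list(mean = mu_t, sd = 0))
  # step 1: pre-clamp moments whose clamped version matches the target
  mu_c <- mu_t
  sd_c <- sd_t
  for (i in 1:60) {
    mm <- censored_normal_moments(mu_c, sd_c, sp$min, sp$max)
    mu_c <- unname(mu_c + (mu_t - mm["mean"]))
    sd_c <- unname(sd_c * if (mm["sd"] > 0) sd_t / mm["sd"] else 1)
  }
  # step 2: pre-spike (base) moments whose spiked version has the
  # pre-clamp moments
  if (!is.null(sp$spike)) {
    p <- sp$spike$prob
    m1 <- mean(sp$spike$mult)                        # E[m], uniform
    m2 <- (sp$spike$mult[2]^3 - sp$spike$mult[1]^3) /
      (3 * diff(sp$spike$mult))                      # E[m^2]
    A <- 1 + p * (m2 - 1)
    B <- 1 + p * (m1 - 1)
    mu_b <- mu_c / B
    s2 <- (sd_c^2 + mu_c^2) / A - mu_b^2
    sd_b <- sqrt(max(s2, 1e-12))
  } else {
    mu_b <- mu_c
    sd_b <- sd_c
  }
  list(mean = unname(mu_b), sd = unname(sd_b))
}

validate_exposure_config <- function(config) {
  for (nm in names(config)) {
    sp <- config[[nm]]
    if (!is.finite(sp$min) || !is.finite(sp$max) || sp$min >= sp$max)
      stop(sprintf("exposure '%s': min must be < max", nm), call. = FALSE)
    if (sp$sd < 0)
      stop(sprintf("exposure '%s': sd must be >= 0", nm), call. = FALSE)
    if (sp$rho < 0 || sp$rho >= 1)
      stop(sprintf("exposure '%s': rho must be in [0, 1)", nm), call. = FALSE)
  }
  invisible(config)
}

#' Generate a weekly national exposure table
#'
#' Draws each exposure as a truncated AR(1) Gaussian series with the
#' configured marginal mean/sd, applies the optional zero floor (rainfall)
#' and haze-spike process (PM10), and attaches an epidemiological-week
#' calendar starting at `start_year`.
#'
#' @param config An [default_exposure_config()]-style configuration.
#' @param n_weeks Number of weekly rows (>= 8).
#' @param seed Integer seed; identical seeds give bit-identical tables.
#' @param start_year First calendar year of the epi-week index (default 2014).
#' @return A data frame with columns `week_index`, `year`, `epiweek` and the
#'   six exposure columns of [exposure_names()].
#' @examples
#' x <- generate_exposures(default_exposure_config(), n_weeks = 261, seed = 1)
#' colMeans(x[exposure_names()])
#' @export
generate_exposures <- function(config = default_exposure_config(),
                               n_weeks, seed, start_year = 2014) {
  n_weeks <- stopifnot_scalar_count(n_weeks, "n_weeks")
  if (n_weeks < 8)
    stop("`n_weeks` must be at least 8 (max lag plus a few rows)",
         call. = FALSE)
  validate_exposure_config(config)
  nms <- names(config)
  cal <- calendar_for_weeks(n_weeks, start_year)

  cor_matrix <- attr(config, "cor_matrix")
  out <- with_seed(seed, {
    # innovations, optionally cross-correlated across exposures
    eps <- matrix(rnorm(n_weeks * length(nms)), n_weeks, length(nms))
    if (!is.null(cor_matrix)) eps <- eps %*% chol(cor_matrix)
    colnames(eps) <- nms
    cols <- list()
    for (nm in nms) {
      sp <- config[[nm]]
      base <- calibrate_base(sp)
      z <- numeric(n_weeks)
      z[1] <- eps[1, nm]
      if (n_weeks > 1) {
        a <- sp$rho
        b <- sqrt(1 - a^2)
        for (t in 2:n_weeks) z[t] <- a * z[t - 1] + b * eps[t, nm]
      }
      x <- base$mean + base$sd * z
      if (isTRUE(sp$zero_floor)) x <- pmax(x, 0)
      if (!is.null(sp$spike)) {
        hit <- runif(n_weeks) < sp$spike$prob
        mult <- runif(n_weeks, sp$spike$mult[1], sp$spike$mult[2])
        x[hit] <- x[hit] * mult[hit]
      }
      cols[[nm]] <- pmin(pmax(x, sp$min), sp$max)
    }
    cols
  })
  cbind(data.frame(week_index = seq_len(n_weeks),
                   year = cal$year, epiweek = cal$epiweek),
        as.data.frame(out))
}

# Epi-week calendar covering at least n_weeks, truncated to n_weeks rows.
calendar_for_weeks <- function(n_weeks, start_year) {
  end_year <- start_year
  cal <- epiweek_calendar(start_year, end_year)
  while (nrow(cal) < n_weeks) {
    end_year <- end_year + 1
    cal <- epiweek_calendar(start_year, end_year)
  }
  cal[seq_len(n_weeks), , drop = FALSE]
}

## ---- truth effect library ------------------------------------------------

#' Truth effect shapes
#'
#' Parametric smooth effects used in a [truth_model()].  Each returns a
#' centered effect: its log-rate contribution is exactly zero at `center`
#' (conventionally the exposure mean), so the model intercept remains the
#' log baseline rate and oracle IRR/PAF values are closed form.
#'
#' `effect_linear` is a straight line through `center`; `effect_threshold`
#' is a hockey stick, flat below `threshold` and linear above it;
#' `effect_inverted_u` is a Gaussian bump peaking at `peak`.
#'
#' @param slope Log-rate change per unit exposure.
#' @param center Exposure value at which the contribution is zero.
#' @param threshold Kink location of the hockey stick.
#' @param peak,width,height Location, scale (sd) and maximum log-rate
#'   contribution of the inverted-U bump (before centering).
#' @return An object of class `truth_effect`.
#' @seealso [eval_effect()], [truth_model()]
#' @export
effect_linear <- function(slope, center) {
  new_truth_effect("linear", list(slope = slope), center)
}

#' @rdname effect_linear
#' @export
effect_threshold <- function(threshold, slope, center) {
  new_truth_effect("threshold", list(threshold = threshold, slope = slope),
                   center)
}

#' @rdname effect_linear
#' @export
effect_inverted_u <- function(peak, width, height, center) {
  if (width <= 0) stop("`width` must be positive", call. = FALSE)
  new_truth_effect("inverted_u",
                   list(peak = peak, width = width, height = height), center)
}

#' @rdname effect_linear
#' @export
effect_zero <- function(center = 0) {
  new_truth_effect("zero", list(), center)
}

new_truth_effect <- function(type, params, center) {
  structure(list(type = type, params = params, center = center),
            class = "truth_effect")
}

raw_effect_value <- function(effect, x) {
  p <- effect$params
  switch(effect$type,
    zero       = rep(0, length(x)),
    linear     = p$slope * x,
    threshold  = p$slope * pmax(x - p$threshold, 0),
    inverted_u = p$height * exp(-(x - p$peak)^2 / (2 * p$width^2)),
    stop(sprintf("unknown truth effect type '%s'", effect$type), call. = FALSE)
  )
}

#' Evaluate a truth effect
#'
#' Returns the centered log-rate contribution `f(x) - f(center)`.
#'
#' @param effect A `truth_effect`.
#' @param x Numeric exposure values.
#' @return Numeric vector, zero at `x == center`.
#' @export
eval_effect <- function(effect, x) {
  stopifnot(inherits(effect, "truth_effect"))
  raw_effect_value(effect, x) - raw_effect_value(effect, effect$center)
}

## ---- truth model ---------------------------------------------------------

#' Construct a ground-truth admission model
#'
#' The generative model for weekly counts: a log-linear rate combining a
#' baseline `beta0`, centered smooth exposure effects at lags 1..3,
#' autoregressive feedback on lagged counts, and weekly/annual seasonal
#' terms.  Counts are drawn from a Poisson or negative binomial family.
#'
#' The autoregressive contribution at lag `n` is
#' `ar[n] * (log1p(Y[t-n]) - log1p(exp(beta0)))`, a smooth function of the
#' raw lagged count that is zero at the stationary baseline, so `beta0`
#' stays interpretable as the log baseline rate.
#'
#' @param beta0 Log baseline weekly rate.
#' @param effects Named list (by exposure name) of named lists (by lag
#'   `"1"`, `"2"`, `"3"`) of [truth effect][effect_linear] objects.
#' @param ar Numeric vector of autoregressive coefficients for lags
#'   `1..length(ar)` (may be empty).
#' @param season_week_amp Amplitude of a sinusoidal weekly-seasonality term
#'   on the log scale (zero disables it).
#' @param trend_year_slope Linear log-scale trend per calendar year,
#'   centered on the observation years (zero disables it).
#' @param family `"poisson"` or `"negbin"`.
#' @param theta Negative binomial size (dispersion) parameter; required
#'   (and `> 0`) when `family = "negbin"`.
#' @return Object of class `truth_model`.
#' @export
truth_model <- function(beta0, effects = list(), ar = numeric(0),
                        season_week_amp = 0, trend_year_slope = 0,
                        family = c("poisson", "negbin"), theta = NULL) {
  family <- match.arg(family)
  if (family == "negbin") {
    if (is.null(theta) || theta <= 0)
      stop("negative binomial truth requires `theta` > 0", call. = FALSE)
  }
  for (exp_nm in names(effects)) {
    for (lag_nm in names(effects[[exp_nm]])) {
      ef <- effects[[exp_nm]][[lag_nm]]
      if (!inherits(ef, "truth_effect"))
        stop("all effects must be `truth_effect` objects", call. = FALSE)
    }
  }
  if (length(ar) > 3)
    stop("autoregressive order is limited to 3 weeks", call. = FALSE)
  structure(list(beta0 = beta0, effects = effects, ar = ar,
                 season_week_amp = season_week_amp,
                 trend_year_slope = trend_year_slope,
                 family = family, theta = theta),
            class = "truth_model")
}

truth_max_lag <- function(truth) {
  lag_e <- 0L
  for (exp_nm in names(truth$effects))
    for (lag_nm in names(truth$effects[[exp_nm]]))
      lag_e <- max(lag_e, as.integer(lag_nm))
  max(lag_e, length(truth$ar))
}

# Deterministic (no AR/no noise) part of the log rate for week t.
truth_fixed_lp <- function(truth, exposures, t, year_center) {
  lp <- truth$beta0
  for (exp_nm in names(truth$effects)) {
    for (lag_nm in names(truth$effects[[exp_nm]])) {
      n <- as.integer(lag_nm)
      if (t - n >= 1) {
        x <- exposures[[exp_nm]][t - n]
        lp <- lp + eval_effect(truth$effects[[exp_nm]][[lag_nm]], x)
      }
    }
  }
  if (truth$season_week_amp != 0)
    lp <- lp + truth$season_week_amp *
      sin(2 * pi * (exposures$epiweek[t] - 1) / 52)
  if (truth$trend_year_slope != 0)
    lp <- lp + truth$trend_year_slope * (exposures$year[t] - year_center)
  lp
}

#' Simulate weekly admission counts from a truth model
#'
#' Draws counts sequentially from the truth model's count family with
#' log-link mean combining exposure effects, autoregressive feedback and
#' seasonal terms.  Pre-sample lagged counts are seeded at the stationary
#' baseline `exp(beta0)`.
#'
#' @param exposures A weekly exposure table from [generate_exposures()].
#' @param truth A [truth_model()].
#' @param seed Integer seed.
#' @param category Optional category label attached to the output.
#' @return Data frame with columns `week_index`, `category`, `count`.
#' @export
generate_admissions <- function(exposures, truth, seed, category = "all") {
  stopifnot(inherits(truth, "truth_model"))
  n <- nrow(exposures)
  if (n < truth_max_lag(truth) + 1)
    stop("exposure horizon must exceed the truth model's maximum lag",
         call. = FALSE)
  mu0 <- exp(truth$beta0)
  year_center <- mean(unique(exposures$year))
  counts <- with_seed(seed, {
    y <- numeric(n)
    for (t in seq_len(n)) {
      lp <- truth_fixed_lp(truth, exposures, t, year_center)
      if (length(truth$ar)) {
        for (j in seq_along(truth$ar)) {
          y_lag <- if (t - j >= 1) y[t - j] else mu0
          lp <- lp + truth$ar[j] * (log1p(y_lag) - log1p(mu0))
        }
      }
      mu <- exp(lp)
      y[t] <- if (truth$family == "poisson") rpois(1L, mu)
              else rnbinom(1L, size = truth$theta, mu = mu)
    }
    y
  })
  data.frame(week_index = exposures$week_index, category = category,
             count = as.integer(counts))
}

## ---- oracles -------------------------------------------------------------

#' True incidence rate ratio of a truth effect
#'
#' Closed-form IRR of a truth model's exposure-lag effect over a grid:
#' `exp(f(x) - f(reference))`, identically 1 at the reference value.
#'
#' @param truth A [truth_model()].
#' @param exposure Exposure name.
#' @param lag Lag in weeks (1..3).
#' @param grid Numeric exposure values.
#' @param reference Reference exposure value; defaults to the effect's
#'   centering value.
#' @return Numeric vector of true IRRs along `grid`.
#' @export
oracle_irr <- function(truth, exposure, lag, grid, reference = NULL) {
  ef <- truth_effect_at(truth, exposure, lag)
  reference <- reference %||% ef$center
  exp(eval_effect(ef, grid) - eval_effect(ef, reference))
}

#' True per-week population attributable fraction
#'
#' PAF of one exposure-lag effect under the truth model, computed on true
#' means: removing the targeted effect multiplies the week-`t` rate by
#' `exp(-f(x[t - lag]))`, so
#' `PAF_t = (1 - exp(-f(x[t - lag]))) * 100`.
#'
#' @inheritParams oracle_irr
#' @param exposures Weekly exposure table the truth acts on.
#' @return Data frame `week_index`, `paf_pct` for weeks `lag + 1` onward.
#' @export
oracle_paf <- function(truth, exposures, exposure, lag) {
  ef <- truth_effect_at(truth, exposure, lag)
  t_idx <- (lag + 1):nrow(exposures)
  f <- eval_effect(ef, exposures[[exposure]][t_idx - lag])
  data.frame(week_index = exposures$week_index[t_idx],
             paf_pct = (1 - exp(-f)) * 100)
}

truth_effect_at <- function(truth, exposure, lag) {
  stopifnot(inherits(truth, "truth_model"))
  ef <- truth$effects[[exposure]][[as.character(lag)]]
  if (is.null(ef)) effect_zero() else ef
}

## ---- station-level daily weather ----------------------------------------

#' Generate daily station weather records with a known spatial surface
#'
#' Places `n_stations` stations uniformly on a bounded planar domain
#' (default 50 x 50 km), builds a true continuous daily surface for one
#' weather variable (a national AR(1) daily value plus a fixed smooth
#' spatial anomaly composed of Gaussian bumps), and records
#' surface-plus-noise observations at each station.  The surface closure is
#' returned so that interpolation error is directly measurable.
#'
#' @param config Exposure configuration providing the variable's marginal.
#' @param n_stations Number of stations (>= 2; leave-one-out needs several).
#' @param n_days Number of days.
#' @param seed Integer seed.
#' @param variable Which exposure's marginal to use (default `"temp_c"`).
#' @param noise_sd Station measurement noise sd; default 10% of the
#'   variable's marginal sd.
#' @param domain_km Side length of the square domain in km.
#' @return List with `stations` (id, x, y), `records`
#'   (station_id, x, y, date, variable, value), `surface` --
#'   a function `(x, y, day)` returning the true value -- and `noise_sd`.
#' @export
generate_station_daily <- function(config = default_exposure_config(),
                                   n_stations, n_days, seed,
                                   variable = "temp_c", noise_sd = NULL,
                                   domain_km = 50) {
  n_stations <- stopifnot_scalar_count(n_stations, "n_stations")
  n_days <- stopifnot_scalar_count(n_days, "n_days")
  if (n_stations < 2)
    stop("`n_stations` must be >= 2 (leave-one-out is undefined otherwise)",
         call. = FALSE)
  sp <- config[[variable]]
  if (is.null(sp)) stop(sprintf("unknown variable '%s'", variable),
                        call. = FALSE)
  noise_sd <- noise_sd %||% (0.1 * sp$sd)

  with_seed(seed, {
    sx <- runif(n_stations, 0, domain_km)
    sy <- runif(n_stations, 0, domain_km)
    # fixed spatial anomaly: three Gaussian bumps
    n_bump <- 3L
    bx <- runif(n_bump, 0, domain_km)
    by <- runif(n_bump, 0, domain_km)
    bamp <- rnorm(n_bump, 0, 0.6 * sp$sd)
    bw <- runif(n_bump, 0.2 * domain_km, 0.5 * domain_km)
    # national daily AR(1) value
    rho_d <- sp$rho
    z <- numeric(n_days)
    z[1] <- rnorm(1)
    if (n_days > 1)
      for (t in 2:n_days)
        z[t] <- rho_d * z[t - 1] + sqrt(1 - rho_d^2) * rnorm(1)
    national <- sp$mean + 0.5 * sp$sd * z

    anomaly <- function(x, y) {
      a <- 0
      for (b in seq_len(n_bump))
        a <- a + bamp[b] * exp(-((x - bx[b])^2 + (y - by[b])^2) /
                                 (2 * bw[b]^2))
      a
    }
    surface <- function(x, y, day) national[day] + anomaly(x, y)

    rec <- expand.grid(station_id = seq_len(n_stations),
                       date = seq_len(n_days))
    rec$x <- sx[rec$station_id]
    rec$y <- sy[rec$station_id]
    rec$variable <- variable
    rec$value <- surface(rec$x, rec$y, rec$date) +
      rnorm(nrow(rec), 0, noise_sd)
    if (isTRUE(sp$zero_floor)) rec$value <- pmax(rec$value, 0)

    list(stations = data.frame(station_id = seq_len(n_stations),
                               x = sx, y = sy),
         records = rec[, c("station_id", "x", "y", "date", "variable",
                           "value")],
         surface = surface,
         noise_sd = noise_sd)
  })
}

## ---- category reference statistics --------------------------------------

#' Admission categories and their weekly-count marginals
#'
#' The fixed 12-category vocabulary with weekly count summary statistics
#' (mean, sd, min, max) used to calibrate per-category synthetic baselines,
#' and the physiological-system grouping used for reporting.
#'
#' @return Data frame with columns `category`, `group`, `mean`, `sd`,
#'   `min`, `max`.
#' @export
ed_category_stats <- function() {
  g_cardio <- "Cardiorespiratory system disorders"
  g_metab <- "Metabolic and digestive system disorders"
  g_other <- "Others"
  out <- rbind(
    data.frame(category = "Cardiovascular disease", group = g_cardio,
               mean = 873.57, sd = 65.92, min = 624, max = 1075),
    data.frame(category = "Chronic respiratory disease", group = g_cardio,
               mean = 598.93, sd = 72.68, min = 421, max = 856),
    data.frame(category = "Respiratory infection", group = g_cardio,
               mean = 2276.84, sd = 529.57, min = 1266, max = 4083),
    data.frame(category = "Infectious and parasitic disease",
               group = g_cardio,
               mean = 1362.46, sd = 222.48, min = 890, max = 2029),
    data.frame(category = "Diabetes mellitus", group = g_metab,
               mean = 66.33, sd = 15.55, min = 26, max = 108),
    data.frame(category = "Digestive disease", group = g_metab,
               mean = 1161.74, sd = 274.48, min = 648, max = 1698),
    data.frame(category = "Endocrine disorders", group = g_metab,
               mean = 323.30, sd = 59.01, min = 206, max = 466),
    data.frame(category = "Genitourinary disorders", group = g_metab,
               mean = 695.89, sd = 55.96, min = 565, max = 835),
    data.frame(category = "Musculoskeletal disease", group = g_other,
               mean = 1211.36, sd = 108.05, min = 893, max = 1496),
    data.frame(category = "Neurological and sense disorders",
               group = g_other,
               mean = 800.29, sd = 51.93, min = 623, max = 964),
    data.frame(category = "Oral diseases", group = g_other,
               mean = 65.76, sd = 10.59, min = 39, max = 105),
    data.frame(category = "Skin diseases", group = g_other,
               mean = 739.26, sd = 62.43, min = 550, max = 879)
  )
  rownames(out) <- NULL
  out
}

#' Default per-category truth models
#'
#' One [truth_model()] per admission category, with the log baseline set to
#' the category's observed weekly mean, mild autoregression, weak
#' seasonality, and a small set of exposure effects whose shapes rotate
#' through the effect library (linear, threshold, inverted-U) so recovery
#' tests span all curve types.
#'
#' @param config Exposure configuration supplying effect centering values.
#' @return Named list of `truth_model` objects, one per category.
#' @export
default_truth_models <- function(config = default_exposure_config()) {
  stats <- ed_category_stats()
  ctr <- function(nm) config[[nm]]$mean
  shapes <- list(
    function() list(rain_mm = list("1" = effect_threshold(12, 0.02,
                                                          ctr("rain_mm")))),
    function() list(temp_c = list("2" = effect_inverted_u(29, 1.2, 0.08,
                                                          ctr("temp_c")))),
    function() list(pm10_ugm3 = list("3" = effect_threshold(45, 0.003,
                                                      ctr("pm10_ugm3")))),
    function() list(wind_kmh = list("1" = effect_linear(-0.01,
                                                        ctr("wind_kmh")))),
    function() list(co_ppm = list("1" = effect_threshold(0.6, 0.8,
                                                         ctr("co_ppm")))),
    function() list(so2_ppb = list("2" = effect_inverted_u(7, 1.5, 0.05,
                                                           ctr("so2_ppb"))))
  )
  out <- list()
  for (i in seq_len(nrow(stats))) {
    out[[stats$category[i]]] <- truth_model(
      beta0 = log(stats$mean[i]),
      effects = shapes[[(i - 1) %% length(shapes) + 1]](),
      ar = c(0.2),
      season_week_amp = 0.02,
      trend_year_slope = 0.01,
      family = "poisson"
    )
  }
  out
}
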