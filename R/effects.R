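# Counterfactual incidence-rate-ratio curves: predicted admissions while
# one exposure-lag term sweeps its observed range and every other term is
# held at its training mean, divided by predicted admissions with the
# targeted exposure also at its mean.

#' Incidence rate ratio curve for one exposure-lag term
#'
#' Builds counterfactual prediction rows with every covariate (including
#' the autoregressive and seasonal terms) at its training mean, varies only
#' the targeted exposure-lag column over quantiles of its observed values,
#' and forms the ratio of predicted admissions to the prediction at the
#' exposure mean.  Under the log link this ratio equals
#' `exp(fhat(x) - fhat(xbar))`; both routes are computed and must agree.
#'
#' Pointwise 95% intervals come from the variance of the linear-predictor
#' difference (basis-row difference quadratic form with the coefficient
#' covariance), exponentiated.  At the reference value the difference is
#' identically zero, so the IRR is exactly 1 and its interval degenerates
#' to `{1}`.
#'
#' @param model An [fit_admission_gam()] model.
#' @param exposure Exposure name (e.g. `"rain_mm"`).
#' @param lag Lag in weeks.
#' @param n_grid Number of quantile-spaced grid points (>= 2); the
#'   reference mean is appended so the grid always contains it exactly.
#' @param level Interval level (default 0.95).
#' @return Object of class `irr_curve`: data frame with `exposure`, `lag`,
#'   `grid_value`, `irr`, `lo`, `hi`, `significant`, `is_reference`,
#'   plus attributes `reference_value` and `ratio_route` (the
#'   ratio-of-predictions values, for consistency checking).
#' @export
irr_curve <- function(model, exposure, lag, n_grid = 100, level = 0.95) {
  stopifnot(inherits(model, "ed_gam"))
  if (!is.numeric(n_grid) || n_grid < 2)
    stop("`n_grid` must be at least 2", call. = FALSE)
  target <- paste0(exposure, "_lag", lag)
  if (!target %in% model$terms)
    stop(sprintf("term '%s' is not in the model", target), call. = FALSE)

  xv <- model$design$data[[target]]
  ref <- mean(xv)
  grid <- quantile(xv, probs = seq(0, 1, length.out = n_grid), type = 7,
                   names = FALSE)
  grid <- sort(unique(c(grid, ref)))

  nd <- counterfactual_rows(model, length(grid) + 1L)
  nd[[target]] <- c(grid, ref)
  Xp <- predict(model$fit, newdata = nd, type = "lpmatrix")
  Xr <- Xp[nrow(Xp), , drop = FALSE]
  Xg <- Xp[-nrow(Xp), , drop = FALSE]
  Xd <- sweep(Xg, 2, as.numeric(Xr))

  beta <- model_beta(model)
  log_irr <- drop(Xd %*% beta)
  se <- sqrt(pmax(rowSums((Xd %*% model_vp(model)) * Xd), 0))
  z <- qnorm(1 - (1 - level) / 2)

  # ratio-of-predictions route (must agree with the difference route)
  mu <- exp(drop(Xg %*% beta))
  mu_ref <- exp(drop(Xr %*% beta))
  ratio <- mu / mu_ref

  out <- data.frame(exposure = exposure, lag = lag, grid_value = grid,
                    irr = exp(log_irr),
                    lo = exp(log_irr - z * se),
                    hi = exp(log_irr + z * se))
  out$significant <- out$lo > 1 | out$hi < 1
  out$is_reference <- grid == ref
  attr(out, "reference_value") <- ref
  attr(out, "ratio_route") <- ratio
  class(out) <- c("irr_curve", "data.frame")
  out
}

# One-or-more rows with every model covariate at its training mean.
counterfactual_rows <- function(model, n) {
  dat <- model$design$data
  cols <- c(model$terms, intersect(c("epiweek", "year"), names(dat)))
  nd <- as.data.frame(lapply(dat[cols], function(v) rep(mean(v), n)))
  nd
}

#' Pointwise IRR interval at one exposure value
#'
#' @inheritParams irr_curve
#' @param value Exposure value at which to evaluate.
#' @return Named numeric: `irr`, `lo`, `hi`.
#' @export
irr_interval <- function(model, exposure, lag, value, level = 0.95) {
  target <- paste0(exposure, "_lag", lag)
  if (!target %in% model$terms)
    stop(sprintf("term '%s' is not in the model", target), call. = FALSE)
  nd <- counterfactual_rows(model, 2L)
  nd[[target]][1] <- value
  nd[[target]][2] <- mean(model$design$data[[target]])
  Xp <- predict(model$fit, newdata = nd, type = "lpmatrix")
  xd <- Xp[1, ] - Xp[2, ]
  est <- sum(xd * model_beta(model))
  se <- sqrt(max(drop(t(xd) %*% model_vp(model) %*% xd), 0))
  z <- qnorm(1 - (1 - level) / 2)
  c(irr = exp(est), lo = exp(est - z * se), hi = exp(est + z * se))
}

#' Flag grid points whose interval excludes 1
#'
#' The reporting convention for a significant IRR: the pointwise interval
#' lies entirely above 1 (harmful) or entirely below 1 (protective).
#'
#' @param curve An [irr_curve()].
#' @return Logical vector along the curve's grid.
#' @export
significance_mask <- function(curve) {
  stopifnot(inherits(curve, "irr_curve"))
  curve$lo > 1 | curve$hi < 1
}

#' IRR curves for every exposure-lag term of a model
#'
#' @inheritParams irr_curve
#' @return A single `data.frame` stacking [irr_curve()] results for every
#'   exposure-lag column in the model.
#' @export
irr_curves_all <- function(model, n_grid = 100, level = 0.95) {
  stopifnot(inherits(model, "ed_gam"))
  design <- model$design
  lag0 <- if (design$include_immediate) 0L else NULL
  out <- NULL
  for (nm in design$exposures) {
    for (k in c(lag0, seq_len(design$max_lag))) {
      if (!paste0(nm, "_lag", k) %in% model$terms) next
      cv <- irr_curve(model, nm, k, n_grid = n_grid, level = level)
      out <- rbind(out, as.data.frame(cv))
    }
  }
  out
}
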