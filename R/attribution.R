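# Population attributable fractions by counterfactual removal of one
# exposure's contribution, and the smoothed PAF-versus-exposure trend
# curves used for reporting.

#' Remove one exposure-lag term from a design
#'
#' Two removal modes are supported.  `"drop-term"` (the default) marks the
#' fitted smooth's contribution for subtraction from the linear predictor
#' -- equivalent to deleting that smooth from the model -- and leaves the
#' design values untouched.  `"set-zero"` literally zeroes the targeted
#' column (classifying every week as unexposed); because zero lies outside
#' most observed exposure ranges this forces the spline to extrapolate,
#' and a warning is emitted when it does.
#'
#' @param design A [build_lag_design()] result.
#' @param exposure Exposure name.
#' @param lag Lag in weeks.
#' @param mode `"drop-term"` or `"set-zero"`.
#' @return The design, with the `removed` attribute describing the
#'   counterfactual (and, for `"set-zero"`, the targeted column zeroed).
#' @export
remove_exposure <- function(design, exposure, lag,
                            mode = c("drop-term", "set-zero")) {
  stopifnot(inherits(design, "lag_design"))
  mode <- match.arg(mode)
  target <- paste0(exposure, "_lag", lag)
  if (!target %in% names(design$data))
    stop(sprintf("column '%s' is not in the design", target), call. = FALSE)
  if (mode == "set-zero") {
    rng <- range(design$data[[target]])
    if (rng[1] > 0 || rng[2] < 0)
      warning(sprintf(
        "set-zero places '%s' outside its observed range [%g, %g]; %s",
        target, rng[1], rng[2],
        "predictions extrapolate the fitted spline"))
    design$data[[target]] <- 0
  }
  attr(design, "removed") <- list(exposure = exposure, lag = lag,
                                  target = target, mode = mode)
  design
}

# Expected counts under removal of one exposure-lag term.
counterfactual_expected <- function(model, exposure, lag,
                                    mode = c("drop-term", "set-zero"),
                                    design = NULL) {
  stopifnot(inherits(model, "ed_gam"))
  mode <- match.arg(mode)
  design <- design %||% model$design
  target <- paste0(exposure, "_lag", lag)
  if (!target %in% model$terms)
    stop(sprintf("term '%s' is not in the model", target), call. = FALSE)
  if (mode == "set-zero") {
    cf <- remove_exposure(design, exposure, lag, mode = "set-zero")
    return(predict_ed(model, cf$data)$expected)
  }
  beta <- model_beta(model)
  Xp <- predict(model$fit, newdata = design$data, type = "lpmatrix")
  idx <- smooth_coef_index(model, target)
  lp <- drop(Xp %*% beta)
  if (!is.null(idx))
    lp <- lp - drop(Xp[, idx, drop = FALSE] %*% beta[idx])
  else if (model$linear_terms)
    lp <- lp - Xp[, target] * beta[target]
  unname(exp(lp))
}

#' Attributable fraction from observed and expected counts
#'
#' The attribution arithmetic used throughout:
#' `(observed - expected) / observed * 100`.
#'
#' @param observed Observed counts (non-zero).
#' @param expected Expected counts under removal of the exposure.
#' @return PAF in percent; negative when the exposure is protective.
#' @examples
#' paf_percent(c(100, 100, 80), c(100, 50, 100))  # 0, 50, -25
#' @export
paf_percent <- function(observed, expected) {
  if (any(observed == 0))
    stop("PAF is undefined for zero observed counts", call. = FALSE)
  (observed - expected) / observed * 100
}

#' Per-week population attributable fraction series
#'
#' Computes, for every usable week, the expected admissions had the
#' targeted exposure been removed (see [remove_exposure()] for the two
#' removal modes), and the attributable fraction
#' `PAF_t = (observed_t - expected_t) / observed_t * 100`.
#' Negative values indicate a protective exposure.  Weeks with zero
#' observed counts are excluded and recorded in the `excluded_weeks`
#' attribute.
#'
#' @inheritParams remove_exposure
#' @param model An [fit_admission_gam()] model.
#' @return Object of class `paf_series`: data frame with `week_index`,
#'   `observed`, `expected`, `paf_pct` plus `exposure`/`lag`/`mode`
#'   attributes.
#' @export
paf_series <- function(model, exposure, lag,
                       mode = c("drop-term", "set-zero")) {
  stopifnot(inherits(model, "ed_gam"))
  mode <- match.arg(mode)
  dat <- model$design$data
  expected <- counterfactual_expected(model, exposure, lag, mode)
  keep <- dat$y != 0
  out <- data.frame(week_index = dat$week_index[keep],
                    observed = dat$y[keep],
                    expected = expected[keep])
  out$paf_pct <- paf_percent(out$observed, out$expected)
  attr(out, "exposure") <- exposure
  attr(out, "lag") <- lag
  attr(out, "mode") <- mode
  attr(out, "excluded_weeks") <- dat$week_index[!keep]
  class(out) <- c("paf_series", "data.frame")
  out
}

#' Smoothed PAF-versus-exposure trend curve
#'
#' Locally-weighted (local-linear, tricube-weighted) regression of the
#' weekly PAF values on the exposure value at the matching lag, evaluated
#' on an evenly spaced grid over the observed exposure range, with a
#' pointwise band from the local-regression standard errors.
#'
#' @param paf A [paf_series()].
#' @param exposure_values The targeted exposure-lag values aligned with the
#'   PAF weeks (same length and order).
#' @param span Local regression span (default 0.75).
#' @param n_grid Evaluation grid size (default 100).
#' @param level Band level (default 0.95).
#' @return Object of class `paf_curve`: data frame `grid_value`,
#'   `paf_trend`, `lo`, `hi`.
#' @export
smooth_paf <- function(paf, exposure_values, span = 0.75, n_grid = 100,
                       level = 0.95) {
  stopifnot(inherits(paf, "paf_series"))
  if (length(exposure_values) != nrow(paf))
    stop("`exposure_values` must align with the PAF series", call. = FALSE)
  if (nrow(paf) < 20)
    stop("at least 20 (exposure, PAF) pairs are required", call. = FALSE)
  df <- data.frame(x = exposure_values, paf = paf$paf_pct)
  fit <- loess(paf ~ x, data = df, degree = 1, span = span,
               family = "gaussian", surface = "direct")
  grid <- seq(min(df$x), max(df$x), length.out = n_grid)
  pr <- predict(fit, newdata = data.frame(x = grid), se = TRUE)
  z <- qnorm(1 - (1 - level) / 2)
  out <- data.frame(grid_value = grid, paf_trend = pr$fit,
                    lo = pr$fit - z * pr$se.fit,
                    hi = pr$fit + z * pr$se.fit)
  attr(out, "exposure") <- attr(paf, "exposure")
  attr(out, "lag") <- attr(paf, "lag")
  attr(out, "span") <- span
  class(out) <- c("paf_curve", "data.frame")
  out
}

#' Map admission categories to physiological-system groups
#'
#' Maps each of the fixed 12 category names to one of the three reporting
#' groups: cardiorespiratory system disorders, metabolic and digestive
#' system disorders, or others.
#'
#' @param categories Character vector of category names.
#' @return Character vector of group labels.
#' @examples
#' group_categories("Cardiovascular disease")
#' @export
group_categories <- function(categories) {
  stats <- ed_category_stats()
  idx <- match(categories, stats$category)
  if (anyNA(idx))
    stop(sprintf("unknown admission category: %s",
                 paste(categories[is.na(idx)], collapse = ", ")),
         call. = FALSE)
  stats$group[idx]
}
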