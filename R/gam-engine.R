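# Penalized regression spline count models for the lagged design: every
# lagged term enters as a low-rank thin-plate-type smooth, the weekly
# seasonal term as a cyclic smooth, with smoothing parameters chosen by
# REML.  Fitting is delegated to mgcv; this module owns the model surface
# (term construction, family handling, scoring, dispersion) used by the
# effects and attribution stages.

#' Smooth term specification
#'
#' @param role Covariate role: `"exposure"`, `"ar"`, `"week"` or `"year"`.
#' @param bs Basis type: `"tp"` (low-rank thin plate regression spline) or
#'   `"cc"` (cyclic cubic, only for the weekly seasonal term).
#' @param k Basis dimension (>= 3).
#' @return Object of class `smooth_spec`.
#' @export
smooth_spec <- function(role = "exposure", bs = c("tp", "cc"), k = 8) {
  bs <- match.arg(bs)
  if (!is.numeric(k) || length(k) != 1L || k < 3)
    stop("basis dimension `k` must be an integer >= 3", call. = FALSE)
  if (bs == "cc" && role != "week")
    stop("the cyclic basis is reserved for the weekly seasonal term",
         call. = FALSE)
  structure(list(role = role, bs = bs, k = as.integer(k)),
            class = "smooth_spec")
}

#' Build a smooth basis and its penalty
#'
#' Constructs the low-rank basis matrix and roughness penalty for one
#' covariate, with the sum-to-zero identifiability constraint absorbed (so
#' every column of the basis sums to zero over the training values and any
#' fitted smooth is centered).  The cyclic basis (`bs = "cc"`, knots at
#' 0.5 and 53.5) matches value and first derivative across the week-1 /
#' week-53 boundary.
#'
#' @param values Training covariate values (>= 3 distinct; `k` is reduced
#'   with a warning when there are fewer than `k` distinct values).
#' @param spec A [smooth_spec()].
#' @return List with `X` (n x q basis matrix), `S` (q x q penalty, positive
#'   semi-definite), and `smooth` (the underlying constructor object,
#'   usable with `mgcv::PredictMat`).
#' @export
build_basis <- function(values, spec = smooth_spec()) {
  stopifnot(inherits(spec, "smooth_spec"))
  u <- length(unique(values))
  if (u < 2L) stop("covariate is constant", call. = FALSE)
  k <- spec$k
  if (u < k) {
    warning(sprintf("only %d distinct values; reducing k from %d", u, k))
    k <- max(3L, u)
  }
  dat <- data.frame(x = values)
  knots <- if (spec$bs == "cc") list(x = c(0.5, 53.5)) else NULL
  sm <- mgcv::smoothCon(mgcv::s(x, bs = spec$bs, k = k),
                        data = dat, knots = knots,
                        absorb.cons = TRUE)[[1]]
  list(X = sm$X, S = sm$S[[1]], smooth = sm)
}

## ---- model fitting -------------------------------------------------------

#' Fit the lagged additive count model
#'
#' Fits weekly counts against penalized-spline smooths of every lagged
#' term in the design (autoregressive `y_lag*` columns and exposure-lag
#' columns), a cyclic smooth of the epi-week and a smooth of the year,
#' with smoothing parameters selected by REML.
#'
#' Families: `"poisson"`; `"quasipoisson"` -- identical point estimates to
#' the Poisson fit with the coefficient covariance scaled by the Pearson
#' dispersion; `"negbin"` -- negative binomial with the size parameter
#' estimated by outer profiling alongside REML.
#'
#' @param design A [build_lag_design()] result.
#' @param family `"poisson"`, `"quasipoisson"` or `"negbin"`.
#' @param terms Smooth term columns to include; defaults to all
#'   autoregressive and exposure-lag columns of the design.
#' @param k_exposure,k_ar,k_week,k_year Basis dimensions.  Defaults (8, 8,
#'   10 cyclic, 4) keep the total effective degrees of freedom well below
#'   the usable rows of a 261-week design.
#' @param include_seasonal Include the `s(epiweek)` and `s(year)` terms.
#' @param cyclic_week Use the cyclic basis for the weekly term (weeks 1 and
#'   52/53 adjacent).  Default `TRUE`.
#' @param linear_terms Enter all lagged terms as plain linear (parametric)
#'   columns instead of smooths -- the unpenalized GLM limit of the model.
#' @param sp Optional fixed smoothing parameter vector passed through to
#'   the optimizer (bypassing REML for those terms).
#' @return Object of class `ed_gam`: list with the underlying `fit`, the
#'   `family`, `design`, `terms`, Pearson `dispersion`, and the
#'   (dispersion-scaled, for quasi-Poisson) coefficient covariance `vp`.
#' @export
fit_admission_gam <- function(design,
                              family = c("poisson", "quasipoisson",
                                         "negbin"),
                              terms = NULL,
                              k_exposure = 8, k_ar = 8, k_week = 10,
                              k_year = 4,
                              include_seasonal = TRUE, cyclic_week = TRUE,
                              linear_terms = FALSE, sp = NULL) {
  stopifnot(inherits(design, "lag_design"))
  family <- match.arg(family)
  dat <- design$data
  if (any(dat$y < 0)) stop("counts must be non-negative", call. = FALSE)
  terms <- terms %||% c(design_ar_terms(design),
                        design_exposure_terms(design))
  missing_terms <- setdiff(terms, names(dat))
  if (length(missing_terms))
    stop(sprintf("term(s) not in design: %s",
                 paste(missing_terms, collapse = ", ")), call. = FALSE)

  term_k <- function(nm) {
    k <- if (grepl("^y_lag", nm)) k_ar else k_exposure
    min(k, length(unique(dat[[nm]])))
  }
  rhs <- if (linear_terms) terms
         else vapply(terms, function(nm)
           sprintf("s(%s, bs = \"tp\", k = %d)", nm, term_k(nm)),
           character(1))
  knots <- NULL
  if (include_seasonal) {
    if (length(unique(dat$epiweek)) >= 4) {
      if (cyclic_week) {
        rhs <- c(rhs, sprintf("s(epiweek, bs = \"cc\", k = %d)",
                              min(k_week, length(unique(dat$epiweek)))))
        knots <- list(epiweek = c(0.5, 53.5))
      } else {
        rhs <- c(rhs, sprintf("s(epiweek, bs = \"tp\", k = %d)",
                              min(k_week, length(unique(dat$epiweek)))))
      }
    }
    n_year <- length(unique(dat$year))
    if (n_year >= 3)
      rhs <- c(rhs, sprintf("s(year, bs = \"tp\", k = %d)",
                            min(k_year, n_year)))
  }
  if (length(rhs) == 0L) rhs <- "1"   # intercept-only null model
  fml <- as.formula(paste("y ~", paste(rhs, collapse = " + ")))

  fam <- switch(family,
                poisson = stats::poisson(),
                quasipoisson = stats::poisson(),  # scaled after the fit
                negbin = mgcv::nb())
  fit <- mgcv::gam(fml, family = fam, data = dat, method = "REML",
                   knots = knots, sp = sp,
                   control = mgcv::gam.control(epsilon = 1e-8,
                                               maxit = 200))
  if (!fit$converged)
    warning("penalized IRLS did not converge; inspect the fit")

  model <- structure(list(fit = fit, family = family, design = design,
                          terms = terms, linear_terms = linear_terms),
                    class = "ed_gam")
  phi <- pearson_dispersion(fit)
  model$dispersion <- phi
  model$vp <- if (family == "quasipoisson") fit$Vp * phi else fit$Vp
  model
}

pearson_dispersion <- function(fit) {
  r <- residuals(fit, type = "pearson")
  edf_resid <- length(r) - sum(fit$edf)
  sum(r^2) / edf_resid
}

#' Pearson dispersion statistic of a fitted model
#'
#' Sum of squared Pearson residuals divided by the residual effective
#' degrees of freedom.  Values well above 1 for a Poisson fit indicate
#' overdispersion (triaging toward quasi-Poisson covariance scaling or a
#' negative binomial family).
#'
#' @param model An `ed_gam` model.
#' @return The dispersion statistic (non-negative scalar).
#' @export
dispersion_stat <- function(model) {
  stopifnot(inherits(model, "ed_gam"))
  pearson_dispersion(model$fit)
}

model_beta <- function(model) coef(model$fit)
model_vp <- function(model) model$vp

#' Effective degrees of freedom of a fitted model
#' @param model An `ed_gam` model.
#' @return Total EDF (including the intercept and, for the negative
#'   binomial, one for the size parameter).
#' @export
total_edf <- function(model) {
  sum(model$fit$edf) + if (model$family == "negbin") 1 else 0
}

#' Predict expected counts from a fitted model
#'
#' @param model An `ed_gam` model.
#' @param newdata Data frame covering every model term; defaults to the
#'   training rows.
#' @param se Also return the pointwise standard error of the linear
#'   predictor (from the coefficient covariance, dispersion-scaled for
#'   quasi-Poisson).
#' @return Data frame with `expected` (response scale), `lp` (linear
#'   predictor) and, if requested, `lp_se`.
#' @export
predict_ed <- function(model, newdata = NULL, se = FALSE) {
  stopifnot(inherits(model, "ed_gam"))
  newdata <- newdata %||% model$design$data
  Xp <- predict(model$fit, newdata = newdata, type = "lpmatrix")
  lp <- drop(Xp %*% model_beta(model))
  out <- data.frame(expected = exp(lp), lp = lp)
  if (se)
    out$lp_se <- sqrt(pmax(rowSums((Xp %*% model_vp(model)) * Xp), 0))
  out
}

## ---- scoring -------------------------------------------------------------

#' Score a fitted model
#'
#' AIC is `-2 loglik + 2 EDF` (with one extra degree of freedom for the
#' negative binomial size parameter) and is undefined -- reported `NA` --
#' for quasi-Poisson, whose fit quality is judged by RMSE and MAPE
#' instead.  MAPE is computed excluding zero-count rows; the number
#' excluded is recorded in the `mape_excluded` field.
#'
#' @param model An `ed_gam` model.
#' @param newdata Optional evaluation rows (defaults to training rows).
#' @return Data frame row with `family`, `max_lag`, `include_immediate`,
#'   `aic`, `rmse`, `mape`, `edf`, `mape_excluded`.
#' @export
score_model <- function(model, newdata = NULL) {
  stopifnot(inherits(model, "ed_gam"))
  newdata <- newdata %||% model$design$data
  pred <- predict_ed(model, newdata)$expected
  obs <- newdata$y
  aic <- if (model$family == "quasipoisson") NA_real_
         else -2 * as.numeric(logLik(model$fit)) + 2 * total_edf(model)
  m <- mape(obs, pred)
  data.frame(family = model$family, max_lag = model$design$max_lag,
             include_immediate = model$design$include_immediate,
             aic = aic, rmse = rmse(obs, pred), mape = m$mape,
             edf = total_edf(model), mape_excluded = m$excluded)
}

rmse <- function(observed, predicted) {
  sqrt(mean((observed - predicted)^2))
}

mape <- function(observed, predicted) {
  nz <- observed != 0
  list(mape = mean(abs((observed[nz] - predicted[nz]) / observed[nz])) * 100,
       excluded = sum(!nz))
}

# AIC/RMSE/MAPE from raw components; the arithmetic backbone of
# score_model, exposed for direct use.
#' Model score from raw components
#'
#' @param loglik Log-likelihood.
#' @param edf Total effective degrees of freedom.
#' @param observed,predicted Count vectors.
#' @return List with `aic`, `rmse`, `mape` (percent, zero-count rows
#'   excluded).
#' @export
model_score <- function(loglik, edf, observed, predicted) {
  list(aic = -2 * loglik + 2 * edf,
       rmse = rmse(observed, predicted),
       mape = mape(observed, predicted)$mape)
}

# Coefficient index range of the smooth on `term`, or NULL if absent.
smooth_coef_index <- function(model, term) {
  for (sm in model$fit$smooth) {
    if (sm$term[1] == term) return(sm$first.para:sm$last.para)
  }
  NULL
}
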