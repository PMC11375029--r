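# Lagged design construction, the epidemiological-week calendar, and PACF
# diagnostics guiding the choice of autoregressive lag order.

#' Epidemiological-week calendar
#'
#' Enumerates epi-weeks by the MMWR convention: weeks run Sunday to
#' Saturday and week 1 of a year is the week containing at least four days
#' of January (equivalently, the week whose Sunday falls between 29
#' December and 4 January).  Years have 52 or 53 weeks; 2014--2018 yields
#' 261 weeks, with 2014 carrying 53.
#'
#' @param start_year,end_year Calendar year range (inclusive).
#' @return Data frame with columns `year`, `epiweek`, `start_date`
#'   (a `Date`, the week's Sunday).
#' @examples
#' nrow(epiweek_calendar(2014, 2018))  # 261
#' @export
epiweek_calendar <- function(start_year, end_year) {
  if (end_year < start_year)
    stop("`end_year` must be >= `start_year`", call. = FALSE)
  starts <- vapply(start_year:(end_year + 1), mmwr_week1_start, numeric(1))
  out <- NULL
  years <- start_year:end_year
  for (i in seq_along(years)) {
    n_wk <- as.integer((starts[i + 1] - starts[i]) / 7)
    out <- rbind(out, data.frame(
      year = years[i],
      epiweek = seq_len(n_wk),
      start_date = as.Date(starts[i] + 7 * (seq_len(n_wk) - 1),
                           origin = "1970-01-01")))
  }
  out
}

# Numeric (days since epoch) Sunday starting MMWR week 1 of `year`:
# the unique Sunday in [Dec 29 of year-1, Jan 4 of year].
mmwr_week1_start <- function(year) {
  jan4 <- as.Date(sprintf("%d-01-04", year))
  dow <- as.integer(format(jan4, "%w"))   # 0 = Sunday
  as.numeric(jan4 - dow)
}

#' Build a lagged regression design
#'
#' Joins a weekly admission series with a weekly exposure table and builds
#' the lagged design used by the count models: the response `y`, lagged
#' responses `y_lag1..l`, per-exposure lag columns `<exposure>_lag<n>` for
#' lags `1..l` (plus lag-0 columns when `include_immediate` is set), and
#' the `epiweek`/`year` seasonal covariates.  The first `max_lag` rows have
#' incomplete lag information and are masked out of the usable design.
#'
#' @param admissions Data frame with `week_index` and `count` columns.
#' @param exposures Weekly exposure table sharing the same `week_index`;
#'   every numeric column other than `week_index`, `year`, `epiweek` is
#'   treated as an exposure.
#' @param max_lag Maximum lag in weeks (1..3).
#' @param include_immediate Also include the current-week (lag 0) exposure
#'   columns.  Default `FALSE`.
#' @return An object of class `lag_design`: a list with `data` (the usable
#'   rows), `max_lag`, `include_immediate`, `exposures` (names), and
#'   `n_total`.
#' @export
build_lag_design <- function(admissions, exposures, max_lag,
                             include_immediate = FALSE) {
  if (!is.numeric(max_lag) || length(max_lag) != 1L || max_lag < 1 ||
      max_lag > 3 || max_lag != round(max_lag))
    stop("`max_lag` must be 1, 2 or 3", call. = FALSE)
  max_lag <- as.integer(max_lag)
  if (!identical(as.integer(admissions$week_index),
                 as.integer(exposures$week_index)))
    stop("admissions and exposures must share an identical week index",
         call. = FALSE)
  n <- nrow(exposures)
  if (n <= max_lag)
    stop("series horizon must exceed `max_lag`", call. = FALSE)

  reserved <- c("week_index", "year", "epiweek")
  expo_nms <- setdiff(names(exposures)[vapply(exposures, is.numeric,
                                              logical(1))], reserved)
  lag_col <- function(x, k) c(rep(NA_real_, k), head(x, n - k))

  full <- data.frame(week_index = exposures$week_index,
                     y = as.numeric(admissions$count))
  for (k in seq_len(max_lag))
    full[[paste0("y_lag", k)]] <- lag_col(full$y, k)
  lag0 <- if (include_immediate) 0L else NULL
  for (nm in expo_nms)
    for (k in c(lag0, seq_len(max_lag)))
      full[[paste0(nm, "_lag", k)]] <- lag_col(exposures[[nm]], k)
  full$epiweek <- exposures$epiweek
  full$year <- exposures$year

  usable <- full[(max_lag + 1):n, , drop = FALSE]
  if (anyNA(usable))
    stop("missing values among usable design rows", call. = FALSE)
  rownames(usable) <- NULL
  structure(list(data = usable, max_lag = max_lag,
                 include_immediate = include_immediate,
                 exposures = expo_nms, n_total = n),
            class = "lag_design")
}

#' Exposure-lag term columns of a lag design
#'
#' @param design A [build_lag_design()] result.
#' @return Character vector of the exposure lag column names (excluding the
#'   autoregressive `y_lag*` columns).
#' @export
design_exposure_terms <- function(design) {
  stopifnot(inherits(design, "lag_design"))
  lag0 <- if (design$include_immediate) 0L else NULL
  unlist(lapply(design$exposures, function(nm)
    paste0(nm, "_lag", c(lag0, seq_len(design$max_lag)))))
}

#' Autoregressive term columns of a lag design
#'
#' @param design A [build_lag_design()] result.
#' @return Character vector of the lagged-response column names.
#' @export
design_ar_terms <- function(design) {
  paste0("y_lag", seq_len(design$max_lag))
}

#' Partial autocorrelation function (Durbin-Levinson)
#'
#' Computes the sample PACF at lags `1..max_lag` via the Durbin-Levinson
#' recursion on the sample autocorrelations, together with the asymptotic
#' 95% white-noise band `+/- 1.96 / sqrt(n)`.
#'
#' @param series Numeric vector (non-constant).
#' @param max_lag Highest lag.
#' @return List with `pacf` (named numeric, lags 1..max_lag), `band`
#'   (positive band half-width), and `n`.
#' @export
pacf_dl <- function(series, max_lag) {
  series <- as.numeric(series)
  max_lag <- stopifnot_scalar_count(max_lag, "max_lag")
  n <- length(series)
  if (n <= max_lag + 1)
    stop("series length must exceed `max_lag` + 1", call. = FALSE)
  if (sd(series) == 0)
    stop("PACF is undefined for a constant series", call. = FALSE)
  x <- series - mean(series)
  # biased sample autocovariances, the standard choice for stationarity
  acv <- vapply(0:max_lag, function(k)
    sum(x[1:(n - k)] * x[(1 + k):n]) / n, numeric(1))
  rho <- acv[-1] / acv[1]

  phi <- matrix(0, max_lag, max_lag)
  pacf <- numeric(max_lag)
  phi[1, 1] <- pacf[1] <- rho[1]
  if (max_lag > 1) {
    for (k in 2:max_lag) {
      num <- rho[k] - sum(phi[k - 1, 1:(k - 1)] * rho[(k - 1):1])
      den <- 1 - sum(phi[k - 1, 1:(k - 1)] * rho[1:(k - 1)])
      phi[k, k] <- pacf[k] <- num / den
      phi[k, 1:(k - 1)] <- phi[k - 1, 1:(k - 1)] -
        phi[k, k] * phi[k - 1, (k - 1):1]
    }
  }
  list(pacf = setNames(pacf, paste0("lag", seq_len(max_lag))),
       band = 1.96 / sqrt(n), n = n)
}
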