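# Inverse distance weighting of station observations to a regular grid,
# leave-one-out selection of the distance power, and weekly aggregation of
# daily fields to national means.

# Core IDW predictor: stations (x, y, value) to arbitrary query points.
# A query within `eps` km of a station takes that station's value exactly.
idw_predict <- function(sx, sy, sv, qx, qy, power, eps = 1e-9) {
  if (length(sx) < 1L) stop("at least one station is required", call. = FALSE)
  if (!is.numeric(power) || length(power) != 1L || power <= 0)
    stop("`power` must be a positive real", call. = FALSE)
  out <- numeric(length(qx))
  for (i in seq_along(qx)) {
    d <- sqrt((sx - qx[i])^2 + (sy - qy[i])^2)
    hit <- which(d < eps)
    if (length(hit)) {
      out[i] <- sv[hit[1L]]
    } else {
      w <- d^(-power)
      out[i] <- sum(w * sv) / sum(w)
    }
  }
  out
}

#' Default interpolation grid over a set of stations
#'
#' A regular grid of square cells covering the stations' bounding box,
#' padded by 10% on each side.
#'
#' @param observations Data frame with `x`, `y` columns (km).
#' @param cell_km Cell size in km (default 1).
#' @param pad Fractional padding of the bounding box (default 0.1).
#' @return List with `x0`, `y0` (origin), `cell_km`, `n_rows`, `n_cols`.
#' @export
make_grid <- function(observations, cell_km = 1, pad = 0.1) {
  rx <- range(observations$x)
  ry <- range(observations$y)
  px <- max(diff(rx), cell_km) * pad
  py <- max(diff(ry), cell_km) * pad
  x0 <- rx[1] - px
  y0 <- ry[1] - py
  list(x0 = x0, y0 = y0, cell_km = cell_km,
       n_cols = max(1L, ceiling((rx[2] + px - x0) / cell_km)),
       n_rows = max(1L, ceiling((ry[2] + py - y0) / cell_km)))
}

#' Inverse distance weighting interpolation to a grid
#'
#' Interpolates one date/variable's station observations onto a regular
#' grid.  The value at each cell center is the distance-power-weighted
#' average of the station values, `sum(w * v) / sum(w)` with
#' `w = d^(-power)`; a cell whose center lies within 1e-9 km of a station
#' takes that station's value exactly.
#'
#' @param observations Data frame with columns `x`, `y`, `value` (one row
#'   per station) and optionally `date`, `variable`.
#' @param power Positive IDW power.
#' @param grid Grid spec from [make_grid()]; computed from the stations by
#'   default.
#' @return Object of class `gridded_field`: list with `values` (an
#'   `n_rows` x `n_cols` matrix), cell-center coordinates `x`, `y`, the
#'   `grid` spec, and any `date`/`variable` carried over.
#' @export
idw_interpolate <- function(observations, power, grid = NULL) {
  if (is.null(observations) || nrow(observations) == 0L)
    stop("empty observation set", call. = FALSE)
  grid <- grid %||% make_grid(observations)
  cx <- grid$x0 + grid$cell_km * (seq_len(grid$n_cols) - 0.5)
  cy <- grid$y0 + grid$cell_km * (seq_len(grid$n_rows) - 0.5)
  q <- expand.grid(x = cx, y = cy)
  v <- idw_predict(observations$x, observations$y, observations$value,
                   q$x, q$y, power)
  structure(list(values = matrix(v, grid$n_rows, grid$n_cols, byrow = TRUE),
                 x = cx, y = cy, grid = grid,
                 date = observations$date[1] %||% NA,
                 variable = observations$variable[1] %||% NA_character_),
            class = "gridded_field")
}

#' Spatial mean of a gridded field
#' @param field A `gridded_field`.
#' @return The mean over all cells.
#' @export
field_mean <- function(field) mean(field$values)

#' Select the IDW power by leave-one-out cross-validation
#'
#' For each candidate power, predicts every station from all the others and
#' computes the leave-one-out RMSE; returns the candidate minimizing the
#' RMSE, ties broken toward the smallest power.
#'
#' @param observations Data frame with `x`, `y`, `value` (>= 3 stations).
#' @param powers Candidate powers (default 0.5 to 5 in steps of 0.25).
#' @return List with `power` (the winner) and `loo` (data frame
#'   `power`, `rmse`).
#' @export
fit_idw_power <- function(observations, powers = seq(0.5, 5, by = 0.25)) {
  n <- nrow(observations)
  if (n < 3L)
    stop("leave-one-out power selection needs at least 3 stations",
         call. = FALSE)
  if (length(powers) < 1L || any(powers <= 0))
    stop("`powers` must be a non-empty vector of positive reals",
         call. = FALSE)
  powers <- sort(powers)
  rmse <- vapply(powers, function(p) {
    pred <- vapply(seq_len(n), function(i)
      idw_predict(observations$x[-i], observations$y[-i],
                  observations$value[-i],
                  observations$x[i], observations$y[i], p), numeric(1))
    sqrt(mean((pred - observations$value)^2))
  }, numeric(1))
  list(power = powers[which.min(rmse)],
       loo = data.frame(power = powers, rmse = rmse))
}

#' Aggregate daily fields to weekly national means
#'
#' Computes each day's spatial mean and averages the days of each epi-week.
#' Every day of every covered epi-week must be present; weeks with missing
#' days raise an error naming the missing dates rather than silently
#' imputing.
#'
#' @param daily Either a list of `gridded_field`s carrying `date`s, or a
#'   data frame with `date` (a `Date`) and `value` (the daily spatial
#'   mean).
#' @param calendar An [epiweek_calendar()] data frame; weeks without any
#'   overlap with `daily` are dropped.
#' @return Data frame `year`, `epiweek`, `value` (weekly mean of daily
#'   spatial means).
#' @export
aggregate_weekly <- function(daily, calendar) {
  if (is.list(daily) && !is.data.frame(daily)) {
    daily <- data.frame(
      date = as.Date(vapply(daily, function(f) as.character(f$date),
                            character(1))),
      value = vapply(daily, field_mean, numeric(1)))
  }
  daily$date <- as.Date(daily$date)
  out <- NULL
  for (i in seq_len(nrow(calendar))) {
    days <- calendar$start_date[i] + 0:6
    present <- days %in% daily$date
    if (!any(present)) next
    if (!all(present))
      stop(sprintf("epi-week %d of %d is missing day(s): %s",
                   calendar$epiweek[i], calendar$year[i],
                   paste(format(days[!present]), collapse = ", ")),
           call. = FALSE)
    out <- rbind(out, data.frame(
      year = calendar$year[i], epiweek = calendar$epiweek[i],
      value = mean(daily$value[match(days, daily$date)])))
  }
  if (is.null(out))
    stop("no calendar week overlaps the supplied daily values",
         call. = FALSE)
  out
}
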