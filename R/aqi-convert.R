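# Zone-level AQI averaging and conversion of AQI index values to pollutant
# concentration units by piecewise-linear breakpoint inversion.

the_aqi_cache <- new.env(parent = emptyenv())

# Frozen checksum of the numeric content of the packaged breakpoint table,
# guarding against accidental edits of the asset.
AQI_BREAKPOINT_CHECKSUM <- 18115.8

#' EPA AQI breakpoint table
#'
#' The piecewise-linear AQI breakpoint bands for PM10 (ug/m3, 24-hr), SO2
#' (ppb, 1-hr) and CO (ppm, 8-hr), transcribed once from the US EPA
#' technical assistance documentation on AQI reporting and shipped as a
#' packaged CSV asset.  Each band maps an AQI interval
#' `[aqi_low, aqi_high]` to a concentration interval
#' `[conc_low, conc_high]`.
#'
#' @return Data frame with columns `pollutant`, `aqi_low`, `aqi_high`,
#'   `conc_low`, `conc_high`, `units`.
#' @export
aqi_breakpoints <- function() {
  if (is.null(the_aqi_cache$table)) {
    path <- system.file("extdata", "aqi_breakpoints.csv",
                        package = "edattrib", mustWork = TRUE)
    tab <- read.csv(path, stringsAsFactors = FALSE)
    chk <- sum(tab$aqi_low + tab$aqi_high + tab$conc_low + tab$conc_high)
    if (abs(chk - AQI_BREAKPOINT_CHECKSUM) > 1e-6)
      stop("packaged AQI breakpoint table failed its checksum",
           call. = FALSE)
    the_aqi_cache$table <- tab
  }
  the_aqi_cache$table
}

# Knot representation of one pollutant's bands: both edges of every band
# become knots, so interpolation is exact at every printed breakpoint and
# strictly increasing across the small integer gaps between bands.
breakpoint_knots <- function(pollutant, table = aqi_breakpoints()) {
  bands <- table[table$pollutant == pollutant, , drop = FALSE]
  if (nrow(bands) == 0L)
    stop(sprintf("no breakpoint bands for pollutant '%s'", pollutant),
         call. = FALSE)
  bands <- bands[order(bands$aqi_low), , drop = FALSE]
  aqi <- as.numeric(rbind(bands$aqi_low, bands$aqi_high))
  conc <- as.numeric(rbind(bands$conc_low, bands$conc_high))
  keep <- !duplicated(aqi)
  list(aqi = aqi[keep], conc = conc[keep], bands = bands)
}

#' Convert AQI index values to concentration units
#'
#' Locates the breakpoint band containing each AQI value and linearly
#' inverts the band:
#' `conc_low + (aqi - aqi_low) / (aqi_high - aqi_low) * (conc_high - conc_low)`.
#' The conversion is exact at every band edge and strictly increasing over
#' the covered AQI range.  Values above the top band are an error
#' (out-of-range is reported, never silently clamped).
#'
#' @param aqi Non-negative AQI values.
#' @param pollutant One of `"pm10_ugm3"`, `"so2_ppb"`, `"co_ppm"`.
#' @param table Breakpoint table (default the packaged asset).
#' @return Concentrations in the pollutant's units (ug/m3, ppb or ppm).
#' @examples
#' aqi_to_concentration(50, "pm10_ugm3")  # top of the "Good" band: 54
#' @export
aqi_to_concentration <- function(aqi, pollutant, table = aqi_breakpoints()) {
  k <- breakpoint_knots(pollutant, table)
  if (any(!is.finite(aqi)) || any(aqi < 0))
    stop("AQI values must be finite and non-negative", call. = FALSE)
  if (any(aqi > max(k$aqi)))
    stop(sprintf("AQI value above the top %s band (max %g)", pollutant,
                 max(k$aqi)), call. = FALSE)
  approx(k$aqi, k$conc, xout = aqi, method = "linear", ties = "ordered")$y
}

#' Convert concentrations to AQI index values (forward EPA formula)
#'
#' The forward piecewise-linear map; within every band it is the exact
#' inverse of [aqi_to_concentration()].
#'
#' @param conc Concentrations in the pollutant's units.
#' @inheritParams aqi_to_concentration
#' @return AQI index values.
#' @export
concentration_to_aqi <- function(conc, pollutant,
                                 table = aqi_breakpoints()) {
  k <- breakpoint_knots(pollutant, table)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and non-negative", call. = FALSE)
  if (any(conc > max(k$conc)))
    stop(sprintf("concentration above the top %s band (max %g)", pollutant,
                 max(k$conc)), call. = FALSE)
  approx(k$conc, k$aqi, xout = conc, method = "linear", ties = "ordered")$y
}

#' Average zone-level AQI series to a national series
#'
#' The national daily value is the arithmetic mean of the zones reporting
#' on that date; the number of zones used is recorded alongside.  Dates in
#' `dates` with no reporting zone are an error.
#'
#' @param zone_series Data frame with columns `zone`, `date`, `pollutant`,
#'   `aqi` (one pollutant, or several -- averaging is per
#'   date-and-pollutant).
#' @param dates Optional vector of dates that must all be covered.
#' @return Data frame `date`, `pollutant`, `aqi` (national mean),
#'   `n_zones`.
#' @export
average_zones <- function(zone_series, dates = NULL) {
  if (nrow(zone_series) == 0L)
    stop("empty zone series", call. = FALSE)
  if (any(zone_series$aqi < 0))
    stop("AQI values must be non-negative", call. = FALSE)
  if (!is.null(dates)) {
    missing <- setdiff(as.character(dates),
                       as.character(unique(zone_series$date)))
    if (length(missing))
      stop(sprintf("no zone reports AQI on date(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
  }
  agg <- aggregate(aqi ~ date + pollutant, data = zone_series, FUN = mean)
  cnt <- aggregate(aqi ~ date + pollutant, data = zone_series, FUN = length)
  agg$n_zones <- cnt$aqi[match(paste(agg$date, agg$pollutant),
                               paste(cnt$date, cnt$pollutant))]
  agg[order(agg$pollutant, agg$date), c("date", "pollutant", "aqi",
                                        "n_zones")]
}

#' National pollutant concentrations from zone AQI series
#'
#' Convenience composition following the study sequence: average the zone
#' AQI values to a national daily series first, then convert the national
#' mean to concentration units.  `convert_first = TRUE` applies the
#' (nonlinear) conversion per zone before averaging, as a sensitivity
#' variant.
#'
#' @inheritParams average_zones
#' @param convert_first Convert each zone's AQI before averaging.
#' @return Data frame `date`, `pollutant`, `concentration`, `n_zones`.
#' @export
zones_to_concentration <- function(zone_series, dates = NULL,
                                   convert_first = FALSE) {
  if (convert_first) {
    zs <- zone_series
    for (p in unique(zs$pollutant)) {
      sel <- zs$pollutant == p
      zs$aqi[sel] <- aqi_to_concentration(zs$aqi[sel], p)
    }
    nat <- average_zones(zs, dates)
    names(nat)[names(nat) == "aqi"] <- "concentration"
    return(nat)
  }
  nat <- average_zones(zone_series, dates)
  nat$concentration <- NA_real_
  for (p in unique(nat$pollutant)) {
    sel <- nat$pollutant == p
    nat$concentration[sel] <- aqi_to_concentration(nat$aqi[sel], p)
  }
  nat[, c("date", "pollutant", "concentration", "n_zones")]
}
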