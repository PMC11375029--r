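# Plain-text serialization: RFC-4180 CSVs for the synthetic dataset and
# design, YAML for truth models and configuration.

#' Write a synthetic dataset to a directory
#'
#' Writes `exposures.csv` (week_index, year, epiweek, six exposure
#' columns), `admissions.csv` (week_index, category, count; all categories
#' stacked), `truth.yaml` (the serialized truth models) and, when station
#' records are supplied, `stations.csv`.
#'
#' @param exposures Weekly exposure table.
#' @param admissions Data frame or list of data frames of weekly counts.
#' @param truths Named list of [truth_model()]s (optional).
#' @param stations Station daily records (optional).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_dataset <- function(exposures, admissions, truths = NULL,
                                    stations = NULL, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(exposures, file.path(dir, "exposures.csv"), row.names = FALSE)
  if (is.list(admissions) && !is.data.frame(admissions))
    admissions <- do.call(rbind, admissions)
  write.csv(admissions, file.path(dir, "admissions.csv"),
            row.names = FALSE)
  if (!is.null(truths))
    yaml::write_yaml(lapply(truths, serialize_truth),
                     file.path(dir, "truth.yaml"))
  if (!is.null(stations))
    write.csv(stations, file.path(dir, "stations.csv"), row.names = FALSE)
  invisible(dir)
}

serialize_truth <- function(truth) {
  stopifnot(inherits(truth, "truth_model"))
  list(beta0 = truth$beta0,
       effects = lapply(truth$effects, function(by_lag)
         lapply(by_lag, function(ef)
           c(list(type = ef$type, center = ef$center), ef$params))),
       ar = as.numeric(truth$ar),
       season_week_amp = truth$season_week_amp,
       trend_year_slope = truth$trend_year_slope,
       family = truth$family,
       theta = truth$theta)
}

deserialize_truth <- function(x) {
  effects <- lapply(x$effects, function(by_lag)
    lapply(by_lag, function(ef) {
      params <- ef[setdiff(names(ef), c("type", "center"))]
      new_truth_effect(ef$type, params, ef$center)
    }))
  truth_model(beta0 = x$beta0, effects = effects,
              ar = as.numeric(x$ar %||% numeric(0)),
              season_week_amp = x$season_week_amp %||% 0,
              trend_year_slope = x$trend_year_slope %||% 0,
              family = x$family %||% "poisson", theta = x$theta)
}

#' Read truth models from a YAML file
#' @param path Path written by [write_synthetic_dataset()].
#' @return Named list of `truth_model` objects.
#' @export
read_truth_yaml <- function(path) {
  lapply(yaml::read_yaml(path), deserialize_truth)
}

#' Serialize a lag design to CSV with a JSON role sidecar
#'
#' The usable rows go to `<path>.csv`; column roles (response, lag
#' structure, seasonal covariates) and the design parameters go to
#' `<path>.json`.
#'
#' @param design A [build_lag_design()] result.
#' @param path Output path stem (without extension).
#' @return `path`, invisibly.
#' @export
write_lag_design <- function(design, path) {
  stopifnot(inherits(design, "lag_design"))
  write.csv(design$data, paste0(path, ".csv"), row.names = FALSE)
  meta <- list(format_version = 1L,
               max_lag = design$max_lag,
               include_immediate = design$include_immediate,
               exposures = design$exposures,
               n_total = design$n_total,
               columns = list(response = "y",
                              ar = design_ar_terms(design),
                              exposure = design_exposure_terms(design),
                              seasonal = c("epiweek", "year")))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a lag design written by [write_lag_design()]
#' @param path Path stem used when writing.
#' @return A `lag_design` object.
#' @export
read_lag_design <- function(path) {
  dat <- read.csv(paste0(path, ".csv"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(data = dat, max_lag = as.integer(meta$max_lag),
                 include_immediate = isTRUE(meta$include_immediate),
                 exposures = meta$exposures,
                 n_total = as.integer(meta$n_total)),
            class = "lag_design")
}

#' Save / load a fitted model
#'
#' Single-file round-trip of an `ed_gam` model (coefficients, covariance,
#' smoothing parameters, design reference and a format-version stamp);
#' loading reproduces predictions exactly.
#'
#' @param model An `ed_gam` model.
#' @param path File path.
#' @return `path` invisibly (save); the model (load).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "ed_gam"))
  model$format_version <- 1L
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "ed_gam"))
    stop("file does not contain a fitted model archive", call. = FALSE)
  model
}
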