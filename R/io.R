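#' Read / write CAT curves as two-column CSV
#'
#' The interchange format for curves is a CSV with header
#' `time_min,thrombin_nM`.
#'
#' @param curve A [cat_curve()].
#' @param path File path.
#' @return `write_cat_curve` returns `path` invisibly; `read_cat_curve`
#'   returns a [cat_curve()].
#' @export
write_cat_curve <- function(curve, path) {
  stopifnot(inherits(curve, "cat_curve"))
  write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cat_curve
#' @export
read_cat_curve <- function(path) {
  df <- read.csv(path)
  if (!all(c("time_min", "thrombin_nM") %in% names(df)))
    stop("curve CSV must have columns time_min, thrombin_nM", call. = FALSE)
  cat_curve(df$time_min, df$thrombin_nM)
}

#' Read / write thrombin model parameters as flat JSON
#'
#' @param params A [thrombin_params()] object.
#' @param path File path; JSON object with keys `k0, k1, k2, kn, kd`.
#' @export
write_params <- function(params, path) {
  p <- .as_params(params)
  jsonlite::write_json(as.list(unclass(p)), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  do.call(thrombin_params, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Validate and read a factor-panel CSV
#'
#' Panels are rows of a CSV with the eight factor columns
#' `fii, fv, fvii, fviii, fix, fx, atiii, pc` (% activity). Missing columns,
#' non-numeric columns, and negative or non-finite values are rejected with
#' diagnostics naming the offending column and rows.
#'
#' @param path File path.
#' @return Data frame of panels (extra columns are preserved).
#' @export
validate_panel_file <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(FACTOR_NAMES, names(df))
  if (length(missing))
    stop("panel file is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (f in FACTOR_NAMES) {
    v <- df[[f]]
    if (!is.numeric(v))
      stop(sprintf("panel column '%s' is not numeric", f), call. = FALSE)
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad))
      stop(sprintf("panel column '%s' has negative or non-finite values in row(s) %s",
                   f, paste(bad, collapse = ", ")), call. = FALSE)
  }
  df
}

#' @rdname validate_panel_file
#' @export
read_panels <- validate_panel_file

#' Write a factor-panel table to CSV
#'
#' @param panels Data frame with the eight factor columns, or list of
#'   [factor_panel()] objects.
#' @param path File path.
#' @export
write_panels <- function(panels, path) {
  X <- as.data.frame(.panels_matrix(panels))
  write.csv(X, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a regression map as JSON
#'
#' @param map A `regression_map`.
#' @param path File path.
#' @export
write_regression_map <- function(map, path) {
  stopifnot(inherits(map, "regression_map"))
  obj <- list(n_samples = map$n_samples,
              terms = lapply(map$terms, function(tr) {
                list(factors = tr$factors,
                     intercept = tr$intercept,
                     coefficients = as.list(tr$coefficients))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_regression_map
#' @export
read_regression_map <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  terms <- lapply(obj$terms, function(tr) {
    factors <- as.character(unlist(tr$factors))
    coefs <- setNames(as.numeric(unlist(tr$coefficients)), factors)
    list(factors = factors, intercept = as.numeric(tr$intercept),
         coefficients = coefs, trace = data.frame())
  })
  structure(list(terms = terms[PARAM_NAMES],
                 n_samples = if (is.null(obj$n_samples)) NA_integer_
                             else obj$n_samples),
            class = "regression_map")
}

#' Read / write a normal region as JSON
#'
#' @param region A `normal_region`.
#' @param path File path.
#' @export
write_normal_region <- function(region, path) {
  stopifnot(inherits(region, "normal_region"))
  obj <- list(times = region$times, lower = region$lower,
              upper = region$upper, mean = region$mean,
              goal_params = if (!is.null(region$goal_params))
                as.list(unclass(region$goal_params)) else NULL,
              metric_bands = region$metric_bands,
              n_curves = region$n_curves)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_normal_region
#' @export
read_normal_region <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(times = obj$times, lower = obj$lower, upper = obj$upper,
                 mean = obj$mean,
                 goal_params = if (!is.null(obj$goal_params))
                   do.call(thrombin_params, as.list(obj$goal_params))
                   else NULL,
                 metric_bands = as.data.frame(obj$metric_bands),
                 n_curves = obj$n_curves),
            class = "normal_region")
}

#' Write a GCM recommendation (with its step log) as JSON
#'
#' @param rec A `gcm_recommendation`.
#' @param path File path.
#' @export
write_recommendation <- function(rec, path) {
  stopifnot(inherits(rec, "gcm_recommendation"))
  obj <- list(input_panel = as.list(rec$input_panel),
              recommended_panel = as.list(rec$panel),
              steps = rec$steps,
              mre_initial = rec$mre_initial,
              mre_final = rec$mre_final,
              anticoagulant = rec$anticoagulant)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a cohort table to CSV
#'
#' @param cohort Long-format cohort data frame
#'   (`patient_id, outcome, time_h`, eight factor columns).
#' @param path File path.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(all(c("patient_id", "outcome", "time_h", FACTOR_NAMES) %in%
                  names(cohort)))
  write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "outcome", "time_h", FACTOR_NAMES)
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("cohort CSV is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}

#' Write a small JSON run manifest next to pipeline outputs
#'
#' Records the inputs, seed and package version of a run; deliberately
#' timestamp-free so identical runs produce identical manifests.
#'
#' @param path File path.
#' @param inputs Named list or character vector of input descriptions.
#' @param seed Seed used by stochastic stages (or NULL).
#' @param extra Optional named list of additional fields.
#' @export
write_manifest <- function(path, inputs = list(), seed = NULL,
                           extra = list()) {
  obj <- c(list(package = "thrombodyn",
                version = as.character(utils::packageVersion("thrombodyn")),
                inputs = inputs, seed = seed), extra)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
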