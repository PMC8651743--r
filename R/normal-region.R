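#' Build the normal CAT region from healthy-donor curves
#'
#' Takes the pointwise minimum, maximum and mean of the healthy curves at
#' each time point. The mean curve is then fitted with [fit_model()] to give
#' `goal_params`, the target goal CAT used by the controller; `metric_bands`
#' records the min/max of peak, peak-time and ETP over the normal set.
#'
#' @param curves List of [cat_curve()]s on a common grid (or set
#'   `resample = TRUE` to linearly resample onto the first curve's grid).
#' @param tf Tissue-factor magnitude used when fitting the goal model.
#' @param resample Allow resampling of mismatched grids.
#' @param fit_goal Fit the goal model to the mean curve (default TRUE).
#' @return A list of class `normal_region` with `times`, `lower`, `upper`,
#'   `mean`, `goal_params`, `metric_bands`, `n_curves`.
#' @export
build_normal_region <- function(curves, tf = 5, resample = FALSE,
                                fit_goal = TRUE) {
  if (!length(curves)) stop("need at least one curve", call. = FALSE)
  stopifnot(all(vapply(curves, inherits, logical(1), "cat_curve")))
  times <- curves[[1]]$times
  Y <- vapply(curves, function(cv) {
    same <- length(cv$times) == length(times) &&
      max(abs(cv$times - times)) <= 1e-9 * max(times)
    if (same) return(cv$thrombin)
    if (!resample)
      stop("curves are on different time grids; set resample = TRUE",
           call. = FALSE)
    approx(cv$times, cv$thrombin, xout = times, rule = 2)$y
  }, numeric(length(times)))
  Y <- matrix(Y, nrow = length(times))
  lower <- apply(Y, 1, min)
  upper <- apply(Y, 1, max)
  mid <- rowMeans(Y)
  goal <- if (fit_goal) fit_model(cat_curve(times, mid), tf = tf)$params
          else NULL
  props <- c("peak", "peak_time", "etp")
  mets <- t(apply(Y, 2, function(y) {
    unclass(cat_metrics(cat_curve(times, y)))[props]
  }))
  bands <- data.frame(property = props,
                      min = apply(mets, 2, min),
                      max = apply(mets, 2, max),
                      row.names = NULL)
  structure(list(times = times, lower = lower, upper = upper, mean = mid,
                 goal_params = goal, metric_bands = bands,
                 n_curves = ncol(Y)),
            class = "normal_region")
}

#' @export
print.normal_region <- function(x, ...) {
  cat(sprintf("Normal CAT region from %d curves, t in [%g, %g] min\n",
              x$n_curves, x$times[1], x$times[length(x$times)]))
  print(x$metric_bands)
  invisible(x)
}

## Curve values on the region grid (linear resampling when needed).
.on_region_grid <- function(curve, region) {
  same <- length(curve$times) == length(region$times) &&
    max(abs(curve$times - region$times)) <= 1e-9 * max(region$times)
  if (same) curve$thrombin
  else approx(curve$times, curve$thrombin, xout = region$times, rule = 2)$y
}

#' Mean relative error of a CAT curve against the normal region
#'
#' At every time point where the curve lies outside the [lower, upper]
#' envelope, the relative excess is measured against the violated bound:
#' `(y - upper)/upper` above, `(lower - y)/lower` below, with an absolute
#' floor of `floor_nM` (1 nM) in the denominator when the violated bound is
#' near zero. Pre-onset points where the upper envelope is below
#' `min_upper` (1 nM) are excluded, since relative error is meaningless at
#' near-zero thrombin. The MRE is the mean over violating points, and 0 for
#' a curve that never leaves the region.
#'
#' @param curve A [cat_curve()].
#' @param region A [build_normal_region()] result.
#' @param floor_nM Denominator floor in nM.
#' @param min_upper Exclude time points with upper envelope below this (nM).
#' @return A non-negative scalar; 0 means the curve is inside the region.
#' @export
mre <- function(curve, region, floor_nM = 1, min_upper = 1) {
  stopifnot(inherits(region, "normal_region"))
  y <- .on_region_grid(curve, region)
  keep <- region$upper >= min_upper
  up <- region$upper[keep]
  lo <- region$lower[keep]
  yy <- y[keep]
  above <- yy > up
  below <- yy < lo
  if (!any(above) && !any(below)) return(0)
  rel <- numeric(length(yy))
  rel[above] <- (yy[above] - up[above]) / pmax(up[above], floor_nM)
  rel[below] <- (lo[below] - yy[below]) / pmax(lo[below], floor_nM)
  mean(rel[above | below])
}

#' Is a CAT curve inside the normal region?
#'
#' @inheritParams mre
#' @param tolerance Maximum admissible [mre()] (default 0: strictly inside).
#' @return Logical flag.
#' @export
in_region <- function(curve, region, tolerance = 0) {
  mre(curve, region) <= tolerance
}
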