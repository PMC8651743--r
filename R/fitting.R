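## Shape-based starting guess: dead time from the 2%-of-peak onset, pole
## scale a from the onset-to-peak time assuming the reference pole pattern
## (-a, -2a, -3a), whose impulse response peaks at 2/27/a^2 at t = ln(3)/a,
## and gain from the observed peak. Falls back to (6, 11, 6, 1, 1).
.init_from_curve <- function(curve, tf) {
  m <- cat_metrics(curve)
  tp <- m[["peak_time"]] - m[["time_delay"]]
  if (!is.finite(tp) || tp <= 0 || m[["peak"]] <= 0)
    return(thrombin_params(6, 11, 6, 1, 1))
  a <- log(3) / tp
  kn <- m[["peak"]] / (tf * (2 / 27) / a^2)
  thrombin_params(6 * a^3, 11 * a^2, 6 * a, max(kn, 1e-6),
                  min(max(m[["time_delay"]], 0), 20))
}

#' Fit the thrombin dynamics model to a measured CAT curve
#'
#' Estimates the five model parameters by minimizing the sum of squared
#' differences between the model curve and the data, using bounded
#' Levenberg-Marquardt least squares (trust-region family,
#' \code{minpack.lm::nls.lm}) with function tolerance `tol` (default 1e-9).
#' Bounds are positivity (1e-6) to 1e6 on `k0`, `k1`, `k2`, `kn` and
#' \eqn{[0, 20]} min on the dead time `kd`; the dead time is a continuous
#' shift because the model curve is evaluated analytically at `t - kd`.
#'
#' @param curve A [cat_curve()] with at least 20 samples.
#' @param tf Tissue-factor impulse magnitude (pM) used in the assay.
#' @param init Initial [thrombin_params()]; by default a shape-based guess
#'   (dead time from the curve onset, pole scale from the onset-to-peak
#'   time, gain from the peak).
#' @param tol Function/parameter tolerance passed to the optimizer.
#' @param max_iter Iteration cap (the optimizer's hard maximum is 1024).
#' @return A list of class `fit_result`: `params` (the fitted
#'   [thrombin_params()]), `residual_sse` (recomputed at the returned
#'   parameters), `converged` flag and `n_iterations`.
#' @examples
#' truth <- thrombin_params(6, 11, 6, 1, 1)
#' curve <- simulate_cat(truth, tf = 5, duration = 30)
#' fit <- fit_model(curve, tf = 5)
#' fit$params
#' @export
fit_model <- function(curve, tf = 5, init = NULL, tol = 1e-9,
                      max_iter = 1024) {
  stopifnot(inherits(curve, "cat_curve"))
  y <- curve$thrombin
  t <- curve$times
  if (length(y) < 20L)
    stop("fit_model needs a curve with at least 20 samples", call. = FALSE)
  if (all(y == 0))
    stop("cannot fit a degenerate all-zero CAT curve", call. = FALSE)
  if (is.null(init)) init <- .init_from_curve(curve, tf)
  init <- .as_params(init)
  upper <- PARAM_UPPER
  upper[["kd"]] <- min(upper[["kd"]], max(t) - diff(t)[1])
  start <- pmin(pmax(unclass(init), PARAM_LOWER), upper)
  fit <- minpack.lm::nls.lm(
    par = start, lower = PARAM_LOWER, upper = upper,
    fn = function(par) .model_thrombin(par, tf, t) - y,
    control = minpack.lm::nls.lm.control(
      ftol = tol, ptol = tol, maxiter = min(max_iter, 1024),
      maxfev = 100 * (length(start) + 1) * 10))
  params <- do.call(thrombin_params, as.list(fit$par))
  sse <- sum((.model_thrombin(params, tf, t) - y)^2)
  structure(list(params = params,
                 residual_sse = sse,
                 converged = fit$info %in% 1:4,
                 n_iterations = fit$niter,
                 message = fit$message),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Model fit (%s, %d iterations), SSE = %.6g\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations, x$residual_sse))
  print(x$params)
  invisible(x)
}

#' Multi-start wrapper around fit_model
#'
#' Runs [fit_model()] from the default (or supplied) initialization plus
#' `n_starts - 1` seeded random initializations drawn from the parameter
#' bound box (log-uniform for the positive parameters, uniform for the dead
#' time), and keeps the lowest-residual fit. Guards against local minima on
#' irregular trauma curves.
#'
#' @inheritParams fit_model
#' @param n_starts Total number of starts (>= 1).
#' @param seed Seed controlling the random initializations.
#' @return The best `fit_result`, with an extra element `n_starts`.
#' @export
fit_multistart <- function(curve, tf = 5, n_starts = 5, seed = 1,
                           init = NULL, tol = 1e-9, max_iter = 1024) {
  stopifnot(n_starts >= 1)
  best <- fit_model(curve, tf = tf, init = init, tol = tol,
                    max_iter = max_iter)
  if (n_starts > 1) {
    set.seed(seed)
    kd_hi <- min(PARAM_UPPER[["kd"]], max(curve$times) / 2)
    for (i in seq_len(n_starts - 1)) {
      st <- thrombin_params(10^runif(1, -6, 6), 10^runif(1, -6, 6),
                            10^runif(1, -6, 6), 10^runif(1, -6, 6),
                            runif(1, 0, kd_hi))
      f <- tryCatch(
        fit_model(curve, tf = tf, init = st, tol = tol, max_iter = max_iter),
        error = function(e) NULL)
      if (!is.null(f) && f$residual_sse < best$residual_sse) best <- f
    }
  }
  best$n_starts <- n_starts
  best
}
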