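#' Coagulation factor panel
#'
#' Concentrations of the eight modeled coagulation factors, in percent
#' activity relative to a healthy reference: factors II, V, VII, VIII, IX, X,
#' antithrombin (ATIII) and protein C. The normal band is 60-140% activity.
#'
#' @param fii,fv,fvii,fviii,fix,fx,atiii,pc Percent activity; non-negative
#'   and finite.
#' @return Named numeric vector of class `factor_panel`.
#' @export
factor_panel <- function(fii, fv, fvii, fviii, fix, fx, atiii, pc) {
  p <- c(fii = as.numeric(fii), fv = as.numeric(fv), fvii = as.numeric(fvii),
         fviii = as.numeric(fviii), fix = as.numeric(fix), fx = as.numeric(fx),
         atiii = as.numeric(atiii), pc = as.numeric(pc))
  if (any(!is.finite(p)) || any(p < 0))
    stop("factor concentrations must be finite and non-negative",
         call. = FALSE)
  structure(p, class = "factor_panel")
}

.as_panel <- function(x) {
  if (inherits(x, "factor_panel")) return(unclass(x))
  x <- unlist(x)
  if (!all(FACTOR_NAMES %in% names(x)))
    stop("panel must contain the eight factors: ",
         paste(FACTOR_NAMES, collapse = ", "), call. = FALSE)
  unclass(do.call(factor_panel, as.list(x[FACTOR_NAMES])))
}

## n x 8 matrix from a data frame, matrix, or list of panels.
.panels_matrix <- function(panels) {
  if (is.data.frame(panels) || is.matrix(panels)) {
    if (!all(FACTOR_NAMES %in% colnames(panels)))
      stop("panel table must have columns ",
           paste(FACTOR_NAMES, collapse = ", "), call. = FALSE)
    X <- as.matrix(as.data.frame(panels)[, FACTOR_NAMES])
  } else {
    X <- do.call(rbind, lapply(panels, .as_panel))
  }
  storage.mode(X) <- "double"
  X
}

## n x 5 matrix from a data frame, matrix, or list of thrombin_params.
.params_matrix <- function(params) {
  if (is.data.frame(params) || is.matrix(params)) {
    if (!all(PARAM_NAMES %in% colnames(params)))
      stop("parameter table must have columns ",
           paste(PARAM_NAMES, collapse = ", "), call. = FALSE)
    P <- as.matrix(as.data.frame(params)[, PARAM_NAMES])
  } else {
    P <- do.call(rbind, lapply(params, function(p) unclass(.as_params(p))))
  }
  storage.mode(P) <- "double"
  P
}

#' Greedy stepwise regression from factor panels to model parameters
#'
#' For each of the five thrombin model parameters independently, sequentially
#' adds the coagulation factor whose linear effect most reduces the residual
#' sum of squares of a least-squares fit, refitting all coefficients at each
#' step. A factor is kept only while the adjusted R-squared increases;
#' selection also stops when all eight factors are in the model. The first
#' factor selected for a parameter is therefore the single best univariate
#' regressor, and training SSE is non-increasing along each parameter's
#' selection path.
#'
#' @param panels Factor panels: a data frame/matrix with the eight factor
#'   columns, or a list of [factor_panel()] objects.
#' @param params Matching model parameters: data frame/matrix with columns
#'   `k0, k1, k2, kn, kd`, or a list of [thrombin_params()].
#' @return A list of class `regression_map` whose `terms` element holds, per
#'   parameter, the ordered selected factors, intercept, coefficients, and a
#'   per-step trace (`step`, `factor`, `sse`, `adj_r2`).
#' @export
fit_stepwise <- function(panels, params) {
  X <- .panels_matrix(panels)
  P <- .params_matrix(params)
  n <- nrow(X)
  if (n < 10L)
    stop("stepwise regression needs at least 10 paired samples", call. = FALSE)
  if (nrow(P) != n)
    stop("panels and params must have the same number of rows", call. = FALSE)
  terms <- setNames(vector("list", length(PARAM_NAMES)), PARAM_NAMES)
  for (j in PARAM_NAMES) {
    y <- P[, j]
    tss <- sum((y - mean(y))^2)
    selected <- character(0)
    trace <- list()
    adj_cur <- 0
    if (tss > 0) {
      repeat {
        remaining <- setdiff(FACTOR_NAMES, selected)
        p_new <- length(selected) + 1L
        if (!length(remaining) || n < p_new + 2L) break
        sses <- vapply(remaining, function(f) {
          fit <- lm.fit(cbind(1, X[, c(selected, f), drop = FALSE]), y)
          sum(fit$residuals^2)
        }, numeric(1))
        fbest <- remaining[which.min(sses)]
        sse_new <- min(sses)
        adj_new <- 1 - (sse_new / (n - p_new - 1)) / (tss / (n - 1))
        if (!is.finite(adj_new) || adj_new <= adj_cur + 1e-12) break
        selected <- c(selected, fbest)
        adj_cur <- adj_new
        trace[[p_new]] <- data.frame(step = p_new, factor = fbest,
                                     sse = sse_new, adj_r2 = adj_new)
      }
    }
    if (length(selected)) {
      cf <- lm.fit(cbind(1, X[, selected, drop = FALSE]), y)$coefficients
      intercept <- unname(cf[1])
      coefs <- setNames(unname(cf[-1]), selected)
    } else {
      intercept <- mean(y)
      coefs <- setNames(numeric(0), character(0))
    }
    terms[[j]] <- list(factors = selected, intercept = intercept,
                       coefficients = coefs,
                       trace = if (length(trace)) do.call(rbind, trace)
                               else data.frame(step = integer(), factor = character(),
                                               sse = numeric(), adj_r2 = numeric()))
  }
  structure(list(terms = terms, n_samples = n), class = "regression_map")
}

#' @export
print.regression_map <- function(x, ...) {
  cat(sprintf("Factor-to-parameter regression map (n = %s):\n",
              x$n_samples))
  for (j in names(x$terms)) {
    tr <- x$terms[[j]]
    cat(sprintf("  %-3s ~ %s\n", j,
                if (length(tr$factors)) paste(tr$factors, collapse = " + ")
                else "(intercept only)"))
  }
  invisible(x)
}

#' Predict model parameters from a factor panel
#'
#' Evaluates the per-parameter linear maps of a [fit_stepwise()] model and
#' projects the result into the valid parameter box (positivity, dead time
#' in \eqn{[0, 20]} min), since an unconstrained linear map can emit invalid
#' dynamics for extreme panels.
#'
#' @param map A `regression_map`.
#' @param panel A single panel: [factor_panel()], named vector, or one-row
#'   data frame with the eight factor columns.
#' @return A [thrombin_params()] object.
#' @export
predict_params <- function(map, panel) {
  stopifnot(inherits(map, "regression_map"))
  p <- .as_panel(panel)
  vals <- vapply(PARAM_NAMES, function(j) {
    tr <- map$terms[[j]]
    tr$intercept + sum(tr$coefficients * p[tr$factors])
  }, numeric(1))
  vals <- pmin(pmax(vals, PARAM_LOWER), PARAM_UPPER)
  do.call(thrombin_params, as.list(vals))
}

#' Predict a CAT curve from a factor panel
#'
#' Composition of [predict_params()] and [simulate_cat()]: the rapid
#' replacement for the 45-60 min CAT assay once the map is trained.
#'
#' @inheritParams predict_params
#' @inheritParams simulate_cat
#' @return A [cat_curve()].
#' @export
predict_cat <- function(map, panel, tf = 5, duration = 60, dt = 1 / 3) {
  simulate_cat(predict_params(map, panel), tf = tf, duration = duration,
               dt = dt)
}

#' Percent error of a modeled CAT property
#'
#' `|model - experiment| / experiment * 100`, the property-wise error used
#' to score predicted peak, peak-time and thrombin potential against values
#' from fits of experimental data.
#'
#' @param model_value,experiment_value Numeric (vectorized); the reference
#'   `experiment_value` must be nonzero.
#' @return Percent error(s), >= 0.
#' @export
percent_error <- function(model_value, experiment_value) {
  if (any(experiment_value == 0))
    stop("percent error is undefined for a zero reference value",
         call. = FALSE)
  abs((model_value - experiment_value) / experiment_value) * 100
}

#' K-fold cross-validation of the panel-to-CAT pipeline
#'
#' Randomly partitions the samples into `k` near-equal folds (sizes differ by
#' at most 1), trains [fit_stepwise()] on each training split, predicts the
#' held-out CAT curves, and scores the percent error of peak, peak-time and
#' ETP against the metrics of curves simulated from each held-out sample's
#' own fitted parameters.
#'
#' @inheritParams fit_stepwise
#' @param curves Optional list of [cat_curve()]s, fitted per sample with
#'   [fit_model()] when `params` is not supplied.
#' @param k Number of folds (>= 2, <= number of samples).
#' @param seed Seed for the fold assignment.
#' @param params Optional precomputed per-sample fitted parameters (same
#'   formats as in [fit_stepwise()]); skips the per-curve fits.
#' @param tf,duration,dt Simulation settings for prediction and reference
#'   curves.
#' @return A list of class `cv_report`: `summary` (per property: mean and SD
#'   of percent error over held-out samples), `per_sample`, `folds`, `k`,
#'   `seed`.
#' @export
cross_validate <- function(panels, curves = NULL, k = 5, seed = 1,
                           params = NULL, tf = 5, duration = 60, dt = 1 / 3) {
  X <- .panels_matrix(panels)
  n <- nrow(X)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("cannot make more folds than samples", call. = FALSE)
  if (is.null(params)) {
    if (is.null(curves))
      stop("supply either curves (to fit) or precomputed params",
           call. = FALSE)
    params <- lapply(curves, function(cv) fit_model(cv, tf = tf)$params)
  }
  P <- .params_matrix(params)
  if (nrow(P) != n)
    stop("panels and params/curves must match in length", call. = FALSE)
  props <- c("peak", "peak_time", "etp")
  ref <- t(vapply(seq_len(n), function(i) {
    pr <- do.call(thrombin_params, as.list(P[i, ]))
    m <- cat_metrics(simulate_cat(pr, tf = tf, duration = duration, dt = dt),
                     params = pr)
    unclass(m)[props]
  }, numeric(3)))
  set.seed(seed)
  folds <- sample(rep(seq_len(k), length.out = n))
  per <- matrix(NA_real_, n, 3, dimnames = list(NULL, props))
  for (f in seq_len(k)) {
    test <- which(folds == f)
    train <- which(folds != f)
    m <- fit_stepwise(X[train, , drop = FALSE], P[train, , drop = FALSE])
    for (i in test) {
      pp <- predict_params(m, X[i, ])
      mm <- cat_metrics(simulate_cat(pp, tf = tf, duration = duration,
                                     dt = dt), params = pp)
      per[i, ] <- percent_error(unclass(mm)[props], ref[i, ])
    }
  }
  summary <- data.frame(property = props,
                        mean_pct_error = colMeans(per),
                        sd_pct_error = apply(per, 2, sd),
                        row.names = NULL)
  structure(list(summary = summary, per_sample = as.data.frame(per),
                 folds = folds, k = k, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (seed %d):\n", x$k, x$seed))
  print(x$summary)
  invisible(x)
}
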