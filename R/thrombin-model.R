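#' Patient-specific thrombin dynamics parameters
#'
#' The five parameters of the delayed third-order transfer function
#' \deqn{Y(s)/U(s) = k_n e^{-k_d s} / (s^3 + k_2 s^2 + k_1 s + k_0),}
#' where the input \eqn{U} is a tissue-factor impulse (pM) and the output
#' \eqn{Y} is the thrombin concentration time-history (nM). `k0` (1/min^3),
#' `k1` (1/min^2) and `k2` (1/min) set the characteristic cubic and hence the
#' system poles; `kn` is the gain absorbing the pM-to-nM unit conversion;
#' `kd` is the dead time (min) between the impulse and thrombin onset.
#'
#' @param k0,k1,k2 Coefficients of the characteristic cubic; positive.
#' @param kn Gain; positive.
#' @param kd Dead time in minutes; non-negative, at most 20.
#' @return A named numeric vector of class `thrombin_params`.
#' @examples
#' p <- thrombin_params(k0 = 6, k1 = 11, k2 = 6, kn = 1, kd = 1)
#' compute_poles(p)
#' @export
thrombin_params <- function(k0, k1, k2, kn, kd) {
  p <- c(k0 = as.numeric(k0), k1 = as.numeric(k1), k2 = as.numeric(k2),
         kn = as.numeric(kn), kd = as.numeric(kd))
  if (any(!is.finite(p)))
    stop("thrombin model parameters must all be finite", call. = FALSE)
  if (any(p[c("k0", "k1", "k2", "kn")] <= 0))
    stop("k0, k1, k2 and kn must be strictly positive", call. = FALSE)
  if (p[["kd"]] < 0)
    stop("dead time kd must be non-negative", call. = FALSE)
  structure(p, class = "thrombin_params")
}

#' @export
print.thrombin_params <- function(x, ...) {
  cat("Thrombin dynamics parameters:\n")
  print(round(unclass(x), 6))
  invisible(x)
}

.as_params <- function(x) {
  if (inherits(x, "thrombin_params")) return(x)
  x <- unlist(x)
  if (is.null(names(x)) && length(x) == 5L) names(x) <- PARAM_NAMES
  do.call(thrombin_params, as.list(x[PARAM_NAMES]))
}

#' Sampled thrombin generation (CAT) curve
#'
#' A thrombin concentration time-history on a uniform grid starting at 0,
#' as produced by the CAT assay (one reading every 20 s by default) or by
#' [simulate_cat()]. Small negative values arising from floating-point
#' undershoot are clipped to zero; thrombin concentration is physically
#' non-negative.
#'
#' @param times Time grid in minutes; uniform, starting at 0.
#' @param thrombin Thrombin concentrations in nM, same length as `times`.
#' @return A list of class `cat_curve` with elements `times` and `thrombin`.
#' @export
cat_curve <- function(times, thrombin) {
  times <- as.numeric(times)
  thrombin <- as.numeric(thrombin)
  if (length(times) < 2L || length(times) != length(thrombin))
    stop("times and thrombin must be equal-length vectors (>= 2 points)",
         call. = FALSE)
  if (any(!is.finite(times)) || any(!is.finite(thrombin)))
    stop("CAT curve values must be finite", call. = FALSE)
  dts <- diff(times)
  if (any(dts <= 0))
    stop("times must be strictly increasing", call. = FALSE)
  if (max(dts) - min(dts) > 1e-9 * max(dts))
    stop("times must be a uniform grid (relative tolerance 1e-9)",
         call. = FALSE)
  thrombin[thrombin < 0] <- 0
  structure(list(times = times, thrombin = thrombin), class = "cat_curve")
}

#' @export
print.cat_curve <- function(x, ...) {
  cat(sprintf("CAT curve: %d points, t in [%g, %g] min, peak %.2f nM\n",
              length(x$times), x$times[1], x$times[length(x$times)],
              max(x$thrombin)))
  invisible(x)
}

#' @export
as.data.frame.cat_curve <- function(x, ...) {
  data.frame(time_min = x$times, thrombin_nM = x$thrombin)
}

## Roots of s^3 + k2 s^2 + k1 s + k0, sorted by real then imaginary part,
## with numerically real roots zapped to the real axis and complex roots
## symmetrized into an exact conjugate pair.
.char_roots <- function(k0, k1, k2) {
  r <- polyroot(c(k0, k1, k2, 1))
  tol <- 1e-8 * max(1, abs(r))
  real_ix <- abs(Im(r)) < tol
  r[real_ix] <- complex(real = Re(r[real_ix]), imaginary = 0)
  cx <- which(!real_ix)
  if (length(cx) == 2L) {
    z <- (r[cx[1]] + Conj(r[cx[2]])) / 2
    r[cx] <- c(z, Conj(z))
  }
  r[order(Re(r), Im(r))]
}

#' Poles of the thrombin transfer function
#'
#' Solves the characteristic equation s^3 + k2 s^2 + k1 s + k0 = 0. The three
#' poles determine the stability and speed of the coagulation response; pole
#' movement under tissue-factor titration or factor spiking is a compact
#' summary of how an intervention reshapes clotting dynamics.
#'
#' @param params A [thrombin_params()] object.
#' @return Complex vector of length 3, sorted by real part then imaginary
#'   part; complex poles appear as conjugate pairs.
#' @export
compute_poles <- function(params) {
  p <- .as_params(params)
  .char_roots(p[["k0"]], p[["k1"]], p[["k2"]])
}

## Impulse response g(t) of 1/(s^3 + k2 s^2 + k1 s + k0) for t >= 0.
## Distinct roots: partial fractions g(t) = sum_i e^{p_i t} / prod_{j!=i}(p_i - p_j).
## Roots coinciding within tolerance use the confluent (repeated-root) forms.
.impulse_response <- function(k0, k1, k2, t) {
  p <- .char_roots(k0, k1, k2)
  sep <- c(abs(p[1] - p[2]), abs(p[1] - p[3]), abs(p[2] - p[3]))
  ## a numerically double root is only resolved to ~sqrt(eps) by polyroot;
  ## switch to the confluent forms well before the residues blow up
  tol <- 1e-6 * max(1, abs(p))
  if (min(sep) > tol) {
    res <- vapply(1:3, function(i) 1 / prod(p[i] - p[-i]), complex(1))
    return(as.vector(Re(exp(outer(t, p)) %*% res)))
  }
  if (max(sep) <= tol) {
    ## triple root
    pr <- mean(Re(p))
    return(t^2 / 2 * exp(pr * t))
  }
  ## one double root p1 (the closest pair) and one simple root p2
  pair <- which.min(sep)
  idx <- list(c(1, 2), c(1, 3), c(2, 3))[[pair]]
  p1 <- mean(Re(p[idx]))
  p2 <- Re(p[-idx])
  d <- p1 - p2
  ## 1/((s-p1)^2 (s-p2)) = A/(s-p1) + B/(s-p1)^2 + C/(s-p2)
  A <- -1 / d^2
  B <- 1 / d
  C <- 1 / d^2
  (A + B * t) * exp(p1 * t) + C * exp(p2 * t)
}

## Model thrombin values at arbitrary times (no clipping of the grid rules);
## used by the simulator and by the least-squares objective.
.model_thrombin <- function(par, tf, times) {
  ts <- times - par[["kd"]]
  y <- numeric(length(times))
  act <- ts > 0
  if (any(act))
    y[act] <- tf * par[["kn"]] *
      .impulse_response(par[["k0"]], par[["k1"]], par[["k2"]], ts[act])
  y[y < 0] <- 0
  y
}

#' Simulate a CAT curve from the thrombin dynamics model
#'
#' Evaluates the response of the delayed third-order model to a tissue-factor
#' impulse of the given magnitude. The impulse is realized analytically:
#' the impulse response of the rational part is computed by partial fractions
#' (with confluent formulas when poles coincide within 1e-8) and shifted by
#' the dead time, so no discretization of the Dirac input is involved.
#' `method = "ode"` instead integrates the equivalent state-space system
#' numerically with \pkg{deSolve}; it exists as an independent cross-check
#' of the analytic path.
#'
#' @param params A [thrombin_params()] object.
#' @param tf Tissue-factor impulse magnitude in pM (default 5, the standard
#'   CAT trigger).
#' @param duration Simulation length in minutes; must exceed the dead time.
#' @param dt Grid spacing in minutes; default 1/3 min = 20 s, the CAT
#'   instrument's sampling interval.
#' @param method `"analytic"` (default) or `"ode"`.
#' @return A [cat_curve()] on the grid `seq(0, duration, by = dt)`.
#' @examples
#' p <- thrombin_params(0.162, 0.99, 1.8, 72.9, 3)
#' curve <- simulate_cat(p)
#' cat_metrics(curve, p)
#' @export
simulate_cat <- function(params, tf = 5, duration = 60, dt = 1 / 3,
                         method = c("analytic", "ode")) {
  method <- match.arg(method)
  p <- .as_params(params)
  if (!is.finite(tf) || tf <= 0)
    stop("tf impulse magnitude must be a positive number", call. = FALSE)
  if (!is.finite(dt) || dt <= 0 || dt >= duration)
    stop("need 0 < dt < duration", call. = FALSE)
  if (duration <= p[["kd"]])
    stop("duration must exceed the dead time kd", call. = FALSE)
  times <- seq(0, duration, by = dt)
  if (method == "analytic") {
    y <- .model_thrombin(p, tf, times)
  } else {
    y <- .ode_thrombin(p, tf, times)
  }
  cat_curve(times, y)
}

## Numerical integration of x' = A x from x(0) = (0, 0, 1), y = kn * tf * x1,
## in companion form; the impulse enters as the initial condition.
.ode_thrombin <- function(p, tf, times) {
  ts <- times - p[["kd"]]
  act <- ts > 0
  y <- numeric(length(times))
  if (!any(act)) return(y)
  A <- rbind(c(0, 1, 0),
             c(0, 0, 1),
             c(-p[["k0"]], -p[["k1"]], -p[["k2"]]))
  tt <- c(0, ts[act])
  sol <- deSolve::ode(y = c(0, 0, 1), times = tt,
                      func = function(t, x, parms) list(as.vector(A %*% x)),
                      parms = NULL, rtol = 1e-10, atol = 1e-12)
  g <- sol[-1, 2]
  out <- tf * p[["kn"]] * g
  out[out < 0] <- 0
  y[act] <- out
  y
}

#' Derived properties of a CAT curve
#'
#' Computes the standard thrombin-generation readouts: `peak` (maximum
#' thrombin, nM), `peak_time` (time of the maximum, first occurrence on
#' ties, min), `time_delay` (onset delay, min), `etp` (endogenous thrombin
#' potential: trapezoidal area under the whole curve, nM min) and `s_tail`
#' (post-peak area, nM min), the tail measure used to choose between the
#' protein C and ATIII interventions.
#'
#' When `params` is supplied the time delay is the model dead time `kd`;
#' otherwise it is the first time the curve reaches `onset_frac` (default 2%)
#' of its peak.
#'
#' @param curve A [cat_curve()].
#' @param params Optional [thrombin_params()] the curve was generated from.
#' @param onset_frac Onset threshold as a fraction of peak, used only when
#'   `params` is absent.
#' @return Named numeric vector of class `cat_metrics` with elements
#'   `peak`, `peak_time`, `time_delay`, `etp`, `s_tail`.
#' @export
cat_metrics <- function(curve, params = NULL, onset_frac = 0.02) {
  stopifnot(inherits(curve, "cat_curve"))
  t <- curve$times
  y <- curve$thrombin
  peak <- max(y)
  if (peak <= 0) {
    m <- c(peak = 0, peak_time = 0, time_delay = 0, etp = 0, s_tail = 0)
    return(structure(m, class = "cat_metrics"))
  }
  ip <- which.max(y)
  peak_time <- t[ip]
  etp <- pracma::trapz(t, y)
  s_tail <- if (ip < length(t)) pracma::trapz(t[ip:length(t)], y[ip:length(t)]) else 0
  time_delay <- if (!is.null(params)) {
    .as_params(params)[["kd"]]
  } else {
    t[which(y >= onset_frac * peak)[1]]
  }
  m <- c(peak = peak, peak_time = peak_time, time_delay = time_delay,
         etp = etp, s_tail = s_tail)
  structure(m, class = "cat_metrics")
}

#' @export
print.cat_metrics <- function(x, ...) {
  cat("CAT metrics:\n")
  print(round(unclass(x), 4))
  invisible(x)
}
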