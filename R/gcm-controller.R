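#' Configuration for the GCM controller
#'
#' Central place for the controller's tunables: the normal concentration
#' band, simulation grid, probe count for the patient-specific effect
#' polynomials, the relative property tolerance below which a correction
#' step makes no change, and the per-step MRE guard.
#'
#' @param band Normal factor-concentration band, % activity.
#' @param tf Tissue-factor impulse magnitude, pM.
#' @param duration,dt Simulation grid, minutes.
#' @param n_probes Probe points per factor/property effect fit.
#' @param property_tol Relative tolerance on a CAT property: when the gap to
#'   the goal value is within this fraction, the step is skipped. Makes the
#'   controller idempotent on already-corrected panels.
#' @param guard_mre If TRUE (default), each tuning step keeps whichever of
#'   the solved dose or the no-op/clip fallback yields the lower predicted
#'   curve MRE, so tuning never pushes the prediction further from normal.
#' @param region_tol MRE at or below which the predicted curve counts as
#'   normal; tuning steps are skipped once this is reached (concentrations
#'   are still clipped into the band).
#' @return List of class `gcm_config`.
#' @export
gcm_config <- function(band = NORMAL_BAND, tf = 5, duration = 60, dt = 1 / 3,
                       n_probes = 9, property_tol = 0.02, guard_mre = TRUE,
                       region_tol = 0) {
  stopifnot(length(band) == 2, band[1] < band[2], tf > 0, dt > 0,
            duration > dt, n_probes >= 3, property_tol >= 0, region_tol >= 0)
  structure(list(band = band, tf = tf, duration = duration, dt = dt,
                 n_probes = n_probes, property_tol = property_tol,
                 guard_mre = guard_mre, region_tol = region_tol),
            class = "gcm_config")
}

## A single CAT property of the predicted curve for a panel.
.cat_property <- function(map, panel, property, config) {
  pp <- predict_params(map, panel)
  curve <- simulate_cat(pp, tf = config$tf, duration = config$duration,
                        dt = config$dt)
  unclass(cat_metrics(curve, params = pp))[[property]]
}

#' Patient-specific factor-to-property effect polynomial
#'
#' Probes the predicted CAT at `n_probes` equally spaced concentration
#' changes of one factor across its feasible range (the changes that keep
#' the factor inside the normal band), and least-squares fits the
#' origin-constrained quadratic
#' `delta_property = a2 * dc^2 + a1 * dc`. The quadratic is the smallest
#' informative local model of each factor's effect; a factor absent from
#' every parameter regression yields the exact zero polynomial.
#'
#' @param map A `regression_map`.
#' @param panel Current factor panel.
#' @param factor One of `"fii", "fv", "fvii", "fviii", "fix", "fx",
#'   "atiii", "pc"`.
#' @param property One of `"peak", "peak_time", "time_delay", "etp",
#'   "s_tail"`.
#' @param n_probes Number of probe points.
#' @param config A [gcm_config()].
#' @return List of class `effect_polynomial` with `a2`, `a1`, `factor`,
#'   `property`, `dc_range`.
#' @export
probe_effect_map <- function(map, panel, factor, property,
                             n_probes = 9, config = gcm_config()) {
  factor <- match.arg(factor, FACTOR_NAMES)
  property <- match.arg(property,
                        c("peak", "peak_time", "time_delay", "etp", "s_tail"))
  p <- .as_panel(panel)
  c0 <- p[[factor]]
  lo <- config$band[1] - c0
  hi <- config$band[2] - c0
  base <- .cat_property(map, p, property, config)
  dcs <- seq(lo, hi, length.out = n_probes)
  dprop <- vapply(dcs, function(d) {
    p2 <- p
    p2[[factor]] <- c0 + d
    .cat_property(map, p2, property, config) - base
  }, numeric(1))
  if (all(abs(dprop) < 1e-12)) {
    a2 <- 0
    a1 <- 0
  } else {
    cf <- lm.fit(cbind(dcs^2, dcs), dprop)$coefficients
    a2 <- unname(cf[1])
    a1 <- unname(cf[2])
  }
  structure(list(factor = factor, property = property, a2 = a2, a1 = a1,
                 dc_range = c(lo, hi)),
            class = "effect_polynomial")
}

#' Solve an effect polynomial for the dose achieving a target change
#'
#' Finds the real roots of `a2 dc^2 + a1 dc = target_delta` inside
#' `dc_bounds` and returns the minimum-magnitude root. When no admissible
#' root exists (target unreachable within the bounds) the best achievable
#' point - a bound endpoint or the quadratic's vertex - is returned and the
#' clamp is flagged. A zero polynomial returns the in-bounds point closest
#' to no change.
#'
#' @param poly An [probe_effect_map()] result.
#' @param target_delta Desired change in the CAT property.
#' @param dc_bounds Admissible concentration-change interval, % activity.
#' @return List with `dc`, `achieved` (polynomial value at `dc`), `target`,
#'   and logical `clamped`.
#' @export
solve_dose <- function(poly, target_delta, dc_bounds) {
  a2 <- poly$a2
  a1 <- poly$a1
  lo <- dc_bounds[1]
  hi <- dc_bounds[2]
  if (!is.finite(lo) || !is.finite(hi) || hi < lo)
    stop("dc_bounds must be a nonempty finite interval", call. = FALSE)
  ach <- function(x) a2 * x^2 + a1 * x
  if (abs(a2) < 1e-14 && abs(a1) < 1e-14) {
    dc <- min(max(0, lo), hi)
    return(list(dc = dc, achieved = 0, target = target_delta,
                clamped = abs(target_delta) > 0))
  }
  roots <- numeric(0)
  if (abs(a2) < 1e-14) {
    roots <- target_delta / a1
  } else {
    disc <- a1^2 + 4 * a2 * target_delta
    if (disc >= 0) roots <- (-a1 + c(1, -1) * sqrt(disc)) / (2 * a2)
  }
  inb <- roots[roots >= lo - 1e-9 & roots <= hi + 1e-9]
  if (length(inb)) {
    dc <- min(max(inb[which.min(abs(inb))], lo), hi)
    return(list(dc = dc, achieved = ach(dc), target = target_delta,
                clamped = FALSE))
  }
  cand <- c(lo, hi)
  if (abs(a2) > 1e-14) {
    v <- -a1 / (2 * a2)
    if (v > lo && v < hi) cand <- c(cand, v)
  }
  err <- abs(ach(cand) - target_delta)
  best <- cand[order(err, abs(cand))][1]
  list(dc = best, achieved = ach(best), target = target_delta, clamped = TRUE)
}

#' Goal-oriented Coagulation Management recommendation
#'
#' One ordered, single pass over the eight coagulation factors producing a
#' personalized concentration recommendation that moves the predicted CAT
#' toward the normal region while keeping every concentration inside the
#' normal 60-140% activity band:
#'
#' 1. factors V and VII, which have limited CAT impact, are clipped into the
#'    band;
#' 2. factor II (the thrombin precursor) is tuned toward the goal peak;
#' 3. factor X takes the residual peak gap (covering a factor II saturated
#'    at a band limit, and countering II's opposite peak-time effect);
#' 4. factor IX is tuned toward the goal time delay;
#' 5. factor VIII fine-tunes the peak-time;
#' 6. the post-peak tail area (sTail) of the updated prediction is compared
#'    with the goal curve's: if already surpassed, protein C is tuned toward
#'    the goal tail, otherwise ATIII; the anticoagulant that is not selected
#'    is clipped into the band.
#'
#' Goal property values are those of the curve simulated from the region's
#' `goal_params` (the model fitted to the normal mean), not band midpoints.
#' Each tuning step solves the patient-specific effect polynomial
#' ([probe_effect_map()], [solve_dose()]) with dose bounds that keep the
#' factor in-band, skips changes when the predicted curve is already inside
#' the normal region or the property is within the configured tolerance of
#' its goal, and (by default) rejects a dose that would increase the
#' predicted-curve MRE. The controller is deterministic,
#' visits each factor exactly once, and always returns a recommendation.
#'
#' @param panel Input factor panel.
#' @param map Trained `regression_map`.
#' @param region A [build_normal_region()] result (with `goal_params`).
#' @param config A [gcm_config()].
#' @return List of class `gcm_recommendation`: `input_panel`, `panel` (the
#'   recommendation), `steps` (one logged row per factor: action, targeted
#'   property, solved dose, clamp flag), predicted curves before/after,
#'   `mre_initial`, `mre_final`, `goal`, and `anticoagulant` (the tuned one).
#' @export
gcm_recommend <- function(panel, map, region, config = gcm_config()) {
  stopifnot(inherits(map, "regression_map"),
            inherits(region, "normal_region"),
            inherits(config, "gcm_config"))
  if (is.null(region$goal_params))
    stop("region has no goal_params; rebuild with fit_goal = TRUE",
         call. = FALSE)
  p0 <- .as_panel(panel)
  p <- p0
  band <- config$band
  goal_curve <- simulate_cat(region$goal_params, tf = config$tf,
                             duration = config$duration, dt = config$dt)
  goal <- unclass(cat_metrics(goal_curve, params = region$goal_params))
  pred <- function(pan) {
    simulate_cat(predict_params(map, pan), tf = config$tf,
                 duration = config$duration, dt = config$dt)
  }
  curve0 <- pred(p)
  mre0 <- mre(curve0, region)
  steps <- list()
  log_step <- function(factor, action, property, target_delta, dc, clamped) {
    steps[[length(steps) + 1L]] <<- data.frame(
      factor = factor, action = action, property = property,
      target_delta = target_delta, dc = dc, clamped = clamped,
      stringsAsFactors = FALSE)
  }
  clip_step <- function(f) {
    old <- p[[f]]
    new <- min(max(old, band[1]), band[2])
    p[[f]] <<- new
    log_step(f, "clip", NA_character_, NA_real_, new - old, new != old)
  }
  tune_step <- function(f, prop) {
    old <- p[[f]]
    dc_fallback <- min(max(old, band[1]), band[2]) - old
    mre_before <- mre(pred(p), region)
    if (mre_before <= config$region_tol) {
      ## predicted curve already normal: nothing to correct, only enforce
      ## the concentration band
      p[[f]] <<- old + dc_fallback
      log_step(f, "in_region", prop, NA_real_, dc_fallback, dc_fallback != 0)
      return(invisible())
    }
    cur <- .cat_property(map, p, prop, config)
    tgt <- goal[[prop]] - cur
    if (abs(tgt) <= config$property_tol * max(abs(goal[[prop]]),
                                              .Machine$double.eps)) {
      p[[f]] <<- old + dc_fallback
      log_step(f, "within_tol", prop, tgt, dc_fallback, dc_fallback != 0)
      return(invisible())
    }
    poly <- probe_effect_map(map, p, f, prop, config$n_probes, config)
    sol <- solve_dose(poly, tgt, c(band[1] - old, band[2] - old))
    dc <- sol$dc
    action <- "tune"
    clamped <- sol$clamped
    if (config$guard_mre && dc != dc_fallback) {
      p_tune <- p; p_tune[[f]] <- old + dc
      p_fall <- p; p_fall[[f]] <- old + dc_fallback
      if (mre(pred(p_tune), region) > mre(pred(p_fall), region) + 1e-12) {
        dc <- dc_fallback
        action <- "guarded"
        clamped <- TRUE
      }
    }
    p[[f]] <<- old + dc
    log_step(f, action, prop, tgt, dc, clamped)
    invisible()
  }
  clip_step("fv")
  clip_step("fvii")
  tune_step("fii", "peak")
  tune_step("fx", "peak")
  tune_step("fix", "time_delay")
  tune_step("fviii", "peak_time")
  cur_tail <- .cat_property(map, p, "s_tail", config)
  if (cur_tail > goal[["s_tail"]]) {
    sel <- "pc"; other <- "atiii"
  } else {
    sel <- "atiii"; other <- "pc"
  }
  tune_step(sel, "s_tail")
  clip_step(other)
  curve1 <- pred(p)
  structure(list(input_panel = p0, panel = p,
                 steps = do.call(rbind, steps),
                 predicted_before = curve0, predicted_after = curve1,
                 mre_initial = mre0, mre_final = mre(curve1, region),
                 goal = goal, anticoagulant = sel, config = config),
            class = "gcm_recommendation")
}

#' @export
print.gcm_recommendation <- function(x, ...) {
  cat("GCM recommendation (% activity):\n")
  print(round(rbind(input = x$input_panel, recommended = x$panel), 1))
  cat(sprintf("Predicted-CAT MRE: %.4f -> %.4f (anticoagulant tuned: %s)\n",
              x$mre_initial, x$mre_final, toupper(x$anticoagulant)))
  invisible(x)
}
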