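#' Center of the healthy thrombin-parameter distribution
#'
#' Stable parameters with poles at (-0.3, -0.6, -0.9) 1/min and a 3 min dead
#' time; at the standard 5 pM trigger the resulting curve peaks near 300 nM
#' around 6.7 min, a typical healthy CAT morphology.
#'
#' @return A [thrombin_params()] object.
#' @export
healthy_params_center <- function() {
  thrombin_params(k0 = 0.162, k1 = 0.99, k2 = 1.8, kn = 72.9, kd = 3)
}

#' Generate synthetic healthy-donor CAT curves
#'
#' Draws parameter sets log-normally around a stable center (redrawing the
#' rare unstable draw), simulates each at the given trigger, and optionally
#' adds Gaussian measurement noise scaled to the curve peak. Stands in for a
#' panel of normal plasma samples.
#'
#' @param n Number of donors.
#' @param seed RNG seed; identical seeds give bit-identical output.
#' @param params_center Center of the log-normal parameter draw.
#' @param dispersion SD of the multiplicative log-normal perturbation.
#' @param noise_sd Measurement noise SD as a fraction of each curve's peak.
#' @param tf,duration,dt Simulation settings.
#' @return List with `curves` (list of [cat_curve()]) and `params` (list of
#'   the generating [thrombin_params()]).
#' @export
generate_healthy_cats <- function(n, seed = 1,
                                  params_center = healthy_params_center(),
                                  dispersion = 0.08, noise_sd = 0,
                                  tf = 5, duration = 60, dt = 1 / 3) {
  stopifnot(n >= 0, dispersion >= 0, noise_sd >= 0)
  set.seed(seed)
  ctr <- unclass(.as_params(params_center))
  curves <- vector("list", n)
  params <- vector("list", n)
  for (i in seq_len(n)) {
    for (try in 1:100) {
      pp <- do.call(thrombin_params,
                    as.list(ctr * exp(rnorm(5, 0, dispersion))))
      if (all(Re(compute_poles(pp)) < 0)) break
    }
    params[[i]] <- pp
    cv <- simulate_cat(pp, tf = tf, duration = duration, dt = dt)
    if (noise_sd > 0) {
      y <- cv$thrombin + rnorm(length(cv$thrombin),
                               0, noise_sd * max(cv$thrombin))
      cv <- cat_curve(cv$times, pmax(y, 0))
    }
    curves[[i]] <- cv
  }
  list(curves = curves, params = params)
}

#' Ground-truth factor-to-parameter map with known sparse supports
#'
#' A constructed `regression_map` used to synthesize closed-loop test data:
#' k0 and k1 depend on factor X, k2 on factor II, the gain kn on factor II
#' (procoagulant) and protein C (anticoagulant), and the dead time kd on
#' factor IX. A panel at 100% activity across the board maps exactly to
#' [healthy_params_center()], and the map is stable (negative-real-part
#' poles) for any panel in the 20-180% activity range. The known supports
#' make stepwise-selection recovery checkable.
#'
#' @return A `regression_map` flagged `synthetic = TRUE`.
#' @export
ground_truth_map <- function() {
  mk <- function(factors, intercept, coefs) {
    list(factors = factors, intercept = intercept,
         coefficients = setNames(coefs, factors),
         trace = data.frame(step = integer(), factor = character(),
                            sse = numeric(), adj_r2 = numeric()))
  }
  terms <- list(
    k0 = mk("fx", 0.082, 8e-4),
    k1 = mk("fx", 0.59, 4e-3),
    k2 = mk("fii", 1.4, 4e-3),
    kn = mk(c("fii", "pc"), 53, c(0.4, -0.2)),
    kd = mk("fix", 4.2, -0.012))
  structure(list(terms = terms, n_samples = NA_integer_, synthetic = TRUE),
            class = "regression_map")
}

#' Generate synthetic factor panels of a given clinical profile
#'
#' Seeded panels for exercising the controller: `"inrange"` draws every
#' factor inside the normal band, `"low"` and `"high"` draw every factor
#' below/above it, `"mixed"` draws each factor independently from one of
#' those three regimes, and `"coagulopathic"` depresses factors II and X
#' (the trauma-like hypocoagulable pattern) with all other factors normal.
#'
#' @param n Number of panels.
#' @param seed RNG seed.
#' @param profile Panel profile; see Details.
#' @return Data frame with the eight factor columns.
#' @export
generate_panels <- function(n, seed = 1,
                            profile = c("inrange", "low", "high", "mixed",
                                        "coagulopathic")) {
  profile <- match.arg(profile)
  set.seed(seed)
  draw <- function(nn, rng) runif(nn, rng[1], rng[2])
  ranges <- list(inrange = c(65, 135), low = c(15, 55), high = c(145, 190))
  out <- matrix(NA_real_, n, 8, dimnames = list(NULL, FACTOR_NAMES))
  for (f in FACTOR_NAMES) {
    out[, f] <- switch(profile,
      inrange = draw(n, ranges$inrange),
      low = draw(n, ranges$low),
      high = draw(n, ranges$high),
      mixed = {
        pick <- sample(names(ranges), n, replace = TRUE)
        vapply(pick, function(r) draw(1, ranges[[r]]), numeric(1))
      },
      coagulopathic = if (f %in% c("fii", "fx")) draw(n, c(20, 50))
                      else draw(n, c(70, 130)))
  }
  as.data.frame(out)
}

#' Scenario for a synthetic longitudinal trauma cohort
#'
#' Describes the first-order equilibration dynamics a generated cohort
#' follows: each factor relaxes toward its scenario equilibrium,
#' `c(t + dt) = eq + (c(t) - eq) exp(-rate dt) + noise`, across the 0/6/12/24 h
#' sampling times. Survivor equilibria lie inside the normal band; the
#' deceased scenario places several factors outside it.
#'
#' @param n Number of patients.
#' @param outcome `"survivor"` or `"deceased"`.
#' @param equilibria Named per-factor equilibrium concentrations
#'   (% activity); defaults depend on `outcome`.
#' @param rate_per_h Relaxation rate (1/h); default ~6 h half-life.
#' @param panel_noise_sd Per-timepoint Gaussian concentration noise
#'   (% activity), truncated at 0.
#' @param cat_noise_sd CAT measurement noise as a fraction of peak.
#' @param seed RNG seed.
#' @param times_h Sampling times in hours.
#' @param init_range Range of the uniform initial-concentration draw, or
#'   NULL to start every patient exactly at equilibrium.
#' @param map Ground-truth `regression_map` used to synthesize CATs.
#' @return List of class `cohort_scenario`.
#' @export
cohort_scenario <- function(n = 50, outcome = c("survivor", "deceased"),
                            equilibria = NULL, rate_per_h = 0.115,
                            panel_noise_sd = 5, cat_noise_sd = 0.01,
                            seed = 1, times_h = c(0, 6, 12, 24),
                            init_range = c(20, 180),
                            map = ground_truth_map()) {
  outcome <- match.arg(outcome)
  if (is.null(equilibria)) {
    equilibria <- if (outcome == "survivor") {
      c(fii = 100, fv = 105, fvii = 95, fviii = 110,
        fix = 100, fx = 95, atiii = 100, pc = 100)
    } else {
      c(fii = 40, fv = 45, fvii = 50, fviii = 165,
        fix = 55, fx = 45, atiii = 50, pc = 160)
    }
  }
  equilibria <- equilibria[FACTOR_NAMES]
  stopifnot(n >= 0, rate_per_h > 0, panel_noise_sd >= 0, cat_noise_sd >= 0,
            !any(is.na(equilibria)))
  inb <- equilibria >= NORMAL_BAND[1] & equilibria <= NORMAL_BAND[2]
  if (outcome == "survivor" && !all(inb))
    stop("survivor equilibria must all lie inside the normal band",
         call. = FALSE)
  if (outcome == "deceased" && all(inb))
    stop("a deceased scenario needs at least one out-of-band equilibrium",
         call. = FALSE)
  structure(list(n = n, outcome = outcome, equilibria = equilibria,
                 rate_per_h = rate_per_h, panel_noise_sd = panel_noise_sd,
                 cat_noise_sd = cat_noise_sd, seed = seed, times_h = times_h,
                 init_range = init_range, map = map),
            class = "cohort_scenario")
}

#' Generate a longitudinal cohort from a scenario
#'
#' @param scenario A [cohort_scenario()].
#' @param cats Also synthesize a CAT curve per patient-timepoint through the
#'   scenario's ground-truth map.
#' @param tf,duration,dt Simulation settings for the synthesized CATs.
#' @return List with `cohort` (long data frame: `patient_id`, `outcome`,
#'   `time_h`, eight factor columns), `curves` (named list keyed
#'   `patientid_timeh`, or NULL), and the `scenario`.
#' @export
generate_cohort <- function(scenario, cats = FALSE, tf = 5, duration = 60,
                            dt = 1 / 3) {
  stopifnot(inherits(scenario, "cohort_scenario"))
  set.seed(scenario$seed)
  eq <- scenario$equilibria
  times <- sort(scenario$times_h)
  rows <- vector("list", scenario$n * length(times))
  curves <- if (cats) list() else NULL
  k <- 0L
  for (i in seq_len(scenario$n)) {
    id <- sprintf("p%03d", i)
    conc <- if (is.null(scenario$init_range)) eq
            else runif(8, scenario$init_range[1], scenario$init_range[2])
    names(conc) <- FACTOR_NAMES
    prev_t <- times[1]
    for (t in times) {
      if (t > prev_t) {
        decay <- exp(-scenario$rate_per_h * (t - prev_t))
        conc <- eq + (conc - eq) * decay +
          rnorm(8, 0, scenario$panel_noise_sd)
        conc <- pmax(conc, 0)
        prev_t <- t
      }
      k <- k + 1L
      rows[[k]] <- data.frame(patient_id = id, outcome = scenario$outcome,
                              time_h = t, as.list(conc),
                              stringsAsFactors = FALSE)
      if (cats) {
        pp <- predict_params(scenario$map, conc)
        cv <- simulate_cat(pp, tf = tf, duration = duration, dt = dt)
        if (scenario$cat_noise_sd > 0) {
          y <- cv$thrombin + rnorm(length(cv$thrombin),
                                   0, scenario$cat_noise_sd * max(cv$thrombin))
          cv <- cat_curve(cv$times, pmax(y, 0))
        }
        curves[[paste(id, t, sep = "_")]] <- cv
      }
    }
  }
  cohort <- do.call(rbind, rows)
  list(cohort = cohort, curves = curves, scenario = scenario)
}

#' Generate an isolated factor-spiking series
#'
#' Emulates spiking increasing amounts of a single factor (II, VIII or X in
#' the wet-lab validation sets) into a base plasma sample: the chosen
#' factor's concentration is `base + level` for each spike level, everything
#' else fixed, with CATs synthesized through the map.
#'
#' @param base_panel The unspiked panel.
#' @param factor Factor to spike.
#' @param levels Non-decreasing spike amounts (% activity); level 0 is the
#'   base sample.
#' @param map A `regression_map`.
#' @param tf,duration,dt Simulation settings.
#' @return List with `panels` (data frame), `curves` (list of
#'   [cat_curve()]) and `levels`.
#' @export
generate_spiking_series <- function(base_panel, factor, levels,
                                    map = ground_truth_map(), tf = 5,
                                    duration = 60, dt = 1 / 3) {
  factor <- match.arg(factor, FACTOR_NAMES)
  if (is.unsorted(levels))
    stop("spike levels must be non-decreasing", call. = FALSE)
  base <- .as_panel(base_panel)
  panels <- do.call(rbind, lapply(levels, function(l) {
    p <- base
    p[[factor]] <- base[[factor]] + l
    as.data.frame(as.list(p))
  }))
  curves <- lapply(seq_len(nrow(panels)), function(i) {
    predict_cat(map, panels[i, ], tf = tf, duration = duration, dt = dt)
  })
  list(panels = panels, curves = curves, levels = levels, factor = factor)
}

#' Generate a tissue-factor titration series
#'
#' Simulates one parameter set under increasing impulse magnitudes
#' (1/5/20 pM by default). Because the model is linear in its input, the
#' curves scale exactly with the trigger concentration.
#'
#' @param params A [thrombin_params()] object.
#' @param magnitudes TF impulse magnitudes in pM.
#' @param duration,dt Simulation grid.
#' @return Named list of [cat_curve()]s, one per magnitude.
#' @export
generate_tf_titration <- function(params, magnitudes = c(1, 5, 20),
                                  duration = 60, dt = 1 / 3) {
  stopifnot(all(magnitudes > 0))
  setNames(lapply(magnitudes, function(m) {
    simulate_cat(params, tf = m, duration = duration, dt = dt)
  }), paste0("tf_", magnitudes, "pM"))
}
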