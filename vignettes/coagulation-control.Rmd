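---
title: "Modeling thrombin generation and goal-oriented coagulation management"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling thrombin generation and goal-oriented coagulation management}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thrombodyn)
```

## The problem

Trauma-induced coagulopathy derails the balance between clotting and
fibrinolysis, and treatment today relies on uncharacterized blood products
given by rules of thumb. The calibrated automated thrombogram (CAT) — the
thrombin concentration time-history of a plasma sample after a
tissue-factor trigger — summarizes a patient's clotting state well, but the
assay takes about an hour, too slow for bedside guidance. Coagulation
factor concentrations, by contrast, can be measured in minutes.
`thrombodyn` implements a control-oriented stack built on that asymmetry:
a compact dynamic model predicts the CAT from eight factor concentrations
(II, V, VII, VIII, IX, X, ATIII, protein C; percent activity), and a
deterministic controller recommends concentration changes that move the
predicted curve into a normal region while keeping every factor inside the
normal 60–140% activity band.

## The thrombin dynamics model

The CAT is modeled as the response of a delayed third-order linear system
to a tissue-factor impulse of magnitude $u$ pM (5 pM by default, the
standard CAT trigger):

$$\frac{Y(s)}{U(s)} = \frac{K_n}{s^3 + K_2 s^2 + K_1 s + K_0}\, e^{-K_d s}.$$

Five patient-specific parameters: $K_0, K_1, K_2$ set the characteristic
cubic and hence the three system poles; $K_n$ is a gain that also absorbs
the pM-to-nM unit conversion (its absolute scale is
implementation-consistent rather than physical); $K_d$ is the dead time in
minutes between trigger and thrombin onset. Time is in minutes and
thrombin in nM throughout.

`simulate_cat()` realizes the impulse analytically: the impulse response
of the rational part is computed by partial fractions over the cubic's
roots and shifted by $K_d$, so no discretization of a Dirac input is ever
needed, causality ($y(t) = 0$ for $t < K_d$) is exact, and the dead time
is a continuous quantity. When two roots coincide within a relative $10^{-6}$
the confluent (repeated-root) formulas take over — `polyroot` resolves a
genuinely double root only to about $\sqrt{\varepsilon}$, so a tighter
switch would let the partial-fraction residues blow up first. An
independent state-space integration (`method = "ode"`, via deSolve)
cross-checks the analytic path to $10^{-4}$ relative in the tests.
Floating-point undershoot below zero is clipped; thrombin concentration is
physically non-negative. The default grid is one sample every 20 s
(`dt = 1/3` min), matching the CAT instrument, over 60 min.

```{r}
p <- healthy_params_center()
curve <- simulate_cat(p)  # 5 pM TF, 60 min, 20 s sampling
cat_metrics(curve, p)
compute_poles(p)
```

## Fitting the model to a measured curve

`fit_model()` minimizes the sum of squared residuals with bounded
Levenberg–Marquardt least squares (minpack.lm), function tolerance
$10^{-9}$, bounds $(10^{-6}, 10^{6})$ on the positive parameters and
$[0, 20]$ min on $K_d$. The bounds are not physically derived — they exist
to keep the optimizer inside valid dynamics; healthy-like fits sit far
from them. The default initialization is read off the curve's shape: dead
time from the 2%-of-peak onset, a pole scale $a$ from the onset-to-peak
time assuming the reference pattern $(-a, -2a, -3a)$, and the gain from
the observed peak. That guess lands close enough that noise-free curves
are recovered to machine precision and local minima are rarely an issue;
`fit_multistart()` adds seeded random restarts from the bound box for
irregular curves. The reported `residual_sse` is always recomputed at the
returned parameters, never taken from optimizer state.

## From factor panels to parameters: stepwise regression

`fit_stepwise()` learns, for each of the five parameters independently, a
greedy forward-selected linear model over the eight factor concentrations:
at each step the factor whose addition most reduces the residual sum of
squares enters, all coefficients are refit, and selection stops when the
adjusted $R^2$ no longer increases (the stopping rule is the package's
concrete reading of "no longer improves the fit"; adjusted $R^2$ penalizes
pure overfitting additions). Regression is on raw parameter values — no
transform — and predictions are projected into the parameter box, since a
linear map can emit invalid dynamics for extreme panels.
`cross_validate()` scores the whole panel-to-CAT pipeline with seeded
k-fold partitions (fold sizes differ by at most one), comparing predicted
peak, peak-time and ETP against the metrics of each held-out sample's own
fitted model, as percent errors
$|x_\mathrm{model} - x_\mathrm{ref}|/x_\mathrm{ref} \times 100$
aggregated as mean ± SD over held-out samples.

## The normal region and the MRE score

`build_normal_region()` takes pointwise min/max/mean envelopes over a set
of healthy-donor curves and fits the model to the mean curve; that fit is
the *goal* — the target CAT the controller steers toward. A curve is
scored by its mean relative error (`mre()`): at each time point outside
the envelope, the relative excess against the violated bound,
$(y - \mathrm{upper})/\mathrm{upper}$ above or
$(\mathrm{lower} - y)/\mathrm{lower}$ below, averaged over violating
points; zero inside. Two numerical choices make the score well-defined:
points where the upper envelope is below 1 nM (pre-onset) are excluded,
and a 1 nM floor guards the denominator when the violated bound is near
zero — relative error against near-zero thrombin is meaningless. A curve
sitting at 1.10× the upper envelope everywhere scores exactly 0.10.
The bound-relative denominator (rather than the mean or the band width) is
a deliberate choice: it makes the score scale-invariant and exactly
interpretable as "fractional excursion beyond normal".

## The GCM controller

`gcm_recommend()` performs one ordered pass over the eight factors —
the controller is $O(n)$ in the factor count, deterministic, and always
terminates with a recommendation:

1. **V, VII**: clipped into the band (limited CAT impact);
2. **II**: tuned toward the goal peak (thrombin precursor, primary
   peak actuator);
3. **X**: takes the residual peak gap — covering a factor II saturated at
   a band limit — and counters II's opposite peak-time effect;
4. **IX**: tuned toward the goal time delay;
5. **VIII**: fine control of peak-time with minimal peak effect;
6. **PC or ATIII**: the updated prediction's post-peak tail area (sTail)
   is compared with the goal curve's; if the goal is surpassed protein C
   is tuned toward the goal tail, otherwise ATIII. The anticoagulant not
   selected is clipped into the band, so the band guarantee holds for
   every factor on every input.

Each tuning step builds a patient-specific effect model
(`probe_effect_map()`): the predicted CAT is simulated at nine equally
spaced concentration changes spanning the factor's feasible in-band range,
and an origin-constrained quadratic
$\Delta\mathrm{property} = a_2\,\Delta c^2 + a_1\,\Delta c$ is fit —
the smallest-parameter local model that captures the saturating,
mildly nonlinear dose effects. `solve_dose()` then returns the
minimum-magnitude in-bounds root achieving the property gap, or the best
achievable point (endpoint or vertex) with a logged clamp event when the
target is out of reach. Dose bounds are always
$[60 - c,\; 140 - c]$, which is what enforces the band invariant
structurally.

Three controller details are this package's own design, because the
published flow is prose-only:

* **Region gate** — when the predicted curve is already inside the normal
  region (MRE at or below `region_tol`, default 0), tuning steps make no
  change beyond band clipping. An in-band panel with a normal prediction
  is returned untouched, and the controller is an exact fixed point on its
  own output.
* **Property tolerance** — a step whose property gap is within
  `property_tol` (2% relative) of the goal value is skipped; this sets the
  controller's idempotence scale.
* **MRE guard** — each solved dose is accepted only if it does not yield a
  higher predicted-curve MRE than the fallback (no change, or the clip
  into band for an out-of-band factor). With in-band inputs this makes
  per-patient non-degradation of the MRE structural rather than
  empirical.

```{r}
region <- build_normal_region(generate_healthy_cats(20, seed = 7)$curves)
map <- ground_truth_map()
patient <- generate_panels(1, seed = 3, profile = "coagulopathic")[1, ]
gcm_recommend(patient, map, region)
```

## Cohort equilibration statistics

`delta_heatmap()` bins patients by their factor concentration at the start
of each period (20%-activity-wide bins from 0 to 200, last bin open — the
exact published edges are not printed anywhere, so round bins are used)
and averages the end-minus-start change per cell; empty cells are `NA`,
never zero. The sign convention is end − start, so equilibration shows as
positive cells in low starting bins. `welch_test()` implements the
standard unequal-variance t statistic with the plus-sign pooled standard
error and Welch–Satterthwaite degrees of freedom — the form every
reference implementation uses — with tiers at the conventional
0.05/0.01/0.001 cutpoints. `convergence_summary()` reports mean ± SD per
factor and timepoint and flags whether each group's final mean sits inside
the normal band.

## What the synthetic generators emulate — and what they do not

The package ships seeded generators so the entire stack is testable
without patient data:

* `generate_healthy_cats()` draws parameters log-normally (dispersion
  0.08) around `healthy_params_center()` — poles $(-0.3, -0.6, -0.9)$
  min$^{-1}$, 3 min dead time, gain giving a ~300 nM peak near 6.7 min at
  5 pM TF — chosen once as a realistic healthy CAT morphology.
* `ground_truth_map()` is a constructed sparse linear map (k0, k1 ← FX;
  k2 ← FII; kn ← FII, PC; kd ← FIX) that sends the all-100% panel exactly
  to the healthy center and stays stable (Routh–Hurwitz:
  $K_1 K_2 > K_0$ with positive coefficients) for panels in 20–180%
  activity. Known supports make stepwise-selection recovery checkable.
* `generate_cohort()` evolves each factor by first-order relaxation toward
  a scenario equilibrium over 0/6/12/24 h
  ($c_{t+\Delta} = c_\mathrm{eq} + (c_t - c_\mathrm{eq})e^{-\lambda\Delta}
  + \varepsilon$, $\lambda$ defaulting to a ~6 h half-life, Gaussian noise
  truncated at 0) — the simplest process reproducing the observed
  low-start-rises / high-start-falls equilibration structure. Survivor
  equilibria are in-band; the deceased scenario places several factors
  outside.
* `generate_spiking_series()` and `generate_tf_titration()` emulate
  isolated factor spiking and trigger titration; the latter's curves scale
  exactly linearly because the model is linear in its input.

These generators reproduce the *statistical shape* of trauma cohort data,
not its biology: real CATs have fluorescence-derived noise structure,
inner-filter artifacts and replicate variability; real factor dynamics
involve transfusion events and interactions the first-order relaxation
ignores; and the true panel-to-parameter relationship is not exactly
linear-sparse. Passing tests therefore demonstrate that the machinery is
correct and self-consistent under the stated generative assumptions —
they do not certify predictive accuracy on clinical data, which requires
the corresponding measured datasets.

## Numerical choices and problem sizes

Optimizer tolerance $10^{-9}$ (the documented fitting tolerance) with an
iteration cap of 1024; peak ties broken at the first attaining index;
onset threshold for delay-without-parameters at 2% of peak; confluence
switch at relative $10^{-6}$ root separation; the controller's dose solver
works on exact quadratic roots, so its only tolerance is the 2% property
skip. The test suite and the acceptance script size their simulations to
run comfortably on a single CPU: 20-donor regions, 40–60-sample training
cohorts, 200 controller patients, 25 recovery fits, 1000 pole checks —
sizes at which every check completes in seconds while still exercising
the asymptotics that matter.

## Known limitations

* The model is linear and third-order by construction; saturation of
  factor effects enters only through the probe-fit quadratics, not the
  plant itself.
* Predicted-parameter clipping can make the panel-to-parameter map locally
  flat at extreme panels, where the controller then sees a zero effect
  polynomial and correctly logs a clamp instead of moving.
* `welch_test()` assumes approximate normality of the per-group changes;
  no multiple-testing correction is applied, matching raw-p reporting
  conventions.
* Translating concentration recommendations into physical doses (plasma
  units, recombinant factor mg) is out of scope.
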