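test_that("parameter and curve constructors enforce their invariants", {
  expect_error(thrombin_params(-1, 11, 6, 1, 1), "positive")
  expect_error(thrombin_params(6, 11, 6, 1, -0.1), "non-negative")
  expect_error(thrombin_params(6, NA, 6, 1, 1), "finite")
  expect_error(cat_curve(c(0, 1, 1.5), c(0, 1, 2)), "uniform")
  expect_error(cat_curve(c(0, 1, 0.5), c(0, 1, 2)), "increasing")
  ## floating-point undershoot is clipped, not rejected
  cv <- cat_curve(c(0, 1, 2), c(0, -1e-12, 3))
  expect_identical(cv$thrombin[2], 0)
})

test_that("simulation matches the partial-fraction closed form for distinct real poles", {
  cv <- simulate_cat(ref_params(kd = 0), tf = 1, duration = 10, dt = 0.1)
  expect_equal(cv$thrombin, ref_closed_form(cv$times), tolerance = 1e-10)
  ## spot value at t = 1
  i1 <- which(abs(cv$times - 1) < 1e-9)
  expect_equal(cv$thrombin[i1], 0.5 * exp(-1) - exp(-2) + 0.5 * exp(-3),
               tolerance = 1e-12)
})

test_that("dead time gives exact causality and the gain acts linearly", {
  p <- thrombin_params(6, 11, 6, 1, 2)
  cv <- simulate_cat(p, tf = 5, duration = 20, dt = 0.25)
  expect_true(all(cv$thrombin[cv$times < 2] == 0))
  expect_true(any(cv$thrombin[cv$times > 2.5] > 0))
  ## linearity in the impulse magnitude, pointwise
  c1 <- simulate_cat(p, tf = 3, duration = 20)
  c2 <- simulate_cat(p, tf = 6, duration = 20)
  expect_equal(c2$thrombin, 2 * c1$thrombin, tolerance = 1e-12)
  ## near-zero gain gives a near-zero curve
  c0 <- simulate_cat(thrombin_params(6, 11, 6, 1e-6, 0), tf = 5,
                     duration = 20)
  expect_lt(max(c0$thrombin), 1e-5)
})

test_that("analytic impulse realization agrees with numerical ODE integration", {
  set.seed(31)
  for (i in 1:5) {
    p <- random_stable_params()
    ca <- simulate_cat(p, duration = 40, dt = 0.5)
    co <- simulate_cat(p, duration = 40, dt = 0.5, method = "ode")
    expect_lt(max(abs(ca$thrombin - co$thrombin)) / max(ca$thrombin), 1e-4)
  }
})

test_that("confluent-root formulas take over when poles coincide", {
  ## double pole at -1, simple pole at -2: g = (-1 + t) e^{-t} + e^{-2t}
  ## from (s+1)^2 (s+2) = s^3 + 4 s^2 + 5 s + 2
  p <- thrombin_params(2, 5, 4, 1, 0)
  cv <- simulate_cat(p, tf = 1, duration = 12, dt = 0.25)
  t <- cv$times
  expect_equal(cv$thrombin, pmax((t - 1) * exp(-t) + exp(-2 * t), 0),
               tolerance = 1e-9)
  ## triple pole at -1: (s+1)^3, g = t^2/2 e^{-t}
  p3 <- thrombin_params(1, 3, 3, 1, 0)
  cv3 <- simulate_cat(p3, tf = 1, duration = 12, dt = 0.25)
  expect_equal(cv3$thrombin, t^2 / 2 * exp(-t), tolerance = 1e-9)
})

test_that("poles solve the characteristic cubic and match an eigenvalue oracle", {
  expect_equal(compute_poles(ref_params()), c(-3 + 0i, -2 + 0i, -1 + 0i),
               tolerance = 1e-10)
  set.seed(17)
  for (i in 1:50) {
    p <- random_stable_params()
    poles <- compute_poles(p)
    ## independent oracle: eigenvalues of the companion matrix
    A <- rbind(c(0, 1, 0), c(0, 0, 1),
               c(-p[["k0"]], -p[["k1"]], -p[["k2"]]))
    ev <- eigen(A, only.values = TRUE)$values
    ev <- ev[order(Re(ev), Im(ev))]
    expect_lt(max(Mod(poles - ev)), 1e-8)
    ## conjugate structure
    expect_equal(sort(Im(poles)), sort(-Im(poles)), tolerance = 1e-10)
  }
})

test_that("stable systems decay: thrombin returns to near zero", {
  set.seed(5)
  for (i in 1:5) {
    p <- random_stable_params(kd_range = c(0, 2))
    slowest <- 1 / min(abs(Re(compute_poles(p))))
    dur <- p[["kd"]] + 10 * slowest
    cv <- simulate_cat(p, duration = dur, dt = dur / 400)
    expect_lt(cv$thrombin[length(cv$thrombin)], 0.01 * max(cv$thrombin))
  }
})

test_that("cat_metrics computes peak, areas, and delay correctly", {
  zero <- cat_curve(seq(0, 10, 0.5), rep(0, 21))
  mz <- cat_metrics(zero)
  expect_equal(unclass(mz), c(peak = 0, peak_time = 0, time_delay = 0,
                              etp = 0, s_tail = 0))
  p <- thrombin_params(0.162, 0.99, 1.8, 72.9, 3)
  cv <- simulate_cat(p)
  m <- cat_metrics(cv, p)
  ## scaling thrombin doubles peak and areas, leaves peak_time alone
  cv2 <- cat_curve(cv$times, 2 * cv$thrombin)
  m2 <- cat_metrics(cv2, p)
  expect_equal(m2[["peak"]], 2 * m[["peak"]])
  expect_equal(m2[["etp"]], 2 * m[["etp"]])
  expect_equal(m2[["s_tail"]], 2 * m[["s_tail"]])
  expect_equal(m2[["peak_time"]], m[["peak_time"]])
  ## time delay is kd with params, onset-threshold without
  expect_equal(m[["time_delay"]], 3)
  m_nop <- cat_metrics(cv)
  expect_gte(m_nop[["time_delay"]], 3)
  expect_lte(m_nop[["time_delay"]], m_nop[["peak_time"]])
  ## invariant ordering
  expect_lte(m[["s_tail"]], m[["etp"]])
})

test_that("peak and peak-time agree with a dense-grid oracle", {
  ## reference case: the coarse-grid peak is within 0.5% of a 100x denser
  ## evaluation of the same closed form
  cv <- simulate_cat(ref_params(), tf = 1, duration = 10, dt = 0.1)
  m <- cat_metrics(cv)
  td <- seq(0, 10, by = 0.001)
  yd <- ref_closed_form(td)
  expect_equal(m[["peak"]], max(yd), tolerance = 5e-3)
  expect_equal(m[["peak_time"]], td[which.max(yd)], tolerance = 5e-2)
})

test_that("simulation rejects invalid inputs", {
  p <- ref_params(kd = 5)
  expect_error(simulate_cat(p, duration = 4), "dead time")
  expect_error(simulate_cat(p, duration = 10, dt = 20), "dt")
  expect_error(simulate_cat(p, tf = -5), "positive")
})
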