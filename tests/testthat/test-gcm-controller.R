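test_that("a factor with no regression effect yields the zero polynomial", {
  map <- ground_truth_map()  # fv appears in no parameter regression
  pan <- factor_panel(100, 100, 100, 100, 100, 100, 100, 100)
  poly <- probe_effect_map(map, pan, "fv", "peak")
  expect_identical(poly$a2, 0)
  expect_identical(poly$a1, 0)
})

test_that("a constructed linear effect is recovered with negligible curvature", {
  ## kd depends linearly on fix alone, and time_delay IS kd, so the
  ## fix -> time_delay effect is exactly linear with slope -0.012
  map <- ground_truth_map()
  pan <- factor_panel(100, 100, 100, 100, 100, 100, 100, 100)
  poly <- probe_effect_map(map, pan, "fix", "time_delay")
  expect_equal(poly$a1, -0.012, tolerance = 1e-6)
  expect_equal(poly$a2, 0, tolerance = 1e-9)
})

test_that("the quadratic effect model predicts held-out doses within 5%", {
  map <- ground_truth_map()
  pan <- factor_panel(100, 100, 100, 100, 100, 100, 100, 100)
  cfg <- gcm_config()
  poly <- probe_effect_map(map, pan, "fii", "peak", n_probes = 9,
                           config = cfg)
  base <- thrombodyn:::.cat_property(map, unclass(pan), "peak", cfg)
  for (dc in c(-27, 13, 31)) {  # off the probe lattice
    p2 <- unclass(pan)
    p2[["fii"]] <- p2[["fii"]] + dc
    truth <- thrombodyn:::.cat_property(map, p2, "peak", cfg) - base
    pred <- poly$a2 * dc^2 + poly$a1 * dc
    expect_lt(abs(pred - truth) / abs(truth), 0.05)
  }
})

test_that("solve_dose picks the exact linear dose and clamps at bounds", {
  lin <- structure(list(a2 = 0, a1 = 2), class = "effect_polynomial")
  s <- solve_dose(lin, 10, c(-50, 50))
  expect_equal(s$dc, 5)
  expect_false(s$clamped)
  s2 <- solve_dose(lin, 200, c(-50, 50))
  expect_equal(s2$dc, 50)
  expect_true(s2$clamped)
  zero <- structure(list(a2 = 0, a1 = 0), class = "effect_polynomial")
  s3 <- solve_dose(zero, 10, c(-50, 50))
  expect_equal(s3$dc, 0)
  expect_true(s3$clamped)
})

test_that("solve_dose returns the minimum-|dc| in-bound root (grid oracle)", {
  set.seed(99)
  grid <- seq(-50, 50, by = 1e-4)
  for (i in 1:20) {
    ## both roots in bounds, well separated, with a clear min-|dc| winner
    r_small <- sample(c(-1, 1), 1) * runif(1, 2, 20)
    r_big <- sample(c(-1, 1), 1) * (abs(r_small) + runif(1, 15, 25))
    a2 <- runif(1, 0.05, 0.5) * sample(c(-1, 1), 1)
    a1 <- -a2 * (r_small + r_big)
    tgt <- -a2 * r_small * r_big
    poly <- structure(list(a2 = a2, a1 = a1), class = "effect_polynomial")
    s <- solve_dose(poly, tgt, c(-50, 50))
    expect_equal(s$dc, r_small, tolerance = 1e-8)
    expect_false(s$clamped)
    ## brute-force grid search agrees on |dc|-minimality
    hit <- grid[abs(a2 * grid^2 + a1 * grid - tgt) < 1e-3]
    expect_lt(abs(min(abs(hit)) - abs(r_small)), 0.01)
  }
})

test_that("an in-range panel with a normal predicted CAT is left untouched", {
  reg <- fixture_region()
  map <- ground_truth_map()
  pan <- factor_panel(100, 100, 100, 100, 100, 100, 100, 100)
  expect_equal(mre(predict_cat(map, pan), reg), 0)
  rec <- gcm_recommend(pan, map, reg)
  expect_equal(rec$panel, rec$input_panel)
  expect_true(all(rec$steps$dc == 0))
})

test_that("step one clips factors V and VII into the band", {
  reg <- fixture_region()
  map <- ground_truth_map()
  pan <- factor_panel(100, 30, 170, 100, 100, 100, 100, 100)
  rec <- gcm_recommend(pan, map, reg)
  expect_equal(unname(rec$panel[["fv"]]), 60)
  expect_equal(unname(rec$panel[["fvii"]]), 140)
})

test_that("every recommendation stays inside the band for any panel profile", {
  reg <- fixture_region()
  map <- ground_truth_map()
  for (prof in c("low", "high", "mixed")) {
    panels <- generate_panels(5, seed = 21, profile = prof)
    for (i in seq_len(nrow(panels))) {
      rec <- gcm_recommend(panels[i, ], map, reg)
      expect_true(all(rec$panel >= 60 & rec$panel <= 140))
    }
  }
})

test_that("the controller is a single ordered pass: one step per factor", {
  reg <- fixture_region()
  map <- ground_truth_map()
  rec <- gcm_recommend(generate_panels(1, seed = 4, "mixed")[1, ], map, reg)
  expect_identical(nrow(rec$steps), 8L)
  expect_setequal(rec$steps$factor,
                  c("fii", "fv", "fvii", "fviii", "fix", "fx", "atiii", "pc"))
  expect_identical(rec$steps$factor[1:2], c("fv", "fvii"))
  expect_identical(rec$steps$factor[3:6], c("fii", "fx", "fix", "fviii"))
  ## the anticoagulant pair closes the pass
  expect_setequal(rec$steps$factor[7:8], c("pc", "atiii"))
})

test_that("coagulopathic cohorts improve and the controller is idempotent", {
  reg <- fixture_region()
  map <- ground_truth_map()
  panels <- generate_panels(10, seed = 3, profile = "coagulopathic")
  for (i in seq_len(nrow(panels))) {
    rec <- gcm_recommend(panels[i, ], map, reg)
    expect_lte(rec$mre_final, rec$mre_initial + 1e-12)
    expect_true(all(rec$panel >= 60 & rec$panel <= 140))
    if (i <= 3) {
      rec2 <- gcm_recommend(as.list(rec$panel), map, reg)
      expect_lt(max(abs(rec2$panel - rec$panel)), 1e-9)
    }
  }
})

test_that("the anticoagulant choice follows the tail comparison", {
  reg <- fixture_region()
  map <- ground_truth_map()
  cfg <- gcm_config()
  goal_tail <- unclass(cat_metrics(
    simulate_cat(reg$goal_params), params = reg$goal_params))[["s_tail"]]
  ## reconstruct the panel state after the six preceding steps from the log
  ## and check the protein C / ATIII branch against the tail rule
  for (seed in c(31, 32, 33)) {
    pan <- generate_panels(1, seed = seed, profile = "mixed")[1, ]
    rec <- gcm_recommend(pan, map, reg)
    p_mid <- thrombodyn:::.as_panel(pan)
    for (k in 1:6) p_mid[[rec$steps$factor[k]]] <-
        p_mid[[rec$steps$factor[k]]] + rec$steps$dc[k]
    tail_mid <- thrombodyn:::.cat_property(map, p_mid, "s_tail", cfg)
    expect_identical(rec$anticoagulant,
                     if (tail_mid > goal_tail) "pc" else "atiii")
  }
})
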