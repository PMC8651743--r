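## Build a paired (panels, params) training set from a linear ground truth.
make_linear_cohort <- function(n, seed, noise_frac = 0) {
  set.seed(seed)
  panels <- generate_panels(n, seed = seed, profile = "mixed")
  P <- t(vapply(seq_len(n), function(i) {
    unclass(predict_params(ground_truth_map(), panels[i, ]))
  }, numeric(5)))
  colnames(P) <- c("k0", "k1", "k2", "kn", "kd")
  if (noise_frac > 0)
    P <- P * (1 + matrix(rnorm(length(P), 0, noise_frac), nrow(P)))
  list(panels = panels, params = as.data.frame(P))
}

test_that("an exact univariate dependence is found first, with exact coefficients", {
  set.seed(2)
  panels <- generate_panels(30, seed = 2, profile = "mixed")
  P <- data.frame(k0 = 2 * panels$fii, k1 = 1, k2 = 1, kn = 1, kd = 1)
  map <- fit_stepwise(panels, P)
  expect_identical(map$terms$k0$factors, "fii")
  expect_equal(unname(map$terms$k0$coefficients), 2, tolerance = 1e-10)
  expect_equal(map$terms$k0$intercept, 0, tolerance = 1e-8)
  ## constant columns select nothing and keep the constant as intercept
  expect_length(map$terms$k1$factors, 0)
  expect_equal(map$terms$k1$intercept, 1)
})

test_that("the first selected factor is the best univariate regressor (exhaustive oracle)", {
  for (s in 1:5) {
    co <- make_linear_cohort(25, seed = 40 + s, noise_frac = 0.05)
    X <- as.matrix(co$panels)
    map <- fit_stepwise(co$panels, co$params)
    for (j in c("k0", "kn", "kd")) {
      y <- co$params[[j]]
      sses <- vapply(colnames(X), function(f) {
        sum(lm(y ~ X[, f])$residuals^2)
      }, numeric(1))
      oracle_first <- names(which.min(sses))
      if (length(map$terms[[j]]$factors))
        expect_identical(map$terms[[j]]$factors[1], oracle_first)
    }
  }
})

test_that("stepwise selection recovers known sparse supports under small noise", {
  truth <- ground_truth_map()
  hits <- 0L
  for (s in 1:10) {
    co <- make_linear_cohort(60, seed = 100 + s, noise_frac = 0.01)
    map <- fit_stepwise(co$panels, co$params)
    ok <- all(vapply(names(truth$terms), function(j) {
      all(truth$terms[[j]]$factors %in% map$terms[[j]]$factors)
    }, logical(1)))
    if (ok) hits <- hits + 1L
    ## greedy monotonicity: SSE non-increasing along the trace
    for (j in names(map$terms)) {
      tr <- map$terms[[j]]$trace
      if (nrow(tr) > 1) expect_true(all(diff(tr$sse) <= 1e-8))
    }
  }
  expect_gte(hits, 9L)
})

test_that("prediction is the linear evaluation, clipped into the parameter box", {
  co <- make_linear_cohort(20, seed = 77, noise_frac = 0.02)
  map <- fit_stepwise(co$panels, co$params)
  pan <- co$panels[3, ]
  pred <- predict_params(map, pan)
  ## independent dot-product oracle
  for (j in names(map$terms)) {
    tr <- map$terms[[j]]
    val <- tr$intercept + sum(tr$coefficients * unlist(pan)[tr$factors])
    val <- min(max(val, c(k0 = 1e-6, k1 = 1e-6, k2 = 1e-6, kn = 1e-6,
                          kd = 0)[j]), 1e6)
    expect_equal(unname(pred[[j]]), unname(val), tolerance = 1e-10)
  }
  ## panel at the training mean predicts the column means of the params
  pan_mean <- colMeans(co$panels)
  pred_mean <- predict_params(map, pan_mean)
  expect_equal(unclass(pred_mean), colMeans(as.matrix(co$params)),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("predicted curves inherit dead-time causality and gain limits", {
  map <- ground_truth_map()
  pan <- factor_panel(100, 100, 100, 100, 100, 100, 100, 100)
  cv <- predict_cat(map, pan)
  pp <- predict_params(map, pan)
  expect_true(all(cv$thrombin[cv$times < pp[["kd"]]] == 0))
  ## low factor IX raises the predicted dead time; curve stays zero longer
  pan2 <- factor_panel(100, 100, 100, 100, 20, 100, 100, 100)
  pp2 <- predict_params(map, pan2)
  expect_gt(pp2[["kd"]], pp[["kd"]])
})

test_that("percent error follows the printed formula", {
  expect_equal(percent_error(115, 100), 15)
  expect_equal(percent_error(100, 100), 0)
  expect_equal(percent_error(80, 100), 20)
  expect_error(percent_error(5, 0), "zero")
})

test_that("cross-validation partitions correctly and is seed-deterministic", {
  co <- make_linear_cohort(22, seed = 55)
  cv1 <- cross_validate(co$panels, params = co$params, k = 4, seed = 9)
  cv2 <- cross_validate(co$panels, params = co$params, k = 4, seed = 9)
  expect_identical(cv1$folds, cv2$folds)
  expect_identical(cv1$summary, cv2$summary)
  expect_true(max(table(cv1$folds)) - min(table(cv1$folds)) <= 1)
  ## leave-one-out: every fold has size 1
  loo <- cross_validate(co$panels, params = co$params, k = 22, seed = 1)
  expect_true(all(table(loo$folds) == 1))
  expect_error(cross_validate(co$panels, params = co$params, k = 23),
               "folds")
})

test_that("closed-loop CV on a noise-free linear cohort has sub-1% errors", {
  co <- make_linear_cohort(40, seed = 13)
  rep <- cross_validate(co$panels, params = co$params, k = 5, seed = 3)
  expect_true(all(rep$summary$mean_pct_error < 1))
})

test_that("CV errors shrink as parameter noise shrinks", {
  err_at <- function(noise) {
    mean(vapply(1:3, function(s) {
      co <- make_linear_cohort(30, seed = 200 + s, noise_frac = noise)
      mean(cross_validate(co$panels, params = co$params, k = 5,
                          seed = s)$summary$mean_pct_error)
    }, numeric(1)))
  }
  expect_lt(err_at(0.005), err_at(0.05))
})
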