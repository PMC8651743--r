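## Shared fixtures, built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

## Normal region built from 20 synthetic healthy donors at the default
## grid; expensive enough to share between test files.
fixture_region <- function() {
  if (is.null(.fixtures$region)) {
    h <- generate_healthy_cats(20, seed = 7)
    .fixtures$healthy <- h
    .fixtures$region <- build_normal_region(h$curves)
  }
  .fixtures$region
}

fixture_healthy <- function() {
  fixture_region()
  .fixtures$healthy
}

## The distinct-real-pole reference case: poles (-1, -2, -3), unit gain,
## whose impulse response is y(t) = e^{-t}/2 - e^{-2t} + e^{-3t}/2.
ref_params <- function(kd = 0) thrombin_params(6, 11, 6, 1, kd)

ref_closed_form <- function(t) {
  ifelse(t <= 0, 0, 0.5 * exp(-t) - exp(-2 * t) + 0.5 * exp(-3 * t))
}

## Random stable parameter sets: poles drawn negative-real or as a damped
## complex pair, assembled into cubic coefficients.
random_stable_params <- function(kn_range = c(10, 150), kd_range = c(0.5, 6)) {
  if (runif(1) < 0.5) {
    poles <- -runif(3, 0.1, 2)
  } else {
    re <- -runif(1, 0.1, 1.5)
    im <- runif(1, 0.05, 1)
    poles <- c(complex(real = re, imaginary = im),
               complex(real = re, imaginary = -im),
               -runif(1, 0.1, 2))
  }
  k2 <- -Re(sum(poles))
  k1 <- Re(poles[1] * poles[2] + poles[1] * poles[3] + poles[2] * poles[3])
  k0 <- -Re(prod(poles))
  thrombin_params(k0, k1, k2, runif(1, kn_range[1], kn_range[2]),
                  runif(1, kd_range[1], kd_range[2]))
}

## Canonical factor order, mirrored here for test bookkeeping.
FACTOR_NAMES <- c("fii", "fv", "fvii", "fviii", "fix", "fx", "atiii", "pc")
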