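fs <- 1000
t2s <- seq(0, 2, by = 1 / fs)

test_that("band-pass preserves mid-band and attenuates out-of-band tones", {
  spec <- filterSpec("butterworth", order = 5, bandHz = c(15, 30), fs = fs)
  mid <- bandpass(sin(2 * pi * 22 * t2s), spec, "causal")
  expect_equal(diff(range(mid[1001:2001])) / 2, 1, tolerance = 0.1)
  far <- bandpass(sin(2 * pi * 60 * t2s), spec, "causal")
  expect_lt(diff(range(far[1001:2001])) / 2, 0.1)
  expect_equal(bandpass(rep(0, 500), spec), rep(0, 500))
  expect_error(filterSpec("butterworth", 5, bandHz = c(15, 600), fs = fs),
               "Nyquist")
})

test_that("chebyshev ARV spec behaves like its analog design", {
  spec <- filterSpec("chebyshev1", order = 4, centerHz = 25, bandwidthHz = 8,
                     fs = fs)
  expect_equal(spec$bandHz, c(21, 29))
  y25 <- bandpass(sin(2 * pi * 25 * t2s), spec, "causal")
  expect_equal(diff(range(y25[1001:2001])) / 2, 1, tolerance = 0.12)
})

test_that("sliding peak-to-peak matches a brute-force window scan", {
  x <- c(rep(2, 50), 5 * (seq_len(150) %% 7) - 3)   # sawtooth-ish
  env <- slidingPeakToPeak(x, fs = 1000, windowMs = 20)
  brute <- vapply(seq_along(x), function(i) {
    w <- x[max(1, i - 19):i]; max(w) - min(w)
  }, numeric(1))
  expect_equal(env, brute)
  expect_equal(slidingPeakToPeak(rep(3, 100), 1000, 10), rep(0, 100))
  # sinusoid spanning at least one period: 2A
  tt <- seq(0, 1, by = 1e-3)
  env2 <- slidingPeakToPeak(4 * sin(2 * pi * 20 * tt), 1000, 100)
  expect_equal(max(env2), 8, tolerance = 1e-2)
})

test_that("beta ARV of an in-band sinusoid is 2A/pi per epoch", {
  spec <- filterSpec("chebyshev1", order = 4, centerHz = 25, bandwidthHz = 8,
                     fs = fs)
  A <- 2
  arv <- betaARV(A * sin(2 * pi * 25 * t2s), spec, epochMs = 100)
  expect_equal(nrow(arv), 20)
  # skip the filter transient epochs
  expect_equal(mean(arv$arv[10:20]), 2 * A / pi, tolerance = 0.1 * 2 * A / pi)
  dc <- betaARV(rep(5, 2001), spec, epochMs = 100)
  expect_lt(mean(dc$arv[10:20]), 0.01)
  expect_equal(betaARV(rep(0, 2001), spec)$arv, rep(0, 20))
})

test_that("MSE and power agree with a trapezoidal oracle and scale correctly", {
  set.seed(7)
  e <- rnorm(501)
  expect_equal(meanSquaredError(e, 0.01), trapzOracle(e^2, 0.01),
               tolerance = 1e-12)
  expect_equal(meanSquaredError(rep(0.3, 100), 0.1), 0.09)
  expect_equal(meanSquaredError(rep(0, 100), 0.1), 0)
  i <- abs(rnorm(501)); z <- runif(501, 0.4, 0.6)
  expect_equal(powerConsumption(i, z, 0.01), 1000 * trapzOracle(z * i^2, 0.01),
               tolerance = 1e-12)
  expect_equal(powerConsumption(rep(2, 100), 0.5, 0.1), 2000)
  expect_equal(powerConsumption(rep(2, 100), 1, 0.1),
               2 * powerConsumption(rep(2, 100), 0.5, 0.1))
  expect_equal(powerConsumption(rep(0, 100), 0.5, 0.1), 0)
  expect_error(powerConsumption(i, -z, 0.01), "non-negative")
})

test_that("metrics are stable under 2x resampling of the same signal", {
  f <- function(tt) sin(2 * pi * 3 * tt) + 0.2 * cos(2 * pi * 7 * tt)
  t1 <- seq(0, 1, by = 1e-3); t2 <- seq(0, 1, by = 5e-4)
  expect_equal(meanSquaredError(f(t1), 1e-3), meanSquaredError(f(t2), 5e-4),
               tolerance = 0.01)
  expect_equal(powerConsumption(abs(f(t1)), 0.5, 1e-3),
               powerConsumption(abs(f(t2)), 0.5, 5e-4), tolerance = 0.01)
})
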