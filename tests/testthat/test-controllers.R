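test_that("controller output follows the sign convention and gain", {
  prop <- controllerProportional(2)
  expect_equal(controllerOutput(prop, 2, 5), -10)
  expect_equal(controllerOutput(prop, 0, 123), 0)
  arv <- controllerARV(target = 0.1)
  expect_equal(controllerOutput(arv, 25, 1), 25)
  expect_equal(controllerOutput(controllerOff(), 3, 5), 0)
})

test_that("gain update matches the linear-ODE closed form", {
  sigma <- 0.1; tauTh <- 50; dt <- 0.001
  # zero drive: exponential decay at rate sigma / tauTheta
  th <- 1
  n <- 400 / dt
  for (i in seq_len(n)) th <- adaptiveGainStep(th, 0, sigma, tauTh, dt)
  expect_equal(th, exp(-sigma * 400 / tauTh), tolerance = 1e-6)
  # the half-life is (tauTheta / sigma) * log(2)
  expect_equal((tauTh / sigma) * log(2), 346.57, tolerance = 1e-3)
  # constant drive: convergence to drive / sigma, and exact invariance there
  expect_equal(adaptiveGainStep(5 / 0.1, 5, 0.1, 50, 0.01), 50)
  th <- 0
  for (i in seq_len(n)) th <- adaptiveGainStep(th, 5, sigma, tauTh, dt)
  expect_equal(th, (5 / sigma) * (1 - exp(-sigma * 400 / tauTh)), tolerance = 1e-5)
})

test_that("gain is non-decreasing without leakage and never negative", {
  set.seed(42)
  th <- 0.5; prev <- th
  for (i in 1:1000) {
    th <- adaptiveGainStep(th, runif(1, 0, 3), sigma = 0, tauTheta = 50, dt = 0.1)
    expect_gte(th, prev)
    prev <- th
  }
  # heavy leakage with discretization undershoot clamps at zero
  expect_identical(adaptiveGainStep(0.01, 0, sigma = 5, tauTheta = 1, dt = 10), 0)
})

test_that("beta drive measures in-band peak-to-peak and rejects out-of-band", {
  fs <- 1000
  t <- seq(0, 2, by = 1 / fs)
  A <- 3
  expect_equal(betaDrive(A * sin(2 * pi * 20 * t), fs), 2 * A, tolerance = 0.1)
  expect_lt(betaDrive(A * sin(2 * pi * 50 * t), fs), 0.1 * 2 * A)
  expect_equal(betaDrive(rep(0, 2001), fs), 0)
  expect_error(betaDrive(rnorm(100), fs), "at least")
})

test_that("error drive is half-wave rectified", {
  expect_equal(errorDrive(0.2, 0.1), 0.1)
  expect_equal(errorDrive(0.05, 0.1), 0)
  expect_equal(errorDrive(0.1, 0.1), 0)
  expect_equal(errorDrive(0.2, 0.1, normalized = TRUE), 1)
})

test_that("the analytic gain bound follows the printed formula", {
  expect_equal(thetaStarBound(c12 = 0, c21 = 5, c22 = 0.5, c11 = 0)$bound,
               0)
  # endogenous-regime couplings: 8 * (4 * 100 * 9 / 0.01)
  expect_equal(thetaStarBound(c12 = 3, c21 = 10, c22 = 0.9)$bound, 2880000)
  expect_equal(thetaStarBound(c12 = 0, c21 = 7, c22 = 0.3, c11 = 2)$bound, 32)
  # diverges monotonically as c22 -> 1
  bs <- vapply(c(0.9, 0.99, 0.999), function(cc)
    thetaStarBound(3, 10, cc)$bound, numeric(1))
  expect_true(all(diff(bs) > 0))
  expect_error(thetaStarBound(3, 10, 1), "undefined")
})

test_that("gain stays nonnegative along adaptive simulations", {
  p <- loopPreset("endogenous")
  h <- perturbedHistory(p, 27)
  for (mode in c("adaptive_abs", "adaptive_beta")) {
    tr <- simulateLoop(p, inputConstant(27),
                       controller = controllerAdaptive(mode, tauTheta = 75,
                                                       sigma = 0.19),
                       duration = 1200, history = h)
    expect_true(all(tr$theta >= 0))
  }
})

test_that("without beta content the adaptive-beta gain decays to nothing", {
  # stable regime at constant input: no oscillation, so the biomarker is ~0
  p <- loopPreset("exogenous")
  ctrl <- controllerAdaptive("adaptive_beta", tauTheta = 50, sigma = 0.1,
                             theta0 = 1)
  tr <- simulateLoop(p, inputConstant(50), controller = ctrl, duration = 5000)
  expect_lt(tr$theta[nrow(tr)], 0.01 * 1)
})
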