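stn <- activationParams(M = 300, B = 17)
gpe <- activationParams(M = 400, B = 75)

test_that("activation at zero drive equals the baseline rate", {
  expect_equal(activation(stn, 0), 17)
  expect_equal(activation(gpe, 0), 75)
})

test_that("activation saturates at (0, a*M) and is strictly increasing", {
  expect_equal(activation(stn, 1e6), 300, tolerance = 1e-12)
  expect_equal(activation(stn, -1e6), 0, tolerance = 1e-12)
  x <- seq(-2000, 2000, length.out = 400)
  v <- activation(gpe, x)
  expect_true(all(diff(v) > 0))
  expect_true(all(v > 0 & v < 400))
  # overflow-safe far into the tails
  expect_true(is.finite(activation(stn, -1e8)))
})

test_that("maximum slope is the output scale", {
  expect_equal(activationMaxSlope(stn), 1, tolerance = 1e-6)
  expect_equal(activationMaxSlope(gpe), 1, tolerance = 1e-6)
  expect_equal(activationMaxSlope(activationParams(400, 75, a = 1.29)), 1.29,
               tolerance = 1e-6)
  # scaling the output scales the slope linearly
  expect_equal(activationMaxSlope(activationParams(300, 17, a = 3)) /
                 activationMaxSlope(stn), 3, tolerance = 1e-6)
})

test_that("shifted activation vanishes at zero and keeps slope and monotonicity", {
  f <- shiftActivation(stn, 12.3)
  expect_equal(f(0), 0)
  y <- seq(-300, 300, length.out = 200)
  expect_true(all(diff(f(y)) > 0))
  # numeric max slope unchanged by the shift
  h <- 1e-4
  slopes <- (f(y + h) - f(y - h)) / (2 * h)
  expect_equal(max(slopes), activationMaxSlope(stn), tolerance = 1e-4)
  f0 <- shiftActivation(stn, 0)
  expect_equal(f0(5), activation(stn, 5) - 17)
})

test_that("equilibria solve the fixed-point equations to tight residual", {
  # decoupled loop: equilibrium at the baselines
  p0 <- loopParams(c12 = 0, c21 = 0, c22 = 0, b1 = 0, b2 = 0)
  eq0 <- findEquilibrium(p0, 10, 10)
  expect_equal(eq0$x1, 17, tolerance = 1e-9)
  expect_equal(eq0$x2, 75, tolerance = 1e-9)

  for (regime in c("endogenous", "exogenous")) {
    p <- loopPreset(regime)
    eq <- findEquilibrium(p, 27, 2)
    expect_lt(eq$residual, 1e-10)
    expect_equal(c(eq$x1, eq$x2), dampedEquilibriumOracle(p, 27, 2),
                 tolerance = 1e-7)
  }
})

test_that("the shifted system vanishes at the origin by construction", {
  p <- loopPreset("endogenous")
  eq <- findEquilibrium(p, 27, 2)
  q1 <- p$c11 * eq$x1 - p$c12 * eq$x2 + p$b1 * 27
  f1 <- shiftActivation(p$S1, q1)
  # at zero deviation the shifted STN equation has zero right-hand side
  expect_equal(-0 + f1(0), 0)
})

test_that("rates stay inside [0, a*M] along simulations from in-band histories", {
  p <- loopPreset("endogenous")
  tr <- simulateLoop(p, inputConstant(27), duration = 1500,
                     history = perturbedHistory(p, 27))
  expect_true(all(tr$x1 >= 0 & tr$x1 <= 300))
  expect_true(all(tr$x2 >= 0 & tr$x2 <= 400))
  ctrl <- controllerAdaptive("adaptive_abs", tauTheta = 75, sigma = 0.1)
  trc <- simulateLoop(p, inputConstant(27), controller = ctrl, duration = 1500,
                      history = perturbedHistory(p, 27))
  expect_true(all(trc$x1 >= 0 & trc$x1 <= 300))
  expect_true(all(trc$x2 >= 0 & trc$x2 <= 400))
})

test_that("constant input with zero couplings gives a constant trajectory", {
  p0 <- loopParams(c12 = 0, c21 = 0, c22 = 0, b1 = 1, b2 = 1)
  tr <- simulateLoop(p0, inputConstant(5), u2 = inputConstant(3),
                     duration = 500)
  expect_lt(diff(range(tr$x1)), 1e-9)
  expect_lt(diff(range(tr$x2)), 1e-9)
})

test_that("sinusoidal cortical input entrains the stable loop at 10/20/30 Hz", {
  p <- loopPreset("exogenous")
  for (f in c(10, 20, 30)) {
    tr <- simulateLoop(p, inputSinusoid(f, 50, 10), duration = 4000)
    df <- dominantFrequency(tr$x1, fs = 1000 / attr(tr, "dt"), transientMs = 2000)
    expect_lt(abs(df - f), attr(df, "bin_hz") + 1e-9)
  }
})
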