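truthS2 <- activationParams(M = 400, B = 75, a = 1.29)

test_that("GPe steady state solves the self-consistency equation", {
  # no self-coupling: the steady state is the activation itself
  expect_equal(gpeSteadyState(truthS2, 0, 80), activation(truthS2, 80),
               tolerance = 1e-10)
  x <- gpeSteadyState(truthS2, 0.35, 100)
  expect_lt(abs(x - activation(truthS2, 100 + 0.35 * x)), 1e-10)
  # saturation for strong drive
  expect_equal(gpeSteadyState(truthS2, 0.35, 1e5), 1.29 * 400, tolerance = 1e-6)
})

test_that("GPe steady state agrees with long-run simulation of the relaxation", {
  # dynamic oracle: tau2 x2' = -x2 + S2(u + c22 x2(t - 4)) simulated to rest
  for (u in c(40, 120)) {
    sol <- integrateDDE(function(t, y, ylag, aux)
      (-y + activation(truthS2, u + 0.35 * ylag(4))) / 14,
      delays = 4, history = 50, config = integratorConfig(0.1, 800), nVars = 1)
    expect_equal(sol$states[nrow(sol$states), 1],
                 gpeSteadyState(truthS2, 0.35, u), tolerance = 1e-6)
  }
})

test_that("GPe steady state is monotone in drive and self-coupling", {
  us <- seq(0, 200, by = 25)
  xs <- vapply(us, function(u) gpeSteadyState(truthS2, 0.3, u), numeric(1))
  expect_true(all(diff(xs) > 0))
  cs <- seq(0, 0.6, by = 0.1)
  xc <- vapply(cs, function(cc) gpeSteadyState(truthS2, cc, 60), numeric(1))
  expect_true(all(diff(xc) > 0))
})

test_that("activation fit recovers known parameters", {
  pairs <- generateRatePairs(truthS2, c22 = 0, n = 60, uRange = c(0, 250),
                             noiseSd = 0, seed = 11)
  fit <- fitActivation(pairs)
  expect_lt(abs(fit$a - 1.29) / 1.29, 0.01)
  expect_lt(abs(fit$params$M - 400) / 400, 0.01)
  expect_lt(abs(fit$params$B - 75) / 75, 0.01)

  noisy <- generateRatePairs(truthS2, c22 = 0, n = 50, uRange = c(0, 250),
                             noiseSd = 0.05, seed = 12)
  fitn <- fitActivation(noisy)
  expect_lt(abs(fitn$a - 1.29) / 1.29, 0.10)
  expect_lt(abs(fitn$params$M - 400) / 400, 0.10)
  expect_error(fitActivation(ratePairs(c(1, 2, 3, 4), rep(5, 4))), "degenerate")
})

test_that("self-coupling estimation recovers the truth on the grid", {
  pairs <- generateRatePairs(truthS2, c22 = 0.35, n = 40, uRange = c(0, 250),
                             noiseSd = 0, seed = 21)
  est <- estimateC22(truthS2, pairs, grid = seq(0, 0.6, by = 0.01))
  expect_equal(est$c22, 0.35)
  expect_lt(est$nlsq, 1e-12)
  # nLSQ at the optimum is no larger than anywhere else on the grid
  expect_true(all(est$nlsq <= est$nlsqValues))

  pairs0 <- generateRatePairs(truthS2, c22 = 0, n = 40, uRange = c(0, 250),
                              noiseSd = 0, seed = 22)
  est0 <- estimateC22(truthS2, pairs0, grid = seq(0, 0.6, by = 0.01))
  expect_equal(est0$c22, 0)
  expect_lt(est0$nlsq, 1e-12)
})

test_that("estimation error shrinks with sample size under noise", {
  grid <- seq(0, 0.6, by = 0.01)
  rmse <- vapply(c(10, 100), function(n) {
    errs <- vapply(1:30, function(r) {
      pr <- generateRatePairs(truthS2, 0.35, n = n, uRange = c(0, 250),
                              noiseSd = 0.05, seed = 1000 + r)
      estimateC22(truthS2, pr, grid)$c22 - 0.35
    }, numeric(1))
    sqrt(mean(errs^2))
  }, numeric(1))
  expect_lt(rmse[2], rmse[1])
})

test_that("stabilizability margin follows c22 * l2", {
  chk <- stabilizabilityCheck(0.35, 1.29)
  expect_true(chk$satisfied)
  expect_equal(chk$margin, 1 - 0.35 * 1.29)
  expect_false(stabilizabilityCheck(1, 1)$satisfied)
  expect_true(stabilizabilityCheck(0, 99)$satisfied)
})
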