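pp <- plantParams()

test_that("plant ARV equals background without stimulation and saturates at the floor", {
  s <- plantStep(NULL, 0, pp, background = 0.5, zE = 0.5)
  expect_equal(s, 0.5)
  shuge <- plantStep(NULL, 1e6, pp, background = 0.5, zE = 0.5)
  expect_equal(shuge, 0.5 * pp$floorFrac, tolerance = 1e-6)
})

test_that("plant ARV decreases monotonically with stimulation current", {
  amps <- seq(0, 4, by = 0.25)
  arv <- vapply(amps, function(a) plantStep(NULL, a, pp, 0.5, 0.5), numeric(1))
  expect_true(all(diff(arv) < 0))
  # impedance growth weakens a fixed current's effect
  lowZ <- plantStep(NULL, 1, pp, 0.5, 0.5)
  highZ <- plantStep(NULL, 1, pp, 0.5, 2.5)
  expect_gt(highZ, lowZ)
})

test_that("scenario schedules follow their piecewise definitions", {
  for (nm in c("target_variation", "beta_variation", "impedance_variation")) {
    sc <- scenarioSpec(nm, pp)
    expect_equal(sc$durationS, 130)
  }
  sc1 <- scenarioSpec("target_variation", pp)
  expect_equal(sc1$target(c(5, 15, 45, 75, 105)), c(10, 0.2, 0.05, 0.15, 10))
  sc2 <- scenarioSpec("beta_variation", pp)
  expect_equal(sc2$target(50), 0.1)
  expect_equal(sc2$background(c(5, 15, 45, 75, 105)),
               c(pp$bgLow, pp$bgHigh, pp$bgLow, pp$bgHigh, pp$bgLow))
  sc3 <- scenarioSpec("impedance_variation", pp)
  expect_equal(sc3$impedance(c(0, 30, 80, 130)), c(0.5, 0.5, 1.5, 2.5))
})

test_that("scenario runs are reproducible and DBS-off normalizes to 100%", {
  sc <- scenarioSpec("target_variation", pp)
  off1 <- runScenario(sc, controllerOff(), seed = 3)
  off2 <- runScenario(sc, controllerOff(), seed = 3)
  expect_identical(off1$traces, off2$traces)
  expect_equal(off1$report$msePct, 100)
  expect_equal(off1$report$powerUw, 0)
  off3 <- runScenario(sc, controllerOff(), seed = 4)
  expect_false(identical(off1$traces$arv, off3$traces$arv))
})

test_that("self-tuning tracks constant-target intervals on the plant", {
  sc <- scenarioSpec("beta_variation", pp)
  st <- runScenario(sc, controllerARV(target = 0.1), seed = 5)
  tr <- st$traces
  # high-background periods, first 5 s of each interval excluded
  for (iv in list(c(15, 40), c(75, 100))) {
    i <- tr$t_s > iv[1] & tr$t_s <= iv[2]
    expect_lt(abs(mean(tr$arv[i]) - 0.1) / 0.1, 0.25)
  }
})

test_that("self-tuning beats low fixed gain on error and high fixed gain on power", {
  for (nm in c("target_variation", "beta_variation", "impedance_variation")) {
    sc <- scenarioSpec(nm, pp)
    st <- runScenario(sc, controllerARV(target = 0.1), seed = 7)
    lo <- runScenario(sc, controllerProportional(5, sign = "positive"), seed = 7)
    hi <- runScenario(sc, controllerProportional(40, sign = "positive"), seed = 7)
    expect_lt(st$report$msePct, lo$report$msePct)
    expect_lt(st$report$powerUw, hi$report$powerUw)
  }
})

test_that("gain grows through the impedance ramp and stimulation idles at high target", {
  sc <- scenarioSpec("impedance_variation", pp)
  st <- runScenario(sc, controllerARV(target = 0.1), seed = 9)
  tr <- st$traces
  blocks <- split(tr$theta[tr$t_s > 30], cut(tr$t_s[tr$t_s > 30], 4))
  expect_true(all(diff(vapply(blocks, mean, numeric(1))) > 0))

  sc1 <- scenarioSpec("target_variation", pp)
  st1 <- runScenario(sc1, controllerARV(target = 0.1), seed = 9)
  tr1 <- st1$traces
  # target 10 uV >> background: stimulation never engages initially
  # (the epoch ending exactly at 10 s already sees the next target segment)
  expect_equal(max(tr1$idbs_ma[tr1$t_s < 10]), 0)
  # ...and winds down after the target returns high
  expect_lt(tr1$idbs_ma[nrow(tr1)], 0.1 * max(tr1$idbs_ma))
})
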