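test_that("dataset validity catches malformed records", {
  expect_error(survivalDataset(numeric(0), integer(0)), "at least one")
  expect_error(survivalDataset(c(1, -2), c(1, 1)), "positive")
  expect_error(survivalDataset(c(1, 2), c(1, 2)), "0 or 1")
  expect_error(survivalDataset(c(1, 2), c(1, 1),
                               sampleId = c("a", "a")), "unique")
  ds <- survivalDataset(c(1, 2), c(1, 0), label = c(1, 0))
  expect_identical(diseaseLabels(ds), c(1L, 0L))
  expect_identical(nSamples(ds[2]), 1L)
  expect_equal(survTimes(ds[2]), 2)
})

test_that("risk sets use the inclusive convention and handle ties", {
  ds <- survivalDataset(c(1, 2, 3), c(1, 1, 1))
  expect_equal(as.integer(riskSet(ds, 2)), c(2L, 3L))
  expect_length(riskSet(ds, 10), 0)
  tied <- survivalDataset(c(5, 5, 1), c(1, 1, 1))
  expect_equal(as.integer(riskSet(tied, 5)), c(1L, 2L))
  expect_error(riskSet(ds, -1), "positive")
})

test_that("Breslow increments match hand computation", {
  ds <- survivalDataset(c(1, 2, 3), c(1, 1, 1))
  bh <- breslowEstimator(ds, c(0, 0, 0))
  expect_equal(hazardIncrements(bh), c(1 / 3, 1 / 2, 1))
  expect_equal(cumulativeHazard(bh, 2.5), 1 / 3 + 1 / 2)

  cens <- survivalDataset(c(1, 2, 3), c(1, 0, 1))
  bh2 <- breslowEstimator(cens, c(0, 0, 0))
  expect_equal(hazardTimes(bh2), c(1, 3))
  expect_equal(hazardIncrements(bh2), c(1 / 3, 1))
  expect_equal(cumulativeHazard(bh2, 3), 4 / 3)

  none <- breslowEstimator(survivalDataset(c(1, 2), c(0, 0)), c(0, 0))
  expect_equal(cumulativeHazard(none, c(0, 5, 100)), c(0, 0, 0))
})

test_that("Breslow at zero scores equals Nelson-Aalen on random data", {
  skip_if_not_installed("survival")
  for (seed in 1:5) {
    ds <- randomDataset(sample(5:20, 1), censorProb = 0.3, seed = seed,
                        withTies = seed %% 2 == 0)
    bh <- breslowEstimator(ds, numeric(nSamples(ds)))
    sf <- survival::survfit(
      survival::Surv(survTimes(ds), eventStatus(ds)) ~ 1, ctype = 1)
    expect_equal(cumulativeHazard(bh, sf$time), sf$cumhaz,
                 tolerance = 1e-12)
  }
})

test_that("Breslow increments scale by exp(-c) under score shifts", {
  ds <- randomDataset(15, seed = 3)
  f <- rnorm(15)
  b0 <- breslowEstimator(ds, f)
  b1 <- breslowEstimator(ds, f + 2)
  expect_equal(hazardIncrements(b1),
               hazardIncrements(b0) * exp(-2), tolerance = 1e-12)
})

test_that("full negative log-likelihood matches hand values", {
  expect_equal(fullNegLogLik(survivalDataset(c(1, 2), c(1, 1)), c(0, 0)),
               1.5)
  expect_equal(fullNegLogLik(survivalDataset(c(1, 2), c(1, 0)),
                             c(log(2), 0)),
               -((log(2) - 2) + (-2)) / 2, tolerance = 1e-12)
  ## censored-only: exposure terms remain
  expect_equal(fullNegLogLik(survivalDataset(c(1, 2), c(0, 0)), c(0, 0)),
               1.5)
})

test_that("discrete-baseline likelihood errors on events off the jump set", {
  ds <- survivalDataset(c(1, 2), c(1, 1))
  bh <- baselineHazard(1, 0.5)    # no hazard increment at t = 2
  expect_error(fullNegLogLik(ds, c(0, 0), bh), "zero baseline")
  ## consistent when the baseline is the Breslow fit of the same data
  bfull <- breslowEstimator(ds, c(0, 0))
  expect_silent(fullNegLogLik(ds, c(0, 0), bfull))
})

test_that("predicted survival follows the closed form and is monotone", {
  expect_equal(predictSurvival(baselineHazard(5, 1), 0, 1), 1.0)
  expect_equal(predictSurvival(baselineHazard(0.5, 1), 0, 1), exp(-1))
  expect_equal(predictSurvival(baselineHazard(0.5, 0.5), log(2), 1),
               exp(-1))
  ds <- randomDataset(30, seed = 7)
  bh <- breslowEstimator(ds, rnorm(30))
  tgrid <- seq(0, max(survTimes(ds)) + 1, length.out = 50)
  s <- predictSurvival(bh, 0.3, tgrid)
  expect_true(all(diff(s) <= 0))
  expect_true(all(s > 0 & s <= 1))
  ## non-increasing in the score as well
  expect_true(all(predictSurvival(bh, 1, tgrid) <=
                    predictSurvival(bh, 0, tgrid)))
})

test_that("survival tables round-trip through CSV", {
  ds <- survivalDataset(c(0.5, exp(1), 3), c(1, 0, 1), label = c(1, 0, 1),
                        sampleId = c("a", "b", "c"))
  path <- tempfile(fileext = ".csv")
  writeSurvivalTable(ds, path)
  back <- readSurvivalTable(path)
  expect_identical(survTimes(back), survTimes(ds))
  expect_identical(eventStatus(back), eventStatus(ds))
  expect_identical(diseaseLabels(back), diseaseLabels(ds))
  expect_identical(sampleIds(back), sampleIds(ds))
  expect_error(readSurvivalTable(writeHistory(data.frame(epoch = 1),
                                              tempfile())),
               "must have columns")
})
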