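test_that("exponential survival times match their class hazards", {
  spec <- simulationSpec(classLogHazards = c(0, 3), nTrain = 5000,
                         nTest = 5000, seed = 7)
  cls <- rep(1:2, each = 5000)
  tt <- simulateSurvivalTimes(spec, cls)
  ## unit-rate class: mean 1 within 3 standard errors
  expect_lt(abs(mean(tt[cls == 1]) - 1), 3 / sqrt(5000))
  ## phi = 3 class: mean exp(-3)
  expect_lt(abs(mean(tt[cls == 2]) - exp(-3)), 3 * exp(-3) / sqrt(5000))
  ## deterministic under the spec seed
  expect_identical(tt, simulateSurvivalTimes(spec, cls))
  expect_error(simulateSurvivalTimes(spec, c(1, 3)), "outside")
})

test_that("median censoring flips exactly half of the above-median records", {
  spec <- simulationSpec(nTrain = 100, nTest = 100, seed = 3)
  cls <- rep(1L, 100)
  tt <- simulateSurvivalTimes(simulationSpec(nTrain = 50, nTest = 50,
                                             seed = 3), cls)
  ds <- survivalDataset(tt, rep(1L, 100))
  out <- applyMedianCensoring(ds, cls, seed = 3)
  cens <- which(eventStatus(out) == 0L)
  expect_length(cens, 25)
  expect_true(all(survTimes(out)[cens] > median(survTimes(out))))
  ## times untouched
  expect_identical(survTimes(out), survTimes(ds))
  ## counting identity over several classes (cohort median, per-class
  ## selection)
  cls2 <- rep(1:3, c(40, 41, 19))
  ds2 <- survivalDataset(rexp(100) + 0.01, rep(1L, 100))
  out2 <- applyMedianCensoring(ds2, cls2, seed = 5)
  med <- median(ds2@time)
  expected <- sum(vapply(1:3, function(k) {
    floor(sum(ds2@time[cls2 == k] > med) / 2)
  }, numeric(1)))
  expect_equal(sum(eventStatus(out2) == 0L), expected)
  expect_true(all(survTimes(out2)[eventStatus(out2) == 0L] > med))
  ## tiny class left unmodified
  one <- survivalDataset(c(1, 2, 3), c(1, 1, 1))
  expect_equal(sum(eventStatus(
    applyMedianCensoring(one, c(1L, 2L, 2L), 1)) == 0L), 0)
  expect_error(applyMedianCensoring(out, cls, 1), "all-event")
})

test_that("two-class images are balanced, bounded and linearly separable", {
  skip_if_not_installed("glmnet")
  spec <- simulationSpec(nTrain = 600, nTest = 400, seed = 11)
  imgs <- makeTwoClassImages(spec)
  expect_identical(dim(imageArray(imgs)), c(28L, 28L, 1L, 1000L))
  px <- range(imageArray(imgs))
  expect_gte(px[1], 0)
  expect_lte(px[2], 1)
  ## balanced within binomial noise
  n1 <- sum(imgs@classId == 1L)
  expect_lt(abs(n1 - 500), 3 * sqrt(1000 * 0.25))
  expect_identical(sum(imgs@role == "train"), 600L)
  ## seeded reproducibility
  expect_identical(imageArray(makeTwoClassImages(spec)), imageArray(imgs))
  ## a plain linear classifier on flattened pixels reaches >= 99%
  X <- t(matrix(imageArray(imgs), 784, 1000))
  y <- imgs@classId - 1L
  tr <- imgs@role == "train"
  fit <- glmnet::glmnet(X[tr, ], y[tr], family = "binomial",
                        lambda = 0.01)
  pred <- predict(fit, X[!tr, ], type = "response") > 0.5
  expect_gte(mean(pred == y[!tr]), 0.99)
})

test_that("nodule images encode the size-graded hazard structure", {
  spec <- simulationSpec(censoringScheme = "nodule", nTrain = 300,
                         nTest = 100, seed = 13)
  sim <- makeNoduleImages(spec)
  imgs <- sim$images
  ds <- sim$dataset
  gt <- sim$groundTruth
  n <- 400
  expect_identical(dim(imageArray(imgs)), c(32L, 32L, 3L, 400L))
  cancer <- diseaseLabels(ds)
  ## equal-probability cancer assignment
  expect_lt(abs(mean(cancer) - 0.5), 3 * sqrt(0.25 / n))
  ## all non-cancer censored; about half of cancer censored
  expect_true(all(eventStatus(ds)[cancer == 0] == 0L))
  evFrac <- mean(eventStatus(ds)[cancer == 1])
  expect_lt(abs(evFrac - 0.5), 3 * sqrt(0.25 / sum(cancer)))
  ## every cancer image carries exactly two patches
  npatch <- vapply(imgs@ledger, function(l) sum(l$kind == "patch"),
                   numeric(1))
  expect_true(all(npatch[cancer == 1] == 2))
  expect_true(all(npatch[cancer == 0] == 0))
  ## size ordering: event cancer > censored cancer > benign-only
  ms <- gt$max_nodule_size
  ev <- eventStatus(ds) == 1L
  censCancer <- cancer == 1 & !ev
  expect_gt(mean(ms[ev]), mean(ms[censCancer]))
  expect_gt(mean(ms[censCancer]), mean(ms[cancer == 0]))
  expect_lte(max(ms[censCancer]), 8)
  expect_lte(max(ms[cancer == 0]), 2)
  ## ledger round trip is lossless
  path <- tempfile(fileext = ".csv")
  writeGroundTruthLedger(gt, path)
  back <- readGroundTruthLedger(path)
  expect_identical(back$time, gt$time)
  expect_identical(back$phi, gt$phi)
  expect_identical(back$sample_id, gt$sample_id)
  expect_identical(back$event, gt$event)
})

test_that("nodule survival times decrease stochastically with nodule size", {
  led <- function(s) data.frame(kind = "patch", x = 1, y = 1, size = s)
  expect_error(noduleSurvival(led(5)[0, ], 0.25, 1), "non-empty")
  ## closed-form mean exp(-scale * maxsize), checked by Monte Carlo
  means <- vapply(c(2, 8, 14), function(s) {
    mean(vapply(1:800, function(k) noduleSurvival(led(s), 0.25, k),
                numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
  expect_lt(abs(means[1] - exp(-0.5)), 4 * exp(-0.5) / sqrt(800))
  ## hazardScale = 0 gives a unit-rate exponential regardless of size
  m0 <- mean(vapply(1:800, function(k) noduleSurvival(led(14), 0, k),
                    numeric(1)))
  expect_lt(abs(m0 - 1), 4 / sqrt(800))
})

test_that("true-phi scorer attains the theoretical concordance", {
  spec <- simulationSpec(classLogHazards = c(0, 3), nTrain = 1000,
                         nTest = 1000, seed = 17)
  set.seed(99)
  cls <- rbinom(2000, 1, 0.5) + 1L
  tt <- simulateSurvivalTimes(spec, cls)
  ds <- survivalDataset(tt, rep(1L, 2000))
  f <- c(0, 3)[cls]
  emp <- as.numeric(concordanceIndex(ds, f))
  theo <- theoreticalCIndex(c(0, 3), sum(cls == 1), sum(cls == 2))
  expect_lt(abs(emp - theo), 0.02)
})

test_that("image sets round-trip through the array container", {
  skip_if_not_installed("arrow")
  spec <- simulationSpec(nTrain = 4, nTest = 2, seed = 23)
  imgs <- makeTwoClassImages(spec)
  path <- tempfile(fileext = ".parquet")
  writeImageSet(imgs, path)
  back <- readImageSet(path)
  expect_equal(imageArray(back), imageArray(imgs), tolerance = 0)
  expect_identical(sampleIds(back), sampleIds(imgs))
  expect_identical(back@classId, imgs@classId)
})
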