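test_that("full-batched loss matches hand-computed fixtures", {
  expect_equal(fullBatchedLoss(survivalDataset(c(1, 2), c(1, 1)), c(0, 0)),
               log(2) / 2, tolerance = 1e-12)
  expect_equal(fullBatchedLoss(survivalDataset(c(1, 2), c(1, 1)), c(1, 0)),
               -((1 - log(exp(1) + 1)) + 0) / 2, tolerance = 1e-12)
  ## only the last-surviving subject has an event: its risk set is itself
  expect_equal(fullBatchedLoss(survivalDataset(c(1, 2), c(0, 1)),
                               c(5, -3)), 0)
  ## no events at all
  expect_equal(fullBatchedLoss(survivalDataset(c(1, 2), c(0, 0)),
                               c(1, 2)), 0)
})

test_that("full-batched loss equals brute-force partial likelihood", {
  for (seed in 1:8) {
    n <- sample(2:6, 1)
    ds <- randomDataset(n, censorProb = 0.3, seed = seed,
                        withTies = seed %% 2 == 0)
    f <- rnorm(n)
    expect_equal(fullBatchedLoss(ds, f),
                 bruteForcePartialNll(survTimes(ds), eventStatus(ds), f),
                 tolerance = 1e-12)
  }
})

test_that("mini-batched loss over the full batch equals full-batched", {
  ds <- randomDataset(40, seed = 2)
  f <- rnorm(40)
  expect_identical(miniBatchedLoss(ds, f, 1:40), fullBatchedLoss(ds, f))
})

test_that("mini-batched loss restricts risk sets to the batch", {
  ds <- survivalDataset(c(10, 1, 2, 0.5), c(1, 1, 1, 1))
  f <- c(9, 0, 0, 9)
  ## batch {2,3} has within-batch times (1,2), both events, scores (0,0)
  expect_equal(miniBatchedLoss(ds, f, c(2L, 3L)), log(2) / 2,
               tolerance = 1e-12)
  ## all-censored batch contributes nothing
  cens <- survivalDataset(c(1, 2, 3), c(0, 0, 1))
  expect_equal(miniBatchedLoss(cens, rnorm(3), 1:2), 0)
  expect_error(miniBatchedLoss(ds, f, 2L), "at least 2")
  expect_error(miniBatchedLoss(ds, f, c(1L, 1L)), "unique")
})

test_that("oracle loss matches hand values and its stationary point", {
  expect_equal(oracleLoss(survivalDataset(c(1, 2), c(1, 1)), c(0, 0)),
               1.5)
  expect_equal(oracleLoss(survivalDataset(c(1, 2), c(1, 0)),
                          c(log(2), 0)),
               fullNegLogLik(survivalDataset(c(1, 2), c(1, 0)),
                             c(log(2), 0)))
  ## single uncensored sample with T* = t is minimised at f = -log(t)
  for (tt in c(0.3, 1, 4)) {
    one <- survivalDataset(tt, 1L)
    opt <- optimize(function(f) oracleLoss(one, f), c(-10, 10))
    expect_equal(opt$minimum, -log(tt), tolerance = 1e-4)
  }
})

test_that("true loss is the oracle loss at the generative scores", {
  expect_equal(trueLoss(survivalDataset(c(1, 2), c(1, 1)), c(1, 1),
                        c(0, 3)), 1.5)
  ds <- randomDataset(25, seed = 9)
  cls <- rbinom(25, 1, 0.5) + 1L
  phi <- c(0, 3)
  expect_equal(trueLoss(ds, cls, phi), oracleLoss(ds, phi[cls]))
  spec <- simulationSpec(classLogHazards = phi, nTrain = 10, nTest = 10)
  expect_equal(trueLoss(ds, cls, spec), trueLoss(ds, cls, phi))
  expect_error(trueLoss(ds, rep(3L, 25), phi), "unknown")
})

test_that("binary cross-entropy and the two-task sum behave", {
  expect_equal(binaryCrossEntropy(c(0.5, 0.5), c(1, 0)), log(2))
  expect_lt(binaryCrossEntropy(c(1, 0), c(1, 0)), 1e-10)
  expect_equal(binaryCrossEntropy(sigmoidScore(0), 1), log(2))
  ds <- survivalDataset(c(1, 2), c(1, 1), label = c(1L, 0L))
  expect_equal(twoTaskLoss(ds, c(0, 0), 1:2), log(2) / 2 + log(2),
               tolerance = 1e-12)
  ## additivity on random batches
  big <- randomDataset(30, seed = 4)
  y <- rbinom(30, 1, 0.5)
  f <- rnorm(30)
  for (k in 1:4) {
    b <- sample(30, 10)
    expect_equal(twoTaskLoss(big, f, b, labels = y),
                 miniBatchedLoss(big, f, b) +
                   binaryCrossEntropy(sigmoidScore(f[b]), y[b]),
                 tolerance = 1e-12)
  }
  expect_error(twoTaskLoss(big, f, 1:5), "labels")
})

test_that("analytic loss gradients match central finite differences", {
  for (seed in 1:4) {
    n <- 12
    ds <- randomDataset(n, censorProb = 0.4, seed = seed,
                        withTies = seed %% 2 == 0)
    f <- rnorm(n)
    y <- rbinom(n, 1, 0.5)
    b <- sort(sample(n, 6))
    relErr <- function(a, g) max(abs(a - g)) / max(abs(g), 1e-8)
    expect_lt(relErr(fullBatchedLossGrad(ds, f),
                     numericGrad(function(z) fullBatchedLoss(ds, z), f)),
              1e-5)
    gm <- numeric(n)
    gm[b] <- miniBatchedLossGrad(ds, f, b)
    expect_lt(relErr(gm,
                     numericGrad(function(z) miniBatchedLoss(ds, z, b),
                                 f)), 1e-5)
    go <- numeric(n)
    go[b] <- oracleLossGrad(ds, f, b)
    expect_lt(relErr(go,
                     numericGrad(function(z) oracleLoss(ds, z, b), f)),
              1e-5)
    gt <- numeric(n)
    gt[b] <- twoTaskLossGrad(ds, f, b, labels = y)
    expect_lt(relErr(gt,
                     numericGrad(function(z)
                       twoTaskLoss(ds, z, b, labels = y), f)), 1e-5)
  }
})

test_that("score shifts leave the partial likelihood invariant but not the full", {
  ds <- randomDataset(20, seed = 5)
  f <- rnorm(20)
  expect_equal(fullBatchedLoss(ds, f + 3), fullBatchedLoss(ds, f),
               tolerance = 1e-10)
  expect_gt(abs(oracleLoss(ds, f + 3) - oracleLoss(ds, f)), 0.1)
})

test_that("epoch batch partitions are disjoint, exhaustive and merge singletons", {
  set.seed(1)
  for (n in c(7, 64, 129, 130)) {
    b <- makeBatches(n, 64L)
    expect_setequal(unlist(b), seq_len(n))
    expect_equal(sum(lengths(b)), n)
    expect_true(all(lengths(b) >= 2))
  }
  expect_error(makeBatches(10, 1L), "at least 2")
})
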