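## Training loop and experiment drivers. Optimisation is plain stochastic
## gradient descent with momentum over random disjoint batch partitions of
## each epoch. For the full-batched objectives the gradient of one epoch
## is the exact full-data gradient, computed in two passes (a cache-free
## forward for the scores, then chunked forward/backward for parameter
## gradients) and applied as a single update -- which is what makes the
## mini-batched loss settle in fewer epochs. Everything is seeded: data,
## initialisation, batch order and evaluation.

#' Training configuration
#'
#' @param lossKind one of `"oracle"`, `"full_batched"`, `"mini_batched"`,
#'   `"two_task"` (mini-batched survival + cross-entropy) or
#'   `"two_task_full"` (full-batched survival + cross-entropy).
#' @param batchSize batch size (>= 2); ignored by the full-batched kinds.
#' @param epochs number of epochs.
#' @param learningRate SGD learning rate.
#' @param momentum SGD momentum coefficient.
#' @param optimizer `"sgd"` (momentum SGD) or `"adam"` (adaptive
#'   moments; the default for the full-batched kinds in the simulation
#'   drivers, where each epoch is one exact gradient step and
#'   per-parameter step scaling converges in far fewer steps).
#' @param seed integer seed controlling batch order (and, through the
#'   drivers, data generation and initialisation).
#' @param clipNorm clip each update's gradients to this global L2 norm
#'   (numerical safeguard against the occasional exploding mini-batch
#'   step; `Inf` disables clipping).
#' @param evalEvery evaluate test loss and metrics every this many epochs
#'   (the final epoch is always evaluated).
#' @return a `trainConfig` list.
#' @export
trainConfig <- function(lossKind = c("mini_batched", "oracle",
                                     "full_batched", "two_task",
                                     "two_task_full"),
                        batchSize = 64L, epochs = 30L,
                        learningRate = 0.01, momentum = 0.9, seed = 1L,
                        clipNorm = 5, optimizer = c("sgd", "adam"),
                        evalEvery = 1L) {
  lossKind <- match.arg(lossKind)
  optimizer <- match.arg(optimizer)
  if (batchSize < 2L) stop("batch size must be at least 2")
  structure(list(lossKind = lossKind, batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs),
                 learningRate = learningRate, momentum = momentum,
                 seed = as.integer(seed), clipNorm = clipNorm,
                 optimizer = optimizer,
                 evalEvery = as.integer(evalEvery)),
            class = "trainConfig")
}

## chunked forward pass without caches; returns the score vector
forwardScores <- function(net, x, chunk = 256L) {
  d <- dim(x)
  nd <- length(d)
  N <- d[nd]
  out <- numeric(N)
  idx <- rep(list(quote(expr = )), nd)
  for (s in seq(1L, N, by = chunk)) {
    e <- min(N, s + chunk - 1L)
    idx[[nd]] <- s:e
    xb <- do.call(`[`, c(list(x), idx, list(drop = FALSE)))
    out[s:e] <- networkForward(net, xb)$output
  }
  out
}

sliceSamples <- function(x, i) {
  d <- dim(x)
  nd <- length(d)
  idx <- rep(list(quote(expr = )), nd)
  idx[[nd]] <- i
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

sgdStep <- function(params, velocity, grads, lr, mom, clipNorm = Inf) {
  if (is.finite(clipNorm)) {
    gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), numeric(1))))
    if (gn > clipNorm)
      grads <- lapply(grads, function(g) g * (clipNorm / gn))
  }
  for (nm in names(grads)) {
    velocity[[nm]] <- mom * velocity[[nm]] - lr * grads[[nm]]
    params[[nm]] <- params[[nm]] + velocity[[nm]]
  }
  list(params = params, velocity = velocity)
}

adamStep <- function(params, state, grads, lr, step,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  if (is.null(state))
    state <- list(m = lapply(grads, function(g) g * 0),
                  v = lapply(grads, function(g) g * 0))
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mh <- state$m[[nm]] / (1 - beta1^step)
    vh <- state$v[[nm]] / (1 - beta2^step)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

## survival + optional classification gradient w.r.t. the scores of one
## batch, given that batch's times / events / labels
batchLossAndGrad <- function(lossKind, f, tt, dd, yy) {
  m <- length(f)
  if (lossKind == "oracle") {
    loss <- -mean(dd * f - exp(f) * tt)
    grad <- -(dd - exp(f) * tt) / m
  } else {
    r <- coxPartialCore(tt, dd, f, wantGrad = TRUE)
    loss <- r$loss
    grad <- r$grad
    if (lossKind %in% c("two_task", "two_task_full")) {
      p <- sigmoidScore(f)
      pc <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      loss <- loss - mean(yy * log(pc) + (1 - yy) * log(1 - pc))
      grad <- grad + (p - yy) / m
    }
  }
  list(loss = loss, grad = grad)
}

#' Train a scoring network on image survival data
#'
#' Runs seeded SGD-with-momentum epochs of the configured loss. For the
#' mini-batched kinds each epoch randomly partitions the data into
#' disjoint batches and recomputes within-batch risk sets from the batch
#' members' observed times at every evaluation; for the full-batched
#' kinds each epoch applies one exact full-data gradient step. Batches
#' without events contribute nothing to the survival loss; their count is
#' reported as the `zeroEventBatches` element of the result.
#'
#' @param net an initialised [NetworkSpec-class].
#' @param images training images (array or [ImageSet-class]); when an
#'   `ImageSet` is given its sample ids must match the dataset's, in
#'   order.
#' @param dataset the training [SurvivalDataset-class].
#' @param config a [trainConfig()].
#' @param testImages,testDataset optional held-out data evaluated on the
#'   `evalEvery` schedule with the full-batched loss value of the same
#'   loss family plus concordance/AUC metrics.
#' @param subgroup optional logical/integer index into the test set
#'   defining the C2 subgroup.
#' @param verbose print one line per evaluated epoch.
#' @return a list with `net` (trained), `history` (one row per epoch:
#'   epoch, train_loss, test_loss, auc, c1, c2), `report` (the final
#'   [MetricReport-class], or NULL without test data) and
#'   `zeroEventBatches`.
#' @export
trainModel <- function(net, images, dataset, config, testImages = NULL,
                       testDataset = NULL, subgroup = NULL,
                       verbose = FALSE) {
  stopifnot(is(net, "NetworkSpec"), is(dataset, "SurvivalDataset"),
            inherits(config, "trainConfig"))
  if (is(images, "ImageSet")) {
    if (!identical(sampleIds(images), sampleIds(dataset)))
      stop("image and survival sample ids are misaligned")
    images <- images@images
  }
  if (is(testImages, "ImageSet")) {
    if (!is.null(testDataset) &&
        !identical(sampleIds(testImages), sampleIds(testDataset)))
      stop("test image and survival sample ids are misaligned")
    testImages <- testImages@images
  }
  n <- nSamples(dataset)
  d <- dim(images)
  if (d[length(d)] != n)
    stop("number of images and survival records differ")
  lossKind <- config$lossKind
  needLabels <- lossKind %in% c("two_task", "two_task_full")
  yAll <- diseaseLabels(dataset)
  if (needLabels && anyNA(yAll))
    stop("the two-task losses require disease labels for every record")
  fullKind <- lossKind %in% c("full_batched", "two_task_full")
  tt <- survTimes(dataset)
  dd <- eventStatus(dataset)
  params <- net@parameters
  velocity <- lapply(params, function(p) p * 0)
  adamState <- NULL
  stepCount <- 0L
  set.seed(config$seed)
  hist <- data.frame(epoch = seq_len(config$epochs), train_loss = NA_real_,
                     test_loss = NA_real_, auc = NA_real_, c1 = NA_real_,
                     c2 = NA_real_)
  zeroEventBatches <- 0L
  report <- NULL
  lrFull <- config$learningRate
  prevLoss <- Inf
  prevParams <- NULL
  for (ep in seq_len(config$epochs)) {
    net@parameters <- params
    if (fullKind) {
      ## full-batch descent with a 3-epoch learning-rate warmup and a
      ## bold-driver safeguard: when the exact loss decreases the rate
      ## regrows gently (capped at its configured value); when it
      ## increases the last step is undone, the rate halved and the
      ## momentum restarted
      f <- forwardScores(net, images)
      bg <- batchLossAndGrad(lossKind, f, tt, dd, yAll)
      if (config$optimizer == "sgd") {
        if (bg$loss > prevLoss + 1e-12) {
          params <- prevParams
          net@parameters <- params
          velocity <- lapply(velocity, function(v) v * 0)
          lrFull <- lrFull / 2
          f <- forwardScores(net, images)
          bg <- batchLossAndGrad(lossKind, f, tt, dd, yAll)
        } else if (is.finite(prevLoss)) {
          lrFull <- min(lrFull * 1.1, config$learningRate)
        }
        prevLoss <- bg$loss
        prevParams <- params
      }
      ## second pass: chunked backward against the full-data score grad
      grads <- NULL
      for (s in seq(1L, n, by = 256L)) {
        e <- min(n, s + 255L)
        fw <- networkForward(net, sliceSamples(images, s:e),
                             keepCache = TRUE)
        g <- networkGradients(net, fw$caches, bg$grad[s:e])
        grads <- if (is.null(grads)) g else
          mapply(`+`, grads, g[names(grads)], SIMPLIFY = FALSE)
      }
      if (config$optimizer == "adam") {
        stepCount <- stepCount + 1L
        up <- adamStep(params, adamState, grads, config$learningRate,
                       stepCount)
        params <- up$params
        adamState <- up$state
      } else {
        up <- sgdStep(params, velocity, grads,
                      lrFull * min(1, ep / 3),
                      config$momentum, config$clipNorm)
        params <- up$params
        velocity <- up$velocity
      }
      hist$train_loss[ep] <- bg$loss
    } else {
      batches <- makeBatches(n, config$batchSize)
      lossSum <- 0
      for (b in batches) {
        net@parameters <- params
        fw <- networkForward(net, sliceSamples(images, b),
                             keepCache = TRUE)
        if (lossKind != "oracle" && !any(dd[b] == 1L))
          zeroEventBatches <- zeroEventBatches + 1L
        bg <- batchLossAndGrad(lossKind, fw$output, tt[b], dd[b], yAll[b])
        grads <- networkGradients(net, fw$caches, bg$grad)
        if (config$optimizer == "adam") {
          stepCount <- stepCount + 1L
          up <- adamStep(params, adamState, grads, config$learningRate,
                         stepCount)
          params <- up$params
          adamState <- up$state
        } else {
          up <- sgdStep(params, velocity, grads, config$learningRate,
                        config$momentum, config$clipNorm)
          params <- up$params
          velocity <- up$velocity
        }
        lossSum <- lossSum + bg$loss * length(b)
      }
      hist$train_loss[ep] <- lossSum / n
    }
    if (!is.null(testImages) && !is.null(testDataset) &&
        (ep %% config$evalEvery == 0L || ep == config$epochs)) {
      net@parameters <- params
      fTest <- forwardScores(net, testImages)
      evKind <- if (lossKind == "oracle") "oracle" else
        if (needLabels) "two_task_full" else "full_batched"
      hist$test_loss[ep] <- batchLossAndGrad(
        evKind, fTest, survTimes(testDataset), eventStatus(testDataset),
        diseaseLabels(testDataset))$loss
      yTest <- diseaseLabels(testDataset)
      report <- evaluateScores(testDataset, fTest, subgroup = subgroup,
                               labels = if (needLabels && !anyNA(yTest))
                                 yTest else NULL)
      hist$c1[ep] <- report@cIndexAll
      hist$c2[ep] <- report@cIndexSubgroup
      hist$auc[ep] <- report@auc
      if (verbose)
        message(sprintf(
          "epoch %d: train %.4f test %.4f c1 %.4f c2 %s auc %s", ep,
          hist$train_loss[ep], hist$test_loss[ep], hist$c1[ep],
          format(hist$c2[ep], digits = 4), format(hist$auc[ep],
                                                  digits = 4)))
    } else if (verbose) {
      message(sprintf("epoch %d: train %.4f", ep, hist$train_loss[ep]))
    }
  }
  net@parameters <- params
  list(net = net, history = hist, report = report,
       zeroEventBatches = zeroEventBatches)
}

## shared data generation for the two-class designs
twoClassStudy <- function(spec) {
  imgs <- makeTwoClassImages(spec)
  cls <- imgs@classId
  times <- simulateSurvivalTimes(spec, cls)
  ds <- survivalDataset(times, rep(1L, length(times)),
                        sampleId = sampleIds(imgs))
  if (spec@censoringScheme == "median_half")
    ds <- applyMedianCensoring(ds, cls, spec@seed)
  tr <- imgs@role == "train"
  list(spec = spec,
       train = list(images = imgs[which(tr)], dataset = ds[which(tr)],
                    classes = cls[tr]),
       test = list(images = imgs[which(!tr)], dataset = ds[which(!tr)],
                   classes = cls[!tr]))
}

runTwoClassSim <- function(censoringScheme, nTrain, nTest, phi, epochs,
                           batchSize, learningRate, fullLearningRate,
                           momentum, seed, losses, evalEvery, verbose) {
  spec <- simulationSpec(classLogHazards = phi,
                         censoringScheme = censoringScheme,
                         nTrain = nTrain, nTest = nTest, seed = seed)
  study <- twoClassStudy(spec)
  subgroup <- if (censoringScheme == "median_half")
    which(eventStatus(study$test$dataset) == 1L) else NULL
  reports <- list()
  histories <- list()
  for (k in seq_along(losses)) {
    lk <- losses[k]
    net <- buildSimNetAB(seed = deriveSeed(seed, 10L + k))
    full <- lk %in% c("full_batched", "two_task_full")
    cfg <- trainConfig(lossKind = lk, batchSize = batchSize,
                       epochs = epochs,
                       learningRate = if (full) fullLearningRate else
                         learningRate,
                       momentum = momentum,
                       seed = deriveSeed(seed, 20L + k),
                       evalEvery = evalEvery)
    res <- trainModel(net, study$train$images, study$train$dataset, cfg,
                      testImages = study$test$images,
                      testDataset = study$test$dataset,
                      subgroup = subgroup, verbose = verbose)
    reports[[lk]] <- res$report
    histories[[lk]] <- res$history
  }
  trueL <- trueLoss(study$test$dataset, study$test$classes, spec)
  list(reports = reports, histories = histories, trueLoss = trueL,
       spec = spec, study = study)
}

#' Run the uncensored two-class simulation (design A)
#'
#' Generates two-class images with exponential survival times (all
#' events), trains the reference CNN under each requested loss, and
#' reports the test concordance index per loss together with the true
#' loss of the generative model on the test set.
#'
#' @param nTrain,nTest sample sizes.
#' @param phi per-class log relative hazards.
#' @param epochs,batchSize,learningRate,momentum,evalEvery training
#'   settings (see [trainConfig()]).
#' @param fullLearningRate learning rate for the full-batched loss
#'   kinds: an epoch there is a single exact full-data gradient step
#'   (run with warmup and a bold-driver safeguard), which tolerates and
#'   needs a larger step than the stochastic regime.
#' @param seed master seed for data, initialisation and batching.
#' @param losses which losses to train.
#' @param verbose print per-epoch progress.
#' @return list with `reports` (a [MetricReport-class] per loss),
#'   `histories`, `trueLoss`, `spec` and the generated `study` data.
#' @export
runSimulationA <- function(nTrain = 10000L, nTest = 1000L, phi = c(0, 3),
                           epochs = 30L, batchSize = 64L,
                           learningRate = 0.01, fullLearningRate = 0.1,
                           momentum = 0.9, seed = 1L,
                           losses = c("oracle", "full_batched",
                                      "mini_batched"),
                           evalEvery = 1L, verbose = FALSE) {
  runTwoClassSim("none", nTrain, nTest, phi, epochs, batchSize,
                 learningRate, fullLearningRate, momentum, seed, losses,
                 evalEvery, verbose)
}

#' Run the censored two-class simulation (design B)
#'
#' As [runSimulationA()] but with median-based censoring applied within
#' each class (half of the records above the class median survival time
#' become censored, times unchanged). Reports C1 over all test pairs and
#' C2 restricted to event cases.
#'
#' @inheritParams runSimulationA
#' @export
runSimulationB <- function(nTrain = 10000L, nTest = 1000L, phi = c(0, 3),
                           epochs = 30L, batchSize = 64L,
                           learningRate = 0.01, fullLearningRate = 0.1,
                           momentum = 0.9, seed = 1L,
                           losses = c("oracle", "full_batched",
                                      "mini_batched"),
                           evalEvery = 1L, verbose = FALSE) {
  runTwoClassSim("median_half", nTrain, nTest, phi, epochs, batchSize,
                 learningRate, fullLearningRate, momentum, seed, losses,
                 evalEvery, verbose)
}

#' Run the nodule-image two-task simulation (design C)
#'
#' Generates nodule-style images (equal cancer / non-cancer probability,
#' two white patches for cancer cases, size-proportional log hazards,
#' 50 percent censoring within cancer, all non-cancer censored), trains
#' the nodule CNN with the two-task loss in the requested batch regimes,
#' and reports AUC, C1 (all samples) and C2 (cancer group).
#'
#' @inheritParams runSimulationA
#' @param hazardScale log relative hazard per pixel of largest nodule
#'   size.
#' @param fullEpochs epochs for the full-batched variant (it may need a
#'   few more exact gradient steps than the mini-batched variant needs
#'   epochs).
#' @export
runSimulationC <- function(nTrain = 10000L, nTest = 1000L, epochs = 30L,
                           batchSize = 64L, learningRate = 0.01,
                           fullLearningRate = 0.1,
                           momentum = 0.9, seed = 1L,
                           losses = c("two_task_full", "two_task"),
                           hazardScale = 0.25, fullEpochs = epochs,
                           evalEvery = 1L, verbose = FALSE) {
  spec <- simulationSpec(classLogHazards = c(0, 0),
                         censoringScheme = "nodule", nTrain = nTrain,
                         nTest = nTest, seed = seed)
  sim <- makeNoduleImages(spec, hazardScale = hazardScale)
  tr <- sim$images@role == "train"
  trainImgs <- sim$images[which(tr)]
  testImgs <- sim$images[which(!tr)]
  trainDs <- sim$dataset[which(tr)]
  testDs <- sim$dataset[which(!tr)]
  subgroup <- which(diseaseLabels(testDs) == 1L)
  reports <- list()
  histories <- list()
  for (k in seq_along(losses)) {
    lk <- losses[k]
    net <- buildSimNetC(seed = deriveSeed(seed, 30L + k))
    full <- lk == "two_task_full"
    cfg <- trainConfig(lossKind = lk, batchSize = batchSize,
                       epochs = if (full) fullEpochs else epochs,
                       learningRate = if (full) fullLearningRate else
                         learningRate,
                       momentum = momentum,
                       seed = deriveSeed(seed, 40L + k),
                       evalEvery = evalEvery)
    res <- trainModel(net, trainImgs, trainDs, cfg,
                      testImages = testImgs, testDataset = testDs,
                      subgroup = subgroup, verbose = verbose)
    reports[[lk]] <- res$report
    histories[[lk]] <- res$history
  }
  list(reports = reports, histories = histories, spec = spec,
       groundTruth = sim$groundTruth)
}

#' Write / read a training history as a metrics CSV
#'
#' Numeric values are serialised at full double precision so a reloaded
#' history reproduces the in-memory one exactly.
#'
#' @param history the history data frame of [trainModel()].
#' @param path file path.
#' @export
writeHistory <- function(history, path) {
  out <- history
  for (cn in names(out))
    if (is.double(out[[cn]]))
      out[[cn]] <- ifelse(is.na(out[[cn]]), "NA",
                          sprintf("%.17g", out[[cn]]))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeHistory
#' @export
readHistory <- function(path) {
  h <- read.csv(path, stringsAsFactors = FALSE)
  for (cn in c("train_loss", "test_loss", "auc", "c1", "c2"))
    if (cn %in% names(h)) h[[cn]] <- as.numeric(h[[cn]])
  h$epoch <- as.integer(h$epoch)
  h
}
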