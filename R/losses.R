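## Training losses defined directly on log relative-hazard scores, so they
## back-propagate through any differentiable scoring model: the partial
## likelihood in full-batched and mini-batched form, the oracle full
## likelihood for simulations with known unit baseline hazard, binary
## cross-entropy, and the two-task sum. Risk sets use the inclusive
## convention R(t) = {i : T*_i >= t}; tied event times share one
## denominator (Breslow handling). Log-sum-exp terms are max-shifted.

## Averaged negative log partial likelihood and its score gradient on a
## (sub)cohort; denominator is the cohort size, events only contribute.
coxPartialCore <- function(time, event, f, wantGrad = FALSE) {
  n <- length(time)
  if (!any(event == 1L)) {
    if (wantGrad) return(list(loss = 0, grad = numeric(n)))
    return(0)
  }
  ord <- order(time)
  ts <- time[ord]
  ds <- event[ord]
  fs <- f[ord]
  M <- max(fs)
  e <- exp(fs - M)
  suff <- rev(cumsum(rev(e)))            # sum over {j : T_j >= T_i}
  first <- match(ts, ts)                 # first index of each tie group
  lse <- log(suff[first]) + M
  loss <- -sum(ds * (fs - lse)) / n
  if (!wantGrad) return(loss)
  S <- suff[first] * exp(M)              # risk-set sums, shared within ties
  w <- ifelse(ds == 1L, 1 / S, 0)
  last <- findInterval(ts, ts)           # last index of each tie group
  cw <- cumsum(w)[last]                  # sum over events with T_i <= T_k
  gs <- -(ds - exp(fs) * cw) / n
  grad <- numeric(n)
  grad[ord] <- gs
  list(loss = loss, grad = grad)
}

checkScores <- function(scores, n) {
  if (length(scores) != n || any(!is.finite(scores)))
    stop("scores must be finite, one per record")
}

checkBatch <- function(batch, n, minSize = 2L) {
  batch <- as.integer(batch)
  if (anyDuplicated(batch) || any(batch < 1L) || any(batch > n))
    stop("batch indices must be unique and valid")
  if (length(batch) < minSize)
    stop("batch size must be at least ", minSize)
  batch
}

#' Full-batched partial-likelihood loss
#'
#' The averaged negative log partial likelihood
#' \deqn{-\frac{1}{n}\sum_i \delta_i\Big[f_i -
#'   \log\!\!\sum_{j \in R(T^*_i)} e^{f_j}\Big],}
#' the survival loss evaluated over the whole dataset with inclusive risk
#' sets. Invariant to adding a constant to all scores; a dataset without
#' events yields 0.
#'
#' @param dataset a [SurvivalDataset-class].
#' @param scores finite numeric, one per record.
#' @return scalar loss.
#' @examples
#' ds <- survivalDataset(c(1, 2), c(1, 1))
#' fullBatchedLoss(ds, c(0, 0))  # log(2) / 2
#' @export
fullBatchedLoss <- function(dataset, scores) {
  stopifnot(is(dataset, "SurvivalDataset"))
  checkScores(scores, nSamples(dataset))
  coxPartialCore(dataset@time, dataset@event, scores)
}

#' @rdname fullBatchedLoss
#' @return `fullBatchedLossGrad` returns the length-n gradient with
#'   respect to the scores.
#' @export
fullBatchedLossGrad <- function(dataset, scores) {
  stopifnot(is(dataset, "SurvivalDataset"))
  checkScores(scores, nSamples(dataset))
  coxPartialCore(dataset@time, dataset@event, scores, wantGrad = TRUE)$grad
}

#' Mini-batched partial-likelihood loss
#'
#' The same expression as [fullBatchedLoss()] but averaged over a batch
#' \eqn{\Omega} with every risk set intersected with \eqn{\Omega}. With
#' the batch equal to the full dataset it reproduces the full-batched loss
#' exactly. Batches may legitimately contain no events (the loss is then
#' 0); the batch size must be at least 2.
#'
#' @param dataset a [SurvivalDataset-class].
#' @param scores finite numeric, one per record of `dataset`.
#' @param batch integer indices forming the batch.
#' @return scalar loss.
#' @export
miniBatchedLoss <- function(dataset, scores, batch) {
  stopifnot(is(dataset, "SurvivalDataset"))
  n <- nSamples(dataset)
  checkScores(scores, n)
  batch <- checkBatch(batch, n)
  coxPartialCore(dataset@time[batch], dataset@event[batch], scores[batch])
}

#' @rdname miniBatchedLoss
#' @return `miniBatchedLossGrad` returns the gradient with respect to the
#'   batch members' scores, in batch order.
#' @export
miniBatchedLossGrad <- function(dataset, scores, batch) {
  stopifnot(is(dataset, "SurvivalDataset"))
  n <- nSamples(dataset)
  checkScores(scores, n)
  batch <- checkBatch(batch, n)
  coxPartialCore(dataset@time[batch], dataset@event[batch], scores[batch],
                 wantGrad = TRUE)$grad
}

#' Oracle loss (full likelihood with known unit baseline)
#'
#' When the generating baseline hazard is known to be
#' \eqn{\lambda_0(t) \equiv 1} (so \eqn{\Lambda_0(t) = t}), the averaged
#' negative full log-likelihood over a batch reduces to
#' \deqn{-\frac{1}{|\Omega|}\sum_{i\in\Omega}
#'   \big[\delta_i f_i - e^{f_i} T^*_i\big].}
#' Unlike the partial-likelihood losses it is not invariant to shifting
#' all scores, because it retains the absolute hazard scale.
#'
#' @inheritParams miniBatchedLoss
#' @param batch integer indices; defaults to the full dataset.
#' @return scalar loss.
#' @export
oracleLoss <- function(dataset, scores, batch = seq_len(nSamples(dataset))) {
  stopifnot(is(dataset, "SurvivalDataset"))
  n <- nSamples(dataset)
  checkScores(scores, n)
  batch <- checkBatch(batch, n, minSize = 1L)
  f <- scores[batch]
  -mean(dataset@event[batch] * f - exp(f) * dataset@time[batch])
}

#' @rdname oracleLoss
#' @export
oracleLossGrad <- function(dataset, scores,
                           batch = seq_len(nSamples(dataset))) {
  stopifnot(is(dataset, "SurvivalDataset"))
  n <- nSamples(dataset)
  checkScores(scores, n)
  batch <- checkBatch(batch, n, minSize = 1L)
  f <- scores[batch]
  -(dataset@event[batch] - exp(f) * dataset@time[batch]) / length(batch)
}

#' True loss of a simulation design
#'
#' The full negative log-likelihood evaluated at the generative ground
#' truth: each record's score is the true log relative hazard of its
#' class and the baseline hazard is the unit rate. Serves as the benchmark
#' floor that the oracle loss settles to during training. Identical to
#' [oracleLoss()] evaluated at the true scores.
#'
#' @param dataset a [SurvivalDataset-class].
#' @param classAssignments integer class index (1-based) per record.
#' @param spec a [SimulationSpec-class] or a numeric vector of per-class
#'   log relative hazards.
#' @return scalar loss.
#' @export
trueLoss <- function(dataset, classAssignments, spec) {
  stopifnot(is(dataset, "SurvivalDataset"))
  phi <- if (is(spec, "SimulationSpec")) spec@classLogHazards else spec
  cls <- as.integer(classAssignments)
  if (length(cls) != nSamples(dataset))
    stop("one class assignment per record is required")
  if (anyNA(cls) || any(cls < 1L) || any(cls > length(phi)))
    stop("record with unknown generating class")
  fullNegLogLik(dataset, phi[cls], baseline = "unit")
}

#' Sigmoid link from log relative hazard to disease probability
#'
#' @param f log relative hazards.
#' @return \eqn{P = 1 / (1 + e^{-f})}.
#' @export
sigmoidScore <- function(f) stats::plogis(f)

#' Binary cross-entropy
#'
#' \eqn{-\frac{1}{m}\sum_i [y_i \log P_i + (1-y_i)\log(1-P_i)]} with the
#' probabilities clamped to \eqn{[10^{-12}, 1-10^{-12}]} before taking
#' logs.
#'
#' @param probabilities predicted probabilities in (0, 1).
#' @param labels 0/1 labels.
#' @return scalar loss.
#' @export
binaryCrossEntropy <- function(probabilities, labels) {
  if (length(probabilities) != length(labels))
    stop("probabilities and labels must have equal length")
  if (anyNA(labels) || !all(labels %in% c(0, 1)))
    stop("labels must be 0 or 1")
  p <- pmin(pmax(probabilities, 1e-12), 1 - 1e-12)
  -mean(labels * log(p) + (1 - labels) * log(1 - p))
}

#' Two-task loss: classification plus survival
#'
#' The sum of the mini-batched partial-likelihood loss and binary
#' cross-entropy over the same batch, with the single network output used
#' twice: raw as the log relative hazard and through the sigmoid link as
#' the disease probability.
#'
#' @inheritParams miniBatchedLoss
#' @param labels 0/1 disease labels, one per record; defaults to the
#'   dataset's labels. Missing labels for batch members are an error.
#' @return scalar loss.
#' @export
twoTaskLoss <- function(dataset, scores, batch,
                        labels = diseaseLabels(dataset)) {
  stopifnot(is(dataset, "SurvivalDataset"))
  n <- nSamples(dataset)
  checkScores(scores, n)
  batch <- checkBatch(batch, n)
  y <- labels[batch]
  if (anyNA(y)) stop("disease labels are required for all batch members")
  miniBatchedLoss(dataset, scores, batch) +
    binaryCrossEntropy(sigmoidScore(scores[batch]), y)
}

#' @rdname twoTaskLoss
#' @return `twoTaskLossGrad` returns the gradient with respect to the
#'   batch members' scores, in batch order.
#' @export
twoTaskLossGrad <- function(dataset, scores, batch,
                            labels = diseaseLabels(dataset)) {
  stopifnot(is(dataset, "SurvivalDataset"))
  n <- nSamples(dataset)
  checkScores(scores, n)
  batch <- checkBatch(batch, n)
  y <- labels[batch]
  if (anyNA(y)) stop("disease labels are required for all batch members")
  miniBatchedLossGrad(dataset, scores, batch) +
    (sigmoidScore(scores[batch]) - y) / length(batch)
}

#' Random batch partition of an epoch
#'
#' Partitions `1:n` into disjoint batches by sampling without replacement,
#' so every sample contributes exactly once per epoch; a trailing batch of
#' size 1 is merged into its predecessor. Uses the current RNG state.
#'
#' @param n number of samples.
#' @param batchSize target batch size (>= 2).
#' @return list of integer index vectors.
#' @export
makeBatches <- function(n, batchSize) {
  if (batchSize < 2L) stop("batch size must be at least 2")
  perm <- sample.int(n)
  nb <- max(1L, ceiling(n / batchSize))
  grp <- rep(seq_len(nb), each = batchSize, length.out = n)
  batches <- split(perm, grp)
  k <- length(batches)
  if (k > 1L && length(batches[[k]]) == 1L) {
    batches[[k - 1L]] <- c(batches[[k - 1L]], batches[[k]])
    batches[[k]] <- NULL
  }
  unname(batches)
}
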