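#' Construct a SurvivalDataset
#'
#' @param time positive observed times.
#' @param event 0/1 event indicators (1 = event, 0 = censored).
#' @param label optional 0/1 disease labels.
#' @param sampleId optional unique identifiers; defaults to `s1, s2, ...`.
#' @return a [SurvivalDataset-class] object.
#' @examples
#' ds <- survivalDataset(time = c(1, 2, 3), event = c(1, 0, 1))
#' survTimes(ds)
#' @export
survivalDataset <- function(time, event, label = NULL, sampleId = NULL) {
  n <- length(time)
  if (is.null(sampleId)) sampleId <- paste0("s", seq_len(n))
  new("SurvivalDataset",
      time = as.numeric(time), event = as.integer(event),
      label = if (is.null(label)) integer(0) else as.integer(label),
      sampleId = as.character(sampleId))
}

#' @describeIn survivalDataset observed times accessor
#' @param x a `SurvivalDataset`.
#' @export
setMethod("survTimes", "SurvivalDataset", function(x) x@time)

#' @export
setMethod("eventStatus", "SurvivalDataset", function(x) x@event)

#' @export
setMethod("diseaseLabels", "SurvivalDataset", function(x) {
  if (length(x@label)) x@label else rep(NA_integer_, length(x@time))
})

#' @export
setMethod("sampleIds", "SurvivalDataset", function(x) x@sampleId)

#' @export
setMethod("nSamples", "SurvivalDataset", function(x) length(x@time))

hasLabels <- function(x) length(x@label) > 0L && !anyNA(x@label)

#' @export
setMethod("show", "SurvivalDataset", function(object) {
  n <- nSamples(object)
  cat("SurvivalDataset with", n, "records;",
      sum(object@event), "events,", sum(object@event == 0L), "censored\n")
  if (length(object@label))
    cat("  labelled:", sum(object@label == 1L, na.rm = TRUE), "positive\n")
  cat("  time range: [", format(min(object@time)), ",",
      format(max(object@time)), "]\n")
})

#' @export
setMethod("[", "SurvivalDataset", function(x, i, j, ..., drop = TRUE) {
  new("SurvivalDataset", time = x@time[i], event = x@event[i],
      label = if (length(x@label)) x@label[i] else integer(0),
      sampleId = x@sampleId[i])
})

#' Risk set at a time point
#'
#' Returns the indices of all records still at risk at time `t`, using the
#' inclusive convention \eqn{R(t) = \{i : T^*_i \ge t\}} of the classical
#' Cox partial likelihood, so that a subject contributes to the risk set at
#' its own observed time.
#'
#' @param dataset a [SurvivalDataset-class].
#' @param t positive anchor time.
#' @return integer vector of member indices with attribute `anchorTime`.
#' @examples
#' riskSet(survivalDataset(c(1, 2, 3), c(1, 1, 1)), 2)
#' @export
riskSet <- function(dataset, t) {
  stopifnot(is(dataset, "SurvivalDataset"))
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t <= 0)
    stop("t must be a single positive number")
  idx <- which(dataset@time >= t)
  attr(idx, "anchorTime") <- t
  idx
}

#' Breslow estimator of the cumulative baseline hazard
#'
#' Given log relative-hazard scores \eqn{f_k}, the increment at each
#' distinct event time \eqn{\tau_j} is
#' \eqn{d_j / \sum_{k \in R(\tau_j)} e^{f_k}}, where \eqn{d_j} counts the
#' events at \eqn{\tau_j} (ties share one denominator) and the risk set is
#' inclusive. With all scores zero this reduces to the Nelson-Aalen
#' estimator. A dataset without events yields the zero step function.
#'
#' @param dataset a [SurvivalDataset-class].
#' @param scores finite numeric scores, one per record.
#' @return a [BaselineHazard-class] object.
#' @export
breslowEstimator <- function(dataset, scores) {
  stopifnot(is(dataset, "SurvivalDataset"))
  n <- nSamples(dataset)
  if (length(scores) != n || any(!is.finite(scores)))
    stop("scores must be finite, one per record")
  ev <- dataset@event == 1L
  if (!any(ev))
    return(new("BaselineHazard", eventTimes = numeric(0),
               increments = numeric(0)))
  tau <- sort(unique(dataset@time[ev]))
  ef <- exp(scores)
  inc <- vapply(tau, function(tt) {
    sum(dataset@event[dataset@time == tt]) / sum(ef[dataset@time >= tt])
  }, numeric(1))
  new("BaselineHazard", eventTimes = tau, increments = inc)
}

#' Construct a BaselineHazard from jumps
#' @param eventTimes strictly increasing positive times.
#' @param increments non-negative increments.
#' @export
baselineHazard <- function(eventTimes, increments) {
  new("BaselineHazard", eventTimes = as.numeric(eventTimes),
      increments = as.numeric(increments))
}

#' @export
setMethod("hazardTimes", "BaselineHazard", function(x) x@eventTimes)

#' @export
setMethod("hazardIncrements", "BaselineHazard", function(x) x@increments)

#' @export
setMethod("cumulativeHazard", "BaselineHazard", function(x, t) {
  if (any(t < 0)) stop("t must be >= 0")
  if (!length(x@eventTimes)) return(rep(0, length(t)))
  cum <- c(0, cumsum(x@increments))
  cum[findInterval(t, x@eventTimes) + 1L]
})

#' @export
setMethod("show", "BaselineHazard", function(object) {
  k <- length(object@eventTimes)
  cat("BaselineHazard step function with", k, "jumps")
  if (k) cat("; Lambda0(max) =", format(sum(object@increments)))
  cat("\n")
})

## Hazard increment lambda0 at exact time points (piece-wise constant
## between event failure times; zero off the jump set).
baselineIncrementAt <- function(baseline, t) {
  idx <- match(t, baseline@eventTimes)
  out <- baseline@increments[idx]
  out[is.na(idx)] <- 0
  out
}

#' Full negative log-likelihood of the extended Cox model
#'
#' Evaluates
#' \deqn{-\frac{1}{n}\sum_i \{\delta_i [f_i + \log\lambda_0(T^*_i)]
#'       - \Lambda_0(T^*_i) e^{f_i}\}}
#' for a given baseline hazard. Pass `baseline = "unit"` for the oracle
#' setting \eqn{\lambda_0(t) \equiv 1} (so \eqn{\Lambda_0(t) = t} and
#' \eqn{\log\lambda_0 = 0}), the ground truth of the simulation designs.
#' With a step-function baseline, \eqn{\lambda_0(T^*_i)} is the increment
#' at the event time; an event at a time carrying zero baseline hazard is
#' an error (log of zero).
#'
#' @param dataset a [SurvivalDataset-class].
#' @param scores finite numeric scores, one per record.
#' @param baseline a [BaselineHazard-class] or the string `"unit"`.
#' @return the averaged negative log-likelihood (scalar).
#' @export
fullNegLogLik <- function(dataset, scores, baseline = "unit") {
  stopifnot(is(dataset, "SurvivalDataset"))
  n <- nSamples(dataset)
  if (length(scores) != n || any(!is.finite(scores)))
    stop("scores must be finite, one per record")
  tt <- dataset@time
  dd <- dataset@event
  if (identical(baseline, "unit")) {
    loglam <- rep(0, n)
    Lam <- tt
  } else {
    stopifnot(is(baseline, "BaselineHazard"))
    lam <- baselineIncrementAt(baseline, tt)
    if (any(dd == 1L & lam <= 0))
      stop("event observed at a time with zero baseline hazard increment")
    loglam <- ifelse(dd == 1L, log(pmax(lam, .Machine$double.xmin)), 0)
    Lam <- cumulativeHazard(baseline, tt)
  }
  -mean(dd * (scores + loglam) - Lam * exp(scores))
}

#' Predicted survival probability
#'
#' \eqn{S(t \mid x) = \exp(-\Lambda_0(t)\, e^{f(x)})}: non-increasing in
#' both `t` and the score.
#'
#' @param baseline a [BaselineHazard-class] or `"unit"`.
#' @param score log relative hazard (scalar).
#' @param t times (>= 0), vectorised.
#' @return survival probabilities in (0, 1].
#' @export
predictSurvival <- function(baseline, score, t) {
  stopifnot(length(score) == 1L, is.finite(score))
  if (any(t < 0)) stop("t must be >= 0")
  Lam <- if (identical(baseline, "unit")) t else cumulativeHazard(baseline, t)
  exp(-Lam * exp(score))
}

#' Read / write survival tables
#'
#' The on-disk survival table is a header-bearing CSV with columns
#' `sample_id`, `time`, `event` and optionally `label`.
#'
#' @param path file path.
#' @return `readSurvivalTable` returns a [SurvivalDataset-class].
#' @export
readSurvivalTable <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(tab)))
    stop("survival table must have columns sample_id, time, event")
  survivalDataset(time = tab$time, event = tab$event,
                  label = if ("label" %in% names(tab)) tab$label else NULL,
                  sampleId = tab$sample_id)
}

#' @rdname readSurvivalTable
#' @param dataset a [SurvivalDataset-class] to write.
#' @export
writeSurvivalTable <- function(dataset, path) {
  tab <- data.frame(sample_id = dataset@sampleId,
                    time = sprintf("%.17g", dataset@time),
                    event = dataset@event, stringsAsFactors = FALSE)
  if (length(dataset@label)) tab$label <- dataset@label
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
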