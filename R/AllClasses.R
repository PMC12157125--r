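#' @useDynLib coxcnn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rexp runif rnorm rbinom median sd quantile glm binomial predict coef
#' @importFrom utils read.csv write.csv head
NULL

#' SurvivalDataset: right-censored survival records
#'
#' Container for a cohort of right-censored survival observations. Each
#' record holds the observed time (the minimum of the event and censoring
#' times), the event indicator (1 = event observed, 0 = censored), an
#' optional binary disease label used by the two-task loss, and a unique
#' sample identifier.
#'
#' @slot time numeric, positive observed times (arbitrary units).
#' @slot event integer, 0/1 event indicators.
#' @slot label integer, 0/1 disease labels; length zero when unlabelled.
#' @slot sampleId character, unique identifiers.
#'
#' @seealso [survivalDataset()], [riskSet()], [breslowEstimator()]
#' @export
setClass("SurvivalDataset",
  representation(time = "numeric", event = "integer",
                 label = "integer", sampleId = "character"),
  validity = function(object) {
    n <- length(object@time)
    if (n < 1L) return("dataset must contain at least one record")
    if (any(!is.finite(object@time)) || any(object@time <= 0))
      return("all observed times must be positive and finite")
    if (length(object@event) != n) return("event length mismatch")
    if (any(is.na(object@event)) || !all(object@event %in% c(0L, 1L)))
      return("event indicators must be 0 or 1")
    if (length(object@label) > 0L) {
      if (length(object@label) != n) return("label length mismatch")
      if (!all(object@label[!is.na(object@label)] %in% c(0L, 1L)))
        return("labels must be 0, 1 or NA")
    }
    if (length(object@sampleId) != n) return("sampleId length mismatch")
    if (anyDuplicated(object@sampleId)) return("sample ids must be unique")
    TRUE
  })

#' BaselineHazard: step-function cumulative baseline hazard
#'
#' A non-decreasing, right-continuous step function \eqn{\Lambda_0(t)} with
#' \eqn{\Lambda_0(0)=0}, represented by its jump locations (the distinct
#' event times) and the hazard increments \eqn{\Delta\Lambda_0} at each.
#'
#' @slot eventTimes numeric, strictly increasing positive jump locations.
#' @slot increments numeric, non-negative increments at each jump.
#'
#' @seealso [breslowEstimator()], [cumulativeHazard()], [predictSurvival()]
#' @export
setClass("BaselineHazard",
  representation(eventTimes = "numeric", increments = "numeric"),
  validity = function(object) {
    if (length(object@eventTimes) != length(object@increments))
      return("eventTimes and increments must have equal length")
    if (length(object@eventTimes) > 0L) {
      if (any(object@eventTimes <= 0)) return("event times must be positive")
      if (is.unsorted(object@eventTimes, strictly = TRUE))
        return("event times must be strictly increasing")
      if (any(object@increments < 0)) return("increments must be >= 0")
    }
    TRUE
  })

#' SimulationSpec: ground truth of a synthetic survival-image study
#'
#' Describes the generative model behind a simulated benchmark: the
#' per-class log relative hazards \eqn{\phi_j}, the constant baseline rate
#' (1 by default, so survival times are exponential with rate
#' \eqn{\exp(\phi_j)}), the censoring scheme, the train/test sizes and the
#' master seed from which all per-stage random substreams are derived.
#'
#' @slot classLogHazards numeric, one log relative hazard per class.
#' @slot baselineRate positive numeric, constant baseline hazard.
#' @slot censoringScheme one of `"none"`, `"median_half"`, `"nodule"`.
#' @slot nTrain,nTest integer sample sizes.
#' @slot seed integer master seed.
#'
#' @export
setClass("SimulationSpec",
  representation(classLogHazards = "numeric", baselineRate = "numeric",
                 censoringScheme = "character", nTrain = "integer",
                 nTest = "integer", seed = "integer"),
  validity = function(object) {
    if (length(object@classLogHazards) < 1L ||
        any(!is.finite(object@classLogHazards)))
      return("classLogHazards must be finite")
    if (length(object@baselineRate) != 1L || object@baselineRate <= 0)
      return("baselineRate must be a single positive number")
    if (!object@censoringScheme %in% c("none", "median_half", "nodule"))
      return("unknown censoring scheme")
    if (object@nTrain < 1L || object@nTest < 1L)
      return("nTrain and nTest must be >= 1")
    TRUE
  })

#' ImageSet: a collection of image samples
#'
#' Images are stored as one numeric array whose last dimension indexes
#' samples; pixel values lie in \[0, 1\]. `classId` records the generating
#' class of each image (when known) and `ledger` optionally holds, for
#' nodule-style images, one data frame per sample describing every
#' synthetic dot and patch (kind, centre, size in pixels).
#'
#' @slot images numeric array, sample index last.
#' @slot sampleIds character identifiers.
#' @slot classId integer generating class per sample (1-based), or empty.
#' @slot role character `"train"`/`"test"` per sample, or empty.
#' @slot ledger list of per-sample nodule data frames, or empty.
#'
#' @export
setClass("ImageSet",
  representation(images = "array", sampleIds = "character",
                 classId = "integer", role = "character", ledger = "list"),
  validity = function(object) {
    d <- dim(object@images)
    n <- d[length(d)]
    if (length(object@sampleIds) != n) return("sampleIds length mismatch")
    if (anyDuplicated(object@sampleIds)) return("sample ids must be unique")
    if (length(object@classId) && length(object@classId) != n)
      return("classId length mismatch")
    if (length(object@role) && length(object@role) != n)
      return("role length mismatch")
    if (length(object@ledger) && length(object@ledger) != n)
      return("ledger length mismatch")
    rng <- range(object@images)
    if (rng[1] < 0 || rng[2] > 1)
      return("pixel values must lie in [0, 1]")
    TRUE
  })

#' NetworkSpec: a layered scoring network and its parameters
#'
#' An architecture description (ordered layer descriptors with kernel
#' counts, sizes, strides and paddings) together with its trainable
#' parameter container. Composing the declared layers over the declared
#' input shape yields the per-layer output sizes returned by
#' [shapeTrace()]; builders check this trace against their reference
#' architecture tables and fail naming the offending layer.
#'
#' @slot name character architecture name.
#' @slot inputShape integer, per-sample input dimensions.
#' @slot layers list of layer descriptors.
#' @slot parameters named list of numeric parameter arrays.
#' @slot outputDim integer output dimension (1 for hazard scorers).
#'
#' @seealso [buildSimNetAB()], [networkForward()], [shapeTrace()]
#' @export
setClass("NetworkSpec",
  representation(name = "character", inputShape = "integer",
                 layers = "list", parameters = "list",
                 outputDim = "integer"))

#' MetricReport: evaluation summary for one trained model
#'
#' @slot cIndexAll concordance index over all samples (C1).
#' @slot cIndexSubgroup concordance index over a subgroup (C2), or NA.
#' @slot auc classification ROC AUC, or NA.
#' @slot nPairsEvaluable number of evaluable pairs behind `cIndexAll`.
#'
#' @export
setClass("MetricReport",
  representation(cIndexAll = "numeric", cIndexSubgroup = "numeric",
                 auc = "numeric", nPairsEvaluable = "numeric"),
  validity = function(object) {
    ok <- function(x) length(x) == 1L && (is.na(x) || (x >= 0 && x <= 1))
    if (!ok(object@cIndexAll)) return("cIndexAll must be in [0,1]")
    if (!ok(object@cIndexSubgroup)) return("cIndexSubgroup must be in [0,1]")
    if (!ok(object@auc)) return("auc must be in [0,1]")
    if (object@nPairsEvaluable < 0) return("nPairsEvaluable must be >= 0")
    TRUE
  })
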