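#' @export
setGeneric("survTimes", function(x) standardGeneric("survTimes"))

#' @export
setGeneric("eventStatus", function(x) standardGeneric("eventStatus"))

#' @export
setGeneric("diseaseLabels", function(x) standardGeneric("diseaseLabels"))

#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @export
setGeneric("hazardTimes", function(x) standardGeneric("hazardTimes"))

#' @export
setGeneric("hazardIncrements", function(x) standardGeneric("hazardIncrements"))

#' Evaluate the cumulative baseline hazard
#'
#' @param x a [BaselineHazard-class] object.
#' @param t numeric vector of times (>= 0).
#' @return numeric vector of \eqn{\Lambda_0(t)} values.
#' @export
setGeneric("cumulativeHazard", function(x, t) standardGeneric("cumulativeHazard"))

#' @export
setGeneric("imageArray", function(x) standardGeneric("imageArray"))

#' Per-layer output sizes of a network
#'
#' @param x a [NetworkSpec-class].
#' @return a data frame with columns `layer`, `kernels`, `kernel`, `output`
#'   mirroring the architecture tables the builders reproduce.
#' @export
setGeneric("shapeTrace", function(x) standardGeneric("shapeTrace"))

#' Total number of trainable parameters
#' @param x a [NetworkSpec-class].
#' @export
setGeneric("parameterCount", function(x) standardGeneric("parameterCount"))
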