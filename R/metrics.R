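#' Concordance index for censored survival predictions
#'
#' Estimates the probability that, over a random comparable pair, the
#' predicted hazards are ordered inversely to the observed survival
#' times. A pair \eqn{(i, j)} is evaluable when \eqn{T^*_i > T^*_j} and
#' \eqn{\delta_j = 1}; it counts as concordant when \eqn{f_i < f_j}.
#' Censored-versus-censored pairs and pairs with equal observed times are
#' never evaluable. Under `tiePolicy = "half"` (default) tied scores
#' contribute 0.5, so uninformative constant predictions score 0.5; under
#' `"strict"` tied scores contribute 0.
#'
#' @param dataset a [SurvivalDataset-class].
#' @param scores finite numeric hazard scores, one per record.
#' @param tiePolicy `"half"` or `"strict"` handling of tied scores.
#' @return the concordance index in \[0, 1\], with the number of
#'   evaluable pairs as attribute `nPairs`.
#' @examples
#' ds <- survivalDataset(c(1, 2, 3), c(1, 1, 1))
#' concordanceIndex(ds, c(3, 2, 1))  # perfect ordering: 1
#' @export
concordanceIndex <- function(dataset, scores,
                             tiePolicy = c("half", "strict")) {
  stopifnot(is(dataset, "SurvivalDataset"))
  tiePolicy <- match.arg(tiePolicy)
  n <- nSamples(dataset)
  checkScores(scores, n)
  tieW <- if (tiePolicy == "half") 0.5 else 0
  tt <- dataset@time
  npairs <- 0
  conc <- 0
  for (j in which(dataset@event == 1L)) {
    sel <- tt > tt[j]
    m <- sum(sel)
    if (!m) next
    npairs <- npairs + m
    fi <- scores[sel]
    conc <- conc + sum(fi < scores[j]) + tieW * sum(fi == scores[j])
  }
  if (npairs == 0)
    stop("no evaluable pairs: need a pair with T_i > T_j and event at j")
  structure(conc / npairs, nPairs = npairs)
}

#' ROC AUC as a rank statistic
#'
#' The probability that a randomly chosen positive outranks a randomly
#' chosen negative, with tied predictions contributing 0.5 (the
#' Mann-Whitney form of the area under the ROC curve).
#'
#' @param probabilities predicted probabilities (any monotone score works).
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
rocAuc <- function(probabilities, labels) {
  if (length(probabilities) != length(labels))
    stop("probabilities and labels must have equal length")
  if (anyNA(labels) || !all(labels %in% c(0, 1)))
    stop("labels must be 0 or 1")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("both label classes must be present")
  r <- rank(probabilities)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Assemble a MetricReport
#'
#' Computes the all-sample concordance index C1, optionally a subgroup
#' concordance index C2 (the dataset and scores are restricted to the
#' subgroup before pair enumeration), and optionally the classification
#' AUC.
#'
#' @param dataset a [SurvivalDataset-class] (typically the test set).
#' @param scores hazard scores, one per record.
#' @param subgroup optional logical or integer index defining the C2
#'   subgroup (e.g. the cancer group, or the event cases).
#' @param labels optional 0/1 labels for the AUC (predicted probabilities
#'   are the sigmoid of the scores).
#' @param tiePolicy tie handling passed to [concordanceIndex()].
#' @return a [MetricReport-class].
#' @export
evaluateScores <- function(dataset, scores, subgroup = NULL, labels = NULL,
                           tiePolicy = "half") {
  c1 <- concordanceIndex(dataset, scores, tiePolicy)
  c2 <- NA_real_
  if (!is.null(subgroup)) {
    sub <- dataset[subgroup]
    c2 <- as.numeric(concordanceIndex(sub, scores[subgroup], tiePolicy))
  }
  auc <- if (is.null(labels)) NA_real_ else
    rocAuc(sigmoidScore(scores), labels)
  new("MetricReport", cIndexAll = as.numeric(c1), cIndexSubgroup = c2,
      auc = auc, nPairsEvaluable = attr(c1, "nPairs"))
}

#' @export
setMethod("show", "MetricReport", function(object) {
  cat("MetricReport\n")
  cat("  C-index (all samples):", format(object@cIndexAll, digits = 4),
      "over", object@nPairsEvaluable, "evaluable pairs\n")
  if (!is.na(object@cIndexSubgroup))
    cat("  C-index (subgroup):   ",
        format(object@cIndexSubgroup, digits = 4), "\n")
  if (!is.na(object@auc))
    cat("  AUC:                  ", format(object@auc, digits = 4), "\n")
})
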