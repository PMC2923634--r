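#' Clustering F-measure
#'
#' Reference-size-weighted best-match F-measure between two labelings of the
#' same events: for reference class i and result class j, precision is
#' `n_ij / |result j|` and recall `n_ij / |reference i|`; each reference
#' class contributes its best harmonic mean over result classes, weighted by
#' `|reference i| / n`. Ranges over [0, 1], reaching 1 exactly when the two
#' labelings are identical up to relabeling. Invariant to permutations of
#' result ids, but not symmetric in its two arguments (the weights follow
#' the reference).
#'
#' @param reference,result label vectors of equal length (any categorical
#'   coding).
#' @return numeric F-measure in [0, 1].
#' @export
fMeasure <- function(reference, result) {
  if (length(reference) != length(result))
    stop("'reference' and 'result' must have equal length")
  n <- length(reference)
  tab <- table(reference, result)
  refSizes <- rowSums(tab)
  resSizes <- colSums(tab)
  P <- sweep(tab, 2L, resSizes, "/")
  R <- tab / refSizes
  F1 <- 2 * P * R / (P + R)
  F1[!is.finite(F1)] <- 0
  sum(refSizes / n * apply(F1, 1L, max))
}

#' Sensitivity and specificity of a rare-population call
#'
#' Events whose result label equals `matchedResultLabel` are called positive;
#' events whose truth label equals `positiveTruthLabel` are truly positive.
#' Sensitivity is the fraction of truly positive events called positive
#' (TP / (TP + FN)); specificity is the fraction of truly negative events
#' called negative (TN / (TN + FP)).
#'
#' @param result integer label per event from a clustering run.
#' @param truth integer ground-truth label per event.
#' @param positiveTruthLabel truth label of the positive (rare) class.
#' @param matchedResultLabel result label treated as the positive call,
#'   typically from [matchRareComponent()].
#' @return named numeric vector `c(sensitivity, specificity)`.
#' @export
sensitivitySpecificity <- function(result, truth, positiveTruthLabel,
                                   matchedResultLabel) {
  if (length(result) != length(truth))
    stop("'result' and 'truth' must have equal length")
  pos <- truth == positiveTruthLabel
  if (!any(pos)) stop("positive class is empty")
  called <- result == matchedResultLabel
  tp <- sum(pos & called)
  fn <- sum(pos & !called)
  tn <- sum(!pos & !called)
  fp <- sum(!pos & called)
  c(sensitivity = tp / (tp + fn), specificity = tn / (tn + fp))
}

#' Match a rare population to a result component
#'
#' Returns the result label holding the largest number of positive-class
#' events; ties break on the smaller label. This automates what is done
#' manually when comparing gated rare populations with algorithm output.
#'
#' @inheritParams sensitivitySpecificity
#' @return single result label.
#' @export
matchRareComponent <- function(result, truth, positiveTruthLabel) {
  if (length(result) != length(truth))
    stop("'result' and 'truth' must have equal length")
  pos <- result[truth == positiveTruthLabel]
  if (!length(pos)) stop("positive class is empty")
  tab <- table(pos)
  cand <- as.integer(names(tab)[tab == max(tab)])
  min(cand)
}
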