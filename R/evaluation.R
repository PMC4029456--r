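#' Seeded fold assignment
#'
#' Disjoint, exhaustive folds of size floor(n/k) or ceiling(n/k) from a
#' seeded shuffle; with \code{stratified = TRUE} each class is shuffled and
#' dealt round-robin so fold class ratios match the data.
#'
#' @param n number of rows.
#' @param k folds (must satisfy k <= n).
#' @param seed shuffle seed.
#' @param stratified balance classes across folds.
#' @param labels class labels, required when \code{stratified}.
#' @return list of k integer index vectors partitioning \code{1:n}.
#' @export
makeFolds <- function(n, k, seed = 1L, stratified = FALSE, labels = NULL) {
  if (k > n) stop("'k' must not exceed the number of rows")
  if (k < 2L) stop("'k' must be >= 2")
  withSeed(seed, {
    if (stratified) {
      if (is.null(labels) || length(labels) != n)
        stop("stratified folds require per-row labels")
      fold <- integer(n)
      offset <- 0L
      for (cl in unique(labels)) {
        idx <- sample(which(labels == cl))
        fold[idx] <- ((seq_along(idx) + offset - 1L) %% k) + 1L
        offset <- offset + length(idx)
      }
    } else {
      sizes <- rep(floor(n / k), k) + (seq_len(k) <= n %% k)
      fold <- integer(n)
      fold[sample(n)] <- rep(seq_len(k), times = sizes)
    }
    unname(split(seq_len(n), fold))
  })
}

#' ROC area under the curve
#'
#' Mann-Whitney formulation: the probability that a random positive outscores
#' a random negative, with ties counted 1/2 (midranks).  Invariant under any
#' strictly monotone transform of the scores.
#'
#' @param scores numeric scores, higher = more likely positive.
#' @param labels labels coercible to negative/positive.
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
  y <- labelBinary(labelFactor(labels))
  np <- sum(y == 1L)
  nn <- sum(y == 0L)
  if (np == 0L || nn == 0L)
    stop("both classes must be present to compute an AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - np * (np + 1) / 2) / (np * nn)
}

#' Classification error at a threshold
#'
#' Fraction of rows whose thresholded score (strictly greater than
#' \code{threshold} = positive) disagrees with the label.
#'
#' @param scores numeric scores.
#' @param labels labels coercible to negative/positive.
#' @param threshold decision threshold (see
#'   \code{\link[=decisionThreshold,RFModel-method]{decisionThreshold}}).
#' @return error fraction in [0, 1].
#' @export
classificationError <- function(scores, labels, threshold = 0.5) {
  y <- labelBinary(labelFactor(labels))
  mean(as.integer(scores > threshold) != y)
}

#' Cross-validate a classifier
#'
#' Standard setup: train on k-1 folds, test on the held-out fold, k times.
#' Reversed setup (\code{cv@reversed}): train on a single fold and test on
#' the other k-1, probing sensitivity to training-set size.  A training
#' split containing a single class is skipped with a warning and recorded as
#' NA.  Reports per-fold AUC and classification error.
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @param data an \linkS4class{EnhancerFeatureSet}.
#' @param cv a \linkS4class{CVSpec}.
#' @return a \linkS4class{CVResult}.
#' @export
crossValidate <- function(spec, data, cv = cvSpec()) {
  n <- nrow(data)
  labels <- regionLabels(data)
  folds <- makeFolds(n, cv@k, cv@seed, cv@stratified, labels)
  auc <- err <- rep(NA_real_, cv@k)
  for (i in seq_along(folds)) {
    if (cv@reversed) {
      trainIdx <- folds[[i]]
      testIdx <- setdiff(seq_len(n), folds[[i]])
    } else {
      testIdx <- folds[[i]]
      trainIdx <- setdiff(seq_len(n), folds[[i]])
    }
    if (length(unique(labels[trainIdx])) < 2L) {
      warning(sprintf("fold %d: single-class training split, skipped", i))
      next
    }
    model <- trainModel(spec, data[trainIdx, ])
    scores <- predictScores(model, data[testIdx, , drop = FALSE])
    if (length(unique(labels[testIdx])) == 2L)
      auc[i] <- rocAuc(scores, labels[testIdx])  # NA for single-class folds
    err[i] <- classificationError(scores, labels[testIdx],
                                  decisionThreshold(model))
  }
  tag <- S4Vectors::metadata(data)$featureSet
  new("CVResult", modelKind = spec@kind,
      featureSetTag = if (is.null(tag) || is.na(tag)) "custom" else tag,
      k = cv@k, reversed = cv@reversed, foldAuc = auc, foldError = err)
}

#' @describeIn crossValidate mean per-fold AUC.
#' @param x a \linkS4class{CVResult}.
#' @export
setMethod("meanAuc", "CVResult", function(x) mean(x@foldAuc, na.rm = TRUE))

#' @describeIn crossValidate standard deviation of per-fold AUC.
#' @export
setMethod("sdAuc", "CVResult", function(x) stats::sd(x@foldAuc[!is.na(x@foldAuc)]))

#' @describeIn crossValidate mean per-fold classification error.
#' @export
setMethod("meanError", "CVResult", function(x) mean(x@foldError, na.rm = TRUE))

#' @describeIn crossValidate standard deviation of per-fold error.
#' @export
setMethod("sdError", "CVResult", function(x) stats::sd(x@foldError[!is.na(x@foldError)]))

#' Validate a trained model on an external region set
#'
#' Features for the validation regions are built with the training-time
#' parameters and restricted to the model's feature columns; metrics are the
#' ROC AUC and the thresholded classification error.  As a bias guard the
#' validation regions must not overlap the training regions (filter with
#' \code{\link{removeOverlapping}} first); any overlap is an error.
#'
#' @param model a trained \linkS4class{EnhancerModel}.
#' @param validationRegions labeled GRanges.
#' @param genome DNAStringSet.
#' @param tracks named list of \linkS4class{SignalTrack}.
#' @param pwms list of \linkS4class{PWM}.
#' @param trainingRegions GRanges the model was trained on (overlap guard).
#' @param params \linkS4class{TrapParams} used at training time.
#' @return list with elements \code{auc} and \code{error}.
#' @export
externalValidate <- function(model, validationRegions, genome, tracks, pwms,
                             trainingRegions, params = trapParams()) {
  if (regionsOverlap(validationRegions, trainingRegions))
    stop("validation regions overlap the training set; remove them with ",
         "removeOverlapping() first")
  need <- unique(sub(":.*$", "", model@featureNames))
  set <- if (all(c("EPI", "MOT") %in% need)) "ALL" else need
  fs <- buildFeatureMatrix(genome, tracks, pwms, validationRegions,
                           featureSet = set, params = params)
  fs <- subsetFeatures(fs, model@featureNames)
  scores <- predictScores(model, fs)
  list(auc = rocAuc(scores, regionLabels(fs)),
       error = classificationError(scores, regionLabels(fs),
                                   decisionThreshold(model)))
}
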