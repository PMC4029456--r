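## Classifier backends. All training goes through trainModel(spec, data);
## data is an EnhancerFeatureSet (or a plain matrix + labels via the
## internal helpers). Scores from predictScores() are oriented so that
## higher means more likely active.

asTrainingMatrix <- function(data) {
  x <- featureValues(data)
  y <- labelBinary(regionLabels(data))
  if (nrow(x) < 2L) stop("at least 2 training rows are required")
  if (length(unique(y)) < 2L)
    stop("single-class training data: both labels must be present")
  list(x = x, y = y)
}

checkFeatureAlignment <- function(model, newdata) {
  x <- if (is(newdata, "EnhancerFeatureSet")) featureValues(newdata)
       else as.matrix(newdata)
  if (is.null(colnames(x)) || !identical(colnames(x), model@featureNames))
    stop("feature columns do not match the training features ",
         "(same names in the same order are required)")
  x
}

#' Train a classifier
#'
#' Dispatches on \code{spec@kind}: \code{"rf"} fits a seeded random forest
#' (\code{nEstimators} trees, default 30); \code{"svm"} standardizes the
#' features to zero mean / unit variance using training statistics and fits
#' an RBF C-SVM; \code{"bde"} discretizes the features into equal-frequency
#' bins and exhaustively searches all parent subsets of the class node up to
#' \code{maxParents}, selecting the subset maximizing the BDe marginal
#' likelihood.
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @param data an \linkS4class{EnhancerFeatureSet} containing both classes.
#' @param ... unused.
#' @return an \linkS4class{EnhancerModel} subclass matching the backend.
#' @export
setMethod("trainModel", signature(spec = "ModelSpec",
                                  data = "EnhancerFeatureSet"),
  function(spec, data, ...) {
    td <- asTrainingMatrix(data)
    switch(spec@kind,
           rf = trainRf(spec, td$x, td$y),
           svm = trainSvm(spec, td$x, td$y),
           bde = trainBdeMatrix(spec, td$x, td$y),
           stop("unknown model kind '", spec@kind, "'"))
  })

trainRf <- function(spec, x, y) {
  p <- ncol(x)
  mtry <- if (is.na(spec@mtry)) max(1L, floor(sqrt(p))) else spec@mtry
  fit <- .rf_train_cpp(x, as.integer(y), spec@nEstimators,
                       as.integer(min(mtry, p)), spec@seed, FALSE)
  new("RFModel", spec = spec, featureNames = colnames(x),
      forest = fit$trees)
}

## random forest fit that also returns OOB permutation importance
## (mean decrease in OOB accuracy); used by the importance module
rfImportanceFit <- function(spec, x, y) {
  p <- ncol(x)
  mtry <- if (is.na(spec@mtry)) max(1L, floor(sqrt(p))) else spec@mtry
  fit <- .rf_train_cpp(x, as.integer(y), spec@nEstimators,
                       as.integer(min(mtry, p)), spec@seed, TRUE)
  stats::setNames(fit$importance, colnames(x))
}

trainSvm <- function(spec, x, y) {
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  gamma <- if (is.na(spec@svmGamma)) 1 / ncol(x) else spec@svmGamma
  yy <- ifelse(y == 1L, 1, -1)
  fit <- .svm_train_cpp(xs, yy, spec@svmCost, gamma, 1e-3, 1000L, spec@seed)
  new("SVMModel", spec = spec, featureNames = colnames(x),
      fit = list(sv = fit$sv, coef = as.numeric(fit$coef), b = fit$b,
                 gamma = gamma, center = center, scale = scale))
}

#' Predict region activity scores
#'
#' Higher scores mean more likely active.  \code{rf}: fraction of trees
#' voting positive; \code{svm}: signed decision value; \code{bde}: posterior
#' probability of the positive class.  The feature columns of
#' \code{newdata} must match the training features exactly (names and
#' order); a permuted column order is an error, never a silent
#' misalignment.
#'
#' @param model a trained \linkS4class{EnhancerModel}.
#' @param newdata an \linkS4class{EnhancerFeatureSet} or numeric matrix with
#'   feature column names.
#' @param ... unused.
#' @return numeric score per region.
#' @export
setMethod("predictScores", "RFModel", function(model, newdata, ...) {
  x <- checkFeatureAlignment(model, newdata)
  as.numeric(.rf_predict_cpp(model@forest, x))
})

#' @rdname predictScores-RFModel-method
#' @export
setMethod("predictScores", "SVMModel", function(model, newdata, ...) {
  x <- checkFeatureAlignment(model, newdata)
  f <- model@fit
  xs <- sweep(sweep(x, 2, f$center), 2, f$scale, "/")
  as.numeric(.svm_decision_cpp(f$sv, f$coef, f$b, f$gamma, xs))
})

#' Per-backend decision threshold
#'
#' Scores strictly above the threshold are classified positive: 0.5 for the
#' random-forest vote fraction, 0 for the SVM decision value, 0.5 for the
#' BDe posterior.
#'
#' @param model a trained \linkS4class{EnhancerModel}.
#' @return numeric threshold.
#' @export
setMethod("decisionThreshold", "RFModel", function(model) 0.5)

#' @rdname decisionThreshold-RFModel-method
#' @export
setMethod("decisionThreshold", "SVMModel", function(model) 0)

#' @rdname decisionThreshold-RFModel-method
#' @export
setMethod("decisionThreshold", "BDEModel", function(model) 0.5)
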