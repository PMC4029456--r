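#' Cross-validated evaluation of a feature subset
#'
#' Convenience composition: restrict the feature matrix to \code{features}
#' and cross-validate; used as the building block of all ablation
#' protocols.
#'
#' @param data an \linkS4class{EnhancerFeatureSet}.
#' @param features non-empty character vector of feature names to keep.
#' @param model a \linkS4class{ModelSpec}.
#' @param cv a \linkS4class{CVSpec}.
#' @return a \linkS4class{CVResult}.
#' @export
reducedModelEval <- function(data, features, model = modelSpec("rf"),
                             cv = cvSpec()) {
  if (!length(features)) stop("feature subset must be non-empty")
  crossValidate(model, subsetFeatures(data, features), cv)
}

#' Mark-removal ablation curves
#'
#' \code{single_mark}: each chromatin mark is removed alone.
#' \code{top_k_marks} / \code{bottom_k_marks}: the K most / least important
#' marks (by \code{ranking}) are removed at once for each K in
#' \code{spec@kRange}.  Each configuration is retrained and cross-validated;
#' the accuracy loss is error(ablated) - error(full model on the same
#' feature set).
#'
#' @param data an \linkS4class{EnhancerFeatureSet} containing EPI features.
#' @param spec an \linkS4class{AblationSpec} with a mark mode.
#' @param ranking feature names ordered most to least important, e.g. from
#'   \code{\link{importanceRanking}}; only its EPI entries are used.
#' @return data.frame with one row per configuration: removed set, K, mean
#'   CV error, mean CV AUC and accuracy loss.
#' @export
ablationCurve <- function(data, spec, ranking) {
  marks <- colnames(data)[featureType(data) == "EPI"]
  if (!length(marks)) stop("no EPI features to ablate")
  rankedMarks <- intersect(ranking, marks)
  if (!setequal(rankedMarks, marks))
    stop("'ranking' must contain every EPI feature")
  full <- crossValidate(spec@model, data, spec@cv)

  configs <- switch(spec@mode,
    single_mark = lapply(marks, function(m) list(removed = m, K = 1L)),
    top_k_marks = lapply(spec@kRange, function(K) {
      if (K > length(marks)) stop("K exceeds the number of marks")
      list(removed = rankedMarks[seq_len(K)], K = K)
    }),
    bottom_k_marks = lapply(spec@kRange, function(K) {
      if (K > length(marks)) stop("K exceeds the number of marks")
      list(removed = rev(rankedMarks)[seq_len(K)], K = K)
    }),
    stop("ablationCurve handles the mark modes; use ",
         "iterativeTfElimination for mode 'iterative_tf'"))

  rows <- lapply(configs, function(cfg) {
    keep <- setdiff(colnames(data), cfg$removed)
    res <- reducedModelEval(data, keep, spec@model, spec@cv)
    data.frame(mode = spec@mode,
               removed = paste(cfg$removed, collapse = ","),
               K = cfg$K, meanError = meanError(res), meanAuc = meanAuc(res),
               accuracyLoss = meanError(res) - meanError(full),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "fullError") <- meanError(full)
  out
}

#' Iterative elimination of least-important transcription factors
#'
#' Starting from the full feature set, repeatedly: rank the MOT features by
#' repeated shadow importance on the current system, remove the 80 per cent
#' least important (floor(0.8 * count)) while at least 5 remain, otherwise
#' remove a single TF; record the cross-validated error after each step;
#' stop when one TF remains.
#'
#' @param data an \linkS4class{EnhancerFeatureSet} containing MOT features.
#' @param impSpec an \linkS4class{ImportanceSpec} used for the per-step
#'   ranking (re-run on each reduced system).
#' @param model,cv classifier and CV layout for the per-step evaluation.
#' @return data.frame trace: step, number of TFs, mean CV error and AUC,
#'   and the surviving TF features (comma-separated).
#' @export
iterativeTfElimination <- function(data, impSpec = importanceSpec(),
                                   model = modelSpec("rf"), cv = cvSpec()) {
  if (!any(featureType(data) == "MOT"))
    stop("no MOT features present")
  current <- data
  step <- 0L
  rows <- list()
  record <- function(step, current) {
    res <- crossValidate(model, current, cv)
    tfs <- colnames(current)[featureType(current) == "MOT"]
    data.frame(step = step, nTf = length(tfs), meanError = meanError(res),
               meanAuc = meanAuc(res),
               tfFeatures = paste(tfs, collapse = ","),
               stringsAsFactors = FALSE)
  }
  rows[[1]] <- record(0L, current)
  repeat {
    tfs <- colnames(current)[featureType(current) == "MOT"]
    if (length(tfs) <= 1L) break
    stepSpec <- impSpec
    stepSpec@seed <- stageSeed(impSpec@seed, 300L + step)
    report <- repeatedImportance(current, stepSpec)
    rankedTfs <- intersect(importanceRanking(report), tfs)
    nRemove <- if (length(tfs) >= 5L) floor(0.8 * length(tfs)) else 1L
    drop <- rev(rankedTfs)[seq_len(nRemove)]
    current <- subsetFeatures(current, setdiff(colnames(current), drop))
    step <- step + 1L
    rows[[step + 1L]] <- record(step, current)
  }
  do.call(rbind, rows)
}
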