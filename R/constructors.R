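#' Construct a SignalTrack
#'
#' @param mark mark name.
#' @param values named list of per-chromosome window-value vectors.
#' @param window window width in bp (default 50).
#' @return a \linkS4class{SignalTrack}.
#' @export
signalTrack <- function(mark, values, window = 50L) {
  new("SignalTrack", mark = as.character(mark), window = as.integer(window),
      values = lapply(values, as.numeric))
}

#' Construct a PWM
#'
#' @param id motif identifier.
#' @param matrix numeric matrix, positions x 4 (A,C,G,T columns).
#' @return a \linkS4class{PWM}.
#' @export
pwm <- function(id, matrix) {
  m <- as.matrix(matrix)
  colnames(m) <- c("A", "C", "G", "T")
  new("PWM", id = as.character(id), matrix = m)
}

#' @describeIn pwm motif length in bp.
#' @param x a \linkS4class{PWM}.
#' @export
setMethod("motifLength", "PWM", function(x) nrow(x@matrix))

#' @describeIn pwm the positions x 4 matrix.
#' @export
setMethod("pwmMatrix", "PWM", function(x) x@matrix)

#' @describeIn pwm the motif identifier.
#' @export
setMethod("pwmId", "PWM", function(x) x@id)

#' @describeIn signalTrack window values of one chromosome (zero-length
#'   numeric for chromosomes without windows).
#' @param x a \linkS4class{SignalTrack}.
#' @param chrom chromosome name.
#' @export
setMethod("trackValues", "SignalTrack", function(x, chrom) {
  if (chrom %in% names(x@values)) x@values[[chrom]] else numeric(0)
})

#' TRAP model parameters
#'
#' @param lambda energy scale, default 0.7.
#' @param r0Slope,r0Intercept length rule for R0 = exp(slope*m + intercept);
#'   defaults 0.584 and -5.66.
#' @param r0Override explicit R0 overriding the length rule (NA = off).
#' @param pseudocount regularization count per matrix cell (default 1).
#' @return a \linkS4class{TrapParams}.
#' @export
trapParams <- function(lambda = 0.7, r0Slope = 0.584, r0Intercept = -5.66,
                       r0Override = NA_real_, pseudocount = 1) {
  new("TrapParams", lambda = lambda, r0Slope = r0Slope,
      r0Intercept = r0Intercept, r0Override = as.numeric(r0Override),
      pseudocount = pseudocount)
}

#' Labeled feature matrix of genomic regions
#'
#' @param values numeric matrix, regions x features; column names carry the
#'   provenance prefix (\code{"EPI:"}, \code{"MOT:"}).
#' @param labels region labels, coercible to a negative/positive factor.
#' @param ids optional region identifiers.
#' @param regions optional GRanges parallel to the rows.
#' @param featureSet optional tag (EPI / MOT / ALL) stored in metadata.
#' @return an \linkS4class{EnhancerFeatureSet}.
#' @export
enhancerFeatureSet <- function(values, labels, ids = NULL, regions = NULL,
                               featureSet = NA_character_) {
  values <- as.matrix(values)
  if (is.null(ids)) ids <- sprintf("region%04d", seq_len(nrow(values)))
  rd <- S4Vectors::DataFrame(id = as.character(ids),
                             label = labelFactor(labels))
  if (!is.null(regions)) rd$region <- regions
  rownames(values) <- ids
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = values), rowData = rd)
  out <- new("EnhancerFeatureSet", se)
  S4Vectors::metadata(out)$featureSet <- featureSet
  out
}

#' @describeIn enhancerFeatureSet the regions x features value matrix.
#' @param x an \linkS4class{EnhancerFeatureSet}.
#' @export
setMethod("featureValues", "EnhancerFeatureSet", function(x)
  SummarizedExperiment::assay(x, "features"))

#' @describeIn enhancerFeatureSet region labels (factor negative/positive).
#' @export
setMethod("regionLabels", "EnhancerFeatureSet", function(x)
  SummarizedExperiment::rowData(x)$label)

#' @describeIn enhancerFeatureSet region identifiers.
#' @export
setMethod("regionIds", "EnhancerFeatureSet", function(x)
  SummarizedExperiment::rowData(x)$id)

#' @describeIn enhancerFeatureSet provenance tag of each feature column
#'   (the part of the name before the first colon).
#' @export
setMethod("featureType", "EnhancerFeatureSet", function(x)
  sub(":.*$", "", colnames(x)))

#' @describeIn enhancerFeatureSet restrict to a feature set
#'   (\code{"EPI"}, \code{"MOT"}, \code{"ALL"}) or to explicit feature names.
#' @param set feature-set tag or character vector of feature names.
#' @export
setMethod("subsetFeatures", "EnhancerFeatureSet", function(x, set, ...) {
  if (length(set) == 1L && set %in% c("EPI", "MOT", "ALL")) {
    keep <- if (set == "ALL") rep(TRUE, ncol(x)) else featureType(x) == set
    if (!any(keep)) stop(sprintf("no '%s' features present", set))
    out <- x[, keep]
    S4Vectors::metadata(out)$featureSet <- set
  } else {
    missing <- setdiff(set, colnames(x))
    if (length(missing))
      stop("unknown feature names: ", paste(missing, collapse = ", "))
    out <- x[, match(set, colnames(x))]
    S4Vectors::metadata(out)$featureSet <- "custom"
  }
  out
})

#' Classifier specification
#'
#' @param kind backend: \code{"rf"} (random forest, 30 trees by default),
#'   \code{"svm"} (RBF C-SVM on standardized features) or \code{"bde"}
#'   (discrete Bayesian classifier scored with the Bayesian-Dirichlet
#'   equivalent marginal likelihood, parent-set cardinality <= 3).
#' @param nEstimators,mtry random-forest settings.
#' @param svmCost,svmGamma SVM settings (gamma NA = 1/p).
#' @param maxParents,nBins,ess,searchBudget BDe settings.
#' @param seed RNG seed for stochastic backends.
#' @return a \linkS4class{ModelSpec}.
#' @export
modelSpec <- function(kind = c("rf", "svm", "bde"), nEstimators = 30L,
                      mtry = NA_integer_, svmCost = 1, svmGamma = NA_real_,
                      maxParents = 3L, nBins = 3L, ess = 1,
                      searchBudget = 1e5, seed = 1L) {
  kind <- match.arg(kind)
  new("ModelSpec", kind = kind, nEstimators = as.integer(nEstimators),
      mtry = as.integer(mtry), svmCost = svmCost, svmGamma = svmGamma,
      maxParents = as.integer(maxParents), nBins = as.integer(nBins),
      ess = ess, searchBudget = searchBudget, seed = as.integer(seed))
}

#' Cross-validation specification
#'
#' @param k folds (10 by default; 4 is conventional for very small sets).
#' @param reversed train on 1 fold, test on the remaining k-1.
#' @param stratified balance class ratios across folds.
#' @param seed fold-shuffle seed.
#' @return a \linkS4class{CVSpec}.
#' @export
cvSpec <- function(k = 10L, reversed = FALSE, stratified = FALSE, seed = 1L) {
  new("CVSpec", k = as.integer(k), reversed = reversed,
      stratified = stratified, seed = as.integer(seed))
}

#' Negative-region sampler specification
#'
#' @param n number of negatives to draw.
#' @param lengthMean,lengthSd Gaussian length model in bp (defaults 270.47
#'   and 112, the observed positive-set statistics).
#' @param exclusions named list of GRanges that samples must not overlap.
#' @param mutualExclusion draws must not overlap each other.
#' @param maxAttemptsFactor attempt budget multiplier (default 1000).
#' @param minLength minimum drawn length, shorter draws are redrawn.
#' @param maxNFraction maximum tolerated fraction of N bases.
#' @param buffer minimum distance (bp) kept from exclusions and other draws;
#'   the default of two 50-bp signal windows prevents any window from
#'   spanning two regions, which would leak correlated signal between
#'   training and test rows on a dense genome.
#' @param seed RNG seed.
#' @return a \linkS4class{SamplerSpec}.
#' @export
samplerSpec <- function(n, lengthMean = 270.47, lengthSd = 112,
                        exclusions = list(), mutualExclusion = TRUE,
                        maxAttemptsFactor = 1000L, minLength = 20L,
                        maxNFraction = 0.5, buffer = 100L, seed = 1L) {
  new("SamplerSpec", n = as.integer(n), lengthMean = lengthMean,
      lengthSd = lengthSd, exclusions = exclusions,
      mutualExclusion = mutualExclusion,
      maxAttemptsFactor = as.integer(maxAttemptsFactor),
      minLength = as.integer(minLength), maxNFraction = maxNFraction,
      buffer = as.integer(buffer), seed = as.integer(seed))
}

#' Synthetic-world configuration
#'
#' See \linkS4class{SyntheticConfig} for the meaning and defaults of every
#' parameter; arguments override the stated defaults.
#'
#' @param ... slots of \linkS4class{SyntheticConfig} to override.
#' @return a \linkS4class{SyntheticConfig}.
#' @export
syntheticConfig <- function(...) {
  args <- list(...)
  for (nm in c("seed", "nChroms", "chromLength", "nPositives", "nMotifs",
               "nDriverMotifs", "nMarks", "windowWidth"))
    if (nm %in% names(args)) args[[nm]] <- as.integer(args[[nm]])
  if ("motifLengthRange" %in% names(args))
    args$motifLengthRange <- as.integer(args$motifLengthRange)
  if ("markNames" %in% names(args) && !"nMarks" %in% names(args))
    args$nMarks <- length(args$markNames)
  do.call(new, c(list("SyntheticConfig"), args))
}

#' Shadow-variable importance specification
#'
#' @param nRepetitions repetitions with fresh contrast variables (default 30).
#' @param maxRfIterations forest iterations per repetition.
#' @param alpha two-sided binomial hit-test level.
#' @param nContrast contrast variables added per repetition (NA = p).
#' @param rf random-forest spec used inside the procedure.
#' @param seed master seed.
#' @return an \linkS4class{ImportanceSpec}.
#' @export
importanceSpec <- function(nRepetitions = 30L, maxRfIterations = 100L,
                           alpha = 0.01, nContrast = NA_integer_,
                           rf = modelSpec("rf"), seed = 1L) {
  new("ImportanceSpec", nRepetitions = as.integer(nRepetitions),
      maxRfIterations = as.integer(maxRfIterations), alpha = alpha,
      nContrast = as.integer(nContrast), rf = rf, seed = as.integer(seed))
}

#' Ablation protocol specification
#'
#' @param mode \code{"single_mark"}, \code{"top_k_marks"},
#'   \code{"bottom_k_marks"} or \code{"iterative_tf"}.
#' @param kRange K values for the mark modes (default 1:7).
#' @param model classifier used for re-training.
#' @param cv cross-validation layout.
#' @return an \linkS4class{AblationSpec}.
#' @export
ablationSpec <- function(mode = c("single_mark", "top_k_marks",
                                  "bottom_k_marks", "iterative_tf"),
                         kRange = 1:7, model = modelSpec("rf"),
                         cv = cvSpec()) {
  new("AblationSpec", mode = match.arg(mode), kRange = as.integer(kRange),
      model = model, cv = cv)
}

#' Pipeline configuration
#'
#' @param synthetic a \linkS4class{SyntheticConfig} (its seed is overridden
#'   by the pipeline seed), or NULL when \code{paths} is given.
#' @param paths named list with elements \code{genome}, \code{positives},
#'   \code{tracks} (vector of bedGraph paths named by mark) and \code{pfm}.
#' @param featureSets subset of EPI / MOT / ALL.
#' @param models classifier kinds or a list of \linkS4class{ModelSpec}.
#' @param cv \linkS4class{CVSpec} for the grid.
#' @param validation run the zero-mark external-validation analog.
#' @param importance optional \linkS4class{ImportanceSpec}.
#' @param ablation optional \linkS4class{AblationSpec}.
#' @param outDir optional output directory for report artifacts.
#' @param seed global seed fanned out deterministically to all stages.
#' @return a \linkS4class{PipelineConfig}.
#' @export
pipelineConfig <- function(synthetic = syntheticConfig(), paths = list(),
                           featureSets = c("EPI", "MOT", "ALL"),
                           models = c("rf", "svm", "bde"), cv = cvSpec(),
                           validation = FALSE, importance = NULL,
                           ablation = NULL, outDir = NA_character_,
                           seed = 1L) {
  new("PipelineConfig", synthetic = synthetic, paths = paths,
      featureSets = featureSets, models = models, cv = cv,
      validation = validation, importance = importance, ablation = ablation,
      outDir = outDir, seed = as.integer(seed))
}
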