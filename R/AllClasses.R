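## Central S4 classes. Regions are GRanges (1-based, closed, as everywhere in
## Bioconductor); BED I/O converts to/from 0-based half-open at the boundary.

#' SignalTrack: fixed-width windowed chromatin signal for one mark
#'
#' Window \code{i} (0-based) covers base interval \code{[i*w, (i+1)*w)} in
#' 0-based genomic coordinates; values are stored as one dense numeric vector
#' per chromosome, with unobserved windows equal to 0.
#'
#' @slot mark single mark name (e.g. \code{"H3K4me1"}).
#' @slot window window width in bp (default 50).
#' @slot values named list of per-chromosome numeric window vectors.
#' @export
setClass("SignalTrack",
  representation(mark = "character", window = "integer", values = "list"),
  validity = function(object) {
    msg <- NULL
    if (length(object@mark) != 1L || !nzchar(object@mark))
      msg <- c(msg, "'mark' must be a single non-empty string")
    if (length(object@window) != 1L || is.na(object@window) || object@window < 1L)
      msg <- c(msg, "'window' must be a positive integer")
    if (length(object@values) && is.null(names(object@values)))
      msg <- c(msg, "'values' must be a named list of numeric vectors")
    for (v in object@values)
      if (!is.numeric(v) || any(!is.finite(v))) {
        msg <- c(msg, "window values must be finite numerics")
        break
      }
    if (is.null(msg)) TRUE else msg
  })

#' PWM: position weight/frequency matrix for one transcription-factor motif
#'
#' The matrix is stored positions x bases, columns in A, C, G, T order.
#' Entries may be raw counts (as in JASPAR PFM files) or probabilities;
#' \code{\link{pwmProbabilities}} converts to a regularized probability
#' matrix.
#'
#' @slot id motif identifier.
#' @slot matrix numeric matrix, m positions x 4 bases (A,C,G,T).
#' @export
setClass("PWM",
  representation(id = "character", matrix = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (length(object@id) != 1L || !nzchar(object@id))
      msg <- c(msg, "'id' must be a single non-empty string")
    m <- object@matrix
    if (!is.numeric(m) || ncol(m) != 4L || nrow(m) < 1L)
      msg <- c(msg, "'matrix' must be a numeric m x 4 matrix with m >= 1")
    else if (any(m < 0) || any(!is.finite(m)))
      msg <- c(msg, "PWM entries must be finite and non-negative")
    if (is.null(msg)) TRUE else msg
  })

#' TrapParams: parameters of the TRAP occupancy model
#'
#' TRAP scores a sequence by the expected number of bound transcription-factor
#' molecules, summing per-site occupancies R0*exp(-E)/(1+R0*exp(-E)) over both
#' strands, where E is the lambda-scaled mismatch energy of the site against
#' the motif consensus.  Defaults follow the model's published calibration:
#' lambda = 0.7 and R0 = exp(0.584*m - 5.66) for motif length m.
#'
#' @slot lambda energy scale (> 0), default 0.7.
#' @slot r0Slope slope of log R0 in motif length, default 0.584.
#' @slot r0Intercept intercept of log R0, default -5.66.
#' @slot r0Override optional explicit R0 (NA_real_ to use the length rule).
#' @slot pseudocount count added per matrix cell before normalization.
#' @export
setClass("TrapParams",
  representation(lambda = "numeric", r0Slope = "numeric",
                 r0Intercept = "numeric", r0Override = "numeric",
                 pseudocount = "numeric"),
  prototype(lambda = 0.7, r0Slope = 0.584, r0Intercept = -5.66,
            r0Override = NA_real_, pseudocount = 1),
  validity = function(object) {
    msg <- NULL
    if (object@lambda <= 0) msg <- c(msg, "'lambda' must be > 0")
    if (!is.na(object@r0Override) && object@r0Override <= 0)
      msg <- c(msg, "'r0Override' must be > 0")
    if (object@pseudocount < 0) msg <- c(msg, "'pseudocount' must be >= 0")
    if (is.null(msg)) TRUE else msg
  })

#' EnhancerFeatureSet: labeled regions x features matrix
#'
#' A \linkS4class{SummarizedExperiment} whose rows are genomic regions and
#' whose columns are features.  Feature provenance is encoded in the column
#' name prefix: \code{"EPI:"} for chromatin-mark features, \code{"MOT:"} for
#' motif-affinity features (\code{"CONTRAST:"} and \code{"SHADOW:"} appear
#' transiently during importance analysis).  Row metadata holds the region
#' \code{id}, the binary \code{label} (factor, levels \code{negative},
#' \code{positive}) and, when known, the source \code{region} (GRanges).
#'
#' @export
setClass("EnhancerFeatureSet", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- NULL
    if (!"features" %in% names(SummarizedExperiment::assays(object)))
      return("assay 'features' is missing")
    x <- SummarizedExperiment::assay(object, "features")
    if (!is.numeric(x)) msg <- c(msg, "feature values must be numeric")
    if (anyNA(x)) msg <- c(msg, "feature values must not contain NA")
    cn <- colnames(x)
    if (is.null(cn) || anyDuplicated(cn) || any(!nzchar(cn)))
      msg <- c(msg, "feature names must be unique and non-empty")
    rd <- SummarizedExperiment::rowData(object)
    if (!"label" %in% names(rd))
      msg <- c(msg, "rowData must contain a 'label' column")
    else {
      lab <- rd$label
      if (!is.factor(lab) || !all(levels(lab) %in% c("negative", "positive")))
        msg <- c(msg, "'label' must be a factor with levels negative/positive")
      if (anyNA(lab)) msg <- c(msg, "labels must not contain NA")
    }
    if (is.null(msg)) TRUE else msg
  })

#' ModelSpec: configuration of one classifier backend
#'
#' @slot kind one of \code{"rf"}, \code{"svm"}, \code{"bde"}.
#' @slot nEstimators number of random-forest trees (default 30).
#' @slot mtry features tried per split (NA = floor(sqrt(p))).
#' @slot svmCost soft-margin C (default 1).
#' @slot svmGamma RBF kernel width (NA = 1/p).
#' @slot maxParents BDe parent-set cardinality bound (default 3).
#' @slot nBins equal-frequency discretization bins for BDe (default 3).
#' @slot ess equivalent sample size of the BDe Dirichlet prior (default 1).
#' @slot searchBudget maximum number of parent subsets scored (default 1e5).
#' @slot seed RNG seed used by stochastic backends.
#' @export
setClass("ModelSpec",
  representation(kind = "character", nEstimators = "integer", mtry = "integer",
                 svmCost = "numeric", svmGamma = "numeric",
                 maxParents = "integer", nBins = "integer", ess = "numeric",
                 searchBudget = "numeric", seed = "integer"),
  prototype(kind = "rf", nEstimators = 30L, mtry = NA_integer_, svmCost = 1,
            svmGamma = NA_real_, maxParents = 3L, nBins = 3L, ess = 1,
            searchBudget = 1e5, seed = 1L),
  validity = function(object) {
    msg <- NULL
    if (!object@kind %in% c("rf", "svm", "bde"))
      msg <- c(msg, sprintf("unknown model kind '%s'", object@kind))
    if (object@nEstimators < 1L) msg <- c(msg, "'nEstimators' must be >= 1")
    if (object@maxParents < 0L) msg <- c(msg, "'maxParents' must be >= 0")
    if (object@nBins < 2L) msg <- c(msg, "'nBins' must be >= 2")
    if (object@ess <= 0) msg <- c(msg, "'ess' must be > 0")
    if (is.null(msg)) TRUE else msg
  })

#' Virtual parent of trained classifiers
#'
#' @slot spec the \linkS4class{ModelSpec} the model was trained with.
#' @slot featureNames feature names (and order) seen at training time.
#' @export
setClass("EnhancerModel", representation("VIRTUAL",
  spec = "ModelSpec", featureNames = "character"))

#' @rdname EnhancerModel-class
#' @slot forest list of fitted trees (internal representation).
#' @export
setClass("RFModel", contains = "EnhancerModel",
         representation(forest = "list"))

#' @rdname EnhancerModel-class
#' @slot fit support vectors, dual coefficients, bias, kernel width and the
#'   training standardization (center/scale), as a list.
#' @export
setClass("SVMModel", contains = "EnhancerModel",
         representation(fit = "list"))

#' @rdname EnhancerModel-class
#' @slot parents names of the selected parent features of the class node.
#' @slot cpt conditional probability table P(class | parent configuration).
#' @slot edges per-feature discretization bin edges from training data.
#' @export
setClass("BDEModel", contains = "EnhancerModel",
         representation(parents = "character", cpt = "matrix",
                        edges = "list", score = "numeric"))

#' CVSpec: cross-validation layout
#'
#' @slot k number of folds (default 10).
#' @slot reversed if TRUE, train on one fold and test on the other k-1.
#' @slot stratified if TRUE, folds balance the class ratio.
#' @slot seed fold-shuffle seed.
#' @export
setClass("CVSpec",
  representation(k = "integer", reversed = "logical", stratified = "logical",
                 seed = "integer"),
  prototype(k = 10L, reversed = FALSE, stratified = FALSE, seed = 1L),
  validity = function(object) {
    if (object@k < 2L) "'k' must be >= 2" else TRUE
  })

#' CVResult: per-fold metrics of one cross-validated model
#'
#' @slot modelKind classifier backend.
#' @slot featureSetTag feature set used (EPI / MOT / ALL / custom).
#' @slot k folds; @slot reversed reversed-CV flag.
#' @slot foldAuc per-fold ROC AUC; @slot foldError per-fold error fraction.
#' @export
setClass("CVResult",
  representation(modelKind = "character", featureSetTag = "character",
                 k = "integer", reversed = "logical",
                 foldAuc = "numeric", foldError = "numeric"),
  validity = function(object) {
    msg <- NULL
    ok <- is.na(object@foldAuc) | (object@foldAuc >= 0 & object@foldAuc <= 1)
    if (!all(ok)) msg <- c(msg, "AUC values must lie in [0,1]")
    ok <- is.na(object@foldError) | (object@foldError >= 0 & object@foldError <= 1)
    if (!all(ok)) msg <- c(msg, "error values must lie in [0,1]")
    if (is.null(msg)) TRUE else msg
  })

#' SamplerSpec: negative-region sampler configuration
#'
#' Negatives are drawn from the genome with chromosome probability
#' proportional to length and a Gaussian length model matched to the positive
#' set; candidates overlapping any exclusion set (or a previous draw, when
#' \code{mutualExclusion}) are rejected and redrawn.
#'
#' @slot n regions to draw.
#' @slot lengthMean,lengthSd Gaussian length model (bp).
#' @slot exclusions named list of GRanges the samples must not overlap.
#' @slot mutualExclusion draws must not overlap each other (default TRUE).
#' @slot maxAttemptsFactor attempt budget is n * this (default 1000).
#' @slot minLength redraw lengths below this (default 20 bp).
#' @slot maxNFraction reject candidates with more than this fraction of N.
#' @slot buffer minimum distance in bp kept from exclusions and other draws
#'   (default 100, two signal windows, so no window spans two regions).
#' @slot seed RNG seed.
#' @export
setClass("SamplerSpec",
  representation(n = "integer", lengthMean = "numeric", lengthSd = "numeric",
                 exclusions = "list", mutualExclusion = "logical",
                 maxAttemptsFactor = "integer", minLength = "integer",
                 maxNFraction = "numeric", buffer = "integer",
                 seed = "integer"),
  prototype(n = 0L, lengthMean = 270.47, lengthSd = 112,
            exclusions = list(), mutualExclusion = TRUE,
            maxAttemptsFactor = 1000L, minLength = 20L, maxNFraction = 0.5,
            buffer = 100L, seed = 1L),
  validity = function(object) {
    msg <- NULL
    if (object@n < 0L) msg <- c(msg, "'n' must be >= 0")
    if (object@lengthMean <= 0) msg <- c(msg, "'lengthMean' must be > 0")
    if (object@lengthSd < 0) msg <- c(msg, "'lengthSd' must be >= 0")
    if (length(object@exclusions) && is.null(names(object@exclusions)))
      msg <- c(msg, "'exclusions' must be a named list of GRanges")
    if (is.null(msg)) TRUE else msg
  })

#' SyntheticConfig: the stated world of the synthetic generator
#'
#' Defaults emulate the real training design at reduced scale: 500 positive
#' enhancer regions (the real set holds 8008) with Gaussian lengths
#' (mean 270.47 bp, sd 112 bp, as observed in the real positive set), 8
#' chromatin marks of which 3 carry graded enhancer effects, and 20 motifs of
#' which 2 "drivers" are planted inside enhancers.
#'
#' @slot seed master seed; @slot nChroms,chromLength genome layout.
#' @slot gcContent genome GC fraction.
#' @slot nPositives number of enhancer regions.
#' @slot posLengthMean,posLengthSd enhancer length model (bp).
#' @slot nMotifs,nDriverMotifs motif pool and planted subset sizes.
#' @slot motifLengthRange inclusive motif length bounds (bp).
#' @slot plantsPerEnhancer Poisson mean of planted driver instances.
#' @slot nMarks,markNames chromatin marks.
#' @slot informativeMarks,effectSizes marks with enhancer effect delta_m.
#' @slot noiseSd additive Gaussian window noise (signal units).
#' @slot windowWidth signal window width (bp, default 50).
#' @slot nonadditivePair two mark names sharing an exclusive-or effect
#'   (empty = off).
#' @slot repeatFraction fraction of the genome turned into 2-mer repeats.
#' @export
setClass("SyntheticConfig",
  representation(seed = "integer", nChroms = "integer",
                 chromLength = "integer", gcContent = "numeric",
                 nPositives = "integer", posLengthMean = "numeric",
                 posLengthSd = "numeric", nMotifs = "integer",
                 nDriverMotifs = "integer", motifLengthRange = "integer",
                 plantsPerEnhancer = "numeric", nMarks = "integer",
                 markNames = "character", informativeMarks = "character",
                 effectSizes = "numeric", noiseSd = "numeric",
                 windowWidth = "integer", nonadditivePair = "character",
                 repeatFraction = "numeric"),
  prototype(seed = 1L, nChroms = 2L, chromLength = 400000L, gcContent = 0.41,
            nPositives = 500L, posLengthMean = 270.47, posLengthSd = 112,
            nMotifs = 20L, nDriverMotifs = 2L, motifLengthRange = c(8L, 12L),
            plantsPerEnhancer = 6, nMarks = 8L,
            markNames = c("H3K4me1", "H3K4me3", "H3K27Ac", "H3K27me3",
                          "H3K36me3", "H3K79me3", "Mef2", "PolII"),
            informativeMarks = c("H3K4me1", "H3K36me3", "Mef2"),
            effectSizes = c(4, 2, 1), noiseSd = 1, windowWidth = 50L,
            nonadditivePair = character(0), repeatFraction = 0.05),
  validity = function(object) {
    msg <- NULL
    if (object@nDriverMotifs > object@nMotifs)
      msg <- c(msg, "driver motifs must be a subset of the motif pool")
    if (!all(object@informativeMarks %in% object@markNames))
      msg <- c(msg, "informative marks must be a subset of markNames")
    if (length(object@effectSizes) != length(object@informativeMarks))
      msg <- c(msg, "one effect size per informative mark is required")
    if (length(object@nonadditivePair) &&
        (length(object@nonadditivePair) != 2L ||
         !all(object@nonadditivePair %in% object@informativeMarks)))
      msg <- c(msg, "nonadditivePair must name two informative marks")
    if (object@gcContent <= 0 && object@gcContent != 0)
      msg <- c(msg, "gcContent must lie in [0,1)")
    if (object@nMarks != length(object@markNames))
      msg <- c(msg, "nMarks must equal length(markNames)")
    if (length(object@motifLengthRange) != 2L ||
        object@motifLengthRange[1] > object@motifLengthRange[2] ||
        object@motifLengthRange[1] < 1L)
      msg <- c(msg, "motifLengthRange must be valid inclusive bounds")
    if (object@repeatFraction < 0 || object@repeatFraction >= 1)
      msg <- c(msg, "repeatFraction must lie in [0,1)")
    if (is.null(msg)) TRUE else msg
  })

#' SyntheticDataset: one realization of the synthetic world
#'
#' @slot genome DNAStringSet.
#' @slot positives GRanges of enhancer regions (label "positive").
#' @slot repeatTracts GRanges of planted low-complexity tracts.
#' @slot pwms list of \linkS4class{PWM}.
#' @slot tracks named list of \linkS4class{SignalTrack}, one per mark.
#' @slot truth record of planted structure (driver motifs, informative marks,
#'   effect sizes, non-additive pair).
#' @export
setClass("SyntheticDataset",
  representation(genome = "DNAStringSet", positives = "GRanges",
                 repeatTracts = "GRanges", pwms = "list", tracks = "list",
                 truth = "list"))

#' ImportanceSpec: shadow-variable importance configuration
#'
#' @slot nRepetitions repetitions with fresh contrast variables (default 30;
#'   500 mirrors the extended randomization option).
#' @slot maxRfIterations forest iterations per repetition (default 100).
#' @slot alpha two-sided binomial hit-test level (default 0.01).
#' @slot nContrast number of contrast variables (NA = number of features).
#' @slot rf the random-forest spec used inside the procedure.
#' @slot seed master seed.
#' @export
setClass("ImportanceSpec",
  representation(nRepetitions = "integer", maxRfIterations = "integer",
                 alpha = "numeric", nContrast = "integer", rf = "ModelSpec",
                 seed = "integer"),
  prototype(nRepetitions = 30L, maxRfIterations = 100L, alpha = 0.01,
            nContrast = NA_integer_, seed = 1L),
  validity = function(object) {
    msg <- NULL
    if (object@nRepetitions < 1L) msg <- c(msg, "'nRepetitions' must be >= 1")
    if (object@alpha <= 0 || object@alpha >= 1)
      msg <- c(msg, "'alpha' must lie in (0,1)")
    if (is.null(msg)) TRUE else msg
  })

#' ImportanceReport: aggregated shadow-variable importance
#'
#' @slot meanZ per-feature Z-score averaged over repetitions.
#' @slot decisions per-feature majority decision
#'   (confirmed / rejected / tentative).
#' @slot contrastConfirmed confirmed contrast variables per repetition.
#' @slot expectedFalseDiscoveries mean confirmed contrasts per repetition.
#' @slot nRepetitions repetitions performed.
#' @export
setClass("ImportanceReport",
  representation(meanZ = "numeric", decisions = "factor",
                 contrastConfirmed = "numeric",
                 expectedFalseDiscoveries = "numeric",
                 nRepetitions = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@expectedFalseDiscoveries < 0)
      msg <- c(msg, "'expectedFalseDiscoveries' must be >= 0")
    if (length(object@meanZ) != length(object@decisions))
      msg <- c(msg, "one decision per feature is required")
    if (is.null(msg)) TRUE else msg
  })

#' AblationSpec: feature-removal protocol
#'
#' @slot mode one of \code{"single_mark"}, \code{"top_k_marks"},
#'   \code{"bottom_k_marks"}, \code{"iterative_tf"}.
#' @slot kRange K values for the mark modes (default 1:7).
#' @slot model classifier spec used for re-training.
#' @slot cv cross-validation spec.
#' @export
setClass("AblationSpec",
  representation(mode = "character", kRange = "integer", model = "ModelSpec",
                 cv = "CVSpec"),
  prototype(mode = "single_mark", kRange = 1:7),
  validity = function(object) {
    if (!object@mode %in% c("single_mark", "top_k_marks", "bottom_k_marks",
                            "iterative_tf"))
      sprintf("unknown ablation mode '%s'", object@mode)
    else TRUE
  })

#' PipelineConfig: one end-to-end analysis run
#'
#' @slot synthetic SyntheticConfig, or NULL when real paths are given.
#' @slot paths named list (genome, positives, tracks, pfm) of input files.
#' @slot featureSets subset of EPI / MOT / ALL to evaluate.
#' @slot models classifier kinds (or ModelSpec list) for the CV grid.
#' @slot cv CVSpec for the grid.
#' @slot validation logical: run the zero-mark external validation analog.
#' @slot importance optional ImportanceSpec.
#' @slot ablation optional AblationSpec.
#' @slot outDir optional output directory.
#' @slot seed global seed fanned out to all stages.
#' @export
setClass("PipelineConfig",
  representation(synthetic = "ANY", paths = "list", featureSets = "character",
                 models = "ANY", cv = "CVSpec", validation = "logical",
                 importance = "ANY", ablation = "ANY", outDir = "character",
                 seed = "integer"),
  prototype(synthetic = NULL, paths = list(),
            featureSets = c("EPI", "MOT", "ALL"),
            models = c("rf", "svm", "bde"), validation = FALSE,
            importance = NULL, ablation = NULL, outDir = NA_character_,
            seed = 1L),
  validity = function(object) {
    if (is.null(object@synthetic) && !length(object@paths))
      "either a synthetic config or input paths must be given"
    else TRUE
  })
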