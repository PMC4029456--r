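## Shadow-variable feature importance with false-discovery control.
##
## One run: the feature system is repeatedly extended with "shadow"
## variables (a row-permuted copy of every column, destroying any label
## association while preserving marginals), a random forest with OOB
## permutation importance is fitted, and each feature scores a "hit" when
## its importance exceeds the best shadow importance. A two-sided binomial
## test on the hit count against Binomial(iterations, 1/2) confirms or
## rejects features at level alpha; undecided features stay tentative.
##
## False-discovery estimation: before each repetition the system is extended
## with CONTRAST variables (permuted copies of real features, cycled) that
## carry no label information by design; the mean number of confirmed
## contrasts per repetition estimates the expected number of false
## discoveries among the real features.

#' Add contrast variables to a feature set
#'
#' Each contrast variable is an independently row-permuted copy of an
#' original feature (cycling over the features when \code{nContrast}
#' exceeds their number); names gain the \code{"CONTRAST:"} prefix and
#' labels are untouched.
#'
#' @param data an \linkS4class{EnhancerFeatureSet}.
#' @param nContrast number of contrast variables (default: one per feature).
#' @param seed optional RNG seed (default: current RNG stream).
#' @return the extended \linkS4class{EnhancerFeatureSet}.
#' @export
addContrastVariables <- function(data, nContrast = ncol(data), seed = NULL) {
  if (nContrast < 1L) stop("'nContrast' must be >= 1")
  expr <- quote({
    x <- featureValues(data)
    src <- rep(seq_len(ncol(x)), length.out = nContrast)
    contrast <- vapply(src, function(j) x[sample.int(nrow(x)), j],
                       numeric(nrow(x)))
    colnames(contrast) <- sprintf("CONTRAST:%s.%d", colnames(x)[src],
                                  seq_len(nContrast))
    enhancerFeatureSet(cbind(x, contrast), regionLabels(data),
                       ids = regionIds(data),
                       featureSet = S4Vectors::metadata(data)$featureSet)
  })
  if (is.null(seed)) eval(expr) else withSeed(seed, eval(expr))
}

#' One shadow-importance run
#'
#' Iterates up to \code{spec@maxRfIterations} times: permute fresh shadows,
#' fit the forest with OOB permutation importance, record hits against the
#' maximum shadow importance, and test hit counts after each iteration;
#' stops early once every feature is confirmed or rejected.  The
#' per-feature Z-score is (importance - mean shadow importance) / sd of the
#' shadow importances, averaged over iterations.
#'
#' @param data an \linkS4class{EnhancerFeatureSet} (both classes present;
#'   may already contain CONTRAST columns, which are treated as ordinary
#'   features here).
#' @param spec an \linkS4class{ImportanceSpec}.
#' @param seed RNG seed for the shadow permutations and forest fits.
#' @return list with \code{decision} (factor per feature:
#'   confirmed/rejected/tentative), \code{z} (mean Z-score), \code{hits}
#'   and \code{iterations}.
#' @export
borutaRun <- function(data, spec = importanceSpec(), seed = spec@seed) {
  x <- featureValues(data)
  y <- labelBinary(regionLabels(data))
  if (length(unique(y)) < 2L) stop("both classes must be present")
  p <- ncol(x)
  labels <- colnames(x)

  withSeed(seed, {
    hits <- stats::setNames(integer(p), labels)
    zsum <- stats::setNames(numeric(p), labels)
    decision <- stats::setNames(rep("tentative", p), labels)
    iters <- 0L
    degenerate <- FALSE
    for (it in seq_len(spec@maxRfIterations)) {
      shadow <- apply(x, 2, function(col) col[sample.int(nrow(x))])
      colnames(shadow) <- paste0("SHADOW:", labels)
      xa <- cbind(x, shadow)
      rfSpec <- spec@rf
      rfSpec@seed <- sample.int(2147483646L, 1L)
      imp <- rfImportanceFit(rfSpec, xa, y)
      if (all(imp == 0)) {
        warning("degenerate forest importance (all zero); ",
                "all features tentative")
        degenerate <- TRUE
        break
      }
      iters <- it
      impReal <- imp[seq_len(p)]
      impShadow <- imp[p + seq_len(p)]
      hits <- hits + as.integer(impReal > max(impShadow))
      sdS <- stats::sd(impShadow)
      if (sdS > 0) zsum <- zsum + (impReal - mean(impShadow)) / sdS
      ## two-sided binomial test at level alpha (alpha/2 per tail)
      undecided <- decision == "tentative"
      pHigh <- pbinom(hits[undecided] - 1L, it, 0.5, lower.tail = FALSE)
      pLow <- pbinom(hits[undecided], it, 0.5)
      decision[undecided][pHigh <= spec@alpha / 2] <- "confirmed"
      decision[undecided][pLow <= spec@alpha / 2] <- "rejected"
      if (!any(decision == "tentative")) break
    }
    list(decision = factor(decision,
                           levels = c("confirmed", "rejected", "tentative")),
         z = if (iters > 0L) zsum / iters else zsum,
         hits = hits, iterations = iters, degenerate = degenerate)
  })
}

#' Repeated shadow importance with false-discovery estimation
#'
#' Runs \code{\link{borutaRun}} \code{nRepetitions} times, each on the data
#' extended with a fresh realization of the contrast variables.  The final
#' Z-score is the mean over repetitions, the decision for each original
#' feature is the majority decision, and the expected number of false
#' discoveries is the mean number of confirmed contrast variables per
#' repetition.
#'
#' @param data an \linkS4class{EnhancerFeatureSet} of original features.
#' @param spec an \linkS4class{ImportanceSpec}.
#' @return an \linkS4class{ImportanceReport}.
#' @export
repeatedImportance <- function(data, spec = importanceSpec()) {
  p <- ncol(data)
  nContrast <- if (is.na(spec@nContrast)) p else spec@nContrast
  feat <- colnames(data)
  nRep <- spec@nRepetitions

  zMat <- matrix(NA_real_, nRep, p, dimnames = list(NULL, feat))
  decMat <- matrix(NA_character_, nRep, p, dimnames = list(NULL, feat))
  contrastConfirmed <- numeric(nRep)
  for (rep in seq_len(nRep)) {
    repSeed <- stageSeed(spec@seed, 100L + rep)
    augmented <- addContrastVariables(data, nContrast, seed = repSeed)
    run <- borutaRun(augmented, spec, seed = stageSeed(spec@seed, 200L + rep))
    isContrast <- startsWith(names(run$hits), "CONTRAST:")
    zMat[rep, ] <- run$z[!isContrast]
    decMat[rep, ] <- as.character(run$decision[!isContrast])
    contrastConfirmed[rep] <- sum(run$decision[isContrast] == "confirmed")
  }
  majority <- apply(decMat, 2, function(d) {
    tab <- table(factor(d, levels = c("confirmed", "rejected", "tentative")))
    top <- names(tab)[tab == max(tab)]
    if (length(top) == 1L) top else "tentative"
  })
  new("ImportanceReport", meanZ = colMeans(zMat),
      decisions = factor(stats::setNames(majority, feat),
                         levels = c("confirmed", "rejected", "tentative")),
      contrastConfirmed = contrastConfirmed,
      expectedFalseDiscoveries = mean(contrastConfirmed),
      nRepetitions = nRep)
}

#' @describeIn repeatedImportance per-feature majority decisions.
#' @param x an \linkS4class{ImportanceReport}.
#' @export
setMethod("importanceDecisions", "ImportanceReport", function(x) {
  stats::setNames(x@decisions, names(x@meanZ))
})

#' @describeIn repeatedImportance per-feature mean Z-scores.
#' @export
setMethod("importanceZ", "ImportanceReport", function(x) x@meanZ)

#' @describeIn repeatedImportance mean confirmed contrasts per repetition.
#' @export
setMethod("expectedFalseDiscoveries", "ImportanceReport",
          function(x) x@expectedFalseDiscoveries)

#' Rank features by importance
#'
#' @param report an \linkS4class{ImportanceReport}.
#' @return feature names ordered from most to least important (by mean Z).
#' @export
importanceRanking <- function(report) {
  names(sort(report@meanZ, decreasing = TRUE))
}
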