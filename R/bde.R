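#' Equal-frequency discretization
#'
#' Bin edges are computed on training rows: the cut between ranks
#' \code{i*n/nBins} and the next value (midpoint), with duplicate edges
#' collapsed.  Test values outside the training range are clamped to the
#' outer bins.  A constant feature yields a single bin and a warning.
#'
#' @param x numeric matrix (rows = regions, columns = features).
#' @param nBins requested bins per feature (default 3).
#' @return list with \code{binned} (integer matrix, 1-based bin codes),
#'   \code{edges} (per-feature numeric cut points) and \code{nBins}
#'   (effective bins per feature).
#' @export
discretizeFeatures <- function(x, nBins = 3L) {
  if (nBins < 2L) stop("'nBins' must be >= 2")
  x <- as.matrix(x)
  n <- nrow(x)
  edges <- lapply(seq_len(ncol(x)), function(j) {
    s <- sort(x[, j])
    if (s[1] == s[n]) return(numeric(0))       # constant feature
    cut <- vapply(seq_len(nBins - 1L), function(b) {
      i <- max(1L, min(n - 1L, floor(b * n / nBins)))
      (s[i] + s[i + 1L]) / 2
    }, numeric(1))
    unique(cut)
  })
  names(edges) <- colnames(x)
  constant <- lengths(edges) == 0L
  if (any(constant))
    warning("constant feature(s) collapsed to a single bin: ",
            paste(colnames(x)[constant], collapse = ", "))
  binned <- applyBinEdges(x, edges)
  list(binned = binned, edges = edges, nBins = lengths(edges) + 1L)
}

applyBinEdges <- function(x, edges) {
  x <- as.matrix(x)
  binned <- matrix(1L, nrow(x), ncol(x), dimnames = dimnames(x))
  for (j in seq_len(ncol(x)))
    binned[, j] <- findInterval(x[, j], edges[[j]]) + 1L
  binned
}

#' BDe marginal-likelihood score of a class-parent configuration
#'
#' Standard Bayesian-Dirichlet equivalent score of the class variable given
#' a partition of the rows into parent configurations, with the uniform
#' prior alpha_jk = ESS/(q r):
#' sum_j [ lnG(a_j) - lnG(a_j + N_j) + sum_k ( lnG(a_jk + N_jk) -
#' lnG(a_jk) ) ].  Computed in log space; zero data scores 0 and the score
#' is invariant under relabeling of parent configurations.
#'
#' @param counts non-negative integer matrix, q parent configurations x r
#'   classes.
#' @param ess equivalent sample size of the Dirichlet prior (default 1).
#' @return log marginal likelihood (numeric scalar).
#' @export
bdeScore <- function(counts, ess = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  q <- nrow(counts)
  r <- ncol(counts)
  ajk <- ess / (q * r)
  aj <- ess / q
  nj <- rowSums(counts)
  sum(lgamma(aj) - lgamma(aj + nj)) +
    sum(lgamma(ajk + counts) - lgamma(ajk))
}

## Exhaustive parent-set search for the class node over all feature subsets
## of size 0..maxParents; ties broken toward smaller subsets, then
## lexicographic feature order (subsets are enumerated in that order and
## only a strictly better score replaces the incumbent).
trainBdeMatrix <- function(spec, x, y) {
  p <- ncol(x)
  maxParents <- min(spec@maxParents, p)
  nSubsets <- sum(vapply(0:maxParents, function(s) choose(p, s), numeric(1)))
  if (nSubsets > spec@searchBudget)
    stop(sprintf(paste0("BDe parent search over %d subsets exceeds the ",
                        "budget of %g; pre-filter the features (e.g. with ",
                        "the importance ranking) or raise 'searchBudget'"),
                 nSubsets, spec@searchBudget))
  disc <- withCallingHandlers(
    discretizeFeatures(x, spec@nBins),
    warning = function(w) invokeRestart("muffleWarning"))
  B <- disc$binned
  nb <- disc$nBins
  yk <- y + 1L

  best <- list(score = -Inf, parents = integer(0))
  for (s in 0:maxParents) {
    subsets <- if (s == 0L) list(integer(0))
               else asplit(combn(p, s), 2)
    for (sub in subsets) {
      sub <- as.integer(sub)
      q <- prod(nb[sub])
      code <- rep(1L, nrow(B))
      mult <- 1L
      for (j in sub) {
        code <- code + (B[, j] - 1L) * mult
        mult <- mult * nb[j]
      }
      counts <- matrix(0, q, 2L)
      tab <- tabulate(code + q * (yk - 1L), nbins = 2L * q)
      counts[, 1] <- tab[seq_len(q)]
      counts[, 2] <- tab[q + seq_len(q)]
      sc <- bdeScore(counts, spec@ess)
      if (sc > best$score + 1e-12) {
        best <- list(score = sc, parents = sub, counts = counts, q = q)
      }
    }
  }

  parents <- colnames(x)[best$parents]
  counts <- best$counts
  q <- best$q
  ajk <- spec@ess / (q * 2)
  aj <- spec@ess / q
  cpt <- (counts + ajk) / (rowSums(counts) + aj)  # P(class | config)
  new("BDEModel", spec = spec, featureNames = colnames(x),
      parents = parents, cpt = cpt,
      edges = disc$edges[best$parents], score = best$score)
}

#' @rdname predictScores-RFModel-method
#' @export
setMethod("predictScores", "BDEModel", function(model, newdata, ...) {
  x <- checkFeatureAlignment(model, newdata)
  if (!length(model@parents))
    return(rep(model@cpt[1, 2], nrow(x)))       # class prior for every row
  xp <- x[, model@parents, drop = FALSE]
  B <- applyBinEdges(xp, model@edges)
  nb <- lengths(model@edges) + 1L
  code <- rep(1L, nrow(B))
  mult <- 1L
  for (j in seq_along(model@parents)) {
    code <- code + (B[, j] - 1L) * mult
    mult <- mult * nb[j]
  }
  as.numeric(model@cpt[code, 2])
})
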