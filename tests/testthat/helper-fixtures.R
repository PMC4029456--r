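## Shared fixtures. Synthetic datasets are generated in code at test time;
## heavier acceptance checks reuse datasets across test files through a
## session-level cache keyed by configuration.

.fixtureCache <- new.env(parent = emptyenv())

## Labeled feature set for one realization of the synthetic world:
## nPositives enhancers + the same number of sampled negatives.
syntheticFeatureSet <- function(seed, nPositives = 500L,
                                chromLength = 400000L, ...) {
  key <- paste(c(seed, nPositives, chromLength, unlist(list(...))),
               collapse = "_")
  if (!is.null(.fixtureCache[[key]])) return(.fixtureCache[[key]])
  cfg <- syntheticConfig(seed = seed, nPositives = nPositives,
                         chromLength = as.integer(chromLength), ...)
  ds <- generateDataset(cfg)
  lenStats <- fitLengthDistribution(ds@positives)
  neg <- sampleNegatives(ds@genome, samplerSpec(
    n = length(ds@positives), lengthMean = lenStats[["mean"]],
    lengthSd = lenStats[["sd"]],
    exclusions = list(positives = ds@positives),
    seed = seed + 5000L))
  fs <- buildFeatureMatrix(ds@genome, ds@tracks, ds@pwms,
                           c(ds@positives, neg), "ALL")
  out <- list(config = cfg, dataset = ds, negatives = neg, features = fs)
  .fixtureCache[[key]] <- out
  out
}

## An "all signals zeroed" world: no mark effects, no planted motifs.
nullFeatureSet <- function(seed, nPositives = 500L, chromLength = 400000L) {
  syntheticFeatureSet(seed, nPositives, chromLength,
                      effectSizes = c(0, 0, 0), plantsPerEnhancer = 0)
}

## tiny deterministic labeled feature set for classifier unit tests:
## feature "EPI:sep" separates the classes perfectly, "MOT:noise" is noise
toyFeatureSet <- function(n = 20L, seed = 1L) {
  withr::with_seed(seed, {
    y <- rep(c("positive", "negative"), each = n / 2)
    sep <- ifelse(y == "positive", 1, 0) * 4 + rnorm(n, sd = 0.3)
    enhancerFeatureSet(cbind("EPI:sep" = sep, "MOT:noise" = rnorm(n)), y)
  })
}

## independent brute-force TRAP oracle, written against the stated model
## (per-site energies, logistic occupancy, both strands) before the C++
## path; deliberately naive and position-by-position
oracleTrap <- function(pwmObj, sequence, params = trapParams()) {
  probs <- pwmProbabilities(pwmObj, params@pseudocount)
  m <- motifLength(probs)
  L <- nchar(sequence)
  if (L < m) return(0)
  r0 <- defaultR0(m, params)
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  total <- 0
  for (strandSeq in c(sequence, revcomp(sequence))) {
    for (i in seq_len(nchar(strandSeq) - m + 1)) {
      site <- substr(strandSeq, i, i + m - 1)
      if (grepl("N", site)) next
      e <- mismatchEnergy(probs, site, params@lambda)
      occ <- r0 * exp(-e) / (1 + r0 * exp(-e))
      total <- total + occ
    }
  }
  total
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

randomDnaSeeded <- function(n, seed) withr::with_seed(seed, randomDna(n))

applyBinEdgesForTest <- function(x, edges)
  enhancerPred:::applyBinEdges(x, edges)

## GRanges builder (1-based closed coordinates, like the package internals)
makeRegionsForTest <- function(chrom, start, end, id = NULL, label = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  if (!is.null(id)) S4Vectors::mcols(gr)$id <- id
  if (!is.null(label))
    S4Vectors::mcols(gr)$label <- factor(label,
                                         levels = c("negative", "positive"))
  gr
}
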