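test_that("contrast variables are permuted copies of real features", {
  fx <- syntheticFeatureSet(308, nPositives = 30L, chromLength = 40000L)
  fs <- fx$features
  p <- ncol(fs)
  aug <- addContrastVariables(fs, nContrast = p, seed = 17L)
  expect_identical(ncol(aug), 2L * p)
  cn <- colnames(aug)
  expect_identical(sum(startsWith(cn, "CONTRAST:")), p)
  ## multiset equality with the source column, but not identical order
  x <- featureValues(aug)
  src <- colnames(fs)[1]
  contrastCol <- cn[startsWith(cn, paste0("CONTRAST:", src))][1]
  expect_identical(sort(unname(x[, src])), sort(unname(x[, contrastCol])))
  ## labels untouched
  expect_identical(regionLabels(aug), regionLabels(fs))
  ## fresh realizations differ between seeds
  aug2 <- addContrastVariables(fs, nContrast = p, seed = 18L)
  expect_false(identical(featureValues(aug2)[, contrastCol],
                         x[, contrastCol]))
})

test_that("a single run confirms an exact copy of the label and only it", {
  withr::with_seed(51, {
    n <- 200L
    y <- rep(c("negative", "positive"), each = n / 2)
    x <- matrix(rnorm(n * 5), n, 5,
                dimnames = list(NULL, paste0("EPI:noise", 1:5)))
    x[, 1] <- as.integer(y == "positive")          # feature = label
    colnames(x)[1] <- "EPI:oracle"
    fs <- enhancerFeatureSet(x, y)
    run <- borutaRun(fs, importanceSpec(maxRfIterations = 25L), seed = 52L)
    expect_identical(as.character(run$decision[["EPI:oracle"]]), "confirmed")
    expect_false(any(run$decision[startsWith(names(run$hits), "EPI:noise")]
                     == "confirmed"))
    expect_identical(names(which.max(run$z)), "EPI:oracle")
  })
})

test_that("one iteration can never decide at alpha = 0.01", {
  toy <- toyFeatureSet(40L, seed = 8L)
  run <- borutaRun(toy, importanceSpec(maxRfIterations = 1L), seed = 9L)
  expect_true(all(run$decision == "tentative"))
  expect_identical(run$iterations, 1L)
})

test_that("repeatedImportance with one repetition matches a single run", {
  fx <- syntheticFeatureSet(309, nPositives = 40L, chromLength = 50000L)
  fs <- fx$features
  spec <- importanceSpec(nRepetitions = 1L, maxRfIterations = 10L,
                         seed = 61L)
  rep1 <- repeatedImportance(fs, spec)
  aug <- addContrastVariables(fs, ncol(fs),
                              seed = enhancerPred:::stageSeed(61L, 101L))
  run <- borutaRun(aug, spec, seed = enhancerPred:::stageSeed(61L, 201L))
  keep <- !startsWith(names(run$hits), "CONTRAST:")
  expect_equal(unname(importanceZ(rep1)), unname(run$z[keep]))
  expect_identical(as.character(importanceDecisions(rep1)),
                   as.character(run$decision[keep]))
})

test_that("all-noise data yields no confirmations and near-zero FDR", {
  ## null simulation, scaled to a handful of seeds for the unit suite;
  ## the 20-seed version runs in the acceptance checks
  for (seed in 71:73) {
    withr::with_seed(seed, {
      n <- 60L
      x <- matrix(rnorm(n * 6), n, 6,
                  dimnames = list(NULL, paste0("EPI:n", 1:6)))
      fs <- enhancerFeatureSet(x, rep(c("negative", "positive"), n / 2))
    })
    rep <- repeatedImportance(fs, importanceSpec(
      nRepetitions = 5L, maxRfIterations = 12L, seed = seed))
    expect_identical(sum(importanceDecisions(rep) == "confirmed"), 0L)
    expect_lte(expectedFalseDiscoveries(rep), 0.5)
  }
})

test_that("reducedModelEval equals full CV on the full subset and checks names", {
  fx <- syntheticFeatureSet(310, nPositives = 40L, chromLength = 50000L)
  fs <- fx$features
  model <- modelSpec("rf", seed = 3L)
  cv <- cvSpec(k = 4, seed = 5)
  full <- crossValidate(model, fs, cv)
  same <- reducedModelEval(fs, colnames(fs), model, cv)
  expect_equal(full@foldError, same@foldError)
  expect_error(reducedModelEval(fs, character(0), model, cv), "non-empty")
  expect_error(reducedModelEval(fs, "MOT:absent", model, cv), "unknown")
})

test_that("ablation modes build the stated removal sets", {
  fx <- syntheticFeatureSet(311, nPositives = 60L, chromLength = 80000L)
  fs <- fx$features
  marks <- colnames(fs)[featureType(fs) == "EPI"]
  ## a deliberately fixed ranking: truth order then the rest
  ranking <- c("EPI:H3K4me1", "EPI:H3K36me3", "EPI:Mef2",
               setdiff(marks, c("EPI:H3K4me1", "EPI:H3K36me3", "EPI:Mef2")),
               colnames(fs)[featureType(fs) == "MOT"])
  spec <- ablationSpec("single_mark", model = modelSpec("rf", seed = 2L),
                       cv = cvSpec(k = 4, seed = 4))
  single <- ablationCurve(fs, spec, ranking)
  expect_identical(nrow(single), length(marks))
  expect_identical(sort(single$removed), sort(marks))

  topSpec <- ablationSpec("top_k_marks", kRange = 1:3,
                          model = modelSpec("rf", seed = 2L),
                          cv = cvSpec(k = 4, seed = 4))
  top <- ablationCurve(fs, topSpec, ranking)
  expect_identical(top$removed[1], "EPI:H3K4me1")
  expect_identical(top$removed[3], "EPI:H3K4me1,EPI:H3K36me3,EPI:Mef2")

  botSpec <- ablationSpec("bottom_k_marks", kRange = 1:2,
                          model = modelSpec("rf", seed = 2L),
                          cv = cvSpec(k = 4, seed = 4))
  bot <- ablationCurve(fs, botSpec, ranking)
  expect_identical(bot$K, 1:2)
  expect_false(any(grepl("H3K4me1", bot$removed)))

  expect_error(ablationCurve(fs, ablationSpec("top_k_marks", kRange = 9L),
                             ranking), "exceeds")
})

test_that("removing every informative mark from EPI data kills the signal", {
  fx <- syntheticFeatureSet(312, nPositives = 60L, chromLength = 80000L)
  epi <- subsetFeatures(fx$features, "EPI")
  keep <- setdiff(colnames(epi),
                  paste0("EPI:", fx$dataset@truth$informativeMarks))
  res <- reducedModelEval(epi, keep, modelSpec("rf", seed = 6L),
                          cvSpec(k = 4, seed = 6))
  expect_lt(meanAuc(res), 0.65)
  expect_gt(meanError(res), 0.3)
})

test_that("iterative TF elimination follows the 80%-or-single rule", {
  ## trace arithmetic: 125 -> 25 -> 5 -> 1 and 4 -> 3 -> 2 -> 1
  counts <- function(n0) {
    trace <- n <- as.integer(n0)
    while (n > 1) {
      n <- n - (if (n >= 5) as.integer(floor(0.8 * n)) else 1L)
      trace <- c(trace, n)
    }
    trace
  }
  expect_identical(counts(125L), c(125L, 25L, 5L, 1L))
  expect_identical(counts(4L), c(4L, 3L, 2L, 1L))

  ## end-to-end on a small system with one driver motif
  fx <- syntheticFeatureSet(313, nPositives = 50L, chromLength = 60000L,
                            nMotifs = 6L, nDriverMotifs = 1L)
  trace <- iterativeTfElimination(
    fx$features,
    importanceSpec(nRepetitions = 2L, maxRfIterations = 8L, seed = 7L),
    model = modelSpec("rf", seed = 8L), cv = cvSpec(k = 4, seed = 9))
  expect_identical(trace$nTf, c(6L, 2L, 1L))   # floor(0.8*6)=4, then single
  ## the planted driver survives to the last step
  expect_identical(trace$tfFeatures[nrow(trace)],
                   paste0("MOT:", fx$dataset@truth$driverMotifs))
})
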