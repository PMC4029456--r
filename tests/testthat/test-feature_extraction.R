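test_that("PWM normalization applies pseudocounts per position", {
  p <- pwm("m", matrix(c(10, 0, 0, 0), 1, 4))
  probs <- pwmProbabilities(p, 1)
  expect_equal(as.numeric(pwmMatrix(probs)), c(11, 1, 1, 1) / 14)
  expect_equal(rowSums(pwmMatrix(probs)), 1)

  ## probabilities in, pseudocount 0 -> unchanged
  q <- pwm("m", matrix(c(0.7, 0.1, 0.1, 0.1), 1, 4))
  expect_equal(pwmMatrix(pwmProbabilities(q, 0)), pwmMatrix(q))

  expect_error(pwmProbabilities(pwm("m", matrix(0, 1, 4)), 0), "all-zero")
})

test_that("mismatch energy matches the hand-evaluated formula", {
  q <- pwm("m", matrix(c(0.7, 0.1, 0.1, 0.1), 1, 4))
  expect_equal(mismatchEnergy(q, "A", 0.7), 0)
  expect_equal(mismatchEnergy(q, "C", 0.7), log(7) / 0.7,
               tolerance = 1e-12)
  ## additive over positions
  q2 <- pwm("m", matrix(c(0.7, 0.1, 0.1, 0.1,
                          0.1, 0.6, 0.2, 0.1), 2, 4, byrow = TRUE))
  expect_equal(mismatchEnergy(q2, "CG", 0.7),
               mismatchEnergy(pwm("a", pwmMatrix(q2)[1, , drop = FALSE]),
                              "C", 0.7) +
               mismatchEnergy(pwm("b", pwmMatrix(q2)[2, , drop = FALSE]),
                              "G", 0.7))
  expect_error(mismatchEnergy(q2, "C"), "length")
})

test_that("R0 follows the motif-length rule and the override", {
  expect_equal(defaultR0(10), exp(0.18), tolerance = 1e-12)
  ## R0 crosses 1 between m = 9 and m = 10 (0.584 m = 5.66 at m ~ 9.69)
  expect_lt(defaultR0(9), 1)
  expect_gt(defaultR0(10), 1)
  expect_equal(defaultR0(10, trapParams(r0Override = 2.5)), 2.5)
})

test_that("TRAP closed forms hold", {
  params <- trapParams(pseudocount = 0)
  ## uniform PWM: every site has E = 0, occupancy R0/(1+R0)
  m <- 10L
  p <- pwm("u", matrix(0.25, m, 4))
  r0 <- defaultR0(m, params)
  for (L in c(10L, 57L, 200L)) {
    a <- trapAffinity(p, randomDnaSeeded(L, L), params)
    expect_equal(a, 2 * (L - m + 1) * r0 / (1 + r0), tolerance = 1e-12)
  }
  ## L < m -> 0 with a warning
  expect_warning(a0 <- trapAffinity(p, "ACGTACGTA", params), "shorter")
  expect_identical(a0, 0)
  expect_error(trapAffinity(p, "", params), "empty")
})

test_that("TRAP affinity is strand-symmetric and bounded", {
  withr::with_seed(7, {
    p <- generatePwms(syntheticConfig(nMotifs = 1L, nDriverMotifs = 1L,
                                      seed = 4L))[[1]]
    for (i in 1:10) {
      s <- randomDna(120)
      rc <- chartr("ACGT", "TGCA",
                   paste(rev(strsplit(s, "")[[1]]), collapse = ""))
      a <- trapAffinity(p, s)
      expect_equal(a, trapAffinity(p, rc), tolerance = 1e-9)
      expect_lte(a, 2 * (nchar(s) - motifLength(p) + 1))
      expect_gte(a, 0)
    }
  })
})

test_that("sites containing N contribute zero occupancy", {
  params <- trapParams(pseudocount = 0)
  m <- 4L
  p <- pwm("u", matrix(0.25, m, 4))
  r0 <- defaultR0(m, params)
  ## one N at position 5 of a 12-mer removes the 4 sites covering it
  a <- trapAffinity(p, "ACGTNACGTACG", params)
  expect_equal(a, 2 * (9 - 4) * r0 / (1 + r0), tolerance = 1e-12)
})

test_that("epiFeature averages every overlapped window, unweighted", {
  tr <- signalTrack("m", list(chr1 = c(1, 3)), 50L)
  ## region covering bases 41..60 (1-based) overlaps both windows
  expect_equal(epiFeature(tr, makeRegionsForTest("chr1", 41, 60)), 2)
  expect_equal(epiFeature(tr, makeRegionsForTest("chr1", 51, 100)), 3)
  ## constant track -> the constant
  trc <- signalTrack("m", list(chr1 = rep(7, 20)), 50L)
  expect_equal(epiFeature(trc, makeRegionsForTest("chr1", 3, 617)), 7)
  ## windows past the recorded extent are imputed 0: (3 + 0) / 2
  expect_equal(epiFeature(tr, makeRegionsForTest("chr1", 51, 150)), 1.5)
  expect_error(epiFeature(tr, makeRegionsForTest("chr9", 1, 10)),
               "unknown chromosome")
})

test_that("epiFeature is invariant to splitting at a window boundary", {
  withr::with_seed(11, {
    v <- rnorm(40)
    tr <- signalTrack("m", list(chr1 = v), 50L)
    whole <- makeRegionsForTest("chr1", 120, 1480)
    left <- makeRegionsForTest("chr1", 120, 1000)    # ends at window edge
    right <- makeRegionsForTest("chr1", 1001, 1480)
    nl <- (1000 - 1) %/% 50 - (120 - 1) %/% 50 + 1   # windows under each part
    nr <- (1480 - 1) %/% 50 - (1001 - 1) %/% 50 + 1
    expect_equal(epiFeature(tr, whole),
                 (epiFeature(tr, left) * nl + epiFeature(tr, right) * nr) /
                   (nl + nr))
  })
})

test_that("buildFeatureMatrix assembles tagged columns in stable order", {
  fx <- syntheticFeatureSet(301, nPositives = 30L, chromLength = 30000L)
  ds <- fx$dataset
  regions <- c(ds@positives, fx$negatives)
  all <- buildFeatureMatrix(ds@genome, ds@tracks, ds@pwms, regions, "ALL")
  epi <- buildFeatureMatrix(ds@genome, ds@tracks, ds@pwms, regions, "EPI")
  mot <- buildFeatureMatrix(ds@genome, list(), ds@pwms, regions, "MOT")
  expect_identical(ncol(epi), 8L)           # the 8 chromatin marks
  expect_identical(ncol(mot), length(ds@pwms))
  expect_identical(colnames(all), c(colnames(epi), colnames(mot)))
  expect_equal(featureValues(all)[, colnames(epi)], featureValues(epi))
  expect_equal(featureValues(all)[, colnames(mot)], featureValues(mot))
  ## row order follows the input regions
  expect_identical(regionIds(all),
                   S4Vectors::mcols(regions)$id)
  ## vectorized EPI equals the per-region operation
  for (i in c(1L, 17L, length(regions))) {
    expect_equal(featureValues(all)[i, "EPI:Mef2"],
                 epiFeature(ds@tracks$Mef2, regions[i]))
  }
  ## region beyond the chromosome end is refused
  bad <- makeRegionsForTest("chr1", 29990, 30050, label = "positive")
  expect_error(
    buildFeatureMatrix(ds@genome, ds@tracks, ds@pwms, bad, "EPI"),
    "beyond")
})

test_that("MOT features respond to planted driver motifs", {
  fx <- syntheticFeatureSet(302, nPositives = 60L, chromLength = 60000L)
  vals <- featureValues(fx$features)
  lab <- regionLabels(fx$features)
  driver <- paste0("MOT:", fx$dataset@truth$driverMotifs[1])
  expect_gt(mean(vals[lab == "positive", driver]),
            mean(vals[lab == "negative", driver]))
})
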