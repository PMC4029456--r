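test_that("all three backends separate a trivially separable toy set", {
  toy <- toyFeatureSet(20L)
  for (kind in c("rf", "svm", "bde")) {
    ## bde: 2 bins so the equal-frequency cut falls on the class boundary
    ## of the balanced toy (3 bins would split inside a cluster)
    model <- trainModel(modelSpec(kind, seed = 3L, nBins = 2L), toy)
    scores <- predictScores(model, toy)
    expect_equal(
      classificationError(scores, regionLabels(toy),
                          decisionThreshold(model)),
      0, info = kind)
  }
  expect_error(trainModel(new("ModelSpec", kind = "rf"),
                          toyFeatureSet(20L)[1:10, ]), "single-class")
})

test_that("rf predictions are deterministic under a fixed seed", {
  fx <- syntheticFeatureSet(304, nPositives = 40L, chromLength = 50000L)
  fs <- fx$features
  m1 <- trainModel(modelSpec("rf", seed = 11L), fs)
  m2 <- trainModel(modelSpec("rf", seed = 11L), fs)
  expect_identical(predictScores(m1, fs), predictScores(m2, fs))
  ## a different seed gives a different forest
  m3 <- trainModel(modelSpec("rf", seed = 12L), fs)
  expect_false(identical(predictScores(m1, fs), predictScores(m3, fs)))
  ## rf scores are vote fractions
  s <- predictScores(m1, fs)
  expect_true(all(s >= 0 & s <= 1))
  expect_true(all(abs(s * 30 - round(s * 30)) < 1e-9))
})

test_that("feature misalignment is an error, not silent misprediction", {
  toy <- toyFeatureSet(20L)
  model <- trainModel(modelSpec("rf", seed = 1L), toy)
  x <- featureValues(toy)
  expect_error(predictScores(model, x[, rev(colnames(x))]), "order")
  expect_error(predictScores(model, x[, 1, drop = FALSE]), "match")
  expect_silent(predictScores(model, x))
})

test_that("equal-frequency discretization matches the stated example", {
  d <- discretizeFeatures(matrix(1:9, 9, 1, dimnames = list(NULL, "f")), 3)
  expect_identical(as.integer(d$binned), rep(1:3, each = 3))
  ## test values below / above the training range clamp to outer bins
  b <- applyBinEdgesForTest(matrix(c(-5, 100), 2, 1,
                                   dimnames = list(NULL, "f")), d$edges)
  expect_identical(as.integer(b), c(1L, 3L))
  expect_warning(discretizeFeatures(matrix(1, 5, 1), 3), "constant")
})

test_that("the BDe score behaves as a proper marginal likelihood", {
  expect_identical(bdeScore(matrix(0, 2, 2)), 0)     # empty product
  ## invariance under relabeling of parent configurations
  counts <- matrix(c(5, 1, 2, 7), 2, 2)
  expect_equal(bdeScore(counts), bdeScore(counts[2:1, ]))
  ## a perfectly predictive binary feature beats the empty parent set
  perfect <- matrix(c(2, 0, 0, 2), 2, 2)      # config x class
  empty <- matrix(c(2, 2), 1, 2)
  expect_gt(bdeScore(perfect, 1), bdeScore(empty, 1))
  expect_error(bdeScore(matrix(-1, 1, 2)), "non-negative")
})

test_that("BDe parent search finds the predictive feature among noise", {
  withr::with_seed(31, {
    n <- 80L
    y <- rep(c("negative", "positive"), each = n / 2)
    x <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(NULL, paste0("EPI:noise", 1:4)))
    signal <- ifelse(y == "positive", 1, 0) + rnorm(n, sd = 0.05)
    fs <- enhancerFeatureSet(cbind(x, "EPI:signal" = signal), y)
    model <- trainModel(modelSpec("bde", seed = 1L), fs)
    expect_true("EPI:signal" %in% model@parents)
    expect_false(any(grepl("noise", model@parents)))
  })
})

test_that("maxParents = 0 yields the class-prior classifier", {
  toy <- toyFeatureSet(20L)
  model <- trainModel(modelSpec("bde", maxParents = 0L), toy)
  expect_length(model@parents, 0L)
  s <- predictScores(model, toy)
  expect_true(all(s == s[1]))                 # prior for every row
  expect_equal(s[1], 0.5, tolerance = 0.05)   # balanced labels
})

test_that("the BDe search budget guards against feature blow-up", {
  withr::with_seed(32, {
    x <- matrix(rnorm(40 * 30), 40, 30,
                dimnames = list(NULL, sprintf("MOT:TF%03d", 1:30)))
    fs <- enhancerFeatureSet(x, rep(c("positive", "negative"), 20))
    ## choose(30,3) + ... = 4525 subsets; a budget of 100 must refuse
    expect_error(trainModel(modelSpec("bde", searchBudget = 100), fs),
                 "budget")
  })
})

test_that("a pure-noise parent does not raise the BDe score in expectation", {
  withr::with_seed(33, {
    diffs <- replicate(100, {
      n <- 40L
      y <- sample(0:1, n, replace = TRUE)
      noise <- sample(1:2, n, replace = TRUE)
      empty <- matrix(c(sum(y == 0), sum(y == 1)), 1, 2)
      withParent <- rbind(c(sum(y == 0 & noise == 1), sum(y == 1 & noise == 1)),
                          c(sum(y == 0 & noise == 2), sum(y == 1 & noise == 2)))
      bdeScore(withParent, 1) - bdeScore(empty, 1)
    })
    expect_lte(mean(diffs), 0)
  })
})

test_that("bde and rf agree on strongly informative chromatin features", {
  fx <- syntheticFeatureSet(314, nPositives = 100L, chromLength = 100000L)
  epi <- subsetFeatures(fx$features, "EPI")
  cv <- cvSpec(k = 5L, seed = 3L)
  aucRf <- meanAuc(crossValidate(modelSpec("rf", seed = 4L), epi, cv))
  aucBde <- meanAuc(crossValidate(modelSpec("bde"), epi, cv))
  expect_lte(abs(aucRf - aucBde), 0.05)
})

test_that("svm standardization lives in the model, not the data", {
  toy <- toyFeatureSet(40L)
  scaled <- enhancerFeatureSet(featureValues(toy) * 1000,
                               regionLabels(toy), ids = regionIds(toy))
  m <- trainModel(modelSpec("svm", seed = 2L), scaled)
  s <- predictScores(m, scaled)
  expect_equal(classificationError(s, regionLabels(scaled), 0), 0)
})
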