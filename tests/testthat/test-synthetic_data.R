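test_that("genome generation honours GC content, repeats and determinism", {
  cfg0 <- syntheticConfig(nChroms = 1L, chromLength = 20000L, gcContent = 0,
                          repeatFraction = 0, seed = 5L)
  g <- generateGenome(cfg0)
  freq <- Biostrings::alphabetFrequency(g$genome[[1]])
  expect_identical(sum(freq[c("C", "G")]), 0L)       # AT-only genome
  expect_length(g$repeatTracts, 0L)

  cfg1 <- syntheticConfig(nChroms = 2L, chromLength = 20000L,
                          repeatFraction = 0.1, seed = 6L)
  g1 <- generateGenome(cfg1)
  expect_gt(sum(GenomicRanges::width(g1$repeatTracts)), 0.05 * 40000)
  ## tract sequence really is a 2-mer run
  tr <- g1$repeatTracts[1]
  s <- as.character(Biostrings::subseq(
    g1$genome[[as.character(GenomicRanges::seqnames(tr))]],
    GenomicRanges::start(tr), GenomicRanges::end(tr)))
  expect_lte(length(unique(strsplit(s, "")[[1]])), 2L)

  ## byte-identical under the same seed
  g2 <- generateGenome(cfg1)
  expect_identical(as.character(g1$genome), as.character(g2$genome))

  expect_error(generateGenome(syntheticConfig(chromLength = 1000L)),
               "infeasible")
})

test_that("generated PWMs are proper probability matrices with a dominant base", {
  cfg <- syntheticConfig(nMotifs = 12L, motifLengthRange = c(6L, 9L),
                         seed = 8L)
  pwms <- generatePwms(cfg)
  expect_length(pwms, 12L)
  expect_identical(names(pwms)[1], "TF001")
  for (p in pwms) {
    m <- pwmMatrix(p)
    expect_true(all(nrow(m) >= 6 & nrow(m) <= 9))
    expect_equal(rowSums(m), rep(1, nrow(m)), tolerance = 1e-9)
    expect_true(all(apply(m, 1, max) >= 0.7))
  }
})

test_that("enhancer placement respects lengths, bounds and non-overlap", {
  cfg <- syntheticConfig(nPositives = 40L, nChroms = 1L,
                         chromLength = 60000L, posLengthSd = 0,
                         seed = 9L)
  g <- generateGenome(cfg)
  pwms <- generatePwms(cfg)
  enh <- placeEnhancers(cfg, g$genome, pwms)
  pos <- enh$positives
  expect_length(pos, 40L)
  ## sd = 0 -> all lengths equal the rounded mean
  expect_true(all(GenomicRanges::width(pos) == round(cfg@posLengthMean)))
  expect_true(all(GenomicRanges::start(pos) >= 1))
  expect_true(all(GenomicRanges::end(pos) <= 60000))
  ## pairwise non-overlap
  hits <- GenomicRanges::countOverlaps(pos, pos)
  expect_true(all(hits == 1L))
  ## genome is only modified inside enhancers
  changed <- which(strsplit(as.character(g$genome[[1]]), "")[[1]] !=
                   strsplit(as.character(enh$genome[[1]]), "")[[1]])
  if (length(changed)) {
    inEnh <- GenomicRanges::countOverlaps(
      makeRegionsForTest("chr1", changed, changed), pos) > 0
    expect_true(all(inEnh))
  }
})

test_that("plantsPerEnhancer = 0 leaves the background sequence untouched", {
  cfg <- syntheticConfig(nPositives = 10L, nChroms = 1L,
                         chromLength = 30000L, plantsPerEnhancer = 0,
                         seed = 10L)
  g <- generateGenome(cfg)
  enh <- placeEnhancers(cfg, g$genome, generatePwms(cfg))
  expect_identical(as.character(g$genome), as.character(enh$genome))
})

test_that("simulated tracks carry the stated class-conditional structure", {
  cfg <- syntheticConfig(nPositives = 20L, nChroms = 1L,
                         chromLength = 50000L, noiseSd = 0,
                         informativeMarks = "H3K4me1", effectSizes = 5,
                         seed = 12L)
  g <- generateGenome(cfg)
  enh <- placeEnhancers(cfg, g$genome, generatePwms(cfg))
  tracks <- simulateTracks(cfg, enh$genome, enh$positives)
  v <- trackValues(tracks$H3K4me1, "chr1")
  overlapped <- unique(unlist(lapply(seq_along(enh$positives), function(i) {
    (((GenomicRanges::start(enh$positives[i]) - 1L) %/% 50L):
       ((GenomicRanges::end(enh$positives[i]) - 1L) %/% 50L)) + 1L
  })))
  expect_true(all(v[overlapped] == 5))
  expect_true(all(v[-overlapped] == 0))
  ## uninformative marks are exactly zero at noiseSd = 0
  expect_true(all(trackValues(tracks$PolII, "chr1") == 0))
})

test_that("an uninformative mark has equal class-conditional window means", {
  ## two-sample comparison over ~2 x 10^4 windows
  cfg <- syntheticConfig(nPositives = 100L, nChroms = 1L,
                         chromLength = 1000000L, noiseSd = 1,
                         seed = 13L)
  g <- generateGenome(cfg)
  enh <- placeEnhancers(cfg, g$genome, generatePwms(cfg))
  tracks <- simulateTracks(cfg, enh$genome, enh$positives)
  v <- trackValues(tracks$H3K4me3, "chr1")        # not informative
  overlapped <- unique(unlist(lapply(seq_along(enh$positives), function(i) {
    (((GenomicRanges::start(enh$positives[i]) - 1L) %/% 50L):
       ((GenomicRanges::end(enh$positives[i]) - 1L) %/% 50L)) + 1L
  })))
  tt <- t.test(v[overlapped], v[-overlapped])
  expect_gt(tt$p.value, 1e-4)
})

test_that("the non-additive pair routes the effect to exactly one mark", {
  cfg <- syntheticConfig(nPositives = 30L, nChroms = 1L,
                         chromLength = 60000L, noiseSd = 0,
                         informativeMarks = c("H3K4me1", "H3K27Ac"),
                         effectSizes = c(5, 5),
                         nonadditivePair = c("H3K4me1", "H3K27Ac"),
                         seed = 14L)
  g <- generateGenome(cfg)
  enh <- placeEnhancers(cfg, g$genome, generatePwms(cfg))
  tracks <- simulateTracks(cfg, enh$genome, enh$positives)
  v1 <- trackValues(tracks$H3K4me1, "chr1")
  v2 <- trackValues(tracks$H3K27Ac, "chr1")
  sawBoth <- c(FALSE, FALSE)
  for (i in seq_along(enh$positives)) {
    win <- (((GenomicRanges::start(enh$positives[i]) - 1L) %/% 50L):
              ((GenomicRanges::end(enh$positives[i]) - 1L) %/% 50L)) + 1L
    m1 <- all(v1[win] == 5)
    m2 <- all(v2[win] == 5)
    expect_true(xor(m1, m2))
    sawBoth <- sawBoth | c(m1, m2)
  }
  expect_true(all(sawBoth))       # the coin uses both sides
})

test_that("generateDataset writes a loadable directory, deterministically", {
  cfg <- syntheticConfig(nPositives = 15L, nChroms = 1L,
                         chromLength = 30000L, nMotifs = 4L, seed = 15L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  ds1 <- generateDataset(cfg, dir = d1)
  ds2 <- generateDataset(cfg, dir = d2)
  files <- c("genome.fa", "positives.bed", "motifs.pfm", "truth.json",
             "config.json", paste0(cfg@markNames, ".bedGraph"))
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)), label = f)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  ## the written inputs reload to the in-memory objects
  g <- readGenomeFasta(file.path(d1, "genome.fa"))
  expect_identical(as.character(g), as.character(ds1@genome))
  pos <- readBed(file.path(d1, "positives.bed"), label = "positive")
  expect_identical(GenomicRanges::start(pos),
                   GenomicRanges::start(ds1@positives))
  tr <- readBedGraph(file.path(d1, "H3K4me1.bedGraph"), 50)
  expect_equal(trackValues(tr, "chr1"),
               trackValues(ds1@tracks$H3K4me1, "chr1"), tolerance = 1e-4)
  pwms <- readJasparPfm(file.path(d1, "motifs.pfm"))
  expect_identical(names(pwms), names(ds1@pwms))
})
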