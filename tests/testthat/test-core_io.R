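test_that("FASTA reading uppercases, folds lines and rejects bad input", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 description", "ACGT"), fa)
  g <- readGenomeFasta(fa)
  expect_identical(names(g), "chr1")
  expect_identical(as.character(g[["chr1"]]), "ACGT")
  expect_identical(Biostrings::width(g), 4L)

  writeLines(c(">a", "acg", "t", ">b", "NN"), fa)
  g <- readGenomeFasta(fa)
  expect_identical(as.character(g[["a"]]), "ACGT")
  expect_identical(as.character(g[["b"]]), "NN")

  writeLines(c(">a", "ACGU"), fa)
  expect_error(readGenomeFasta(fa))
  writeLines(c(">a", "ACGR"), fa)          # IUPAC code, not allowed
  expect_error(readGenomeFasta(fa), "outside")
  writeLines(c(">a", "ACGT", ">a", "TT"), fa)
  expect_error(readGenomeFasta(fa), "duplicate")
})

test_that("BED coordinates are half-open and round-trip with ids", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t0\t100", bed)
  r <- readBed(bed)
  expect_identical(GenomicRanges::start(r), 1L)
  expect_identical(GenomicRanges::end(r), 100L)
  expect_identical(GenomicRanges::width(r), 100L)    # length L covers L bases

  writeLines("chr1\t100\t100", bed)
  expect_error(readBed(bed), "start >= end")
  writeLines("chr1\t1.5\t100", bed)
  expect_error(readBed(bed), "non-integer")

  regions <- makeRegionsForTest(c("chr1", "chr2", "chr1"), c(1, 51, 500),
                                c(100, 80, 777), id = c("a", "b", "c"))
  writeBed(regions, bed)
  back <- readBed(bed)
  expect_identical(as.character(GenomicRanges::seqnames(back)),
                   c("chr1", "chr2", "chr1"))
  expect_identical(GenomicRanges::start(back), c(1L, 51L, 500L))
  expect_identical(GenomicRanges::end(back), c(100L, 80L, 777L))
  expect_identical(S4Vectors::mcols(back)$id, c("a", "b", "c"))
})

test_that("bedGraph windows are grid-checked and gaps impute 0", {
  bg <- withr::local_tempfile(fileext = ".bedGraph")
  writeLines(c("chr1\t0\t50\t1.0", "chr1\t50\t100\t3.0"), bg)
  tr <- readBedGraph(bg, 50, mark = "m")
  expect_equal(trackValues(tr, "chr1"), c(1, 3))

  writeLines("chr1\t25\t75\t1.0", bg)
  expect_error(readBedGraph(bg, 50), "grid")

  writeLines(c("chr1\t0\t50\t2.0", "chr1\t100\t150\t4.0"), bg)
  expect_equal(trackValues(readBedGraph(bg, 50), "chr1"), c(2, 0, 4))

  writeLines(c("chr1\t0\t50\t2.0", "chr1\t0\t50\t4.0"), bg)
  expect_error(readBedGraph(bg, 50), "overlap")

  ## a short final window is legal; a short interior one is not
  writeLines(c("chr1\t0\t50\t2.0", "chr1\t50\t80\t4.0"), bg)
  expect_equal(trackValues(readBedGraph(bg, 50), "chr1"), c(2, 4))
  writeLines(c("chr1\t0\t30\t2.0", "chr1\t50\t100\t4.0"), bg)
  expect_error(readBedGraph(bg, 50), "short")
})

test_that("JASPAR PFM parsing preserves counts and catches malformed records", {
  pfm <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">M1", "A [ 10 0 ]", "C [ 0 10 ]", "G [ 0 0 ]", "T [ 0 0 ]"),
             pfm)
  p <- readJasparPfm(pfm)
  expect_length(p, 1L)
  expect_identical(motifLength(p$M1), 2L)
  expect_equal(pwmMatrix(p$M1)[, "A"], c(10, 0))
  expect_equal(pwmMatrix(p$M1)[, "C"], c(0, 10))
  ## consensus of the counts is AC
  expect_identical(
    paste(c("A", "C", "G", "T")[apply(pwmMatrix(p$M1), 1, which.max)],
          collapse = ""), "AC")

  writeLines(">M1", pfm)
  expect_error(readJasparPfm(pfm), "4 base rows")
  writeLines(c(">M1", "A [ 10 ]", "C [ 0 10 ]", "G [ 0 0 ]", "T [ 0 0 ]"),
             pfm)
  expect_error(readJasparPfm(pfm), "unequal")
})

test_that("a many-record PFM file round-trips with unique ids", {
  ## the real motif library holds 125 insect motifs; emulate that size
  cfg <- syntheticConfig(nMotifs = 125L, seed = 3L)
  pwms <- generatePwms(cfg)
  pfm <- withr::local_tempfile(fileext = ".pfm")
  writeJasparPfm(pwms, pfm)
  back <- readJasparPfm(pfm)
  expect_length(back, 125L)
  expect_false(anyDuplicated(names(back)) > 0)
  expect_equal(pwmMatrix(back$TF077), pwmMatrix(pwms$TF077),
               tolerance = 1e-6)
})

test_that("regionsOverlap follows half-open abutment semantics", {
  r <- function(chrom, s0, e0)        # BED-style 0-based half-open input
    makeRegionsForTest(chrom, s0 + 1, e0)
  expect_true(regionsOverlap(r("chr1", 0, 100), r("chr1", 99, 200)))
  expect_false(regionsOverlap(r("chr1", 0, 100), r("chr1", 100, 200)))
  expect_false(regionsOverlap(r("chr1", 0, 100), r("chr2", 0, 100)))
  ## symmetry
  expect_true(regionsOverlap(r("chr1", 99, 200), r("chr1", 0, 100)))
})

test_that("feature tables round-trip losslessly with EPI/MOT prefixes", {
  vals <- matrix(c(pi, exp(1), 1 / 3, 12345.6789), 2, 2,
                 dimnames = list(NULL, c("EPI:H3K4me1", "MOT:TF001")))
  fs <- enhancerFeatureSet(vals, c("positive", "negative"),
                           ids = c("r1", "r2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeFeatureTable(fs, path)
  back <- readFeatureTable(path)
  expect_equal(featureValues(back), featureValues(fs), tolerance = 1e-11)
  expect_identical(colnames(back), c("EPI:H3K4me1", "MOT:TF001"))
  expect_identical(featureType(back), c("EPI", "MOT"))
  expect_identical(as.character(regionLabels(back)),
                   c("positive", "negative"))
  expect_identical(regionIds(back), c("r1", "r2"))

  writeLines(c("id\tEPI:a\tlabel", "r1\t1.0\tpositive", "r2\tpositive"),
             path)
  expect_error(readFeatureTable(path))
})

test_that("random valid files round-trip for BED and bedGraph", {
  withr::with_seed(99, {
    for (i in 1:5) {
      n <- sample(3:20, 1)
      s0 <- sort(sample(0:5000, n))
      len <- sample(10:200, n, replace = TRUE)
      gr <- makeRegionsForTest("chrX", s0 + 1, s0 + len,
                               id = sprintf("r%02d", seq_len(n)))
      f <- withr::local_tempfile(fileext = ".bed")
      writeBed(gr, f)
      back <- readBed(f)
      expect_identical(GenomicRanges::start(back), GenomicRanges::start(gr))
      expect_identical(GenomicRanges::end(back), GenomicRanges::end(gr))

      v <- round(rnorm(sample(5:30, 1)), 4)
      tr <- signalTrack("m", list(chr1 = v), 50L)
      f2 <- withr::local_tempfile(fileext = ".bedGraph")
      writeBedGraph(tr, f2)
      expect_equal(trackValues(readBedGraph(f2, 50), "chr1"), v)
    }
  })
})
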