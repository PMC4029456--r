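#' Length distribution of a region set
#'
#' Sample mean and standard deviation (n-1 denominator) of region lengths,
#' used to length-match negative samples to the positive set.
#'
#' @param regions GRanges with at least 2 regions.
#' @return named numeric vector \code{c(mean, sd)}.
#' @export
fitLengthDistribution <- function(regions) {
  if (length(regions) < 2L)
    stop("at least 2 regions are required to fit a length distribution")
  len <- GenomicRanges::width(regions)
  c(mean = mean(len), sd = stats::sd(len))
}

#' Sample random negative regions
#'
#' Draws exactly \code{spec@n} regions labeled negative: lengths are
#' Gaussian(\code{lengthMean}, \code{lengthSd}) rounded, redrawn while below
#' \code{minLength}; the chromosome is chosen with probability proportional
#' to its length and the start uniformly.  Candidates overlapping any
#' exclusion set (or, when \code{mutualExclusion}, any previous draw), or
#' containing more than \code{maxNFraction} N bases, are rejected and
#' redrawn.  If the attempt budget \code{n * maxAttemptsFactor} is exhausted
#' the error names the exclusion set that rejected most candidates.
#'
#' @param genome DNAStringSet, or a named vector of chromosome lengths (the
#'   N-content filter then cannot run).
#' @param spec a \linkS4class{SamplerSpec}.
#' @return GRanges of \code{spec@n} regions with \code{label = "negative"}.
#' @export
sampleNegatives <- function(genome, spec) {
  sizes <- chromLengths(genome)
  hasSeq <- is(genome, "DNAStringSet")
  excl <- lapply(spec@exclusions, function(gr) {
    split(data.frame(start = GenomicRanges::start(gr),
                     end = GenomicRanges::end(gr)),
          as.character(GenomicRanges::seqnames(gr)))
  })
  rejections <- stats::setNames(numeric(length(excl)), names(excl))
  if (spec@n == 0L) return(GenomicRanges::GRanges())

  withSeed(spec@seed, {
    n <- spec@n
    accStart <- accEnd <- vector("list", length(sizes))
    names(accStart) <- names(accEnd) <- names(sizes)
    for (ch in names(sizes)) accStart[[ch]] <- accEnd[[ch]] <- numeric(0)
    out <- vector("list", n)
    budget <- as.numeric(n) * spec@maxAttemptsFactor
    attempts <- 0
    got <- 0L
    collisions <- 0
    while (got < n) {
      if (attempts >= budget) {
        tightest <- if (length(rejections) && any(rejections > 0))
          names(which.max(rejections)) else "mutual exclusion"
        stop("negative sampling exhausted ", format(budget),
             " attempts; tightest exclusion: ", tightest)
      }
      attempts <- attempts + 1
      len <- round(rnorm(1L, spec@lengthMean, spec@lengthSd))
      while (len < spec@minLength)
        len <- round(rnorm(1L, spec@lengthMean, spec@lengthSd))
      len <- as.integer(len)
      chrom <- if (length(sizes) == 1L) names(sizes)
               else sample(names(sizes), 1L, prob = sizes)
      if (len > sizes[[chrom]]) next
      st <- sample.int(sizes[[chrom]] - len + 1L, 1L)
      en <- st + len - 1L
      stb <- st - spec@buffer        # buffered bounds for distance checks
      enb <- en + spec@buffer

      hit <- FALSE
      for (nm in names(excl)) {
        e <- excl[[nm]][[chrom]]
        if (!is.null(e) && any(stb <= e$end & enb >= e$start)) {
          rejections[[nm]] <- rejections[[nm]] + 1
          hit <- TRUE
          break
        }
      }
      if (hit) next
      if (spec@mutualExclusion &&
          length(accStart[[chrom]]) &&
          any(stb <= accEnd[[chrom]] & enb >= accStart[[chrom]])) {
        ## deadlock escape: a long collision streak against previous draws
        ## means the accepted set blocks the remaining space (e.g. one draw
        ## mid-gap when only edge-to-edge placements fit); restart the set
        collisions <- collisions + 1
        if (collisions > 200) {
          for (ch in names(sizes)) accStart[[ch]] <- accEnd[[ch]] <- numeric(0)
          out <- vector("list", n)
          got <- 0L
          collisions <- 0
        }
        next
      }
      collisions <- 0
      if (hasSeq && spec@maxNFraction < 1) {
        nFrac <- Biostrings::letterFrequency(
          Biostrings::subseq(genome[[chrom]], st, en), "N") / len
        if (nFrac > spec@maxNFraction) next
      }
      got <- got + 1L
      accStart[[chrom]] <- c(accStart[[chrom]], st)
      accEnd[[chrom]] <- c(accEnd[[chrom]], en)
      out[[got]] <- c(chrom = chrom, start = st, end = en)
    }
    df <- as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE)
    makeRegions(df$chrom, as.integer(df$start), as.integer(df$end),
                id = sprintf("neg%04d", seq_len(n)), label = "negative")
  })
}

#' Remove candidates overlapping a reference set
#'
#' Keeps exactly the candidates with no overlap (>= 1 shared base) against
#' any reference region; input order is preserved.  Abutting regions are
#' kept, matching half-open BED semantics.
#'
#' @param candidates GRanges to filter.
#' @param reference GRanges to filter against.
#' @return the filtered GRanges.
#' @export
removeOverlapping <- function(candidates, reference) {
  if (!length(candidates) || !length(reference)) return(candidates)
  hits <- suppressWarnings(
    GenomicRanges::countOverlaps(candidates, reference,
                                 ignore.strand = TRUE))
  candidates[hits == 0L]
}
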