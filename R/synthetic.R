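## Synthetic world: a genome with i.i.d. bases, low-complexity repeat
## tracts, enhancer regions carrying planted PWM instances for a subset of
## "driver" motifs, and windowed chromatin tracks whose informative marks
## are elevated over enhancers.

#' Generate a random genome with low-complexity repeat tracts
#'
#' Bases are i.i.d. with P(G) = P(C) = gcContent/2.  Repeat tracts are runs
#' of one 2-mer (100-300 bp) overwriting the background until
#' \code{repeatFraction} of the genome is covered; they are returned as
#' annotated regions, emulating the low-complexity annotation used to
#' repeat-mask negative sets.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param seed RNG seed (derived from the config seed by default).
#' @return list with \code{genome} (DNAStringSet) and \code{repeatTracts}
#'   (GRanges).
#' @export
generateGenome <- function(config, seed = stageSeed(config@seed, 1L)) {
  if (config@chromLength < 10 * config@posLengthMean)
    stop("infeasible config: chromosomes must be >= 10x the mean ",
         "enhancer length")
  withSeed(seed, {
    gc <- config@gcContent
    probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    chroms <- stats::setNames(
      lapply(seq_len(config@nChroms), function(i)
        paste(sample(c("A", "C", "G", "T"), config@chromLength,
                     replace = TRUE, prob = probs), collapse = "")),
      paste0("chr", seq_len(config@nChroms)))

    tracts <- list()
    if (config@repeatFraction > 0) {
      target <- config@repeatFraction * config@nChroms * config@chromLength
      placed <- 0
      occupied <- lapply(chroms, function(x) cbind(start = integer(0),
                                                   end = integer(0)))
      attempts <- 0L
      while (placed < target && attempts < 10000L) {
        attempts <- attempts + 1L
        chrom <- sample(names(chroms), 1L)
        len <- sample(100:300, 1L)
        st <- sample.int(config@chromLength - len + 1L, 1L)
        occ <- occupied[[chrom]]
        if (nrow(occ) && any(st <= occ[, "end"] & st + len - 1L >= occ[, "start"]))
          next
        unit <- paste(sample(c("A", "C", "G", "T"), 2L, replace = TRUE),
                      collapse = "")
        run <- strtrim(strrep(unit, ceiling(len / 2)), len)
        substr(chroms[[chrom]], st, st + len - 1L) <- run
        occupied[[chrom]] <- rbind(occ, cbind(start = st, end = st + len - 1L))
        tracts[[length(tracts) + 1L]] <- data.frame(chrom = chrom, start = st,
                                                    end = st + len - 1L)
        placed <- placed + len
      }
    }
    repeatTracts <- if (length(tracts)) {
      df <- do.call(rbind, tracts)
      GenomicRanges::sort(makeRegions(df$chrom, df$start, df$end))
    } else GenomicRanges::GRanges()
    list(genome = Biostrings::DNAStringSet(unlist(chroms)),
         repeatTracts = repeatTracts)
  })
}

## near-identity of two consensus strings at any ungapped offset (either
## strand): true when >= 70% of an overlap of >= 5 bp matches
consensusSimilar <- function(a, b) {
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  av <- strsplit(a, "")[[1]]
  for (bs in c(b, rc(b))) {
    bv <- strsplit(bs, "")[[1]]
    for (off in seq(-(length(bv) - 5L), length(av) - 5L)) {
      ia <- seq(max(1L, off + 1L), min(length(av), off + length(bv)))
      ib <- ia - off
      if (length(ia) >= 5L &&
          mean(av[ia] == bv[ib]) >= 0.7) return(TRUE)
    }
  }
  FALSE
}

#' Generate random motif models
#'
#' Each PWM position has one dominant base with probability in [0.8, 0.95]
#' (remainder split evenly), so planted instances are detectable; lengths
#' are uniform over \code{motifLengthRange} and ids follow the
#' \code{"TF001"} style.  The first \code{nDriverMotifs} are the drivers
#' planted inside enhancers; non-driver motifs are redrawn while their
#' consensus nearly matches a driver consensus, so that "uninformative"
#' motifs really are uninformative by construction.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param seed RNG seed.
#' @return named list of \linkS4class{PWM}.
#' @export
generatePwms <- function(config, seed = stageSeed(config@seed, 2L)) {
  withSeed(seed, {
    drawOne <- function(i) {
      m <- sample(config@motifLengthRange[1]:config@motifLengthRange[2], 1L)
      dom <- sample.int(4L, m, replace = TRUE)
      pd <- runif(m, 0.8, 0.95)
      mat <- matrix((1 - pd) / 3, m, 4L)
      mat[cbind(seq_len(m), dom)] <- pd
      pwm(sprintf("TF%03d", i), mat)
    }
    consensusOf <- function(p)
      paste(c("A", "C", "G", "T")[apply(pwmMatrix(p), 1, which.max)],
            collapse = "")
    driverCons <- character(0)
    pwms <- vector("list", config@nMotifs)
    for (i in seq_len(config@nMotifs)) {
      for (try in 1:100) {
        cand <- drawOne(i)
        if (i <= config@nDriverMotifs ||
            !any(vapply(driverCons, consensusSimilar,
                        logical(1), b = consensusOf(cand))))
          break
      }
      if (i <= config@nDriverMotifs)
        driverCons <- c(driverCons, consensusOf(cand))
      pwms[[i]] <- cand
    }
    stats::setNames(pwms, vapply(pwms, pwmId, character(1)))
  })
}

## sample one sequence realization from a probability PWM
samplePwmInstance <- function(probs) {
  m <- pwmMatrix(probs)
  paste(apply(m, 1L, function(p) sample(c("A", "C", "G", "T"), 1L, prob = p)),
        collapse = "")
}

#' Place enhancer regions and plant driver-motif instances
#'
#' Draws \code{nPositives} mutually non-overlapping regions with Gaussian
#' lengths (redrawn while shorter than twice the longest motif), then
#' overwrites each enhancer with Poisson(\code{plantsPerEnhancer}) sampled
#' driver-motif instances at uniform non-overlapping offsets on a random
#' strand.  Planted instances never straddle enhancer boundaries.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param genome DNAStringSet (from \code{\link{generateGenome}}).
#' @param pwms motif pool (from \code{\link{generatePwms}}); the first
#'   \code{nDriverMotifs} entries are planted.
#' @param seed RNG seed.
#' @return list with the updated \code{genome} and \code{positives}
#'   (labeled GRanges).
#' @export
placeEnhancers <- function(config, genome, pwms,
                           seed = stageSeed(config@seed, 3L)) {
  withSeed(seed, {
    chroms <- lapply(as.list(as.character(genome)), identity)
    sizes <- vapply(chroms, nchar, integer(1))
    maxMotif <- if (length(pwms)) max(vapply(pwms, motifLength, integer(1)))
                else config@motifLengthRange[2]
    minLen <- 2L * maxMotif
    n <- config@nPositives

    drawLength <- function() {
      repeat {
        len <- round(rnorm(1L, config@posLengthMean, config@posLengthSd))
        if (len >= minLen) return(as.integer(len))
      }
    }

    if (n == 0L)
      return(list(genome = genome,
                  positives = GenomicRanges::GRanges()))
    placed <- lapply(names(chroms), function(x)
      cbind(start = integer(0), end = integer(0)))
    names(placed) <- names(chroms)
    out <- vector("list", n)
    attempts <- 0L
    budget <- 1000L * max(1L, n)
    i <- 1L
    while (i <= n) {
      if (attempts >= budget)
        stop("could not place ", n, " enhancers within the attempt budget")
      attempts <- attempts + 1L
      len <- drawLength()
      chrom <- sample(names(chroms), 1L, prob = sizes)
      if (len > sizes[[chrom]]) next
      st <- sample.int(sizes[[chrom]] - len + 1L, 1L)
      occ <- placed[[chrom]]
      ## keep two signal windows of spacing so no window spans two enhancers
      gap <- 2L * config@windowWidth
      if (nrow(occ) && any(st - gap <= occ[, "end"] &
                           st + len - 1L + gap >= occ[, "start"]))
        next
      placed[[chrom]] <- rbind(occ, cbind(start = st, end = st + len - 1L))
      out[[i]] <- data.frame(chrom = chrom, start = st, end = st + len - 1L)
      i <- i + 1L
    }
    df <- do.call(rbind, out)

    ## plant driver-motif instances; edits are collected and applied per
    ## chromosome in one pass (substr<- on a long string copies it wholly)
    drivers <- pwms[seq_len(config@nDriverMotifs)]
    if (length(drivers) && config@plantsPerEnhancer > 0) {
      driverProbs <- lapply(drivers, pwmProbabilities, pseudocount = 0)
      plantPos <- integer(0)
      plantSeq <- character(0)
      plantChrom <- character(0)
      for (r in seq_len(nrow(df))) {
        k <- rpois(1L, config@plantsPerEnhancer)
        if (k == 0L) next
        used <- cbind(start = integer(0), end = integer(0))
        for (s in seq_len(k)) {
          d <- sample.int(length(drivers), 1L)
          inst <- samplePwmInstance(driverProbs[[d]])
          if (sample(c(TRUE, FALSE), 1L))
            inst <- as.character(
              Biostrings::reverseComplement(Biostrings::DNAString(inst)))
          m <- nchar(inst)
          len <- df$end[r] - df$start[r] + 1L
          if (m > len) next
          for (try in 1:100) {
            off <- sample.int(len - m + 1L, 1L)
            if (!nrow(used) ||
                !any(off <= used[, "end"] & off + m - 1L >= used[, "start"])) {
              plantChrom <- c(plantChrom, df$chrom[r])
              plantPos <- c(plantPos, df$start[r] + off - 1L)
              plantSeq <- c(plantSeq, inst)
              used <- rbind(used, cbind(start = off, end = off + m - 1L))
              break
            }
          }
        }
      }
      for (chrom in unique(plantChrom)) {
        chars <- strsplit(chroms[[chrom]], "")[[1]]
        sel <- which(plantChrom == chrom)
        for (i in sel) {
          m <- nchar(plantSeq[i])
          chars[plantPos[i]:(plantPos[i] + m - 1L)] <-
            strsplit(plantSeq[i], "")[[1]]
        }
        chroms[[chrom]] <- paste(chars, collapse = "")
      }
    }
    positives <- makeRegions(df$chrom, df$start, df$end,
                             id = sprintf("pos%04d", seq_len(nrow(df))),
                             label = "positive")
    list(genome = Biostrings::DNAStringSet(unlist(chroms)),
         positives = positives)
  })
}

#' Simulate windowed chromatin tracks
#'
#' Window value = delta_m * 1[window overlaps an enhancer] + N(0, noiseSd),
#' with delta_m = 0 for uninformative marks.  When \code{nonadditivePair}
#' names two marks, a fair coin per enhancer routes the whole effect to
#' exactly one of the pair (each alone is weakly informative; jointly they
#' separate the classes), emulating non-additive enhancer chromatin
#' signatures.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param genome DNAStringSet.
#' @param positives enhancer GRanges.
#' @param seed RNG seed.
#' @return named list of \linkS4class{SignalTrack}, one per mark.
#' @export
simulateTracks <- function(config, genome, positives,
                           seed = stageSeed(config@seed, 4L)) {
  withSeed(seed, {
    w <- config@windowWidth
    sizes <- chromLengths(genome)
    nWin <- ceiling(sizes / w)
    deltas <- stats::setNames(rep(0, config@nMarks), config@markNames)
    deltas[config@informativeMarks] <- config@effectSizes

    pair <- config@nonadditivePair
    coin <- if (length(pair))
      sample(pair, length(positives), replace = TRUE) else character(0)

    ## per chromosome: 0-based window index range of each enhancer
    posChrom <- as.character(seqnames(positives))
    firstWin <- (start(positives) - 1L) %/% w
    lastWin <- (end(positives) - 1L) %/% w

    effectVector <- function(chrom, markDelta, enhancerSel) {
      v <- numeric(nWin[[chrom]])
      rows <- which(posChrom == chrom & enhancerSel)
      for (r in rows)
        v[(firstWin[r]:lastWin[r]) + 1L] <- markDelta
      v
    }

    tracks <- lapply(config@markNames, function(mark) {
      sel <- if (mark %in% pair) coin == mark
             else rep(TRUE, length(positives))
      vals <- lapply(names(sizes), function(chrom) {
        eff <- effectVector(chrom, deltas[[mark]], sel)
        eff + rnorm(length(eff), 0, config@noiseSd)
      })
      names(vals) <- names(sizes)
      signalTrack(mark, vals, w)
    })
    stats::setNames(tracks, config@markNames)
  })
}

#' Generate a full synthetic dataset
#'
#' Composes \code{\link{generateGenome}}, \code{\link{generatePwms}},
#' \code{\link{placeEnhancers}} and \code{\link{simulateTracks}} under
#' deterministic per-stage seeds derived from \code{config@seed}.  When
#' \code{dir} is given, all inputs are written in the formats the readers
#' accept (FASTA, BED, one bedGraph per mark, JASPAR PFM text) together with
#' JSON records of the configuration and the planted truth.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @param dir optional output directory.
#' @param pwms optional externally supplied motif pool (reused, not
#'   regenerated) so that validation datasets share motifs with training.
#' @return a \linkS4class{SyntheticDataset}.
#' @export
generateDataset <- function(config, dir = NULL, pwms = NULL) {
  gen <- generateGenome(config)
  if (is.null(pwms)) pwms <- generatePwms(config)
  enh <- placeEnhancers(config, gen$genome, pwms)
  tracks <- simulateTracks(config, enh$genome, enh$positives)
  truth <- list(
    driverMotifs = names(pwms)[seq_len(config@nDriverMotifs)],
    informativeMarks = config@informativeMarks,
    effectSizes = as.list(stats::setNames(config@effectSizes,
                                          config@informativeMarks)),
    nonadditivePair = config@nonadditivePair)
  ds <- new("SyntheticDataset", genome = enh$genome,
            positives = enh$positives, repeatTracts = gen$repeatTracts,
            pwms = pwms, tracks = tracks, truth = truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    Biostrings::writeXStringSet(ds@genome, file.path(dir, "genome.fa"))
    writeBed(ds@positives, file.path(dir, "positives.bed"))
    if (length(ds@repeatTracts))
      writeBed(ds@repeatTracts, file.path(dir, "repeats.bed"))
    for (mark in names(ds@tracks))
      writeBedGraph(ds@tracks[[mark]],
                    file.path(dir, paste0(mark, ".bedGraph")))
    writeJasparPfm(ds@pwms, file.path(dir, "motifs.pfm"))
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    jsonlite::write_json(configAsList(config), file.path(dir, "config.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  ds
}

#' Prefix every chromosome name of a synthetic dataset
#'
#' Validation datasets are fresh genome realizations: renaming their
#' chromosomes (e.g. \code{"val_chr1"}) makes explicit that they share no
#' coordinate space with the training genome, so overlap guards against the
#' training regions behave correctly.
#'
#' @param ds a \linkS4class{SyntheticDataset}.
#' @param prefix string prepended to every chromosome name.
#' @return the renamed \linkS4class{SyntheticDataset}.
#' @export
prefixChromNames <- function(ds, prefix = "val_") {
  renameGr <- function(gr) {
    if (!length(gr)) return(gr)
    out <- GenomicRanges::GRanges(
      paste0(prefix, as.character(seqnames(gr))),
      IRanges::IRanges(start(gr), end(gr)))
    S4Vectors::mcols(out) <- S4Vectors::mcols(gr)
    out
  }
  names(ds@genome) <- paste0(prefix, names(ds@genome))
  ds@positives <- renameGr(ds@positives)
  ds@repeatTracts <- renameGr(ds@repeatTracts)
  ds@tracks <- lapply(ds@tracks, function(tr) {
    names(tr@values) <- paste0(prefix, names(tr@values))
    tr
  })
  ds
}

configAsList <- function(config) {
  nm <- slotNames(class(config))
  stats::setNames(lapply(nm, function(s) slot(config, s)), nm)
}
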