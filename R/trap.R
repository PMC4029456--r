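#' Normalize a PWM to a regularized probability matrix
#'
#' Adds \code{pseudocount} to every cell and renormalizes each position
#' (row) to sum to 1: p(j,b) = (count(j,b)+pc) / (sum_b count(j,b) + 4 pc).
#' A matrix that already holds probabilities is returned unchanged when
#' \code{pseudocount = 0}.
#'
#' @param x a \linkS4class{PWM}.
#' @param pseudocount count added per cell (default 1); must be > 0 if the
#'   matrix contains zero entries, since the TRAP energy takes log-ratios.
#' @return a \linkS4class{PWM} whose matrix rows sum to 1.
#' @export
pwmProbabilities <- function(x, pseudocount = 1) {
  if (pseudocount < 0) stop("'pseudocount' must be >= 0")
  m <- pwmMatrix(x)
  rs <- rowSums(m)
  if (pseudocount == 0 && any(rs == 0))
    stop("all-zero PWM position with pseudocount 0")
  p <- (m + pseudocount) / (rs + 4 * pseudocount)
  if (pseudocount == 0 && any(p == 0))
    stop("zero PWM entries require a positive pseudocount")
  pwm(pwmId(x), p)
}

#' TRAP mismatch energy of one site
#'
#' E = (1/lambda) * sum_j ln( p(j, b*_j) / p(j, b_j) ), where b*_j is the
#' highest-probability base at position j.  E >= 0, with equality exactly on
#' a consensus sequence, and E is additive over positions.
#'
#' @param probs a probability \linkS4class{PWM}
#'   (see \code{\link{pwmProbabilities}}).
#' @param subseq character m-mer over A/C/G/T.
#' @param lambda energy scale (default 0.7).
#' @return non-negative energy (dimensionless).
#' @export
mismatchEnergy <- function(probs, subseq, lambda = 0.7) {
  m <- pwmMatrix(probs)
  bases <- strsplit(toupper(subseq), "")[[1]]
  if (length(bases) != nrow(m))
    stop("subsequence length must equal the motif length")
  b <- match(bases, c("A", "C", "G", "T"))
  if (anyNA(b)) stop("subsequence must contain only A/C/G/T")
  pmax <- apply(m, 1, max)
  pobs <- m[cbind(seq_len(nrow(m)), b)]
  sum(log(pmax / pobs)) / lambda
}

#' Default TRAP R0 from the motif-length rule
#'
#' R0 = exp(r0Slope * m + r0Intercept) with the published defaults
#' exp(0.584 m - 5.66); an explicit \code{r0Override} wins.
#'
#' @param m motif length in bp.
#' @param params a \linkS4class{TrapParams}.
#' @return R0 (> 0).
#' @export
defaultR0 <- function(m, params = trapParams()) {
  if (m < 1) stop("motif length must be >= 1")
  if (!is.na(params@r0Override)) return(params@r0Override)
  exp(params@r0Slope * m + params@r0Intercept)
}

#' TRAP binding affinity of a sequence for one motif
#'
#' Expected number of bound molecules: the sum over both strands and all
#' L - m + 1 sites of the occupancy R0 e^{-E} / (1 + R0 e^{-E}), with E the
#' site mismatch energy.  Sites containing an N contribute 0; sequences
#' shorter than the motif score 0 with a warning.
#'
#' @param x a \linkS4class{PWM} (counts or probabilities).
#' @param sequence character DNA string over A/C/G/T/N.
#' @param params a \linkS4class{TrapParams}.
#' @return affinity in [0, 2 (L - m + 1)].
#' @export
trapAffinity <- function(x, sequence, params = trapParams()) {
  if (!nzchar(sequence)) stop("empty sequence")
  probs <- pwmProbabilities(x, params@pseudocount)
  m <- motifLength(probs)
  if (nchar(sequence) < m) {
    warning(sprintf("sequence shorter than motif '%s' (%d < %d): affinity 0",
                    pwmId(x), nchar(sequence), m))
    return(0)
  }
  r0 <- defaultR0(m, params)
  .trap_affinity_cpp(toupper(sequence), pwmMatrix(probs), params@lambda, r0)
}

#' Mean chromatin signal of a region
#'
#' Unweighted arithmetic mean of the values of every window overlapping the
#' region; a partially overlapped window counts fully.  Windows beyond the
#' recorded track extent are imputed as 0.
#'
#' @param track a \linkS4class{SignalTrack}.
#' @param region a single-range GRanges on a chromosome known to the track's
#'   genome (an unknown chromosome is an error).
#' @return mean signal (numeric scalar).
#' @export
epiFeature <- function(track, region) {
  if (length(region) != 1L) stop("'region' must be a single range")
  chrom <- as.character(seqnames(region))
  if (!chrom %in% names(track@values))
    stop("unknown chromosome '", chrom, "' for mark ", track@mark)
  w <- track@window
  first <- (start(region) - 1L) %/% w        # 0-based window indices
  last <- (end(region) - 1L) %/% w
  v <- track@values[[chrom]]
  vals <- numeric(last - first + 1L)
  inTrack <- seq(first, last)[seq(first, last) < length(v)]
  vals[inTrack - first + 1L] <- v[inTrack + 1L]
  mean(vals)
}

#' Build the labeled feature matrix for a region set
#'
#' EPI columns (\code{"EPI:<mark>"}) are window-averaged mark signal; MOT
#' columns (\code{"MOT:<id>"}) are TRAP affinities of the region sequence.
#' Row order follows the input regions.
#'
#' @param genome DNAStringSet.
#' @param tracks named list of \linkS4class{SignalTrack} (may be empty for
#'   \code{featureSet = "MOT"}).
#' @param pwms list of \linkS4class{PWM} (may be empty for \code{"EPI"}).
#' @param regions labeled GRanges (metadata column \code{label}).
#' @param featureSet \code{"ALL"}, \code{"EPI"} or \code{"MOT"}.
#' @param params \linkS4class{TrapParams} for the MOT features.
#' @return an \linkS4class{EnhancerFeatureSet}.
#' @export
buildFeatureMatrix <- function(genome, tracks, pwms, regions,
                               featureSet = c("ALL", "EPI", "MOT"),
                               params = trapParams()) {
  featureSet <- match.arg(featureSet)
  lab <- S4Vectors::mcols(regions)$label
  if (is.null(lab)) stop("regions must carry a 'label' metadata column")
  sizes <- chromLengths(genome)
  chroms <- as.character(seqnames(regions))
  if (!all(chroms %in% names(sizes)))
    stop("region on a chromosome absent from the genome")
  if (any(end(regions) > sizes[chroms]) || any(start(regions) < 1L))
    stop("region beyond chromosome end")

  blocks <- list()
  if (featureSet %in% c("ALL", "EPI")) {
    if (!length(tracks)) stop("no signal tracks supplied for EPI features")
    ## vectorized window-mean: same rule as epiFeature(), computed per
    ## chromosome with cumulative sums (8000 per-region S4 calls are slow)
    epi <- vapply(tracks, function(tr) {
      w <- tr@window
      first <- (start(regions) - 1L) %/% w     # 0-based window indices
      last <- (end(regions) - 1L) %/% w
      out <- numeric(length(regions))
      for (chrom in unique(chroms)) {
        if (!chrom %in% names(tr@values))
          stop("unknown chromosome '", chrom, "' for mark ", tr@mark)
        v <- tr@values[[chrom]]
        cs <- cumsum(c(0, v))
        sel <- which(chroms == chrom)
        lo <- pmin(first[sel], length(v))      # windows past the track = 0
        hi <- pmin(last[sel] + 1L, length(v))
        out[sel] <- (cs[hi + 1L] - cs[lo + 1L]) / (last[sel] - first[sel] + 1L)
      }
      out
    }, numeric(length(regions)))
    epi <- matrix(epi, nrow = length(regions),
                  dimnames = list(NULL, paste0("EPI:", vapply(tracks,
                    function(tr) tr@mark, character(1)))))
    blocks$epi <- epi
  }
  if (featureSet %in% c("ALL", "MOT")) {
    if (!length(pwms)) stop("no PWMs supplied for MOT features")
    seqs <- as.character(Biostrings::subseq(genome[chroms],
                                            start = start(regions),
                                            end = end(regions)))
    probs <- lapply(pwms, function(p)
      pwmMatrix(pwmProbabilities(p, params@pseudocount)))
    r0 <- vapply(pwms, function(p)
      defaultR0(motifLength(p), params), numeric(1))
    shortSeq <- nchar(seqs) < max(vapply(pwms, motifLength, integer(1)))
    if (any(shortSeq))
      warning(sum(shortSeq), " region(s) shorter than the longest motif; ",
              "affinity 0 for the missing sites")
    mot <- .trap_affinity_batch_cpp(toupper(seqs), probs, params@lambda, r0)
    colnames(mot) <- paste0("MOT:", vapply(pwms, pwmId, character(1)))
    blocks$mot <- mot
  }
  values <- do.call(cbind, blocks)
  ids <- S4Vectors::mcols(regions)$id
  if (is.null(ids)) ids <- sprintf("region%04d", seq_along(regions))
  enhancerFeatureSet(values, lab, ids = ids, regions = granges(regions),
                     featureSet = featureSet)
}
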