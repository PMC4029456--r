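## Internal helpers.

## Deterministic fan-out of one master seed into per-stage seeds, kept below
## 2^31 so the result is always a valid R integer seed.
stageSeed <- function(seed, stage) {
  as.integer(((as.numeric(seed) * 48271 + as.numeric(stage) * 10007) %%
                2147483646) + 1)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`; the
## caller's RNG stream is restored afterwards.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

labelFactor <- function(x) {
  factor(as.character(x), levels = c("negative", "positive"))
}

## binary 0/1 vector from a label factor
labelBinary <- function(labels) as.integer(labels == "positive")

chromLengths <- function(genome) {
  if (is(genome, "DNAStringSet"))
    stats::setNames(Biostrings::width(genome), names(genome))
  else if (is.numeric(genome) && !is.null(names(genome)))
    genome
  else stop("'genome' must be a DNAStringSet or a named length vector")
}

## GRanges constructor from parallel vectors (1-based closed coordinates)
makeRegions <- function(chrom, start, end, id = NULL, label = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
  if (!is.null(id)) S4Vectors::mcols(gr)$id <- id
  if (!is.null(label)) S4Vectors::mcols(gr)$label <- labelFactor(label)
  gr
}
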