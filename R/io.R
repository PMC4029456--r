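#' Read a genome from FASTA
#'
#' Every record becomes a chromosome; sequences are stored uppercase and may
#' contain only A, C, G, T, N.  Duplicate record names, empty sequences and
#' other letters (including IUPAC ambiguity codes) are rejected.
#'
#' @param path FASTA file.
#' @return a \code{DNAStringSet} named by the first word of each header.
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ## read as raw strings first: readDNAStringSet silently drops letters
  ## outside the DNA alphabet, but here they must be a hard error
  raw <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e)
                    stop("malformed FASTA in ", path, ": ",
                         conditionMessage(e)))
  names(raw) <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(names(raw)))
    stop("duplicate chromosome names in ", path)
  if (any(Biostrings::width(raw) == 0))
    stop("empty sequence record in ", path)
  seqs <- toupper(as.character(raw))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("sequence contains letters outside A/C/G/T/N: ",
         paste(names(raw)[bad], collapse = ", "))
  Biostrings::DNAStringSet(stats::setNames(seqs, names(raw)))
}

#' Read and write BED intervals
#'
#' BED is 0-based half-open; the returned GRanges is 1-based closed, so a BED
#' line \code{chr1 0 100} becomes \code{chr1:1-100} (width 100).  A fourth
#' column, when present, is kept as the region \code{id}.
#'
#' @param path BED file (>= 3 tab-separated columns, no header).
#' @param label optional label ("positive"/"negative") assigned to all
#'   regions.
#' @return \code{readBed}: a GRanges with optional \code{id}/\code{label}
#'   metadata columns.
#' @export
readBed <- function(path, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = "character", quote = "",
                    comment.char = "#")
  if (ncol(tab) < 3L) stop("BED requires at least 3 columns: ", path)
  start0 <- suppressWarnings(as.numeric(tab[[2]]))
  end0 <- suppressWarnings(as.numeric(tab[[3]]))
  if (anyNA(start0) || anyNA(end0) ||
      any(start0 != round(start0)) || any(end0 != round(end0)))
    stop("non-integer coordinates in ", path)
  if (any(start0 < 0)) stop("negative start coordinate in ", path)
  if (any(start0 >= end0))
    stop("empty or inverted interval (start >= end) in ", path)
  id <- if (ncol(tab) >= 4L) tab[[4]] else NULL
  makeRegions(tab[[1]], start0 + 1, end0, id = id, label = label)
}

#' @rdname readBed
#' @param regions a GRanges; metadata column \code{id} becomes BED column 4.
#' @return \code{writeBed}: the path, invisibly.
#' @export
writeBed <- function(regions, path) {
  df <- data.frame(chrom = as.character(seqnames(regions)),
                   start = start(regions) - 1L, end = end(regions))
  id <- S4Vectors::mcols(regions)$id
  if (!is.null(id)) df$name <- id
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read fixed-window bedGraph signal
#'
#' Intervals must align to the window grid: starts are multiples of the
#' window width and each interval spans exactly one window (the last window
#' of a chromosome may be shorter).  Windows absent from the file are imputed
#' as 0 signal.
#'
#' @param path bedGraph file (chrom, start, end, value).
#' @param windowWidth grid width in bp (default 50).
#' @param mark mark name stored in the track (defaults to the file name).
#' @return a \linkS4class{SignalTrack}.
#' @export
readBedGraph <- function(path, windowWidth = 50L,
                         mark = sub("\\.[^.]*$", "", basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path)
  w <- as.integer(windowWidth)
  tab <- read.table(path, sep = "\t", header = FALSE, quote = "",
                    comment.char = "#",
                    colClasses = c("character", "numeric", "numeric",
                                   "numeric"))
  if (any(tab[[2]] %% w != 0))
    stop("bedGraph interval start off the ", w, "-bp grid in ", path)
  len <- tab[[3]] - tab[[2]]
  if (any(len <= 0) || any(len > w))
    stop("bedGraph interval longer than one window in ", path)
  idx <- tab[[2]] %/% w
  ## a short (< w) interval is only legal as the last window of a chromosome
  shortOk <- !duplicated(tab[[1]], fromLast = TRUE)
  if (any(len < w & !shortOk))
    stop("short bedGraph window before the end of a chromosome in ", path)
  values <- lapply(split(seq_len(nrow(tab)), tab[[1]]), function(rows) {
    i <- idx[rows]
    if (anyDuplicated(i)) stop("overlapping bedGraph windows in ", path)
    v <- numeric(max(i) + 1L)
    v[i + 1L] <- tab[[4]][rows]
    v
  })
  signalTrack(mark, values, w)
}

#' @rdname readBedGraph
#' @param track a \linkS4class{SignalTrack}.
#' @return \code{writeBedGraph}: the path, invisibly.
#' @export
writeBedGraph <- function(track, path) {
  w <- track@window
  rows <- do.call(rbind, lapply(names(track@values), function(chrom) {
    v <- track@values[[chrom]]
    i <- seq_along(v) - 1L
    data.frame(chrom = chrom, start = i * w, end = (i + 1L) * w, value = v)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read and write JASPAR-style PFM text
#'
#' The dialect is \code{">ID name"} headers followed by four rows
#' \code{"A [ 10 0 ... ]"} (and C, G, T); the stored matrix is transposed to
#' positions x bases.
#'
#' @param path PFM text file.
#' @return \code{readJasparPfm}: a named list of \linkS4class{PWM}.
#' @export
readJasparPfm <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no PFM records in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  pwms <- lapply(seq_along(starts), function(k) {
    header <- sub("^>\\s*", "", lines[starts[k]])
    id <- strsplit(header, "\\s+")[[1]][1]
    body <- lines[(starts[k] + 1L):(ends[k])]
    if (starts[k] == ends[k] || length(body) != 4L)
      stop("PFM record '", id, "' must have exactly 4 base rows")
    base <- toupper(sub("^\\s*([A-Za-z]).*$", "\\1", body))
    if (!setequal(base, c("A", "C", "G", "T")))
      stop("PFM record '", id, "' must have one row per base A/C/G/T")
    counts <- lapply(body, function(l) {
      ## strip the base letter and any brackets, then read the numbers
      s <- gsub("[][]", " ", sub("^\\s*[A-Za-z]", "", l))
      scan(text = s, what = numeric(), quiet = TRUE)
    })
    if (length(unique(lengths(counts))) != 1L)
      stop("PFM record '", id, "' has rows of unequal length")
    mat <- do.call(cbind, counts[order(match(base, c("A", "C", "G", "T")))])
    if (any(mat < 0)) stop("negative counts in PFM record '", id, "'")
    pwm(id, mat)
  })
  ids <- vapply(pwms, pwmId, character(1))
  if (anyDuplicated(ids)) stop("duplicate PFM ids in ", path)
  stats::setNames(pwms, ids)
}

#' @rdname readJasparPfm
#' @param pwms list of \linkS4class{PWM}.
#' @return \code{writeJasparPfm}: the path, invisibly.
#' @export
writeJasparPfm <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", pwmId(p)), con)
    m <- pwmMatrix(p)
    for (b in 1:4)
      writeLines(sprintf("%s [ %s ]", c("A", "C", "G", "T")[b],
                         paste(format(m[, b], trim = TRUE), collapse = " ")),
                 con)
  }
  invisible(path)
}

#' Do two regions overlap?
#'
#' TRUE iff the regions are on the same chromosome and share at least one
#' base.  Under BED half-open semantics abutting intervals (end of one equal
#' to start of the next) do not overlap.
#'
#' @param a,b GRanges (may hold several regions; overlap is any-vs-any).
#' @return logical.
#' @export
regionsOverlap <- function(a, b) {
  ## comparing ranges from disjoint chromosome sets is legitimate (they
  ## cannot overlap); the Seqinfo merge note is noise here
  suppressWarnings(
    length(GenomicRanges::findOverlaps(a, b, ignore.strand = TRUE)) > 0)
}

#' Write and read a labeled feature table
#'
#' Tab-separated text with a header row \code{id}, one column per feature
#' (names keep their EPI:/MOT: provenance prefix) and a final \code{label}
#' column; values round-trip losslessly at 12 significant digits.
#'
#' @param x an \linkS4class{EnhancerFeatureSet}.
#' @param path output file.
#' @return \code{writeFeatureTable}: the path, invisibly.
#' @export
writeFeatureTable <- function(x, path) {
  vals <- featureValues(x)
  df <- data.frame(id = regionIds(x),
                   signif(vals, 12),
                   label = as.character(regionLabels(x)),
                   check.names = FALSE)
  colnames(df) <- c("id", colnames(vals), "label")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @return \code{readFeatureTable}: an \linkS4class{EnhancerFeatureSet}.
#' @export
readFeatureTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    quote = "", fill = FALSE)
  cn <- colnames(tab)
  if (cn[1] != "id" || cn[length(cn)] != "label")
    stop("feature table must have an 'id' first column and a 'label' last ",
         "column: ", path)
  feat <- as.matrix(tab[, setdiff(seq_along(cn), c(1L, length(cn))),
                        drop = FALSE])
  if (!is.numeric(feat) || anyNA(feat))
    stop("missing or non-numeric feature value in ", path)
  enhancerFeatureSet(feat, tab$label, ids = tab$id)
}
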