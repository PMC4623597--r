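#' Strand-shifted read footprints
#'
#' Each sequenced read is represented by its start position and strand
#' only; the fragment is modelled as a 200 nt extension from the read
#' start in the read direction, and the read's contribution is the
#' central 100 nt of that extension. For a plus-strand read starting at
#' 0-based position `s` this is `[s+50, s+150)`; for a minus-strand read
#' the mirror image upstream of `s`. Coordinates falling below the
#' contig start are clipped.
#'
#' @param reads width-1 `GRanges` of read start positions with strand.
#' @return `GRanges` of 100 nt footprints (clipped reads may be shorter;
#'   reads whose footprint lies entirely below position 1 are dropped).
#' @export
readFootprints <- function(reads) {
  stopifnot(all(width(reads) == 1L))
  st <- as.character(strand(reads))
  if (any(st == "*")) stop("reads must have strand + or -")
  s0 <- start(reads) - 1L                      # 0-based read start
  lo0 <- ifelse(st == "+", s0 + 50L, s0 - 149L)
  hi0 <- lo0 + 100L                            # half-open
  lo0 <- pmax(lo0, 0L)
  keep <- hi0 > 0L
  gr <- GRanges(seqnames(reads)[keep],
                IRanges(lo0[keep] + 1L, hi0[keep]),
                strand = st[keep])
  S4Vectors::mcols(gr) <- S4Vectors::mcols(reads)[keep, , drop = FALSE]
  gr
}

#' Per-base coverage track from strand-shifted reads
#'
#' Applies [readFootprints()] and piles the footprints up into a
#' per-chromosome run-length-encoded coverage vector.
#'
#' @inheritParams readFootprints
#' @return an `RleList` of per-base coverage, one element per
#'   chromosome.
#' @export
transformPileup <- function(reads) {
  coverage(readFootprints(reads))
}

#' Quantify peak signal as reads per million
#'
#' Counts, per sample, the reads whose strand-shifted central 100 nt
#' footprint overlaps each peak by at least 1 bp, and scales counts to
#' reads per million aligned reads (RPM) using per-sample totals.
#'
#' @param peaks `GRanges` of peak intervals (names become locus ids).
#' @param reads width-1 `GRanges` of read starts with strand and a
#'   `sample` metadata column.
#' @param totals named per-sample aligned-read totals; defaults to the
#'   number of reads per sample in `reads`.
#' @return a [SignalMatrix-class] (loci x samples).
#' @export
quantifyRpm <- function(peaks, reads, totals = NULL) {
  stopifnot(!is.null(reads$sample))
  samples <- if (is.null(totals)) sort(unique(as.character(reads$sample)))
             else names(totals)
  if (is.null(totals))
    totals <- table(factor(as.character(reads$sample), samples))
  totals <- setNames(as.numeric(totals), samples)
  if (any(totals <= 0)) stop("zero aligned-read total for sample(s): ",
                             paste(samples[totals <= 0], collapse = ", "))
  fp <- readFootprints(reads)
  counts <- sapply(samples, function(s)
    countOverlaps(peaks, fp[fp$sample == s], minoverlap = 1L))
  counts <- matrix(counts, nrow = length(peaks),
                   dimnames = list(names(peaks), samples))
  SignalMatrix(counts = counts, librarySize = totals, rowRanges = peaks)
}

#' Peak filter configuration
#'
#' Filtering thresholds for consensus peaks: a peak must reach at least
#' `minRpm` in one or more ChIP samples, must not exceed `maxInputRpm`
#' in any input (non-ChIPed) sample, and must not overlap the blacklist.
#'
#' @param minRpm minimum ChIP RPM required in at least one sample
#'   (default 1).
#' @param maxInputRpm maximum tolerated input RPM in any input sample
#'   (default 0.5).
#' @param blacklist `GRanges` of artifact regions to exclude.
#' @return a list with class `"PeakFilterConfig"`.
#' @export
peakFilterConfig <- function(minRpm = 1, maxInputRpm = 0.5,
                             blacklist = GRanges()) {
  stopifnot(minRpm > 0, maxInputRpm > 0)
  structure(list(minRpm = minRpm, maxInputRpm = maxInputRpm,
                 blacklist = blacklist), class = "PeakFilterConfig")
}

#' Filter consensus peaks on signal, input and blacklist
#'
#' Drops loci whose RPM is below `minRpm` in all ChIP samples, loci whose
#' input RPM exceeds `maxInputRpm` in any input sample, and loci
#' overlapping the blacklist. Idempotent.
#'
#' @param chip a [SignalMatrix-class] of ChIP samples.
#' @param input a [SignalMatrix-class] of input samples over the same
#'   loci (`NULL` skips the input rule).
#' @param config a [peakFilterConfig()].
#' @return character vector of retained locus ids.
#' @export
filterPeaks <- function(chip, input = NULL,
                        config = peakFilterConfig()) {
  rpm <- rpmValues(chip)
  keep <- apply(rpm >= config$minRpm, 1L, any)
  if (!is.null(input)) {
    irpm <- rpmValues(input)
    stopifnot(nrow(irpm) == nrow(rpm))
    keep <- keep & !apply(irpm > config$maxInputRpm, 1L, any)
  }
  if (length(config$blacklist) > 0L) {
    hit <- countOverlaps(SummarizedExperiment::rowRanges(chip),
                         config$blacklist) > 0L
    keep <- keep & !hit
  }
  rownames(rpm)[keep]
}

#' Read a BED6-like read-start table
#'
#' Expects columns chrom, start (0-based read start), end, sample,
#' score, strand; returns width-1 `GRanges` of read starts with a
#' `sample` column.
#'
#' @param path TSV path without header.
#' @return `GRanges`.
#' @export
readReadTable <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("chrom", "start", "end", "sample",
                                "score", "strand"))
  GRanges(d$chrom, IRanges(d$start + 1L, width = 1L), strand = d$strand,
          sample = d$sample)
}

#' Read peaks from a BED3+ file
#'
#' @param path BED path (0-based half-open, no header).
#' @return `GRanges`, named by the 4th column when present.
#' @export
readPeakBed <- function(path) {
  d <- read.table(path, sep = "\t", header = FALSE)
  gr <- GRanges(d[[1L]], IRanges(d[[2L]] + 1L, d[[3L]]))
  if (ncol(d) >= 4L) names(gr) <- d[[4L]]
  gr
}

#' Write peaks as BED3+
#'
#' @param gr `GRanges` (names become the 4th column).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePeakBed <- function(gr, path) {
  d <- data.frame(as.character(seqnames(gr)), start(gr) - 1L, end(gr))
  if (!is.null(names(gr))) d$name <- names(gr)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
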