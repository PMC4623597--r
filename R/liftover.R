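#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   countOverlaps findOverlaps reduce coverage resize distance
#'   distanceToNearest
#' @importFrom IRanges IRanges
NULL

# cumulative 0-based block starts on source and target (strand coords)
.blockStarts <- function(ch) {
  b <- ch@blocks
  n <- nrow(b)
  off <- function(gap) if (n > 1L) c(0, cumsum(b$size + gap)[-n]) else 0
  list(s = ch@sStart + off(b$dt), t = ch@tStart + off(b$dq), size = b$size)
}

# map 0-based half-open [qs0, qe0) through one chain; NULL if no aligned base
.chainMap <- function(ch, qs0, qe0) {
  bs <- .blockStarts(ch)
  s1 <- pmax(qs0, bs$s)
  s2 <- pmin(qe0, bs$s + bs$size)
  o <- pmax(0, s2 - s1)
  mapped <- sum(o)
  if (mapped == 0) return(NULL)
  idx <- o > 0
  tlo <- bs$t[idx] + (s1[idx] - bs$s[idx])
  thi <- tlo + o[idx]
  lo <- min(tlo); hi <- max(thi)
  if (ch@tStrand == "-") {
    tmp <- lo
    lo <- ch@tSize - hi
    hi <- ch@tSize - tmp
  }
  list(mapped = mapped, chrom = ch@tChrom, lo = lo, hi = hi)
}

#' Map an interval to the other assembly through alignment chains
#'
#' liftOver-style coordinate conversion: the query maps when at least
#' `minMappedFraction` of its bases fall in aligned blocks of a single
#' chain; the result is the target-assembly interval spanned by the mapped
#' bases, reported on the plus strand (minus-strand chain coordinates are
#' flipped via `size - x`). Among chains meeting the threshold the one
#' covering the most query bases wins (ties: higher score, then input
#' order). A query chromosome absent from the chains is simply unmapped.
#'
#' @param q query interval, a length-1 `GRanges` on the source assembly.
#' @param chains a [ChainSet-class].
#' @param minMappedFraction minimum fraction of query bases that must lie
#'   in aligned blocks (default 0.95, the liftOver `-minMatch` default).
#' @return an [OrthologyResult-class] with status `"full"` or
#'   `"unmapped"`.
#' @export
mapInterval <- function(q, chains, minMappedFraction = 0.95) {
  stopifnot(is(q, "GRanges"), length(q) == 1L)
  qs0 <- start(q) - 1L
  qe0 <- end(q)
  w <- qe0 - qs0
  best <- NULL
  bestKey <- c(-Inf, -Inf, Inf)
  for (i in seq_along(chains@chains)) {
    ch <- chains@chains[[i]]
    if (ch@sChrom != as.character(seqnames(q))) next
    m <- .chainMap(ch, qs0, qe0)
    if (is.null(m)) next
    key <- c(m$mapped, ch@score, -i)
    if (key[1L] > bestKey[1L] ||
        (key[1L] == bestKey[1L] && key[2L] > bestKey[2L]) ||
        (key[1L] == bestKey[1L] && key[2L] == bestKey[2L] &&
         key[3L] > bestKey[3L])) {
      best <- m
      bestKey <- key
    }
  }
  if (is.null(best) || best$mapped / w < minMappedFraction)
    return(new("OrthologyResult", status = "unmapped",
               mapped = GRanges(), offset = 0))
  new("OrthologyResult", status = "full",
      mapped = GRanges(best$chrom, IRanges(best$lo + 1L, best$hi)),
      offset = 0)
}

#' Assay-specific parameters for the sub-interval orthology scan
#'
#' Loci of different assays are scanned for orthologous sub-windows with
#' assay-matched granularity: histone-acetylation loci (3-5 kbp) in 300 bp
#' increments, DNase hypersensitive sites (200 bp) and Foxp3 binding sites
#' (300 bp) in 50 bp increments. The sub-window length equals the scan
#' step (the smallest unit consistent with the increment scheme).
#'
#' @param assay one of `"h3k27ac"`, `"dnase"`, `"foxp3"`.
#' @param step scan increment in bp (overrides the assay default).
#' @param subwindow sub-window length in bp (default: `step`).
#' @return a list with class `"AssayScanParams"`.
#' @export
assayScanParams <- function(assay = c("h3k27ac", "dnase", "foxp3"),
                            step = NULL, subwindow = NULL) {
  assay <- match.arg(assay)
  if (is.null(step)) step <- switch(assay, h3k27ac = 300L, dnase = 50L,
                                    foxp3 = 50L)
  if (is.null(subwindow)) subwindow <- step
  stopifnot(step > 0, subwindow >= step)
  structure(list(assay = assay, step = as.integer(step),
                 subwindow = as.integer(subwindow)),
            class = "AssayScanParams")
}

#' Iterative center-outward orthology search
#'
#' First attempts to map the full locus; on failure, fixed-length
#' sub-windows are evaluated at centers `c0, c0 - step, c0 + step,
#' c0 - 2*step, ...` (ties between the two sides broken toward the lower
#' coordinate), restricted to windows lying entirely within the locus.
#' The first sub-window that maps is returned with status
#' `"subinterval"` and its signed center offset; otherwise the locus is
#' unmapped.
#'
#' @inheritParams mapInterval
#' @param params an [assayScanParams()] list.
#' @return an [OrthologyResult-class].
#' @export
iterativeOrthologSearch <- function(q, chains, params,
                                    minMappedFraction = 0.95) {
  stopifnot(inherits(params, "AssayScanParams"), is(q, "GRanges"),
            length(q) == 1L)
  qs0 <- start(q) - 1L
  qe0 <- end(q)
  w <- qe0 - qs0
  sw <- params$subwindow
  if (sw > w) stop("subwindow longer than query locus")
  full <- mapInterval(q, chains, minMappedFraction)
  if (full@status == "full") return(full)
  c0 <- qs0 + w %/% 2L
  half <- sw %/% 2L
  kmax <- w %/% params$step + 1L
  for (k in 0:kmax) {
    for (centre in unique(c(c0 - k * params$step, c0 + k * params$step))) {
      lo <- centre - half
      hi <- lo + sw
      if (lo < qs0 || hi > qe0) next
      sub <- GRanges(seqnames(q), IRanges(lo + 1L, hi))
      res <- mapInterval(sub, chains, minMappedFraction)
      if (res@status == "full")
        return(new("OrthologyResult", status = "subinterval",
                   mapped = res@mapped, offset = centre - c0))
    }
  }
  new("OrthologyResult", status = "unmapped", mapped = GRanges(), offset = 0)
}
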