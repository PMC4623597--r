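#' Build the cross-species union atlas of regulatory elements
#'
#' Maps every human peak into the mouse assembly and vice versa (via
#' [iterativeOrthologSearch()]) and merges the two peak sets into a single
#' locus set. A human peak and a mouse peak collapse into one genetically
#' conserved locus when their cross-mappings overlap reciprocally (each
#' mapped interval overlaps the partner peak by at least 1 bp);
#' many-to-one conflicts are resolved by largest total overlap, then
#' lowest human coordinate. A peak that maps but meets no partner peak
#' remains genetically conserved, with the mapped interval standing in
#' for the (epigenetically inactive) partner locus, so its signal there
#' stays quantifiable. Unmappable peaks become species-only loci. Every
#' input peak is represented exactly once; overlapping same-species
#' peaks are merged first, with a warning.
#'
#' @param peaksH,peaksM peak intervals (`GRanges`) for human and mouse.
#' @param chainsH2M,chainsM2H [ChainSet-class]s mapping human to mouse
#'   coordinates and back.
#' @param params an [assayScanParams()] list.
#' @param minMappedFraction see [mapInterval()].
#' @return a [UnionAtlas-class].
#' @export
buildUnionAtlas <- function(peaksH, peaksM, chainsH2M, chainsM2H,
                            params = assayScanParams("h3k27ac"),
                            minMappedFraction = 0.95) {
  redH <- reduce(peaksH)
  redM <- reduce(peaksM)
  if (length(redH) < length(peaksH) || length(redM) < length(peaksM))
    warning("overlapping same-species peaks were merged before mapping")
  peaksH <- redH
  peaksM <- redM

  mapOne <- function(p, chains) {
    lapply(seq_along(p), function(i) {
      r <- iterativeOrthologSearch(p[i], chains, params, minMappedFraction)
      if (r@status == "unmapped") NULL else r@mapped
    })
  }
  mapH <- mapOne(peaksH, chainsH2M)
  mapM <- mapOne(peaksM, chainsM2H)

  # candidate reciprocal pairs, via vectorized overlap of the mapped
  # intervals with the partner peak set
  ovlTable <- function(mapped, partner) {
    has <- !vapply(mapped, is.null, logical(1))
    if (!any(has)) return(NULL)
    gr <- GRanges(
      vapply(mapped[has], function(g) as.character(seqnames(g)), ""),
      IRanges(vapply(mapped[has], start, 0), vapply(mapped[has], end, 0)))
    hits <- findOverlaps(gr, partner)
    if (length(hits) == 0L) return(NULL)
    q <- S4Vectors::queryHits(hits)
    s <- S4Vectors::subjectHits(hits)
    o <- pmin(end(gr)[q], end(partner)[s]) -
      pmax(start(gr)[q], start(partner)[s]) + 1L
    data.frame(self = which(has)[q], other = s, o = o)
  }
  t1 <- ovlTable(mapH, peaksM)   # human mapping overlaps mouse peak
  t2 <- ovlTable(mapM, peaksH)   # mouse mapping overlaps human peak
  pairs <- NULL
  if (!is.null(t1) && !is.null(t2)) {
    key1 <- paste(t1$self, t1$other)
    key2 <- paste(t2$other, t2$self)
    common <- intersect(key1, key2)
    if (length(common)) {
      i1 <- match(common, key1)
      i2 <- match(common, key2)
      pairs <- cbind(t1$self[i1], t1$other[i1], t1$o[i1] + t2$o[i2])
    }
  }

  usedH <- logical(length(peaksH))
  usedM <- logical(length(peaksM))
  loci <- list()
  addLocus <- function(hGr, mGr, status, hPeak, mPeak) {
    loci[[length(loci) + 1L]] <<- data.frame(
      humanChrom = if (is.null(hGr)) NA_character_ else
        as.character(seqnames(hGr)),
      humanStart = if (is.null(hGr)) NA_integer_ else start(hGr),
      humanEnd = if (is.null(hGr)) NA_integer_ else end(hGr),
      mouseChrom = if (is.null(mGr)) NA_character_ else
        as.character(seqnames(mGr)),
      mouseStart = if (is.null(mGr)) NA_integer_ else start(mGr),
      mouseEnd = if (is.null(mGr)) NA_integer_ else end(mGr),
      geneticStatus = status, humanPeak = hPeak, mousePeak = mPeak)
  }

  if (!is.null(pairs)) {
    ord <- order(-pairs[, 3L], start(peaksH)[pairs[, 1L]], pairs[, 1L],
                 pairs[, 2L])
    for (r in ord) {
      i <- pairs[r, 1L]; j <- pairs[r, 2L]
      if (usedH[i] || usedM[j]) next
      usedH[i] <- usedM[j] <- TRUE
      addLocus(peaksH[i], peaksM[j], "conserved", TRUE, TRUE)
    }
  }
  for (i in which(!usedH)) {
    if (is.null(mapH[[i]])) {
      addLocus(peaksH[i], NULL, "human_only", TRUE, FALSE)
    } else {
      addLocus(peaksH[i], mapH[[i]], "conserved", TRUE, FALSE)
    }
  }
  for (j in which(!usedM)) {
    if (is.null(mapM[[j]])) {
      addLocus(NULL, peaksM[j], "mouse_only", FALSE, TRUE)
    } else {
      addLocus(mapM[[j]], peaksM[j], "conserved", FALSE, TRUE)
    }
  }
  tab <- do.call(rbind, loci)
  tab <- cbind(atlasId = sprintf("atlas_%05d", seq_len(nrow(tab))), tab)
  rownames(tab) <- tab$atlasId
  new("UnionAtlas", loci = tab)
}
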