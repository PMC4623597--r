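#' @import methods
#' @importFrom BiocGenerics sort
#' @importFrom S4Vectors DataFrame metadata
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#'   RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowRanges
#' @importFrom stats coef cor dbinom lm median na.omit p.adjust pbinom
#'   phyper pnorm pt quantile rbinom rnbinom rnorm runif sd setNames var
#' @importFrom utils head read.table write.table
NULL

#' Pairwise-alignment chain between two assemblies
#'
#' A `Chain` holds one gapped alignment between a source assembly (the
#' assembly queries live on; always plus strand, as in UCSC chain files)
#' and a target assembly. Block coordinates follow the UCSC chain format:
#' `size` aligned bases, then `dt` unaligned bases on the source and `dq`
#' on the target before the next block. Target coordinates are stored in
#' target-strand coordinates exactly as in the file, so a parsed chain
#' round-trips bit-exactly through [writeChainFile()].
#'
#' @slot score alignment score.
#' @slot sChrom,sSize,sStart,sEnd source sequence name, length and span.
#' @slot tChrom,tSize,tStrand,tStart,tEnd target sequence name, length,
#'   strand (`"+"` or `"-"`) and span in target-strand coordinates.
#' @slot blocks `data.frame` with integer columns `size`, `dt`, `dq`;
#'   the final block has `dt = dq = 0`.
#' @slot id chain identifier.
#' @export
setClass("Chain", representation(
  score  = "numeric",
  sChrom = "character", sSize = "numeric", sStart = "numeric", sEnd = "numeric",
  tChrom = "character", tSize = "numeric", tStrand = "character",
  tStart = "numeric", tEnd = "numeric",
  blocks = "data.frame",
  id     = "character"
))

setValidity("Chain", function(object) {
  b <- object@blocks
  msg <- character()
  if (!all(c("size", "dt", "dq") %in% names(b)))
    return("blocks must have columns size, dt, dq")
  if (nrow(b) == 0L) msg <- c(msg, "chain has no blocks")
  if (any(b$size <= 0)) msg <- c(msg, "block sizes must be > 0")
  if (any(b$dt < 0) || any(b$dq < 0)) msg <- c(msg, "gaps must be >= 0")
  n <- nrow(b)
  if (n > 0L && (b$dt[n] != 0 || b$dq[n] != 0))
    msg <- c(msg, "final block must have dt = dq = 0")
  if (sum(b$size + b$dt) != object@sEnd - object@sStart)
    msg <- c(msg, "blocks do not sum to source span")
  if (sum(b$size + b$dq) != object@tEnd - object@tStart)
    msg <- c(msg, "blocks do not sum to target span")
  if (!object@tStrand %in% c("+", "-")) msg <- c(msg, "bad target strand")
  if (object@sStart < 0 || object@sEnd > object@sSize)
    msg <- c(msg, "source span outside sequence")
  if (object@tStart < 0 || object@tEnd > object@tSize)
    msg <- c(msg, "target span outside sequence")
  if (length(msg)) msg else TRUE
})

#' Set of chains indexed by source chromosome
#'
#' @slot chains list of [Chain-class] objects.
#' @export
setClass("ChainSet", representation(chains = "list"))

setValidity("ChainSet", function(object) {
  if (!all(vapply(object@chains, is, logical(1), "Chain")))
    return("all elements must be Chain objects")
  TRUE
})

#' @describeIn ChainSet-class construct a set from individual chains.
#' @param ... `Chain` objects (or a single list of them).
#' @export
ChainSet <- function(...) {
  x <- list(...)
  if (length(x) == 1L && is.list(x[[1L]]) && !is(x[[1L]], "Chain"))
    x <- x[[1L]]
  new("ChainSet", chains = x)
}

#' @export
setMethod("length", "ChainSet", function(x) length(x@chains))

#' @export
setMethod("[[", "ChainSet", function(x, i) x@chains[[i]])

setMethod("show", "Chain", function(object) {
  cat(sprintf("Chain %s: %s:%d-%d -> %s:%d-%d (%s), %d block(s), score %g\n",
              object@id, object@sChrom, object@sStart, object@sEnd,
              object@tChrom, object@tStart, object@tEnd, object@tStrand,
              nrow(object@blocks), object@score))
})

setMethod("show", "ChainSet", function(object) {
  cat(sprintf("ChainSet with %d chain(s) on source sequence(s): %s\n",
              length(object),
              paste(unique(vapply(object@chains, slot, "", "sChrom")),
                    collapse = ", ")))
})

#' Result of mapping an interval across assemblies
#'
#' @slot status `"full"`, `"subinterval"` or `"unmapped"`.
#' @slot mapped mapped interval on the target assembly, reported on the
#'   plus strand (length-0 `GRanges` when unmapped).
#' @slot offset signed distance (bp) of the successful sub-window center
#'   from the query center; 0 for full mappings.
#' @export
setClass("OrthologyResult", representation(
  status = "character", mapped = "GRanges", offset = "numeric"))

setValidity("OrthologyResult", function(object) {
  if (!object@status %in% c("full", "subinterval", "unmapped"))
    return("bad status")
  if ((object@status == "unmapped") != (length(object@mapped) == 0L))
    return("status unmapped iff mapped absent")
  TRUE
})

setMethod("show", "OrthologyResult", function(object) {
  if (object@status == "unmapped") {
    cat("OrthologyResult: unmapped\n")
  } else {
    cat(sprintf("OrthologyResult: %s at %s:%d-%d (offset %+d)\n",
                object@status, as.character(GenomicRanges::seqnames(object@mapped)),
                GenomicRanges::start(object@mapped),
                GenomicRanges::end(object@mapped), object@offset))
  }
})

#' @describeIn OrthologyResult-class mapping status accessor.
#' @param x an `OrthologyResult`.
#' @export
orthologyStatus <- function(x) x@status

#' @describeIn OrthologyResult-class mapped target interval accessor.
#' @export
mappedInterval <- function(x) x@mapped

#' @describeIn OrthologyResult-class sub-window offset accessor.
#' @export
searchOffset <- function(x) x@offset

#' Cross-species union atlas of regulatory elements
#'
#' The union atlas merges two species' peak sets into one locus set: peaks
#' whose cross-mappings reciprocally overlap collapse into a single
#' genetically conserved locus; peaks that map into the other assembly but
#' hit no partner peak stay genetically conserved (the partner interval is
#' the mapped orthologous interval, epigenetically inactive there); peaks
#' that cannot be mapped become species-only loci.
#'
#' @slot loci `data.frame` with columns `atlasId`, `humanChrom`,
#'   `humanStart`, `humanEnd`, `mouseChrom`, `mouseStart`, `mouseEnd`
#'   (NA for the missing species), `geneticStatus` in
#'   `{conserved, human_only, mouse_only}`, and logical `humanPeak`,
#'   `mousePeak` flags marking which species contributed an observed peak.
#' @export
setClass("UnionAtlas", representation(loci = "data.frame"))

setValidity("UnionAtlas", function(object) {
  l <- object@loci
  need <- c("atlasId", "humanChrom", "humanStart", "humanEnd",
            "mouseChrom", "mouseStart", "mouseEnd", "geneticStatus",
            "humanPeak", "mousePeak")
  if (!all(need %in% names(l))) return("missing atlas columns")
  if (!all(l$geneticStatus %in% c("conserved", "human_only", "mouse_only")))
    return("bad geneticStatus")
  bothPresent <- !is.na(l$humanStart) & !is.na(l$mouseStart)
  if (!all((l$geneticStatus == "conserved") == bothPresent))
    return("conserved iff both intervals present")
  if (anyDuplicated(l$atlasId)) return("duplicate atlas ids")
  TRUE
})

#' @describeIn UnionAtlas-class locus table accessor.
#' @param x a `UnionAtlas`.
#' @export
atlasLoci <- function(x) x@loci

#' @describeIn UnionAtlas-class genetic conservation status per locus.
#' @export
geneticStatus <- function(x) x@loci$geneticStatus

#' @describeIn UnionAtlas-class loci with a human interval, as `GRanges`
#'   named by atlas id.
#' @export
humanRanges <- function(x) .atlasRanges(x@loci, "human")

#' @describeIn UnionAtlas-class loci with a mouse interval, as `GRanges`
#'   named by atlas id.
#' @export
mouseRanges <- function(x) .atlasRanges(x@loci, "mouse")

.atlasRanges <- function(l, sp) {
  keep <- !is.na(l[[paste0(sp, "Start")]])
  gr <- GenomicRanges::GRanges(
    l[[paste0(sp, "Chrom")]][keep],
    IRanges::IRanges(l[[paste0(sp, "Start")]][keep],
                     l[[paste0(sp, "End")]][keep]))
  names(gr) <- l$atlasId[keep]
  gr$atlasId <- l$atlasId[keep]
  gr
}

#' @export
setMethod("length", "UnionAtlas", function(x) nrow(x@loci))

setMethod("show", "UnionAtlas", function(object) {
  tab <- table(factor(object@loci$geneticStatus,
                      c("conserved", "human_only", "mouse_only")))
  cat(sprintf(paste0("UnionAtlas with %d loci ",
                     "(%d conserved, %d human-only, %d mouse-only)\n"),
              nrow(object@loci), tab[1L], tab[2L], tab[3L]))
})

#' Locus-by-sample signal matrix in reads per million
#'
#' Thin [SummarizedExperiment::RangedSummarizedExperiment-class] subclass
#' holding an `"rpm"` assay (reads per million aligned reads), optionally
#' a raw `"counts"` assay, and per-sample aligned-read totals in
#' `colData(x)$librarySize`. When no locus coordinates are supplied the
#' row ranges are width-1 placeholders on seqname `"unplaced"`.
#'
#' @export
setClass("SignalMatrix", contains = "RangedSummarizedExperiment")

setValidity("SignalMatrix", function(object) {
  if (!"rpm" %in% SummarizedExperiment::assayNames(object))
    return("missing 'rpm' assay")
  if (any(SummarizedExperiment::assay(object, "rpm") < 0))
    return("RPM values must be >= 0")
  ls <- SummarizedExperiment::colData(object)$librarySize
  if (is.null(ls) || any(ls <= 0))
    return("colData must carry positive librarySize")
  TRUE
})

#' @describeIn SignalMatrix-class construct from a counts or RPM matrix.
#' @param counts raw read-count matrix (loci x samples), or `NULL` when
#'   `rpm` is supplied directly.
#' @param librarySize per-sample aligned-read totals (length = ncol).
#' @param rpm precomputed RPM matrix; computed from `counts` if omitted.
#' @param rowRanges optional `GRanges` of locus coordinates.
#' @export
SignalMatrix <- function(counts = NULL, librarySize, rpm = NULL,
                         rowRanges = NULL) {
  if (is.null(rpm)) {
    stopifnot(!is.null(counts), length(librarySize) == ncol(counts))
    rpm <- sweep(counts, 2L, librarySize, "/") * 1e6
  }
  assays <- list(rpm = rpm)
  if (!is.null(counts)) assays$counts <- counts
  cd <- DataFrame(librarySize = librarySize, row.names = colnames(rpm))
  if (is.null(rowRanges)) {
    rowRanges <- GenomicRanges::GRanges(
      "unplaced", IRanges::IRanges(seq_len(nrow(rpm)), width = 1L))
    names(rowRanges) <- rownames(rpm)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays, rowRanges = rowRanges, colData = cd)
  new("SignalMatrix", se)
}

#' @describeIn SignalMatrix-class RPM matrix accessor.
#' @param x a `SignalMatrix`.
#' @export
rpmValues <- function(x) SummarizedExperiment::assay(x, "rpm")

#' @describeIn SignalMatrix-class per-sample aligned-read totals.
#' @export
librarySizes <- function(x) {
  setNames(SummarizedExperiment::colData(x)$librarySize, colnames(x))
}
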