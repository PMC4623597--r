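#' Filter GWAS catalog studies by independent SNP count
#'
#' Keeps studies that identified strictly more than `minSnps`
#' independent associated variants.
#'
#' @param catalog `data.frame` with columns `variant`, `chrom`, `pos`,
#'   `trait`, `study`.
#' @param minSnps strict lower bound on unique variants per study
#'   (default 5).
#' @return the catalog subset.
#' @export
filterStudies <- function(catalog, minSnps = 5L) {
  if (nrow(catalog) == 0L) return(catalog)
  nPer <- tapply(catalog$variant, catalog$study,
                 function(v) length(unique(v)))
  keep <- names(nPer)[nPer > minSnps]
  catalog[catalog$study %in% keep, , drop = FALSE]
}

#' Expand regulatory elements into risk regions
#'
#' Takes broad regions (element +/- `span`, default 100 kbp) around
#' regulatory elements so that disease-associated polymorphisms across
#' the whole haplotype block are captured; when the most proximal gene
#' body extends beyond that window, the region is widened to cover it.
#' Overlapping regions are merged (which removes over-counting from
#' multiple elements on one haplotype) and coordinates are clipped at
#' contig bounds.
#'
#' @param elements `GRanges` of regulatory elements.
#' @param genes `GRanges` of gene bodies (or `NULL` to skip the
#'   gene-body extension).
#' @param span flank in bp (default 1e5).
#' @param chromSizes named contig lengths for clipping (optional).
#' @return merged, disjoint `GRanges`.
#' @export
expandRiskRegions <- function(elements, genes = NULL, span = 1e5,
                              chromSizes = NULL) {
  lo <- start(elements) - span
  hi <- end(elements) + span
  if (!is.null(genes) && length(genes) > 0L) {
    d <- distanceToNearest(elements, genes)
    q <- S4Vectors::queryHits(d)
    s <- S4Vectors::subjectHits(d)
    lo[q] <- pmin(lo[q], start(genes)[s])
    hi[q] <- pmax(hi[q], end(genes)[s])
  }
  lo <- pmax(lo, 1L)
  if (!is.null(chromSizes)) {
    sz <- chromSizes[as.character(seqnames(elements))]
    hi <- pmin(hi, sz)
  }
  reduce(GRanges(seqnames(elements), IRanges(lo, hi)))
}

#' Disease-set enrichment in risk regions
#'
#' One-tailed (upper) hypergeometric test of the overlap between a
#' disease set's variants and the risk regions, with all catalog
#' variants as the universe modelling the null: `N` catalog variants of
#' which `K` fall in regions; `n` disease-set variants of which `k`
#' fall in regions; `p = P(X >= k)`.
#'
#' @param catalog filtered catalog (`data.frame` with `variant`,
#'   `chrom`, `pos`, `trait`).
#' @param traits character vector of traits forming the disease set.
#' @param regions `GRanges` of (merged) risk regions.
#' @return list with `N`, `K`, `n`, `k`, `p`.
#' @export
enrichmentTest <- function(catalog, traits, regions) {
  cat1 <- catalog[!duplicated(catalog$variant), , drop = FALSE]
  inRegion <- countOverlaps(GRanges(cat1$chrom,
                                    IRanges(cat1$pos, width = 1L)),
                            regions) > 0L
  inSet <- cat1$trait %in% traits
  n <- sum(inSet)
  if (n == 0L) stop("empty disease set")
  N <- nrow(cat1)
  K <- sum(inRegion)
  k <- sum(inRegion & inSet)
  list(N = N, K = K, n = n, k = k, p = .hyperUpper(k, K, n, N))
}

#' Partition risk elements by conservation category
#'
#' Divides risk-containing regulatory elements into four nested
#' categories: genetically non-conserved; genetically conserved;
#' conserved and lineage-specific in human; conserved and
#' lineage-specific in both species. Unannotated elements go to
#' `"unknown"` with a warning.
#'
#' @param conserved logical per element (genetic conservation; NA =
#'   unannotated).
#' @param lsHuman,lsBoth logical per element: lineage-specific
#'   epigenetic activity in human / in both species.
#' @return `data.frame` with `category` and `count` (and `fraction`).
#' @export
conservationPartition <- function(conserved, lsHuman, lsBoth) {
  stopifnot(length(conserved) == length(lsHuman),
            length(conserved) == length(lsBoth))
  cat <- rep("unknown", length(conserved))
  known <- !is.na(conserved)
  if (any(!known)) warning(sum(!known), " unannotated element(s)")
  cat[known & !conserved] <- "non_conserved"
  cat[known & conserved] <- "conserved"
  cat[known & conserved & lsHuman %in% TRUE] <- "conserved_ls_human"
  cat[known & conserved & lsBoth %in% TRUE] <- "conserved_ls_both"
  lev <- c("non_conserved", "conserved", "conserved_ls_human",
           "conserved_ls_both", "unknown")
  tab <- table(factor(cat, lev))
  out <- data.frame(category = lev, count = as.integer(tab))
  out$fraction <- out$count / sum(out$count)
  out[out$count > 0L | out$category != "unknown", , drop = FALSE]
}
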