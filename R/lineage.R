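#' Pseudocount-stabilised log2 fold change
#'
#' `log2((a + 0.5) / (b + 0.5))`: the symmetric 0.5 pseudocount shrinks
#' fold changes of low-count loci toward zero, reducing noise.
#'
#' @param a,b non-negative signal values (e.g. Treg and Teff RPM).
#' @return vector of log2 fold changes.
#' @export
log2FoldChange <- function(a, b) {
  stopifnot(all(a >= 0), all(b >= 0))
  log2((a + 0.5) / (b + 0.5))
}

#' Classify lineage specificity of regulatory elements in both species
#'
#' An element is called `up` when its log2 fold change (e.g. aTreg vs
#' Teff) reaches `tau`, `down` at `-tau`, otherwise `ns`, independently
#' per species; the combined 9-way class is `"<human>/<mouse>"`.
#' Species-only loci (NA fold change in the missing species) are
#' classified only in their own species and get a combined class such as
#' `"up/."`.
#'
#' @param lfcHuman,lfcMouse per-locus log2 fold changes (NA allowed for
#'   species-only loci).
#' @param tau fold-change threshold on the log2 scale (default 1, i.e.
#'   2-fold).
#' @return `data.frame` with columns `human`, `mouse` (factors
#'   up/down/ns) and `class`.
#' @export
classifySpecificity <- function(lfcHuman, lfcMouse, tau = 1) {
  stopifnot(tau > 0, length(lfcHuman) == length(lfcMouse))
  lab <- function(x) {
    out <- ifelse(is.na(x), NA_character_,
                  ifelse(x >= tau, "up", ifelse(x <= -tau, "down", "ns")))
    factor(out, levels = c("up", "down", "ns"))
  }
  h <- lab(lfcHuman)
  m <- lab(lfcMouse)
  cls <- paste(ifelse(is.na(h), ".", as.character(h)),
               ifelse(is.na(m), ".", as.character(m)), sep = "/")
  data.frame(human = h, mouse = m, class = cls)
}

# upper-tail hypergeometric p: P(X >= k) drawing n from N with K marked
.hyperUpper <- function(k, K, n, N) {
  phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' Cross-species overlap enrichment of lineage-specific elements
#'
#' One-sided (upper-tail) hypergeometric test of the overlap between the
#' human and mouse lineage-specific element sets, per direction, with
#' the genetically conserved atlas loci as the universe.
#'
#' @param classes a `data.frame` from [classifySpecificity()]; rows with
#'   NA in either species are excluded from the universe.
#' @return `data.frame` with one row per direction (`up`, `down`):
#'   universe size `N`, set sizes `nHuman`, `nMouse`, `overlap` and
#'   upper-tail `p`.
#' @export
overlapEnrichment <- function(classes) {
  ok <- !is.na(classes$human) & !is.na(classes$mouse)
  if (!any(ok)) stop("empty universe: no loci classified in both species")
  h <- classes$human[ok]
  m <- classes$mouse[ok]
  N <- sum(ok)
  do.call(rbind, lapply(c("up", "down"), function(dir) {
    K <- sum(h == dir)
    n <- sum(m == dir)
    k <- sum(h == dir & m == dir)
    data.frame(direction = dir, N = N, nHuman = K, nMouse = n,
               overlap = k, p = .hyperUpper(k, K, n, N))
  }))
}

#' Overlap enrichment along a rank-cutoff scan
#'
#' Rather than fixing a fold-change threshold, elements are ranked by
#' fold change in each species (descending for `up`, ascending for
#' `down`) and the cross-species overlap of the top-`k` sets is tested
#' at every requested cutoff, showing whether conservation of the
#' lineage program depends on the cutoff choice.
#'
#' @param lfcHuman,lfcMouse per-locus log2 fold changes (no NAs).
#' @param ranks integer vector of rank cutoffs (default: 10 log-spaced
#'   cutoffs up to the locus count).
#' @return `data.frame` with columns `direction`, `k`, `overlap`, `p`.
#' @export
rankCutoffScan <- function(lfcHuman, lfcMouse, ranks = NULL) {
  stopifnot(length(lfcHuman) == length(lfcMouse),
            !anyNA(lfcHuman), !anyNA(lfcMouse))
  N <- length(lfcHuman)
  if (is.null(ranks))
    ranks <- unique(pmax(1L, round(exp(seq(log(10), log(N), length.out = 10)))))
  do.call(rbind, lapply(c("up", "down"), function(dir) {
    oH <- order(lfcHuman, decreasing = (dir == "up"))
    oM <- order(lfcMouse, decreasing = (dir == "up"))
    do.call(rbind, lapply(ranks, function(k) {
      ov <- length(intersect(oH[seq_len(k)], oM[seq_len(k)]))
      data.frame(direction = dir, k = k, overlap = ov,
                 p = .hyperUpper(ov, k, k, N))
    }))
  }))
}

#' Assign regulatory elements to genes
#'
#' All genes whose body lies within `window` bp of the element are
#' assigned; when none qualifies, the single nearest gene by TSS
#' distance (same chromosome) is used as fallback.
#'
#' @param elements `GRanges` (names become element ids).
#' @param genes `GRanges` of gene bodies with metadata columns `gene`
#'   (id) and `tss` (TSS coordinate, 1-based).
#' @param window assignment window in bp (default 100 kb).
#' @return `data.frame` with columns `element`, `gene`, `viaWindow`.
#' @export
assignToGenes <- function(elements, genes, window = 1e5) {
  if (length(genes) == 0L) stop("empty gene model set")
  if (is.null(names(elements)))
    names(elements) <- sprintf("el_%04d", seq_along(elements))
  hits <- findOverlaps(elements, genes, maxgap = window)
  res <- data.frame(
    element = names(elements)[S4Vectors::queryHits(hits)],
    gene = genes$gene[S4Vectors::subjectHits(hits)],
    viaWindow = rep(TRUE, length(hits)))
  unassigned <- setdiff(names(elements), res$element)
  if (length(unassigned)) {
    tss <- GRanges(seqnames(genes), IRanges(genes$tss, width = 1L))
    idx <- match(unassigned, names(elements))
    nearestRows <- lapply(idx, function(i) {
      d <- distanceToNearest(elements[i], tss)
      if (length(d) == 0L) return(NULL)
      data.frame(element = names(elements)[i],
                 gene = genes$gene[S4Vectors::subjectHits(d)],
                 viaWindow = FALSE)
    })
    nearestRows <- nearestRows[!vapply(nearestRows, is.null, logical(1))]
    if (length(nearestRows)) res <- rbind(res, do.call(rbind, nearestRows))
  }
  if (!all(names(elements) %in% res$element))
    warning("elements with no assignable gene: ",
            paste(setdiff(names(elements), res$element), collapse = ", "))
  res[order(res$element), , drop = FALSE]
}

#' Expression concordance of element classes
#'
#' For each combined lineage class, genes most proximal to elements of
#' the class are collected (mouse ids translated through the homology
#' map) and the per-species distribution of their expression log2 fold
#' change is summarised as an ECDF, with two-sample Kolmogorov-Smirnov
#' tests of each class against a reference class.
#'
#' @param classes combined class label per element (from
#'   [classifySpecificity()]).
#' @param elementGenes character vector: most proximal (expressed) gene
#'   per element, human ids.
#' @param exprHuman,exprMouse named vectors of expression log2 fold
#'   change by gene id (human/mouse naming respectively).
#' @param homology `data.frame` with columns `human`, `mouse` mapping
#'   gene ids; human ids missing from it are reported via a warning and
#'   dropped from the mouse-side comparison.
#' @param reference reference class for the KS comparisons (default
#'   `"ns/ns"`).
#' @return list with `curves` (`data.frame`: class, species, gene, lfc)
#'   and `tests` (`data.frame`: class, species, D, p; NA when a class
#'   has fewer than 3 genes, with a warning).
#' @export
expressionConcordance <- function(classes, elementGenes, exprHuman,
                                  exprMouse, homology,
                                  reference = "ns/ns") {
  stopifnot(length(classes) == length(elementGenes))
  unmapped <- setdiff(unique(elementGenes), homology$human)
  if (length(unmapped))
    warning("gene ids without mouse homolog: ",
            paste(head(unmapped, 5L), collapse = ", "),
            if (length(unmapped) > 5L) ", ...")
  mouseId <- homology$mouse[match(elementGenes, homology$human)]
  curves <- rbind(
    data.frame(class = classes, species = "human", gene = elementGenes,
               lfc = unname(exprHuman[elementGenes])),
    data.frame(class = classes, species = "mouse", gene = mouseId,
               lfc = unname(exprMouse[mouseId])))
  curves <- curves[!is.na(curves$lfc), , drop = FALSE]
  tests <- do.call(rbind, lapply(split(curves, curves[c("class", "species")]),
                                 function(d) {
    if (nrow(d) == 0L) return(NULL)
    cls <- d$class[1L]; sp <- d$species[1L]
    if (cls == reference) return(NULL)
    ref <- curves$lfc[curves$class == reference & curves$species == sp]
    if (nrow(d) < 3L || length(ref) < 3L) {
      warning("class ", cls, " (", sp, "): fewer than 3 genes, test skipped")
      return(data.frame(class = cls, species = sp, D = NA_real_,
                        p = NA_real_))
    }
    ks <- suppressWarnings(stats::ks.test(d$lfc, ref))
    data.frame(class = cls, species = sp, D = unname(ks$statistic),
               p = ks$p.value)
  }))
  rownames(tests) <- NULL
  list(curves = curves, tests = tests)
}

#' Mobility and functional homology of lineage-specific elements
#'
#' Asks whether the lineage program is conserved at the gene level even
#' where individual elements are not:
#' * Q1 (mobility): genes with a lineage-specific element in both
#'   species in the same direction, but at non-orthologous positions
#'   (no single atlas locus lineage-specific in both). Expression
#'   concordance of those genes is counted and tested by permuting gene
#'   expression labels.
#' * Q2: lineage-specific elements whose orthologous interval exists
#'   (genetically conserved) but is epigenetically inactive (no peak)
#'   in the other species.
#' * Q3 (loosened): per gene, the maximally lineage-specific element in
#'   each species (|lfc| above `tauLoose`), restricted to genes with at
#'   least weak differential expression (|lfc| > 0.5 or q < 0.01);
#'   direction concordance across species is counted and permuted as in
#'   Q1.
#'
#' @param classes `data.frame` from [classifySpecificity()] plus columns
#'   `atlasId`, `lfcHuman`, `lfcMouse`.
#' @param atlas a [UnionAtlas-class] (peak presence flags used for Q2).
#' @param geneOf named character: gene assigned to each atlas id.
#' @param exprHuman,exprMouse named expression lfc vectors by gene
#'   (human gene ids; mouse translated upstream).
#' @param exprQ named FDR q-values by gene (optional, used by the weak
#'   expression filter; `NULL` disables the q rule).
#' @param tauLoose loosened |lfc| threshold for Q3 (default 0.5).
#' @param nPerm permutations for the empirical p (default 1000).
#' @param seed RNG seed.
#' @return list with `q1`, `q2`, `q3`, each a list of counts (and for
#'   Q1/Q3 `nConcordant`, `nGenes`, `pEmpirical`).
#' @export
mobilityAnalysis <- function(classes, atlas, geneOf, exprHuman, exprMouse,
                             exprQ = NULL, tauLoose = 0.5, nPerm = 1000L,
                             seed = 1L) {
  set.seed(seed)
  stopifnot(all(c("atlasId", "human", "mouse", "lfcHuman", "lfcMouse")
                %in% names(classes)))
  gene <- unname(geneOf[classes$atlasId])
  lsH <- !is.na(classes$human) & classes$human != "ns"
  lsM <- !is.na(classes$mouse) & classes$mouse != "ns"
  lsBoth <- lsH & lsM &
    as.character(classes$human) == as.character(classes$mouse)

  concordant <- function(genes, dir, eh, em) {
    sgn <- ifelse(dir == "up", 1, -1)
    ok <- !is.na(eh[genes]) & !is.na(em[genes])
    genes <- genes[ok]; sgn <- sgn[ok]
    sum(sign(eh[genes]) == sgn & sign(em[genes]) == sgn)
  }

  # Q1: same gene, lineage-specific in both species, but never at one
  # orthologous locus
  q1genes <- character(); q1dir <- character()
  for (g in unique(gene[!is.na(gene)])) {
    rows <- which(gene == g)
    if (any(lsBoth[rows])) next
    for (dir in c("up", "down")) {
      hasH <- any(lsH[rows] & classes$human[rows] == dir, na.rm = TRUE)
      hasM <- any(lsM[rows] & classes$mouse[rows] == dir, na.rm = TRUE)
      if (hasH && hasM) { q1genes <- c(q1genes, g); q1dir <- c(q1dir, dir) }
    }
  }
  permP <- function(genes, dirs) {
    if (length(genes) == 0L)
      return(list(nConcordant = 0L, nGenes = 0L, pEmpirical = NA_real_))
    obs <- concordant(genes, dirs, exprHuman, exprMouse)
    allg <- intersect(names(exprHuman), names(exprMouse))
    perm <- vapply(seq_len(nPerm), function(i) {
      fake <- sample(allg, length(genes), replace = length(genes) > length(allg))
      concordant(fake, dirs, exprHuman, exprMouse)
    }, numeric(1))
    list(nConcordant = obs, nGenes = length(genes),
         pEmpirical = (1 + sum(perm >= obs)) / (nPerm + 1))
  }
  q1 <- permP(q1genes, q1dir)

  # Q2: lineage-specific, genetically conserved, but no peak in the
  # other species
  loci <- atlasLoci(atlas)
  idx <- match(classes$atlasId, loci$atlasId)
  consv <- loci$geneticStatus[idx] == "conserved"
  q2 <- list(
    humanLsInactiveInMouse = sum(lsH & consv & !loci$mousePeak[idx],
                                 na.rm = TRUE),
    mouseLsInactiveInHuman = sum(lsM & consv & !loci$humanPeak[idx],
                                 na.rm = TRUE))

  # Q3: maximally lineage-specific element per gene, loosened threshold,
  # weak-expression gene filter
  q3genes <- character(); q3dir <- character()
  weak <- function(g) {
    e <- exprHuman[g]
    if (is.na(e)) return(FALSE)
    abs(e) > 0.5 || (!is.null(exprQ) && !is.na(exprQ[g]) && exprQ[g] < 0.01)
  }
  for (g in unique(gene[!is.na(gene)])) {
    rows <- which(gene == g)
    bh <- rows[which.max(abs(classes$lfcHuman[rows]))]
    bm <- rows[which.max(abs(classes$lfcMouse[rows]))]
    if (length(bh) == 0L || length(bm) == 0L) next
    if (is.na(classes$lfcHuman[bh]) || is.na(classes$lfcMouse[bm])) next
    if (abs(classes$lfcHuman[bh]) <= tauLoose ||
        abs(classes$lfcMouse[bm]) <= tauLoose) next
    if (sign(classes$lfcHuman[bh]) != sign(classes$lfcMouse[bm])) next
    if (!weak(g)) next
    q3genes <- c(q3genes, g)
    q3dir <- c(q3dir, if (classes$lfcHuman[bh] > 0) "up" else "down")
  }
  q3 <- permP(q3genes, q3dir)
  list(q1 = q1, q2 = q2, q3 = q3)
}
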