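#' Classify binding-site conservation at orthologous positions
#'
#' Given occupancy (RPM) for the two species at orthologous positions of
#' genetically conserved loci, calls binding `both` when occupancy
#' reaches the robust-quantification floor in both species,
#' `human_only` / `mouse_only` when it does in one, and excludes loci
#' below the floor in both (insufficient binding for robust
#' quantification).
#'
#' @param occupancyHuman,occupancyMouse non-negative occupancy per
#'   conserved locus.
#' @param floor robust-quantification floor in RPM (default 1).
#' @return factor with levels `both`, `human_only`, `mouse_only`;
#'   `NA` for excluded loci.
#' @export
classifyOccupancy <- function(occupancyHuman, occupancyMouse, floor = 1) {
  stopifnot(length(occupancyHuman) == length(occupancyMouse),
            all(occupancyHuman >= 0, na.rm = TRUE),
            all(occupancyMouse >= 0, na.rm = TRUE))
  h <- occupancyHuman >= floor
  m <- occupancyMouse >= floor
  out <- rep(NA_character_, length(h))
  out[h & m] <- "both"
  out[h & !m] <- "human_only"
  out[!h & m] <- "mouse_only"
  factor(out, levels = c("both", "human_only", "mouse_only"))
}

#' Classify binding conservation from site intervals
#'
#' Maps each human binding site into the mouse assembly (iterative
#' center-outward scan with binding-site parameters), pairs it with
#' overlapping mouse sites, and classifies occupancy with
#' [classifyOccupancy()]. Sites that cannot be mapped are not part of
#' the conserved-class analysis and are returned separately.
#'
#' @param sitesHuman,sitesMouse `GRanges` with an `occupancy` metadata
#'   column (RPM).
#' @param chains [ChainSet-class] mapping human to mouse coordinates.
#' @param floor robust-quantification floor (RPM).
#' @param params scan parameters (default `assayScanParams("foxp3")`).
#' @return list with `classes` (`data.frame`: human site index, paired
#'   mouse occupancy, class) and `unmapped` (`GRanges` of unmappable
#'   human sites).
#' @export
classifyBindingConservation <- function(sitesHuman, sitesMouse, chains,
                                        floor = 1,
                                        params = assayScanParams("foxp3")) {
  stopifnot(!is.null(sitesHuman$occupancy), !is.null(sitesMouse$occupancy))
  occM <- rep(0, length(sitesHuman))
  mappedOk <- logical(length(sitesHuman))
  for (i in seq_along(sitesHuman)) {
    r <- iterativeOrthologSearch(sitesHuman[i], chains, params)
    if (r@status == "unmapped") next
    mappedOk[i] <- TRUE
    hit <- findOverlaps(r@mapped, sitesMouse)
    if (length(hit) > 0L)
      occM[i] <- max(sitesMouse$occupancy[S4Vectors::subjectHits(hit)])
  }
  cls <- classifyOccupancy(sitesHuman$occupancy[mappedOk], occM[mappedOk],
                           floor)
  list(classes = data.frame(site = which(mappedOk),
                            occupancyHuman = sitesHuman$occupancy[mappedOk],
                            occupancyMouse = occM[mappedOk],
                            class = cls),
       unmapped = sitesHuman[!mappedOk])
}

#' Acetylation change by binding-conservation class
#'
#' Two-sample t-test of the acetylation log2 fold change of each binding
#' class against the background of all acetylated loci, per species,
#' with conventional significance stars (0.05 / 0.01 / 0.001).
#'
#' @param classes factor of binding classes per locus (NA excluded).
#' @param lfcHuman,lfcMouse acetylation log2 fold changes for the same
#'   loci.
#' @param backgroundHuman,backgroundMouse fold changes of all acetylated
#'   loci (the background distribution).
#' @return `data.frame` with columns `class`, `species`, `n`, `t`, `p`,
#'   `stars`.
#' @export
acetylationChangeByClass <- function(classes, lfcHuman, lfcMouse,
                                     backgroundHuman, backgroundMouse) {
  starsOf <- function(p) {
    if (is.na(p)) "" else if (p < 0.001) "***" else if (p < 0.01) "**"
    else if (p < 0.05) "*" else ""
  }
  do.call(rbind, lapply(levels(classes), function(cl) {
    do.call(rbind, lapply(c("human", "mouse"), function(sp) {
      x <- (if (sp == "human") lfcHuman else lfcMouse)[classes %in% cl]
      bg <- if (sp == "human") backgroundHuman else backgroundMouse
      if (length(x) < 2L)
        return(data.frame(class = cl, species = sp, n = length(x),
                          t = NA_real_, p = NA_real_, stars = ""))
      if (sd(x) == 0 && sd(bg) == 0) stop("degenerate variance in t-test")
      tt <- stats::t.test(x, bg)
      data.frame(class = cl, species = sp, n = length(x),
                 t = unname(tt$statistic), p = tt$p.value,
                 stars = starsOf(tt$p.value))
    }))
  }))
}

# does the region [gr] contain >=1 motif match on either strand?
.motifPresent <- function(seqs, motif) {
  fwd <- Biostrings::vcountPattern(motif, seqs, fixed = FALSE) > 0L
  rev <- Biostrings::vcountPattern(
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif))),
    seqs, fixed = FALSE) > 0L
  fwd | rev
}

#' Motif enrichment in binding sites versus flanking background
#'
#' Compares motif occurrence (presence/absence per region, both strands,
#' IUPAC consensus) in binding sites against their two 200 nt flanking
#' regions, as an empirical enrichment over local chance: Fisher's exact
#' test on the 2x2 region-count table.
#'
#' @param sites `GRanges` of binding sites.
#' @param genome a named `DNAStringSet` of contig sequences.
#' @param motif IUPAC consensus (default `"RYAAAYA"`, the forkhead
#'   core).
#' @param flank flank length in bp (default 200). Flanks extending past
#'   a contig end are truncated with a warning.
#' @return list with `table` (2x2 matrix), `oddsRatio` (sample odds
#'   ratio `ad/bc`), and `p` (Fisher's exact, two-sided).
#' @export
motifEnrichment <- function(sites, genome, motif = "RYAAAYA",
                            flank = 200L) {
  stopifnot(nchar(motif) > 0L)
  lens <- setNames(Biostrings::width(genome), names(genome))
  getSeq <- function(gr) {
    s <- pmax(1L, start(gr))
    e <- pmin(end(gr), lens[as.character(seqnames(gr))])
    if (any(s > start(gr) | e < end(gr)))
      warning("flank truncated at contig boundary")
    keep <- s <= e
    Biostrings::DNAStringSet(vapply(which(keep), function(i)
      as.character(Biostrings::subseq(genome[[as.character(seqnames(gr)[i])]],
                                      s[i], e[i])), character(1)))
  }
  siteSeq <- getSeq(sites)
  left <- GRanges(seqnames(sites), IRanges(start(sites) - flank,
                                           start(sites) - 1L))
  right <- GRanges(seqnames(sites), IRanges(end(sites) + 1L,
                                            end(sites) + flank))
  flankSeq <- c(getSeq(left), getSeq(right))
  sPos <- sum(.motifPresent(siteSeq, motif))
  fPos <- sum(.motifPresent(flankSeq, motif))
  tab <- matrix(c(sPos, length(siteSeq) - sPos,
                  fPos, length(flankSeq) - fPos), 2L, 2L,
                dimnames = list(c("present", "absent"),
                                c("site", "flank")))
  ft <- stats::fisher.test(tab)
  oddsRatio <- (tab[1, 1] * tab[2, 2]) / (tab[2, 1] * tab[1, 2])
  list(table = tab, oddsRatio = oddsRatio, p = ft$p.value)
}

#' Repression of genes near binding sites
#'
#' One-sided two-sample Kolmogorov-Smirnov test of the expression log2
#' fold change of genes assigned to each binding class against all
#' expressed genes, asking whether bound genes are shifted toward
#' repression.
#'
#' @param classGenes named list: gene ids per binding class.
#' @param exprLfc named expression log2 fold changes for all expressed
#'   genes (the background).
#' @param alternative KS alternative; the default `"greater"` tests for
#'   a downward (repressive) shift of the bound set.
#' @return `data.frame` with columns `class`, `n`, `D`, `p`.
#' @export
repressionByBinding <- function(classGenes, exprLfc,
                                alternative = "greater") {
  do.call(rbind, lapply(names(classGenes), function(cl) {
    x <- exprLfc[intersect(classGenes[[cl]], names(exprLfc))]
    if (length(x) < 3L) {
      warning("class ", cl, ": fewer than 3 genes, test skipped")
      return(data.frame(class = cl, n = length(x), D = NA_real_,
                        p = NA_real_))
    }
    ks <- suppressWarnings(stats::ks.test(x, exprLfc,
                                          alternative = alternative))
    data.frame(class = cl, n = length(x), D = unname(ks$statistic),
               p = ks$p.value)
  }))
}
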