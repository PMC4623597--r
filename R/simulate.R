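#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators with defaults
#' that emulate the comparative Treg/Teff study design: two assemblies
#' related by indels/inversions/breaks, H3K27ac loci with planted
#' conservation classes and negative-binomial read counts over the
#' aTreg/rTreg/Teff/Tn subsets (2/4/2/4 biological replicates), a donor
#' cohort with planted allelic-imbalance effects, and a GWAS catalog
#' with planted trait enrichment.
#'
#' @param seed master RNG seed.
#' @param chromSizes named lengths of the source-assembly chromosomes.
#' @param insertionRate,deletionRate,inversionRate,breakRate expected
#'   events per bp when deriving the second assembly.
#' @param indelMeanLength,inversionMeanLength mean event lengths (bp).
#' @param locusCount number of regulatory loci to plant.
#' @param locusWidth locus width in bp (H3K27ac scale).
#' @param classProportions named proportions for planted classes
#'   `conservedActive`, `humanOnlyLS`, `mouseOnlyLS`, `bothLS`,
#'   `discordant`; the remainder is split between genetically
#'   non-conserved human-only and mouse-only loci.
#' @param foldEffect linear fold change of lineage-specific loci
#'   (aTreg/rTreg vs Teff/Tn).
#' @param nbMean,nbDispersion negative-binomial read-count model for a
#'   library of one million reads (mean count at an average locus;
#'   dispersion = 1/size).
#' @param rho cross-species correlation of baseline log2 signal at
#'   genetically conserved loci.
#' @param signalSdLog2 spread of baseline log2 signal across loci.
#' @param replicates named replicate counts per cell type.
#' @param exprEffect,exprNoiseSd scale and noise of the gene-expression
#'   fold change planted concordantly with each locus class.
#' @param donorCount donors in the allele-specific cohort.
#' @param aseFraction fraction of elements with a planted allelic
#'   effect.
#' @param aseTheta planted allelic ratio for affected elements
#'   (in `(0.5, 1)`).
#' @param aseDepthMean,aseDepthSize negative-binomial per-donor read
#'   depth at heterozygous variants (ChIP and input).
#' @param variantsPerElementMax per-element variant count is uniform on
#'   `1:variantsPerElementMax`.
#' @param ldLinkedFraction fraction of multi-variant elements whose
#'   extra variants are in perfect LD with the first.
#' @param cohortMafRange common-variant MAF range for cohort genotypes.
#' @param panelSize individuals per reference-population panel.
#' @param populations reference population names.
#' @param catalogSize GWAS catalog size (variants).
#' @param gwasEnrichment named fold enrichment of each disease set's
#'   variants inside target regions.
#' @return a list with class `"SimulationConfig"`.
#' @export
simulationConfig <- function(seed = 1L,
                             chromSizes = c(chrA1 = 1e6),
                             insertionRate = 2e-5, deletionRate = 2e-5,
                             inversionRate = 2e-6, breakRate = 1e-6,
                             indelMeanLength = 150,
                             inversionMeanLength = 2000,
                             locusCount = 2000L, locusWidth = 1000L,
                             classProportions = c(conservedActive = 0.85,
                                                  humanOnlyLS = 0.015,
                                                  mouseOnlyLS = 0.015,
                                                  bothLS = 0.001,
                                                  discordant = 0.0005),
                             foldEffect = 4, nbMean = 50,
                             nbDispersion = 0.01, rho = 0.5,
                             signalSdLog2 = 1.5,
                             replicates = c(aTreg = 2L, rTreg = 4L,
                                            Teff = 2L, Tn = 4L),
                             exprEffect = 1, exprNoiseSd = 0.3,
                             donorCount = 6L, aseFraction = 0.1,
                             aseTheta = 0.75, aseDepthMean = 35,
                             aseDepthSize = 6,
                             variantsPerElementMax = 3L,
                             ldLinkedFraction = 0.2,
                             cohortMafRange = c(0.2, 0.5),
                             panelSize = 60L,
                             populations = c("afr", "eur", "ceu", "chb",
                                             "jpt"),
                             catalogSize = 500L,
                             gwasEnrichment = c(autoimmune = 5,
                                                metabolic = 1,
                                                psychiatric = 1)) {
  stopifnot(sum(classProportions) <= 1, aseTheta > 0.5, aseTheta < 1,
            all(c(insertionRate, deletionRate, inversionRate,
                  breakRate) >= 0), all(chromSizes > 0))
  structure(as.list(environment()), class = "SimulationConfig")
}

# exponential event length, at least 1 bp
.rlen <- function(n, mean) pmax(1L, as.integer(stats::rexp(n, 1 / mean)))

#' Simulate a pair of assemblies and the chain relating them
#'
#' Derives assembly B from assembly A by sampling insertions,
#' deletions, inversions and chromosome breaks, and emits the chain set
#' that exactly encodes the relation plus a per-base truth map (one row
#' per aligned segment). With all perturbation rates zero the chain is
#' the identity.
#'
#' @param config a [simulationConfig()].
#' @return list with `chains` ([ChainSet-class], A as source),
#'   `truth` (`data.frame`: `chromA`, `startA` (0-based), `chromB`,
#'   `startB` (0-based, plus strand), `len`, `strand`),
#'   `chromSizesA`, `chromSizesB`.
#' @export
simulateGenomePair <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  if (any(config$chromSizes <= 0)) stop("zero-length chromosome")
  set.seed(config$seed)
  chains <- list()
  truth <- list()
  sizesB <- numeric()
  chainCount <- 0L

  for (chrom in names(config$chromSizes)) {
    L <- config$chromSizes[[chrom]]
    rates <- c(ins = config$insertionRate, del = config$deletionRate,
               inv = config$inversionRate, brk = config$breakRate)
    nEv <- stats::rpois(4L, rates * L)
    type <- rep(names(rates), nEv)
    pos <- sort(sample.int(L, length(type)))
    type <- sample(type)   # decouple type from position order
    len <- integer(length(type))
    len[type %in% c("ins", "del")] <-
      .rlen(sum(type %in% c("ins", "del")), config$indelMeanLength)
    len[type == "inv"] <- .rlen(sum(type == "inv"),
                                config$inversionMeanLength)

    bIndex <- 1L
    bChrom <- function() sprintf("%s_B%d", chrom, bIndex)
    bPos <- 0L
    aPos <- 0L
    blocks <- NULL        # data.frame size/dt/dq under construction
    chainMeta <- NULL     # sStart/tStart/tChrom/strand of open chain

    pendingDt <- 0L; pendingDq <- 0L
    localChains <- list()

    emitAligned <- function(aStart, bStart, size, strand) {
      truth[[length(truth) + 1L]] <<- data.frame(
        chromA = chrom, startA = aStart, chromB = bChrom(),
        startB = bStart, len = size, strand = strand)
    }
    closeChain <- function() {
      if (is.null(blocks)) { pendingDt <<- 0L; pendingDq <<- 0L; return() }
      n <- nrow(blocks)
      blocks$dt[n] <<- 0L; blocks$dq[n] <<- 0L
      chainCount <<- chainCount + 1L
      span <- sum(blocks$size + blocks$dt)
      tspan <- sum(blocks$size + blocks$dq)
      localChains[[length(localChains) + 1L]] <<- list(
        sChrom = chrom, sStart = chainMeta$sStart,
        sEnd = chainMeta$sStart + span,
        tChrom = chainMeta$tChrom, tStrand = chainMeta$tStrand,
        tStartPlus = chainMeta$tStart, tSpan = tspan,
        blocks = blocks, id = as.character(chainCount))
      blocks <<- NULL; chainMeta <<- NULL
      pendingDt <<- 0L; pendingDq <<- 0L
    }
    addAligned <- function(size) {
      if (size <= 0L) return()
      if (is.null(blocks)) {
        chainMeta <<- list(sStart = aPos, tStart = bPos,
                           tChrom = bChrom(), tStrand = "+")
        blocks <<- data.frame(size = size, dt = 0L, dq = 0L)
      } else {
        n <- nrow(blocks)
        blocks$dt[n] <<- blocks$dt[n] + pendingDt
        blocks$dq[n] <<- blocks$dq[n] + pendingDq
        blocks <<- rbind(blocks, data.frame(size = size, dt = 0L, dq = 0L))
      }
      pendingDt <<- 0L; pendingDq <<- 0L
      emitAligned(aPos, bPos, size, "+")
      aPos <<- aPos + size
      bPos <<- bPos + size
    }

    i <- 1L
    while (i <= length(pos)) {
      p <- pos[i] - 1L      # 0-based event position
      if (p <= aPos) { i <- i + 1L; next }
      evLen <- len[i]
      addAligned(p - aPos)
      if (type[i] == "ins") {
        pendingDq <- pendingDq + evLen
        bPos <- bPos + evLen
      } else if (type[i] == "del") {
        evLen <- min(evLen, L - aPos)
        pendingDt <- pendingDt + evLen
        aPos <- aPos + evLen
      } else if (type[i] == "inv") {
        evLen <- min(evLen, L - aPos)
        if (evLen > 0L) {
          closeChain()
          chainCount <- chainCount + 1L
          localChains[[length(localChains) + 1L]] <- list(
            sChrom = chrom, sStart = aPos, sEnd = aPos + evLen,
            tChrom = bChrom(), tStrand = "-", tStartPlus = bPos,
            tSpan = evLen,
            blocks = data.frame(size = evLen, dt = 0L, dq = 0L),
            id = as.character(chainCount))
          truth[[length(truth) + 1L]] <- data.frame(
            chromA = chrom, startA = aPos, chromB = bChrom(),
            startB = bPos, len = evLen, strand = "-")
          aPos <- aPos + evLen
          bPos <- bPos + evLen
        }
      } else {              # chromosome break
        closeChain()
        sizesB[bChrom()] <- bPos
        bIndex <- bIndex + 1L
        bPos <- 0L
      }
      i <- i + 1L
    }
    addAligned(L - aPos)
    closeChain()
    sizesB[bChrom()] <- bPos

    for (lc in localChains) {
      bSize <- sizesB[[lc$tChrom]]
      if (lc$tStrand == "+") {
        tStart <- lc$tStartPlus
      } else {
        tStart <- bSize - (lc$tStartPlus + lc$tSpan)
      }
      chains[[length(chains) + 1L]] <- new(
        "Chain", score = sum(lc$blocks$size),
        sChrom = lc$sChrom, sSize = as.numeric(L),
        sStart = as.numeric(lc$sStart), sEnd = as.numeric(lc$sEnd),
        tChrom = lc$tChrom, tSize = as.numeric(bSize),
        tStrand = lc$tStrand, tStart = as.numeric(tStart),
        tEnd = as.numeric(tStart + lc$tSpan),
        blocks = lc$blocks, id = lc$id)
    }
  }
  list(chains = ChainSet(chains),
       truth = do.call(rbind, truth),
       chromSizesA = config$chromSizes,
       chromSizesB = sizesB)
}

# sample a width-w interval uniformly from a set of 0-based segments
.placeInSegments <- function(n, segStart, segLen, w, chrom) {
  room <- segLen - w + 1
  ok <- which(room > 0)
  if (length(ok) == 0L) return(NULL)
  segIdx <- ok[sample.int(length(ok), n, replace = TRUE, prob = room[ok])]
  off <- floor(runif(n) * room[segIdx])
  data.frame(chrom = chrom[segIdx], start = segStart[segIdx] + off,
             segment = segIdx)
}

#' Simulate the regulatory epigenome of both species
#'
#' Plants `locusCount` regulatory loci with classes drawn from the
#' configured proportions, then draws negative-binomial read counts per
#' cell type and replicate in both species (library size one million,
#' so counts are RPM-scaled). Lineage-specific loci carry the
#' configured fold effect between the Treg-lineage subsets
#' (aTreg/rTreg) and the conventional subsets (Teff/Tn) in the
#' affected species; `discordant` loci go up in human and down in
#' mouse. Genetically non-conserved loci have zero signal in the
#' missing species. Each locus gets a proximal gene whose expression
#' fold change is planted concordantly with the locus class.
#'
#' When a `genomePair` is supplied, conserved loci are placed inside
#' aligned chain segments (with the orthologous mouse interval derived
#' from the truth map) and non-conserved loci inside unaligned
#' sequence; loci that do not fit are dropped with a warning.
#'
#' @param config a [simulationConfig()].
#' @param genomePair optional result of [simulateGenomePair()].
#' @return list with `truth` (per-locus `data.frame`: class, direction,
#'   planted log2 fold changes), `rpmHuman`, `rpmMouse` (loci x
#'   samples), `samples` (`data.frame`: sample, cellType, replicate),
#'   `expression` (`data.frame`: gene, human and mouse lfc, q),
#'   `homology`, and (with a genome pair) `peaksHuman`, `peaksMouse`
#'   (`GRanges`).
#' @export
simulateEpigenome <- function(config, genomePair = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)
  n <- config$locusCount
  pr <- config$classProportions
  rest <- 1 - sum(pr)
  classes <- c(names(pr), "humanOnlyPeak", "mouseOnlyPeak")
  prob <- c(pr, rest / 2, rest / 2)
  cls <- sample(classes, n, replace = TRUE, prob = prob)
  dir <- ifelse(runif(n) < 0.5, 1, -1)
  dir[cls == "conservedActive" | cls %in% c("humanOnlyPeak",
                                            "mouseOnlyPeak")] <- 0

  tauLfc <- log2(config$foldEffect)
  lfcH <- ifelse(cls %in% c("humanOnlyLS", "bothLS", "discordant"),
                 dir * tauLfc, 0)
  lfcM <- ifelse(cls %in% c("mouseOnlyLS", "bothLS"), dir * tauLfc,
                 ifelse(cls == "discordant", -dir * tauLfc, 0))
  lfcH[cls == "mouseOnlyPeak"] <- NA
  lfcM[cls == "humanOnlyPeak"] <- NA

  # correlated baseline log2 signal across species
  mu <- log2(config$nbMean)
  z <- rnorm(n)
  zH <- mu + config$signalSdLog2 * z
  zM <- mu + config$signalSdLog2 *
    (config$rho * z + sqrt(1 - config$rho^2) * rnorm(n))

  reps <- config$replicates
  samples <- data.frame(
    sample = unlist(lapply(names(reps), function(ct)
      sprintf("%s_r%d", ct, seq_len(reps[[ct]])))),
    cellType = rep(names(reps), reps))
  treg <- samples$cellType %in% c("aTreg", "rTreg")

  drawSpecies <- function(base, lfc, present) {
    m <- matrix(0, n, nrow(samples),
                dimnames = list(sprintf("locus_%05d", seq_len(n)),
                                samples$sample))
    for (j in seq_len(nrow(samples))) {
      eff <- ifelse(treg[j] & !is.na(lfc), 2^lfc, 1)
      muV <- 2^base * ifelse(is.na(lfc), 0, eff)
      muV[!present] <- 0
      cnt <- rnbinom(n, mu = pmax(muV, 1e-9),
                     size = 1 / config$nbDispersion)
      cnt[muV == 0] <- 0
      m[, j] <- cnt
    }
    m
  }
  rpmH <- drawSpecies(zH, lfcH, present = cls != "mouseOnlyPeak")
  rpmM <- drawSpecies(zM, lfcM, present = cls != "humanOnlyPeak")

  gene <- sprintf("GENE%05d", seq_len(n))
  exprH <- ifelse(is.na(lfcH), NA,
                  config$exprEffect * lfcH + rnorm(n, 0, config$exprNoiseSd))
  exprM <- ifelse(is.na(lfcM), NA,
                  config$exprEffect * lfcM + rnorm(n, 0, config$exprNoiseSd))
  expression <- data.frame(gene = gene, lfcHuman = exprH, lfcMouse = exprM,
                           q = runif(n))
  homology <- data.frame(human = gene, mouse = tolower(gene))

  out <- list(truth = data.frame(locus = rownames(rpmH), class = cls,
                                 direction = dir, lfcHuman = lfcH,
                                 lfcMouse = lfcM, gene = gene),
              rpmHuman = rpmH, rpmMouse = rpmM, samples = samples,
              expression = expression, homology = homology)

  if (!is.null(genomePair)) {
    w <- config$locusWidth
    tr <- genomePair$truth
    conservedCls <- !cls %in% c("humanOnlyPeak", "mouseOnlyPeak")
    segOk <- tr$strand == "+" & tr$len >= w + 2L
    place <- .placeInSegments(sum(conservedCls), tr$startA[segOk],
                              tr$len[segOk], w, tr$chromA[segOk])
    alignedA <- GRanges(tr$chromA, IRanges(tr$startA + 1L,
                                           tr$startA + tr$len))
    gapsA <- GenomicRanges::setdiff(
      GRanges(names(genomePair$chromSizesA),
              IRanges(1L, genomePair$chromSizesA)),
      alignedA)
    alignedB <- GRanges(tr$chromB, IRanges(tr$startB + 1L,
                                           tr$startB + tr$len))
    gapsB <- GenomicRanges::setdiff(
      GRanges(names(genomePair$chromSizesB),
              IRanges(1L, genomePair$chromSizesB)),
      alignedB)
    hOnly <- .placeInSegments(sum(cls == "humanOnlyPeak"),
                              start(gapsA) - 1L, width(gapsA), w,
                              as.character(seqnames(gapsA)))
    mOnly <- .placeInSegments(sum(cls == "mouseOnlyPeak"),
                              start(gapsB) - 1L, width(gapsB), w,
                              as.character(seqnames(gapsB)))
    coordH <- data.frame(chrom = rep(NA_character_, n), start = NA_real_)
    coordM <- data.frame(chrom = rep(NA_character_, n), start = NA_real_)
    ci <- which(conservedCls)
    if (!is.null(place)) {
      coordH$chrom[ci] <- place$chrom
      coordH$start[ci] <- place$start
      seg <- which(segOk)[place$segment]
      coordM$chrom[ci] <- tr$chromB[seg]
      coordM$start[ci] <- tr$startB[seg] + (place$start - tr$startA[seg])
    }
    hi <- which(cls == "humanOnlyPeak")
    if (!is.null(hOnly)) {
      coordH$chrom[hi] <- hOnly$chrom[seq_along(hi)]
      coordH$start[hi] <- hOnly$start[seq_along(hi)]
    }
    mi <- which(cls == "mouseOnlyPeak")
    if (!is.null(mOnly)) {
      coordM$chrom[mi] <- mOnly$chrom[seq_along(mi)]
      coordM$start[mi] <- mOnly$start[seq_along(mi)]
    }
    okH <- !is.na(coordH$start)
    okM <- !is.na(coordM$start)
    dropped <- (cls != "mouseOnlyPeak" & !okH) |
      (cls != "humanOnlyPeak" & !okM)
    if (any(dropped))
      warning(sum(dropped), " locus/loci could not be placed and were dropped")
    ph <- which(okH)
    pm <- which(okM)
    out$peaksHuman <- GRanges(coordH$chrom[ph],
                              IRanges(coordH$start[ph] + 1L, width = w))
    names(out$peaksHuman) <- rownames(rpmH)[ph]
    out$peaksMouse <- GRanges(coordM$chrom[pm],
                              IRanges(coordM$start[pm] + 1L, width = w))
    names(out$peaksMouse) <- rownames(rpmM)[pm]
    out$placed <- !dropped
  }
  out
}

#' Simulate reads realising a count matrix
#'
#' Draws plus-strand read start positions whose strand-shifted central
#' 100 nt footprints fall entirely inside each peak, so that
#' [quantifyRpm()] recovers the count matrix exactly.
#'
#' @param peaks named `GRanges` (wider than 150 bp).
#' @param counts matrix (peaks x samples) of read counts.
#' @param seed RNG seed.
#' @return width-1 `GRanges` of read starts with a `sample` column.
#' @export
simulateReads <- function(peaks, counts, seed = 1L) {
  set.seed(seed)
  stopifnot(nrow(counts) == length(peaks), all(width(peaks) >= 150L))
  out <- list()
  for (j in seq_len(ncol(counts))) {
    tot <- counts[, j]
    idx <- rep(seq_along(peaks), tot)
    lo <- start(peaks)[idx] - 50L          # footprint start == peak start
    hi <- end(peaks)[idx] - 149L
    st <- lo + floor(runif(length(idx)) * (hi - lo + 1L))
    out[[j]] <- GRanges(seqnames(peaks)[idx], IRanges(st, width = 1L),
                        strand = "+", sample = colnames(counts)[j])
  }
  sort(do.call(c, out))
}

#' Simulate a donor cohort with planted allelic imbalance
#'
#' Draws donor genotypes at common variants inside each element,
#' negative-binomial per-donor read depths, and allelic read counts:
#' heterozygous variants of planted elements emit ChIP reads with
#' alternate-allele probability `aseTheta` while input DNA stays
#' balanced at 0.5; all other depths are balanced binomials. Panel
#' genotype matrices for five reference populations are generated with
#' optional perfect-LD duplicate variants to exercise LD collapsing.
#'
#' @param config a [simulationConfig()].
#' @param elements character vector of element ids.
#' @return list with `truth` (per-element `data.frame`: element, ase,
#'   theta), `variants` (`data.frame`: variant, element, maf, linkedTo),
#'   `calls`, `chipDepths`, `inputDepths` (`data.frame`s as consumed by
#'   [callAllelicImbalance()]), and `panel` (list of dosage matrices).
#' @export
simulateCohort <- function(config, elements) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 2L)
  nEl <- length(elements)
  ase <- runif(nEl) < config$aseFraction
  donors <- sprintf("donor%02d", seq_len(config$donorCount))

  vl <- list(); calls <- list(); chip <- list(); input <- list()
  panel <- lapply(config$populations, function(p) NULL)
  names(panel) <- config$populations
  panelRows <- list()

  for (e in seq_len(nEl)) {
    k <- sample.int(config$variantsPerElementMax, 1L)
    linked <- k > 1L && runif(1) < config$ldLinkedFraction
    maf <- runif(1L, config$cohortMafRange[1L], config$cohortMafRange[2L])
    gBase <- rbinom(config$donorCount, 2L, maf)
    panelBase <- lapply(config$populations, function(p)
      rbinom(config$panelSize, 2L, maf))
    for (v in seq_len(k)) {
      vid <- sprintf("%s_v%d", elements[e], v)
      isLinked <- linked && v > 1L
      if (isLinked) {
        g <- gBase
        pg <- panelBase
      } else if (v == 1L) {
        g <- gBase
        pg <- panelBase
      } else {
        maf2 <- runif(1L, config$cohortMafRange[1L],
                      config$cohortMafRange[2L])
        g <- rbinom(config$donorCount, 2L, maf2)
        pg <- lapply(config$populations, function(p)
          rbinom(config$panelSize, 2L, maf2))
      }
      vl[[length(vl) + 1L]] <- data.frame(
        variant = vid, element = elements[e], maf = maf,
        linkedTo = if (isLinked) sprintf("%s_v1", elements[e])
                   else NA_character_)
      panelRows[[vid]] <- pg
      geno <- c("hom_ref", "het", "hom_alt")[g + 1L]
      calls[[length(calls) + 1L]] <- data.frame(
        donor = donors, variant = vid, genotype = geno, passQC = TRUE)
      hetD <- donors[g == 1L]
      if (length(hetD)) {
        depthC <- rnbinom(length(hetD), mu = config$aseDepthMean,
                          size = config$aseDepthSize) + 1L
        depthI <- rnbinom(length(hetD), mu = config$aseDepthMean,
                          size = config$aseDepthSize) + 1L
        th <- if (ase[e]) config$aseTheta else 0.5
        altC <- rbinom(length(hetD), depthC, th)
        altI <- rbinom(length(hetD), depthI, 0.5)
        chip[[length(chip) + 1L]] <- data.frame(
          donor = hetD, variant = vid, element = elements[e],
          ref = depthC - altC, alt = altC)
        input[[length(input) + 1L]] <- data.frame(
          donor = hetD, variant = vid, element = elements[e],
          ref = depthI - altI, alt = altI)
      }
    }
  }
  variants <- do.call(rbind, vl)
  panel <- lapply(seq_along(config$populations), function(ip) {
    m <- do.call(rbind, lapply(panelRows, function(pg) pg[[ip]]))
    rownames(m) <- names(panelRows)
    m
  })
  names(panel) <- config$populations
  list(truth = data.frame(element = elements, ase = ase,
                          theta = ifelse(ase, config$aseTheta, 0.5)),
       variants = variants,
       calls = do.call(rbind, calls),
       chipDepths = do.call(rbind, chip),
       inputDepths = do.call(rbind, input),
       panel = panel)
}

#' Simulate per-DHS polymorphism summaries with optional constraint
#'
#' Emulates the window census over DNase hypersensitive sites: each DHS
#' window contains a Poisson number of SNPs with a skewed MAF spectrum;
#' in conserved DHSs, high-MAF SNPs (MAF >= `suppressAbove`) are thinned
#' by the suppression fraction, planting the constraint gradient that
#' steepens the conserved group's count-exceeding-bin curve.
#'
#' @param nDhs number of DHSs.
#' @param conservedFraction fraction labelled genetically conserved.
#' @param suppression fraction of high-MAF SNPs removed from conserved
#'   DHS windows (0 = no planted effect).
#' @param suppressAbove MAF above which a variant counts as high-MAF
#'   for the planted suppression (default 0.25, the upper bins).
#' @param snpRate mean SNPs per window.
#' @param seed RNG seed.
#' @return `data.frame` with columns `conserved`, `nSnps`, `maxMaf`.
#' @export
simulateDhsVariation <- function(nDhs, conservedFraction = 0.5,
                                 suppression = 0, suppressAbove = 0.25,
                                 snpRate = 3, seed = 1L) {
  set.seed(seed)
  conserved <- runif(nDhs) < conservedFraction
  m <- stats::rpois(nDhs, snpRate)
  idx <- rep.int(seq_len(nDhs), m)
  maf <- 0.5 * rbeta(length(idx), 0.3, 1.2)
  drop <- conserved[idx] & maf >= suppressAbove &
    runif(length(idx)) < suppression
  keep <- !drop
  maxMaf <- rep(0, nDhs)
  if (any(keep)) {
    agg <- tapply(maf[keep], idx[keep], max)
    maxMaf[as.integer(names(agg))] <- agg
  }
  nSnps <- tabulate(idx[keep], nbins = nDhs)
  data.frame(conserved = conserved, nSnps = nSnps, maxMaf = maxMaf)
}

#' @importFrom stats rbeta
NULL

#' Simulate a GWAS catalog with planted trait enrichment
#'
#' Places background variants uniformly over the genome; variants of
#' disease sets with fold enrichment `f > 1` land inside the target
#' regions with probability `min(1, f * L / G)` (`L` = total region
#' length, `G` = genome length). Traits are grouped into studies whose
#' sizes straddle the >5-SNP study filter.
#'
#' @param config a [simulationConfig()].
#' @param regions target regions (`GRanges`).
#' @param chromSizes named contig lengths.
#' @return catalog `data.frame`: `variant`, `chrom`, `pos`, `trait`,
#'   `study`, `diseaseSet`.
#' @export
simulateGwasCatalog <- function(config, regions, chromSizes) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 3L)
  sets <- names(config$gwasEnrichment)
  G <- sum(chromSizes)
  L <- sum(width(regions))
  nTot <- config$catalogSize
  setOf <- sample(sets, nTot, replace = TRUE)
  pos <- integer(nTot); chrom <- character(nTot)
  csCum <- cumsum(chromSizes)
  regW <- width(regions)
  for (i in seq_len(nTot)) {
    f <- config$gwasEnrichment[[setOf[i]]]
    pIn <- min(1, f * L / G)
    if (runif(1) < pIn && length(regions) > 0L) {
      r <- sample.int(length(regions), 1L, prob = regW)
      chrom[i] <- as.character(seqnames(regions))[r]
      pos[i] <- start(regions)[r] + floor(runif(1) * regW[r])
    } else {
      g <- floor(runif(1) * G)
      ci <- findInterval(g, c(0, csCum), rightmost.closed = TRUE)
      chrom[i] <- names(chromSizes)[ci]
      pos[i] <- g - c(0, csCum)[ci] + 1L
    }
  }
  # studies per disease set: one undersized study (exactly 5 variants)
  # plus adequately sized ones, exercising the >5-SNP filter
  study <- character(nTot)
  for (s in sets) {
    idx <- which(setOf == s)
    nSmall <- min(5L, length(idx))
    study[idx[seq_len(nSmall)]] <- paste0(s, "_small")
    if (length(idx) > nSmall)
      study[idx[(nSmall + 1L):length(idx)]] <-
        paste0(s, "_study", 1L + (seq_len(length(idx) - nSmall) %% 2L))
  }
  data.frame(variant = sprintf("rs%06d", seq_len(nTot)), chrom = chrom,
             pos = pos, trait = paste0(setOf, "_trait"), study = study,
             diseaseSet = setOf)
}
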