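#' Random-choice read deduplication
#'
#' Removes potentially monoclonal reads by keeping exactly one read,
#' chosen uniformly at random, per (chromosome, start, strand) key.
#' Unlike score-based deduplication this avoids reference-alignment
#' bias. Deterministic for a fixed seed.
#'
#' @param reads width-1 `GRanges` of read starts.
#' @param seed RNG seed.
#' @return the retained subset of `reads`.
#' @export
dedupRandom <- function(reads, seed = 1L) {
  set.seed(seed)
  key <- paste(as.character(seqnames(reads)), start(reads),
               as.character(strand(reads)), sep = ":")
  perm <- sample(length(reads))
  keepPerm <- !duplicated(key[perm])
  sort(reads[perm[keepPerm]])
}

#' Exact two-tailed binomial test for allelic imbalance
#'
#' Exact binomial p-value against a 0.5 allelic ratio, using the
#' minimum-likelihood convention: the p-value is the total probability
#' of outcomes no more likely than the observed one. At success
#' probability 0.5 this coincides with doubling the smaller tail.
#'
#' @param refN,altN reference/alternate read counts (vectors;
#'   `refN + altN` must be positive).
#' @return vector of two-tailed p-values.
#' @export
binomTwoTailed <- function(refN, altN) {
  stopifnot(length(refN) == length(altN))
  n <- refN + altN
  if (any(n <= 0)) stop("zero total depth")
  vapply(seq_along(n), function(i) {
    d <- dbinom(0:n[i], n[i], 0.5)
    sum(d[d <= d[altN[i] + 1L] * (1 + 1e-7)])
  }, numeric(1))
}

#' Filter heterozygous SNPs for the allele-specific analysis
#'
#' Applies, conjunctively, the reliability rules for testable SNPs:
#' calls must pass QC; the SNP must be heterozygous in at least 2
#' donors; homozygous in at least 2 donors; and must not show allelic
#' imbalance in input (non-ChIPed) DNA at nominal p < 0.05 (exact
#' two-tailed binomial on the pooled het-donor input depths). SNPs
#' without an input record are dropped with a warning.
#'
#' @param calls `data.frame` with columns `donor`, `variant`,
#'   `genotype` (`"hom_ref"`, `"het"`, `"hom_alt"`), `passQC`.
#' @param inputDepths `data.frame` with columns `donor`, `variant`,
#'   `ref`, `alt` for input DNA.
#' @return `data.frame` per variant: `variant`, `nHet`, `nHom`,
#'   `inputP`, `retained`.
#' @export
filterHetSnps <- function(calls, inputDepths) {
  calls <- calls[calls$passQC, , drop = FALSE]
  variants <- unique(calls$variant)
  rows <- lapply(variants, function(v) {
    cv <- calls[calls$variant == v, , drop = FALSE]
    nHet <- sum(cv$genotype == "het")
    nHom <- sum(cv$genotype %in% c("hom_ref", "hom_alt"))
    hetDonors <- cv$donor[cv$genotype == "het"]
    inp <- inputDepths[inputDepths$variant == v &
                         inputDepths$donor %in% hetDonors, , drop = FALSE]
    if (nHet > 0L && nrow(inp) == 0L) {
      warning("variant ", v, ": no input record, dropped")
      return(data.frame(variant = v, nHet = nHet, nHom = nHom,
                        inputP = NA_real_, retained = FALSE))
    }
    inputP <- if (nrow(inp) == 0L) NA_real_ else
      binomTwoTailed(sum(inp$ref), sum(inp$alt))
    retained <- nHet >= 2L && nHom >= 2L &&
      (!is.na(inputP) && inputP >= 0.05)
    data.frame(variant = v, nHet = nHet, nHom = nHom, inputP = inputP,
               retained = retained)
  })
  do.call(rbind, rows)
}

#' Drop uninformative heterozygous polymorphisms
#'
#' SNPs whose two-tailed binomial p exceeds the cutoff provide little
#' evidence for allele-specific enhancer usage and are removed before
#' aggregation. The boundary is inclusive: `p == cutoff` is retained.
#'
#' @param pvals binomial p-values.
#' @param cutoff retention threshold (default 0.2).
#' @return logical vector, `TRUE` for retained SNPs.
#' @export
prefilterSnps <- function(pvals, cutoff = 0.2) {
  pvals <= cutoff
}

#' Collapse variants in tight linkage disequilibrium
#'
#' Within an element, variants whose genotype correlation satisfies
#' `r^2 > r2` in every reference population are treated as one signal
#' and collapsed to the highest-depth representative. Variants absent
#' from the panel are treated as independent, with a warning.
#'
#' @param variants character vector of variant ids (one element's
#'   variants).
#' @param depth named total read depth per variant (representative
#'   choice).
#' @param panel named list (one entry per population) of genotype
#'   dosage matrices, variants x individuals, rownames = variant ids.
#' @param r2 linkage threshold (default 0.99).
#' @return character vector of representative variant ids.
#' @export
ldCollapse <- function(variants, depth, panel, r2 = 0.99) {
  k <- length(variants)
  if (k <= 1L) return(variants)
  absent <- variants[!vapply(variants, function(v)
    all(vapply(panel, function(m) v %in% rownames(m), logical(1))),
    logical(1))]
  if (length(absent))
    warning("variants absent from panel treated as independent: ",
            paste(absent, collapse = ", "))
  linked <- matrix(FALSE, k, k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      vi <- variants[i]; vj <- variants[j]
      if (vi %in% absent || vj %in% absent) next
      ok <- all(vapply(panel, function(m) {
        r <- suppressWarnings(cor(m[vi, ], m[vj, ]))
        !is.na(r) && r^2 > r2
      }, logical(1)))
      linked[i, j] <- linked[j, i] <- ok
    }
  }
  # connected components by label propagation (k is small)
  comp <- seq_len(k)
  repeat {
    new <- comp
    for (i in seq_len(k))
      new[i] <- min(comp[linked[i, ] | seq_len(k) == i])
    if (identical(new, comp)) break
    comp <- new
  }
  unname(vapply(split(seq_len(k), comp), function(idx)
    variants[idx][which.max(depth[variants[idx]])], character(1)))
}

#' Aggregate SNP-level imbalance evidence for one element
#'
#' Combines the p-values of an element's contributing variants with
#' Fisher's statistic `-2 * sum(log p)` (valid under allelic read-depth
#' independence) and calibrates it against an empirical null built by
#' aggregating the same number of uniform p-value draws under identical
#' assumptions. When the contributing p-values were pre-selected below
#' a cutoff, pass it as `nullMax` so the null draws share the
#' selection; with `nullMax = 1` the empirical p converges to the
#' chi-square tail with `2k` degrees of freedom.
#'
#' @param pvals contributing p-values (>= 1).
#' @param nNull number of null aggregations (default 10000).
#' @param seed RNG seed.
#' @param nullMax upper bound of the uniform null draws (default 1).
#' @return list with `statistic`, `k`, `p` (empirical, add-one
#'   convention, in `(0, 1]`).
#' @export
aggregateElement <- function(pvals, nNull = 10000L, seed = 1L,
                             nullMax = 1) {
  stopifnot(length(pvals) >= 1L, nNull >= 10L)
  set.seed(seed)
  if (any(pvals == 0)) {
    warning("p-value of 0 clamped to smallest positive double")
    pvals[pvals == 0] <- .Machine$double.xmin
  }
  k <- length(pvals)
  obs <- -2 * sum(log(pvals))
  nullStat <- rowSums(matrix(-2 * log(runif(nNull * k, 0, nullMax)),
                             nNull, k))
  list(statistic = obs, k = k,
       p = (1 + sum(nullStat >= obs)) / (nNull + 1))
}

# shared-null aggregation for many elements grouped by k
.aggregateElements <- function(pvalList, nNull, seed, nullMax) {
  set.seed(seed)
  ks <- lengths(pvalList)
  stats <- vapply(pvalList, function(p)
    -2 * sum(log(pmax(p, .Machine$double.xmin))), numeric(1))
  p <- numeric(length(pvalList))
  for (k in sort(unique(ks))) {
    nullStat <- rowSums(matrix(-2 * log(runif(nNull * k, 0, nullMax)),
                               nNull, k))
    idx <- which(ks == k)
    ecount <- vapply(stats[idx], function(s) sum(nullStat >= s), numeric(1))
    p[idx] <- (1 + ecount) / (nNull + 1)
  }
  data.frame(element = names(pvalList), k = ks, statistic = stats, p = p,
             row.names = NULL)
}

#' QQ summary of element-level p-values
#'
#' Observed p-values (sorted) against uniform order-statistic
#' expectations, both on the -log10 scale, with observed values capped
#' (default at 5) for display.
#'
#' @param pvals element-level empirical p-values.
#' @param cap cap on observed -log10 p (default 5).
#' @return `data.frame` with columns `expected`, `observed` (capped),
#'   most significant first.
#' @export
qqSummary <- function(pvals, cap = 5) {
  n <- length(pvals)
  if (n == 0L) return(data.frame(expected = numeric(), observed = numeric()))
  obs <- -log10(sort(pvals))
  expd <- -log10(seq_len(n) / (n + 1))
  data.frame(expected = expd, observed = pmin(obs, cap))
}

#' Zygosity-normalized read-count values
#'
#' Makes per-individual allele-resolved read counts comparable across
#' zygosity: individuals with at most `minReads` reads at the variant
#' are excluded, heterozygous per-allele RPMs are doubled (a het allele
#' is sampled at half the depth of a homozygote's), and all values are
#' divided by the dataset mean.
#'
#' @param rpm per-observation RPM values (one per homozygote, one per
#'   het allele).
#' @param genotype `"hom"` or `"het"` per observation.
#' @param nReads supporting read count per observation.
#' @param minReads exclusion threshold: observations need more than
#'   this many reads (default 5).
#' @return `data.frame` with columns `value` (normalized) and `kept`.
#' @export
zygosityNormalize <- function(rpm, genotype, nReads, minReads = 5L) {
  stopifnot(length(rpm) == length(genotype), length(rpm) == length(nReads))
  kept <- nReads > minReads
  if (!any(kept)) stop("all individuals excluded by the read threshold")
  v <- ifelse(genotype == "het", 2 * rpm, rpm)
  v[!kept] <- NA_real_
  v <- v / mean(v[kept])
  data.frame(value = v, kept = kept)
}

#' Combine heterozygous and homozygous allele-specificity evidence
#'
#' Heterozygous (within-individual imbalance) and homozygous
#' (between-individual t-test) observations are independent, so the
#' product of their p-values estimates the joint significance of allele
#' specificity. With one side missing, the available side is returned
#' and flagged.
#'
#' @param pHet p-value from the heterozygous imbalance test (or NA).
#' @param pHom p-value from the homozygous two-sample t-test (or NA).
#' @return list with `p`, `sides` (`"both"`, `"het"`, `"hom"`).
#' @export
combinedZygosityTest <- function(pHet, pHom) {
  hetOk <- !is.na(pHet)
  homOk <- !is.na(pHom)
  if (!hetOk && !homOk) stop("both sides missing")
  if (hetOk && homOk) return(list(p = pHet * pHom, sides = "both"))
  list(p = if (hetOk) pHet else pHom, sides = if (hetOk) "het" else "hom")
}

#' Genotype regression over the extended {0, 1, 2, 3} domain
#'
#' Ordinary least squares of zygosity-normalized values on genotype
#' codes where 0 and 3 are the two homozygote classes and heterozygous
#' individuals contribute their two allelic values at codes 1 and 2.
#'
#' @param values normalized values.
#' @param codes regressor codes in `{0, 1, 2, 3}`.
#' @return list with `slope`, `intercept`, `se`, `t`, `p`, `n`.
#' @export
genotypeRegression <- function(values, codes) {
  stopifnot(length(values) == length(codes), length(values) >= 3L)
  if (length(unique(codes)) < 2L) stop("rank-deficient design")
  fit <- lm(values ~ codes)
  s <- summary(fit)$coefficients
  list(slope = unname(s["codes", "Estimate"]),
       intercept = unname(s["(Intercept)", "Estimate"]),
       se = unname(s["codes", "Std. Error"]),
       t = unname(s["codes", "t value"]),
       p = unname(s["codes", "Pr(>|t|)"]),
       n = length(values))
}

#' Compare genotype-regression slopes between two groups
#'
#' Fits each group's regression with its own (fixed, i.e. estimated)
#' intercept and tests the slope difference with a two-tailed t-test on
#' `n1 + n2 - 4` degrees of freedom, using the pooled residual
#' variance.
#'
#' @param valuesA,codesA observations for group A.
#' @param valuesB,codesB observations for group B.
#' @return list with `slopeA`, `slopeB`, `t`, `df`, `p`.
#' @export
slopeComparison <- function(valuesA, codesA, valuesB, codesB) {
  fitPart <- function(v, cd) {
    stopifnot(length(v) >= 3L, length(unique(cd)) >= 2L)
    fit <- lm(v ~ cd)
    list(slope = unname(coef(fit)[2L]),
         rss = sum(stats::residuals(fit)^2),
         sxx = sum((cd - mean(cd))^2), n = length(v))
  }
  a <- fitPart(valuesA, codesA)
  b <- fitPart(valuesB, codesB)
  df <- a$n + b$n - 4L
  sp2 <- (a$rss + b$rss) / df
  tstat <- (a$slope - b$slope) / sqrt(sp2 * (1 / a$sxx + 1 / b$sxx))
  list(slopeA = a$slope, slopeB = b$slope, t = tstat, df = df,
       p = 2 * pt(abs(tstat), df, lower.tail = FALSE))
}

#' Allele-specific acetylation calling across elements
#'
#' Full element-level pipeline: SNP reliability filtering
#' ([filterHetSnps()]), exact binomial imbalance per variant on pooled
#' het-donor ChIP depths ([binomTwoTailed()]), removal of uninformative
#' SNPs ([prefilterSnps()]), optional LD collapsing within elements
#' ([ldCollapse()]), and Fisher aggregation against an empirical null
#' whose uniform draws share the prefilter selection
#' ([aggregateElement()]).
#'
#' @param depths ChIP allelic depths: `data.frame` with columns
#'   `donor`, `variant`, `element`, `ref`, `alt`.
#' @param calls genotype calls (see [filterHetSnps()]).
#' @param inputDepths input-DNA allelic depths (same columns as
#'   `depths`, `element` optional).
#' @param panel LD reference panel for [ldCollapse()], or `NULL` to
#'   skip collapsing.
#' @param cutoff SNP prefilter cutoff (default 0.2).
#' @param nNull empirical-null size (default 10000).
#' @param seed RNG seed.
#' @return `data.frame` per testable element: `element`, `k`,
#'   `statistic`, `p`.
#' @export
callAllelicImbalance <- function(depths, calls, inputDepths, panel = NULL,
                                 cutoff = 0.2, nNull = 10000L, seed = 1L) {
  snpStat <- filterHetSnps(calls, inputDepths)
  keepVar <- snpStat$variant[snpStat$retained]
  hetKey <- paste(calls$donor, calls$variant)[calls$genotype == "het" &
                                                calls$passQC]
  d <- depths[depths$variant %in% keepVar &
                paste(depths$donor, depths$variant) %in% hetKey, ,
              drop = FALSE]
  if (nrow(d) == 0L)
    return(data.frame(element = character(), k = integer(),
                      statistic = numeric(), p = numeric()))
  agg <- stats::aggregate(cbind(ref, alt) ~ variant + element, d, sum)
  agg$p <- binomTwoTailed(agg$ref, agg$alt)
  agg <- agg[prefilterSnps(agg$p, cutoff), , drop = FALSE]
  if (nrow(agg) == 0L)
    return(data.frame(element = character(), k = integer(),
                      statistic = numeric(), p = numeric()))
  depth <- setNames(agg$ref + agg$alt, agg$variant)
  pvalList <- lapply(split(agg, agg$element), function(e) {
    vars <- e$variant
    if (!is.null(panel) && length(vars) > 1L)
      vars <- ldCollapse(vars, depth, panel)
    setNames(e$p[match(vars, e$variant)], vars)
  })
  .aggregateElements(pvalList, nNull = nNull, seed = seed,
                     nullMax = cutoff)
}
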