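#' Genome-wide epigenetic conservation correlation
#'
#' Pearson correlation of log-scaled signal (log2(RPM + 0.5)) between the
#' two species, computed over genetically conserved loci only:
#' non-conserved loci cannot, by definition, be epigenetically conserved
#' and are excluded.
#'
#' @param humanRpm,mouseRpm per-locus RPM vectors for one cell type in
#'   each species (replicate means).
#' @param conserved logical vector marking genetically conserved loci
#'   (`NULL` = all loci are conserved).
#' @return Pearson `r` on the conserved loci.
#' @export
epigeneticCorrelation <- function(humanRpm, mouseRpm, conserved = NULL) {
  stopifnot(length(humanRpm) == length(mouseRpm))
  if (is.null(conserved)) conserved <- rep(TRUE, length(humanRpm))
  h <- humanRpm[conserved]
  m <- mouseRpm[conserved]
  if (length(h) < 3L)
    stop("need at least 3 genetically conserved loci")
  cor(log2(h + 0.5), log2(m + 0.5))
}

#' Fraction of genetically conserved loci per stratum
#'
#' Stratifies loci (e.g. by RPM quantile bin or TSS-distance bin) and
#' reports the fraction of genetically conserved loci per stratum.
#' Empty strata are absent from the result rather than reported as zero.
#'
#' @param conserved logical vector (genetic conservation per locus).
#' @param stratum factor of the same length.
#' @return `data.frame` with columns `stratum`, `n`, `fraction`.
#' @export
conservedFractionByStratum <- function(conserved, stratum) {
  stopifnot(length(conserved) == length(stratum))
  stratum <- factor(stratum)
  n <- tapply(conserved, stratum, length)
  frac <- tapply(conserved, stratum, mean)
  keep <- !is.na(n)
  data.frame(stratum = names(n)[keep], n = as.integer(n[keep]),
             fraction = as.numeric(frac[keep]), row.names = NULL)
}

#' Quantile strata for signal values
#'
#' Convenience binning of a continuous covariate (RPM, TSS distance)
#' into quantile strata for [conservedFractionByStratum()].
#'
#' @param x numeric vector.
#' @param n number of quantile bins.
#' @return factor of bin labels, ordered low to high.
#' @export
quantileStrata <- function(x, n = 5L) {
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n + 1L),
                        na.rm = TRUE))
  cut(x, breaks = br, include.lowest = TRUE)
}
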