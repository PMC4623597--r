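#' Write donor genotypes and allelic depths as VCF
#'
#' Emits a minimal VCF 4.2 file with one sample column per donor and
#' `GT:AD` fields, the format the allele-specific module consumes.
#'
#' @param calls genotype calls (`data.frame` with `donor`, `variant`,
#'   `genotype`, `passQC`), as produced by [simulateCohort()].
#' @param depths allelic depths (`data.frame` with `donor`, `variant`,
#'   `ref`, `alt`); donors without a depth record get `AD=.,.`.
#' @param variants `data.frame` with `variant`, `chrom`, `pos` (1-based);
#'   defaults to placing variants consecutively on contig `"chrS"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGenotypeVcf <- function(calls, depths, path, variants = NULL) {
  donors <- sort(unique(calls$donor))
  vids <- unique(calls$variant)
  if (is.null(variants))
    variants <- data.frame(variant = vids, chrom = "chrS",
                           pos = seq_along(vids) * 1000L)
  gtOf <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                      "Description=\"Allelic depths\">"),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", donors),
                     collapse = "\t")), con)
  callKey <- paste(calls$donor, calls$variant)
  depthKey <- paste(depths$donor, depths$variant)
  for (v in vids) {
    vi <- match(v, variants$variant)
    cells <- vapply(donors, function(d) {
      ci <- match(paste(d, v), callKey)
      if (is.na(ci)) return("./.")
      di <- match(paste(d, v), depthKey)
      ad <- if (is.na(di)) ".,." else
        paste0(depths$ref[di], ",", depths$alt[di])
      paste0(gtOf[[calls$genotype[ci]]], ":", ad)
    }, character(1))
    writeLines(paste(c(variants$chrom[vi], variants$pos[vi], v, "A", "G",
                       ".", "PASS", ".", "GT:AD", cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read donor genotypes and allelic depths from a VCF
#'
#' Extracts `GT` and `AD` fields into the tables the allele-specific
#' module consumes. Parsing is delegated to `VariantAnnotation`.
#'
#' @param path VCF path.
#' @return list with `calls` (`donor`, `variant`, `genotype`, `passQC`)
#'   and `depths` (`donor`, `variant`, `ref`, `alt`; het/hom rows with
#'   recorded depths only).
#' @export
readGenotypeVcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("readGenotypeVcf requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  gt <- VariantAnnotation::geno(vcf)$GT
  ad <- VariantAnnotation::geno(vcf)$AD
  donors <- colnames(gt)
  vids <- rownames(gt)
  genoOf <- c("0/0" = "hom_ref", "0|0" = "hom_ref",
              "0/1" = "het", "0|1" = "het", "1|0" = "het",
              "1/1" = "hom_alt", "1|1" = "hom_alt")
  pass <- VariantAnnotation::filt(vcf) %in% c("PASS", ".")
  calls <- NULL; depths <- NULL
  for (j in seq_along(donors)) {
    g <- genoOf[gt[, j]]
    keep <- !is.na(g)
    calls <- rbind(calls, data.frame(
      donor = donors[j], variant = vids[keep], genotype = unname(g[keep]),
      passQC = pass[keep]))
    for (i in which(keep)) {
      a <- ad[[i, j]]
      if (length(a) == 2L && !anyNA(a))
        depths <- rbind(depths, data.frame(
          donor = donors[j], variant = vids[i], ref = a[1L], alt = a[2L]))
    }
  }
  list(calls = calls, depths = depths)
}
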