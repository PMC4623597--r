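library(GenomicRanges)

test_that("random deduplication keeps one read per position key, reproducibly", {
  r <- GRanges("c1", IRanges(c(rep(100, 5), 200, 300), width = 1),
               strand = c(rep("+", 5), "+", "-"),
               readId = 1:7)
  d1 <- dedupRandom(r, seed = 4)
  expect_equal(length(d1), 3L)
  expect_equal(sort(start(d1)), c(100, 200, 300))
  # all-unique input passes through
  u <- GRanges("c1", IRanges(1:5, width = 1), strand = "+")
  expect_equal(length(dedupRandom(u, seed = 1)), 5L)
  # same seed, same selection; the choice is among the duplicates
  d2 <- dedupRandom(r, seed = 4)
  expect_identical(d1$readId, d2$readId)
  expect_true(d1$readId[start(d1) == 100] %in% 1:5)
})

test_that("two-tailed binomial p-values follow the minimum-likelihood convention", {
  expect_equal(binomTwoTailed(5, 5), 1)
  expect_equal(binomTwoTailed(10, 0), 2 / 1024)
  expect_equal(binomTwoTailed(8, 2), 112 / 1024)
  expect_error(binomTwoTailed(0, 0), "zero total")
  # cross-check against the standard exact test over a grid
  for (n in c(7, 12, 20, 33)) {
    for (k in c(0, 1, n %/% 3, n %/% 2, n)) {
      expect_equal(binomTwoTailed(n - k, k),
                   stats::binom.test(k, n, 0.5)$p.value,
                   tolerance = 1e-12)
    }
  }
})

test_that("exact-test conservatism bounds the null rejection rate at depth 20", {
  set.seed(55)
  alt <- rbinom(10000, 20, 0.5)
  p <- binomTwoTailed(20 - alt, alt)
  rate <- mean(p < 0.05)
  expect_lte(rate, 0.05)
  expect_gte(rate, 0.02)
})

test_that("SNP prefilter keeps the 0.2 boundary inclusively", {
  expect_equal(prefilterSnps(c(0.21, 0.2, 0.05)), c(FALSE, TRUE, TRUE))
  expect_length(prefilterSnps(numeric()), 0L)
})

test_that("heterozygous-SNP filtering applies all four rules conjunctively", {
  mkCalls <- function(genos, v = "v1")
    data.frame(donor = sprintf("d%d", seq_along(genos)), variant = v,
               genotype = genos, passQC = TRUE)
  balInput <- function(v = "v1", donors = c("d1", "d2", "d3"))
    data.frame(donor = donors, variant = v, ref = 10, alt = 10)

  # het in a single donor is dropped
  r <- filterHetSnps(mkCalls(c("het", "hom_ref", "hom_ref", "hom_alt")),
                     balInput())
  expect_false(r$retained)
  # input imbalance (20, 5) gives p < 0.05 and drops the SNP
  r2 <- filterHetSnps(mkCalls(c("het", "het", "hom_ref", "hom_alt")),
                      data.frame(donor = c("d1", "d2"), variant = "v1",
                                 ref = c(10, 10), alt = c(3, 2)))
  expect_equal(r2$inputP, binomTwoTailed(20, 5))
  expect_lt(r2$inputP, 0.05)
  expect_false(r2$retained)
  # het in 3, hom in 2, balanced input, QC pass: retained
  r3 <- filterHetSnps(mkCalls(c("het", "het", "het", "hom_ref", "hom_alt")),
                      balInput())
  expect_true(r3$retained)
  # failed-QC calls do not count
  calls <- mkCalls(c("het", "het", "het", "hom_ref", "hom_alt"))
  calls$passQC[1] <- FALSE
  r4 <- filterHetSnps(calls, balInput())
  expect_equal(r4$nHet, 2L)
  # het SNP with no input record is dropped with a warning
  expect_warning(
    r5 <- filterHetSnps(mkCalls(c("het", "het", "hom_ref", "hom_alt")),
                        balInput(v = "other")),
    "no input record")
  expect_false(r5$retained)
})

test_that("LD collapsing matches hand-computed r2 on a toy haploid panel", {
  # toy 4-haplotype panel: r2 = D^2 / (p1 q1 p2 q2)
  panelOf <- function(v1, v2) {
    m <- rbind(v1 = v1, v2 = v2)
    list(afr = m, eur = m, ceu = m, chb = m, jpt = m)
  }
  depth <- c(v1 = 50, v2 = 30)
  # perfectly co-inherited: r2 = 1 -> collapse to highest depth
  expect_equal(ldCollapse(c("v1", "v2"), depth,
                          panelOf(c(1, 1, 0, 0), c(1, 1, 0, 0))), "v1")
  # D = 0: both retained
  expect_setequal(ldCollapse(c("v1", "v2"), depth,
                             panelOf(c(1, 1, 0, 0), c(1, 0, 1, 0))),
                  c("v1", "v2"))
  # r2 = 1/3 by hand (p11 = 1/4, p1 = 1/2, p2 = 1/4):
  # D = 1/8, D^2/(p1 q1 p2 q2) = (1/64)/(3/64) = 1/3 -> not collapsed
  v2 <- c(1, 0, 0, 0)
  expect_equal(suppressWarnings(cor(c(1, 1, 0, 0), v2))^2, 1 / 3,
               tolerance = 1e-12)
  expect_setequal(ldCollapse(c("v1", "v2"), depth,
                             panelOf(c(1, 1, 0, 0), v2)),
                  c("v1", "v2"))
  # linkage must hold in every population
  mixed <- panelOf(c(1, 1, 0, 0), c(1, 1, 0, 0))
  mixed$jpt <- rbind(v1 = c(1, 1, 0, 0), v2 = c(1, 0, 1, 0))
  expect_setequal(ldCollapse(c("v1", "v2"), depth, mixed),
                  c("v1", "v2"))
  # absent-from-panel variants are independent, with a warning
  expect_warning(
    keep <- ldCollapse(c("v1", "vX"), c(v1 = 5, vX = 9),
                       panelOf(c(1, 0, 1, 0), c(0, 1, 0, 1))),
    "absent from panel")
  expect_setequal(keep, c("v1", "vX"))
})

test_that("Fisher aggregation reproduces the statistic and chi-square limit", {
  a <- aggregateElement(c(0.01, 0.04), nNull = 1000, seed = 1)
  expect_equal(a$statistic, -2 * (log(0.01) + log(0.04)), tolerance = 1e-12)
  expect_equal(a$statistic, 15.648, tolerance = 1e-3)
  # identity aggregation: empirical p approaches the single p-value
  a1 <- aggregateElement(0.05, nNull = 1e5, seed = 2)
  expect_equal(a1$p, 0.05, tolerance = 0.02)
  # chi-square(2k) tail in the large-null limit
  for (k in c(1, 2, 5)) {
    set.seed(k)
    pv <- runif(k, 0.01, 0.6)
    ag <- aggregateElement(pv, nNull = 1e5, seed = 10 + k)
    expect_equal(ag$p, pchisq(ag$statistic, df = 2 * k,
                              lower.tail = FALSE),
                 tolerance = 0.01)
  }
  # zero p-values are clamped with a warning
  expect_warning(aggregateElement(c(0, 0.1), nNull = 100, seed = 1),
                 "clamped")
})

test_that("QQ summary caps observed values and exposes planted divergence", {
  # perfectly uniform grid sits on the diagonal
  n <- 99
  grid <- (1:n) / (n + 1)
  qq <- qqSummary(grid)
  expect_equal(qq$observed, qq$expected, tolerance = 1e-12)
  # extreme p-values are capped at 5
  expect_equal(max(qqSummary(c(1e-9, 0.5))$observed), 5)
  # planted signal diverges above the diagonal in the tail
  set.seed(12)
  ps <- c(runif(950), rbeta(50, 0.05, 1))
  qq2 <- qqSummary(ps)
  expect_gt(qq2$observed[1] - qq2$expected[1], 0.5)
})

test_that("zygosity normalization doubles het values and mean-normalizes", {
  r <- zygosityNormalize(c(2, 3, 3), c("het", "hom", "hom"),
                         nReads = c(10, 10, 10))
  # het 2.0 doubles to 4.0 before mean division (mean of 4,3,3 = 10/3)
  expect_equal(r$value, c(4, 3, 3) / (10 / 3))
  # homozygous cohort with equal values normalizes to 1
  r2 <- zygosityNormalize(rep(7, 4), rep("hom", 4), rep(20, 4))
  expect_equal(r2$value, rep(1, 4))
  # an individual with exactly 5 reads is excluded (needs more than 5)
  r3 <- zygosityNormalize(c(2, 3), c("hom", "hom"), nReads = c(5, 10))
  expect_false(r3$kept[1])
  expect_true(is.na(r3$value[1]))
  expect_error(zygosityNormalize(1, "hom", 2), "excluded")
})

test_that("zygosity product test combines independent sides", {
  expect_equal(combinedZygosityTest(0.01, 0.1)$p, 0.001)
  expect_equal(combinedZygosityTest(1, 1)$p, 1)
  oneSide <- combinedZygosityTest(NA, 0.02)
  expect_equal(oneSide$p, 0.02)
  expect_equal(oneSide$sides, "hom")
  expect_error(combinedZygosityTest(NA, NA), "both sides")
  # a concordant effect in het and hom beats each component
  set.seed(20)
  wins <- mean(replicate(300, {
    pHet <- binomTwoTailed(10, 25)
    hom0 <- rnorm(4, 0); hom1 <- rnorm(4, 1.5)
    pHom <- stats::t.test(hom0, hom1)$p.value
    comb <- combinedZygosityTest(pHet, pHom)$p
    comb < pHet && comb < pHom
  }))
  expect_gte(wins, 0.95)
})

test_that("genotype regression over {0,1,2,3} recovers planted slopes", {
  # exact linear data: slope 1, zero residuals
  r <- suppressWarnings(genotypeRegression(c(0, 1, 2, 3), c(0, 1, 2, 3)))
  expect_equal(r$slope, 1)
  expect_lt(abs(r$p), 1e-10)
  expect_error(genotypeRegression(c(1, 2, 3), c(1, 1, 1)),
               "rank-deficient")
  # parameter recovery: slope 0.5, noise sd 0.1, n = 20
  set.seed(31)
  hits <- mean(replicate(200, {
    codes <- sample(0:3, 20, replace = TRUE)
    vals <- 0.2 + 0.5 * codes + rnorm(20, 0, 0.1)
    est <- genotypeRegression(vals, codes)$slope
    est >= 0.4 && est <= 0.6
  }))
  expect_gte(hits, 0.95)
})

test_that("slope comparison uses pooled variance with n1 + n2 - 4 df", {
  set.seed(41)
  codes <- rep(0:3, 5)
  vals <- 1 + 0.3 * codes + rnorm(20, 0, 0.2)
  same <- slopeComparison(vals, codes, vals, codes)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$df, 36)
  # a planted slope difference is detected
  vals2 <- 1 - 0.3 * codes + rnorm(20, 0, 0.2)
  diffR <- slopeComparison(vals, codes, vals2, codes)
  expect_lt(diffR$p, 0.001)
})

test_that("element pipeline is calibrated under the global null", {
  els <- sprintf("el_%04d", 1:600)
  cfg <- simulationConfig(seed = 61, aseFraction = 0)
  co <- simulateCohort(cfg, els)
  res <- callAllelicImbalance(co$chipDepths, co$calls, co$inputDepths,
                              panel = co$panel, nNull = 5000, seed = 7)
  expect_gt(nrow(res), 100)
  expect_true(all(res$p > 0 & res$p <= 1))
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("element pipeline detects planted imbalance with high power", {
  els <- sprintf("el_%04d", 1:200)
  cfg <- simulationConfig(seed = 62, aseFraction = 1, aseTheta = 0.75)
  co <- simulateCohort(cfg, els)
  d <- co$chipDepths
  perVar <- tapply(d$ref + d$alt, d$variant,
                   function(x) length(x) >= 2 && all(x >= 30))
  okEls <- unique(d$element[d$variant %in% names(perVar)[perVar]])
  res <- callAllelicImbalance(d, co$calls, co$inputDepths,
                              panel = co$panel, nNull = 5000, seed = 8)
  pw <- mean(res$p[res$element %in% okEls] < 0.05)
  expect_gte(pw, 0.8)
})

test_that("genotype VCF round-trips through write and read", {
  cfg <- simulationConfig(seed = 71, donorCount = 4L)
  co <- simulateCohort(cfg, sprintf("e%02d", 1:10))
  tmp <- tempfile(fileext = ".vcf")
  writeGenotypeVcf(co$calls, co$chipDepths, tmp)
  back <- readGenotypeVcf(tmp)
  # genotype calls survive
  key <- function(d) paste(d$donor, d$variant)
  m <- match(key(co$calls), key(back$calls))
  expect_false(anyNA(m))
  expect_equal(back$calls$genotype[m], co$calls$genotype)
  expect_true(all(back$calls$passQC))
  # recorded het depths survive
  m2 <- match(key(co$chipDepths), key(back$depths))
  expect_false(anyNA(m2))
  expect_equal(back$depths$ref[m2], co$chipDepths$ref)
  expect_equal(back$depths$alt[m2], co$chipDepths$alt)
})
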