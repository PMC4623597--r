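library(GenomicRanges)

test_that("log2 fold change uses the symmetric 0.5 pseudocount", {
  expect_equal(log2FoldChange(7.5, 1.5), 2)
  expect_equal(log2FoldChange(0, 0), 0)
  x <- c(0.3, 1, 10, 250)
  expect_equal(log2FoldChange(x, x), rep(0, 4))
  expect_error(log2FoldChange(-1, 1))
})

test_that("specificity classification thresholds per species and partitions", {
  cl <- classifySpecificity(c(1.5, 1.5, 1.5, NA, 0.2),
                            c(1.2, 0.1, -1.5, 1.4, NA), tau = 1)
  expect_equal(cl$class, c("up/up", "up/ns", "up/down", "./up", "ns/."))
  # partition: class counts sum to locus count
  set.seed(1)
  lh <- rnorm(500); lm <- rnorm(500)
  cl2 <- classifySpecificity(lh, lm)
  expect_equal(sum(table(cl2$class)), 500L)
})

test_that("overlap enrichment matches the exhaustive hypergeometric oracle", {
  # N=10, human set 5, mouse set 4, overlap 4 -> 5/210
  h <- factor(rep(c("up", "ns"), c(5, 5)), levels = c("up", "down", "ns"))
  m <- factor(c(rep("up", 4), "ns", "ns", "ns", "ns", "ns", "ns"),
              levels = c("up", "down", "ns"))
  res <- overlapEnrichment(data.frame(human = h, mouse = m,
                                      class = paste(h, m, sep = "/")))
  expect_equal(res$p[res$direction == "up"], 5 / 210, tolerance = 1e-12)

  # zero overlap sits at the maximal tail: p = 1 only when forced
  h0 <- factor(c("up", "ns", "ns", "ns"), levels = c("up", "down", "ns"))
  m0 <- factor(c("ns", "up", "ns", "ns"), levels = c("up", "down", "ns"))
  res0 <- overlapEnrichment(data.frame(human = h0, mouse = m0,
                                       class = NA))
  expect_equal(res0$p[res0$direction == "up"], 1)

  # agreement with brute-force enumeration for N <= 15
  set.seed(7)
  for (i in 1:25) {
    N <- sample(4:15, 1)
    K <- sample(1:N, 1); n <- sample(1:N, 1)
    h <- factor(rep(c("up", "ns"), c(K, N - K)), levels = c("up", "down", "ns"))
    m <- factor(sample(rep(c("up", "ns"), c(n, N - n))),
                levels = c("up", "down", "ns"))
    k <- sum(h == "up" & m == "up")
    res <- overlapEnrichment(data.frame(human = h, mouse = m, class = NA))
    expect_equal(res$p[res$direction == "up"], hyperUpperEnum(k, K, n, N),
                 tolerance = 1e-12)
  }
  expect_error(overlapEnrichment(data.frame(human = factor(NA),
                                            mouse = factor(NA),
                                            class = NA)), "universe")
})

test_that("rank-cutoff scan tracks ranking agreement", {
  lfc <- seq(3, -3, length.out = 40)
  res <- rankCutoffScan(lfc, lfc, ranks = c(5, 10, 40))
  expect_equal(res$overlap[res$direction == "up"], c(5, 10, 40))
  # full-universe cutoff forces complete overlap and p = 1
  expect_equal(res$p[res$k == 40], c(1, 1))
  # minimal p at small cutoffs for identical rankings
  expect_lt(min(res$p[res$k == 5]), 1e-5)

  # independent rankings give non-extreme p values on average
  set.seed(11)
  ps <- replicate(40, {
    r <- rankCutoffScan(rnorm(60), rnorm(60), ranks = 15)
    r$p[1]
  })
  expect_gt(mean(ps), 0.2)
  expect_lt(mean(ps), 0.9)
})

test_that("elements are assigned to genes by window then nearest TSS", {
  genes <- GRanges("c1", IRanges(c(50000, 300000), width = 2000),
                   gene = c("A", "B"), tss = c(50000, 300000))
  # 40 kb from gene A body, 248 kb from gene B -> {A}
  el <- GRanges("c1", IRanges(10000, 10500))
  names(el) <- "e1"
  res <- assignToGenes(el, genes)
  expect_equal(res$gene, "A")
  expect_true(res$viaWindow)
  # no gene within 100 kb -> single nearest gene by TSS distance
  el2 <- GRanges("c1", IRanges(170000, 170500))
  names(el2) <- "e2"
  res2 <- assignToGenes(el2, genes)
  expect_false(res2$viaWindow)
  expect_equal(res2$gene, "A")   # TSS at 50 kb is 120 kb away, B is 129.5
  # element inside a gene body includes that gene
  el3 <- GRanges("c1", IRanges(50500, 50600))
  names(el3) <- "e3"
  expect_true("A" %in% assignToGenes(el3, genes)$gene)
  expect_error(assignToGenes(el, genes[0]), "empty gene model")
})

test_that("expression concordance detects planted concordant classes", {
  # identical samples: D = 0, p ~ 1
  set.seed(21)
  nGene <- 400
  genes <- sprintf("G%03d", 1:nGene)
  hom <- data.frame(human = genes, mouse = tolower(genes))
  exprH <- setNames(rnorm(nGene), genes)
  exprM <- setNames(rnorm(nGene), tolower(genes))
  classes <- rep("ns/ns", nGene)
  upIdx <- 1:40
  classes[upIdx] <- "up/up"
  exprH[upIdx] <- rnorm(40, 2, 0.4)
  exprM[upIdx] <- rnorm(40, 2, 0.4)
  res <- expressionConcordance(classes, genes, exprH, exprM, hom)
  expect_lt(res$tests$p[res$tests$class == "up/up" &
                          res$tests$species == "human"], 0.01)
  expect_lt(res$tests$p[res$tests$class == "up/up" &
                          res$tests$species == "mouse"], 0.01)

  # disjoint-support classes reach D = 1
  cl2 <- rep(c("up/up", "ns/ns"), each = 50)
  g2 <- genes[1:100]
  eH <- setNames(c(rnorm(50, 10, 0.1), rnorm(50, -10, 0.1)), g2)
  eM <- setNames(eH, tolower(g2))
  res2 <- expressionConcordance(cl2, g2, eH, eM, hom)
  expect_equal(res2$tests$D[res2$tests$class == "up/up" &
                              res2$tests$species == "human"], 1)

  # tiny classes are skipped with a warning
  w <- testthat::capture_warnings(
    expressionConcordance(c("up/up", "ns/ns", "ns/ns", "ns/ns"),
                          genes[1:4], exprH, exprM, hom))
  expect_true(any(grepl("fewer than 3", w)))
  # unmapped gene ids are reported
  expect_warning(
    expressionConcordance(rep("ns/ns", 4), c("NOPE", genes[2:4]),
                          exprH, exprM, hom),
    "without mouse homolog")
})

test_that("mobility analysis counts planted scenarios deterministically", {
  # atlas of 8 loci at gene G1: human-ls at locus 1, mouse-ls at locus 2
  # (mobile); gene G2 has a both-ls locus (not mobile)
  mkAtlas <- function(n) {
    new("UnionAtlas", loci = data.frame(
      atlasId = sprintf("a%02d", 1:n), humanChrom = "c1",
      humanStart = seq(1000, by = 5000, length.out = n),
      humanEnd = seq(1400, by = 5000, length.out = n),
      mouseChrom = "c1", mouseStart = seq(1000, by = 5000, length.out = n),
      mouseEnd = seq(1400, by = 5000, length.out = n),
      geneticStatus = "conserved", humanPeak = TRUE,
      mousePeak = c(FALSE, rep(TRUE, n - 1L))))
  }
  at <- mkAtlas(8)
  classes <- data.frame(
    atlasId = sprintf("a%02d", 1:8),
    human = factor(c("up", "ns", "up", "ns", "ns", "ns", "ns", "ns"),
                   c("up", "down", "ns")),
    mouse = factor(c("ns", "up", "up", "ns", "ns", "ns", "ns", "ns"),
                   c("up", "down", "ns")),
    lfcHuman = c(2, 0, 2, 0, 0, 0, 0, 0),
    lfcMouse = c(0, 2, 2, 0, 0, 0, 0, 0))
  geneOf <- setNames(c("G1", "G1", "G2", "G2", "G3", "G3", "G4", "G4"),
                     classes$atlasId)
  exprH <- setNames(c(2, 1.8, 0, 0), paste0("G", 1:4))
  exprM <- setNames(c(2, 1.9, 0, 0), paste0("G", 1:4))
  res <- mobilityAnalysis(classes, at, geneOf, exprH, exprM, nPerm = 200,
                          seed = 3)
  expect_equal(res$q1$nGenes, 1L)          # G1 mobile (a3 blocks G2)
  expect_equal(res$q1$nConcordant, 1L)     # G1 expression concordant up
  # a1 is human-ls at a locus with no mouse peak -> Q2 human side >= 1
  expect_gte(res$q2$humanLsInactiveInMouse, 1L)
  # determinism under a fixed seed
  res2 <- mobilityAnalysis(classes, at, geneOf, exprH, exprM, nPerm = 200,
                           seed = 3)
  expect_identical(res, res2)

  # no lineage-specific elements anywhere -> all counts zero
  classes0 <- classes
  classes0$human[] <- "ns"; classes0$mouse[] <- "ns"
  classes0$lfcHuman <- 0; classes0$lfcMouse <- 0
  res0 <- mobilityAnalysis(classes0, at, geneOf, exprH, exprM,
                           nPerm = 100, seed = 1)
  expect_equal(res0$q1$nGenes, 0L)
  expect_equal(res0$q2$humanLsInactiveInMouse, 0L)
  expect_equal(res0$q3$nGenes, 0L)
})

test_that("p-values from the lineage statistics stay in [0, 1] under permutation", {
  set.seed(33)
  ps <- replicate(200, {
    h <- factor(sample(rep(c("up", "ns"), c(6, 14))), c("up", "down", "ns"))
    m <- factor(sample(rep(c("up", "ns"), c(5, 15))), c("up", "down", "ns"))
    overlapEnrichment(data.frame(human = h, mouse = m,
                                 class = NA))$p[1]
  })
  expect_true(all(ps >= 0 & ps <= 1))
  # discrete conservative upper-tail p: roughly uniform, biased upward
  expect_gt(mean(ps), 0.4)
})
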