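library(GenomicRanges)

test_that("simulated genome pairs encode the relation exactly", {
  # zero perturbation rates: identity chain, intervals map to themselves
  cfg0 <- simulationConfig(seed = 1, chromSizes = c(cA = 20000),
                           insertionRate = 0, deletionRate = 0,
                           inversionRate = 0, breakRate = 0)
  gp0 <- simulateGenomePair(cfg0)
  expect_equal(length(gp0$chains), 1L)
  r <- mapInterval(GRanges("cA", IRanges(5001, 5200)), gp0$chains)
  expect_equal(start(mappedInterval(r)), 5001)
  expect_equal(end(mappedInterval(r)), 5200)

  # deletions: queries inside the gap are unmapped, flanks map with the
  # deletion offset
  cfgD <- simulationConfig(seed = 6, chromSizes = c(cA = 50000),
                           insertionRate = 0, deletionRate = 6e-5,
                           inversionRate = 0, breakRate = 0,
                           indelMeanLength = 1000)
  gpD <- simulateGenomePair(cfgD)
  ch <- gpD$chains[[1]]
  expect_gt(nrow(ch@blocks), 1L)
  bs <- ch@sStart + cumsum(ch@blocks$size + ch@blocks$dt)
  gapStart <- bs[1] - ch@blocks$dt[1]         # 0-based gap interval
  gapLen <- ch@blocks$dt[1]
  expect_gt(gapLen, 0L)
  inside <- GRanges("cA", IRanges(gapStart + 1L, gapStart + gapLen))
  expect_equal(orthologyStatus(mapInterval(inside, gpD$chains)),
               "unmapped")
  # right flank maps, shifted left by the accumulated deletion
  right <- GRanges("cA", IRanges(gapStart + gapLen + 2L,
                                 gapStart + gapLen + 101L))
  rr <- mapInterval(right, gpD$chains)
  expect_equal(orthologyStatus(rr), "full")
  expect_equal(start(mappedInterval(rr)), start(right) - gapLen)

  # inversions: a minus-strand chain whose mapped intervals reverse order
  cfgI <- simulationConfig(seed = 9, chromSizes = c(cA = 50000),
                           insertionRate = 0, deletionRate = 0,
                           inversionRate = 1e-4, breakRate = 0,
                           inversionMeanLength = 3000)
  gpI <- simulateGenomePair(cfgI)
  strands <- vapply(gpI$chains@chains, slot, "", "tStrand")
  expect_true("-" %in% strands)
  inv <- gpI$chains[[which(strands == "-")[1]]]
  a1 <- GRanges("cA", IRanges(inv@sStart + 11, inv@sStart + 20))
  a2 <- GRanges("cA", IRanges(inv@sStart + 111, inv@sStart + 120))
  m1 <- mappedInterval(mapInterval(a1, gpI$chains))
  m2 <- mappedInterval(mapInterval(a2, gpI$chains))
  expect_gt(start(m1), start(m2))     # order reverses through the inversion

  # chromosome breaks produce multiple target chromosomes
  cfgB <- simulationConfig(seed = 11, chromSizes = c(cA = 80000),
                           insertionRate = 0, deletionRate = 0,
                           inversionRate = 0, breakRate = 1e-4)
  gpB <- simulateGenomePair(cfgB)
  expect_gt(length(gpB$chromSizesB), 1L)

  # every emitted chain passes its invariants and the truth map tiles
  for (gp in list(gp0, gpD, gpI, gpB)) {
    for (ch2 in gp$chains@chains)
      expect_true(validObject(ch2, test = TRUE))
    expect_equal(sum(gp$truth$len),
                 sum(vapply(gp$chains@chains,
                            function(c) sum(c@blocks$size), numeric(1))))
  }
  expect_error(simulateGenomePair(
    simulationConfig(chromSizes = c(cA = -5))))
})

test_that("simulation is deterministic for a fixed seed", {
  cfg <- simulationConfig(seed = 5, chromSizes = c(cA = 40000),
                          insertionRate = 1e-4, deletionRate = 1e-4,
                          inversionRate = 2e-5, breakRate = 5e-6,
                          locusCount = 150L)
  gp1 <- simulateGenomePair(cfg)
  gp2 <- simulateGenomePair(cfg)
  expect_identical(gp1$truth, gp2$truth)
  tmp1 <- tempfile(); tmp2 <- tempfile()
  writeChainFile(gp1$chains, tmp1)
  writeChainFile(gp2$chains, tmp2)
  expect_identical(readLines(tmp1), readLines(tmp2))

  s1 <- simulateEpigenome(cfg)
  s2 <- simulateEpigenome(cfg)
  expect_identical(s1$rpmHuman, s2$rpmHuman)
  expect_identical(s1$truth, s2$truth)

  co1 <- simulateCohort(cfg, sprintf("e%02d", 1:20))
  co2 <- simulateCohort(cfg, sprintf("e%02d", 1:20))
  expect_identical(co1$chipDepths, co2$chipDepths)
  expect_identical(co1$panel, co2$panel)

  g1 <- simulateGwasCatalog(cfg, GRanges("c1", IRanges(1, 1e4)),
                            c(c1 = 1e6))
  g2 <- simulateGwasCatalog(cfg, GRanges("c1", IRanges(1, 1e4)),
                            c(c1 = 1e6))
  expect_identical(g1, g2)
})

test_that("planted epigenome classes carry their expected fold changes", {
  cfg <- simulationConfig(seed = 17, locusCount = 4000L)
  sim <- simulateEpigenome(cfg)
  ctMean <- function(m, ct)
    rowMeans(m[, sim$samples$cellType == ct, drop = FALSE])
  lfcH <- log2FoldChange(ctMean(sim$rpmHuman, "aTreg"),
                         ctMean(sim$rpmHuman, "Teff"))
  lfcM <- log2FoldChange(ctMean(sim$rpmMouse, "aTreg"),
                         ctMean(sim$rpmMouse, "Teff"))
  cls <- sim$truth$class
  up <- sim$truth$direction == 1
  # both-ls loci at fold effect 4: mean lfc ~ 2 in both species
  expect_equal(mean(lfcH[cls == "bothLS" & up]), 2, tolerance = 0.35)
  expect_equal(mean(lfcM[cls == "bothLS" & up]), 2, tolerance = 0.35)
  # conserved-active loci: mean lfc ~ 0
  expect_equal(mean(lfcH[cls == "conservedActive"]), 0, tolerance = 0.1)
  # species-only loci have zero signal in the missing species
  expect_true(all(sim$rpmHuman[cls == "mouseOnlyPeak", ] == 0))
  expect_true(all(sim$rpmMouse[cls == "humanOnlyPeak", ] == 0))
  # discordant loci move in opposite directions
  disc <- cls == "discordant" & up
  if (any(disc)) expect_lt(mean(lfcM[disc]), -1)
})

test_that("cohort allelic depths respect genotypes and planted effects", {
  cfg <- simulationConfig(seed = 23, aseFraction = 0.5, aseTheta = 0.8)
  co <- simulateCohort(cfg, sprintf("e%03d", 1:150))
  # depth rows exist only for het donors
  key <- paste(co$calls$donor, co$calls$variant)
  genoOf <- setNames(co$calls$genotype, key)
  expect_true(all(genoOf[paste(co$chipDepths$donor,
                               co$chipDepths$variant)] == "het"))
  # ref + alt is the total depth and is positive
  expect_true(all(co$chipDepths$ref + co$chipDepths$alt > 0))
  # planted elements show elevated alt fractions in ChIP but not input
  aseVars <- co$variants$variant[co$variants$element %in%
                                   co$truth$element[co$truth$ase]]
  fracChip <- with(co$chipDepths[co$chipDepths$variant %in% aseVars, ],
                   sum(alt) / sum(ref + alt))
  fracInput <- with(co$inputDepths[co$inputDepths$variant %in% aseVars, ],
                    sum(alt) / sum(ref + alt))
  expect_gt(fracChip, 0.7)
  expect_lt(abs(fracInput - 0.5), 0.05)
  # linked variants share panel rows in every population
  linked <- co$variants[!is.na(co$variants$linkedTo), ]
  if (nrow(linked)) {
    v <- linked$variant[1]; v0 <- linked$linkedTo[1]
    for (pop in names(co$panel))
      expect_identical(co$panel[[pop]][v, ], co$panel[[pop]][v0, ])
  }
})

test_that("planted-class recovery reaches 95 percent at fold 4, depth 50", {
  cfg <- simulationConfig(seed = 29, locusCount = 5000L, signalSdLog2 = 0)
  sim <- simulateEpigenome(cfg)
  ctMean <- function(m, ct)
    rowMeans(m[, sim$samples$cellType == ct, drop = FALSE])
  lfcH <- log2FoldChange(ctMean(sim$rpmHuman, "aTreg"),
                         ctMean(sim$rpmHuman, "Teff"))
  lfcM <- log2FoldChange(ctMean(sim$rpmMouse, "aTreg"),
                         ctMean(sim$rpmMouse, "Teff"))
  lfcH[sim$truth$class == "mouseOnlyPeak"] <- NA
  lfcM[sim$truth$class == "humanOnlyPeak"] <- NA
  cl <- classifySpecificity(lfcH, lfcM)
  map <- c("ns/ns" = "conservedActive", "up/ns" = "humanOnlyLS",
           "down/ns" = "humanOnlyLS", "ns/up" = "mouseOnlyLS",
           "ns/down" = "mouseOnlyLS", "up/up" = "bothLS",
           "down/down" = "bothLS", "up/down" = "discordant",
           "down/up" = "discordant", "./up" = "mouseOnlyPeak",
           "./down" = "mouseOnlyPeak", "./ns" = "mouseOnlyPeak",
           "up/." = "humanOnlyPeak", "down/." = "humanOnlyPeak",
           "ns/." = "humanOnlyPeak")
  acc <- mean(map[cl$class] == sim$truth$class)
  expect_gte(acc, 0.95)
})
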