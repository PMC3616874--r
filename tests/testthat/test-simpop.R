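test_that("simulation is deterministic and validates its configuration", {
  cfg <- simConfig(nChromosomes = 1, nMarkersPerChrom = 40, Ne = 30,
                   nBurninGenerations = 10, splitSizes = c(20, 20),
                   nQtl = 10, seed = 11)
  b1 <- simulateBasePopulation(cfg)
  b2 <- simulateBasePopulation(cfg)
  expect_identical(haplotypes(b1), haplotypes(b2))
  p1 <- splitAndDiverge(b1, cfg)
  p2 <- splitAndDiverge(b2, cfg)
  expect_identical(haplotypes(p1$popA), haplotypes(p2$popA))
  expect_identical(haplotypes(p1$popB), haplotypes(p2$popB))

  expect_error(simConfig(Ne = 1), "Ne")
  expect_error(simConfig(h2 = 0), "h2")
  expect_error(simConfig(nQtl = 100, nMarkersPerChrom = 10, nChromosomes = 2),
               "nQtl")
  expect_error(splitAndDiverge(b1, simConfig(splitSizes = c(0, 20))))
})

test_that("burn-in-free haplotypes are unlinked draws from the initial frequencies", {
  cfg <- simConfig(nChromosomes = 1, nMarkersPerChrom = 200, Ne = 400,
                   nBurninGenerations = 0, splitSizes = c(10, 10),
                   nQtl = 10, seed = 5)
  base <- simulateBasePopulation(cfg)
  p <- colMeans(haplotypes(base))
  # initialization is U(0.05, 0.95): no frequency may escape that band by
  # more than binomial noise on 800 haplotypes
  expect_true(all(p > 0.05 - 4 * sqrt(0.05 * 0.95 / 800)))
  expect_true(all(p < 0.95 + 4 * sqrt(0.05 * 0.95 / 800)))
  ld <- adjacentLd(base)
  # independent draws: adjacent r2 is pure sampling noise, E(r2) ~ 1/nHap
  expect_lt(mean(ld$r2, na.rm = TRUE), 5 / 800)
})

test_that("burn-in LD approaches the drift-recombination expectation 1/(1 + 4 Ne c)", {
  r2seed <- vapply(1:5, function(s) {
    cfg <- simConfig(nChromosomes = 1, chromLengthMorgans = 1,
                     nMarkersPerChrom = 500, Ne = 100,
                     nBurninGenerations = 200, splitSizes = c(10, 10),
                     nQtl = 10, seed = 100 + s)
    base <- simulateBasePopulation(cfg)
    ld <- adjacentLd(base)
    keep <- pmin(ld$fA, 1 - ld$fA) > 0.05 & pmin(ld$fB, 1 - ld$fB) > 0.05
    mean(ld$r2[keep], na.rm = TRUE)
  }, numeric(1))
  cbar <- 0.5 * (1 - exp(-2 * (1 / 499)))
  expected <- 1 / (1 + 4 * 100 * cbar)
  obs <- mean(r2seed)
  expect_gt(obs, expected / 2)
  expect_lt(obs, expected * 2)
})

test_that("identical founder samples with no divergence share their LD exactly", {
  cfg <- simConfig(nChromosomes = 1, nMarkersPerChrom = 120, Ne = 60,
                   nBurninGenerations = 40, nDivergenceGenerations = 0,
                   splitSizes = c(30, 30), nQtl = 10, seed = 21)
  base <- simulateBasePopulation(cfg)
  pops <- splitAndDiverge(base, cfg, founderOverlap = 1,
                          founderSizes = c(30, 30))
  rA <- adjacentLd(pops$popA)$r
  rB <- adjacentLd(pops$popB)$r
  ok <- is.finite(rA) & is.finite(rB)
  expect_gt(cor(rA[ok], rB[ok]), 0.99)
})

test_that("LD consistency decays with divergence time", {
  lower <- vapply(1:10, function(s) {
    run <- function(gens) {
      cfg <- simConfig(nChromosomes = 1, nMarkersPerChrom = 150, Ne = 80,
                       nBurninGenerations = 80, nDivergenceGenerations = gens,
                       splitSizes = c(120, 120), nQtl = 10, seed = 300 + s)
      pops <- splitAndDiverge(simulateBasePopulation(cfg), cfg)
      ldConsistency(adjacentLd(pops$popA), adjacentLd(pops$popB))$meanConsistency
    }
    run(50) < run(5)
  }, logical(1))
  expect_gte(sum(lower), 8)
})

test_that("trait architecture hits the target genetic correlation and scale", {
  s <- smallSim(31)
  # perfect correlation: effect vectors proportional
  cfg1 <- s$cfg; cfg1@rG <- 1
  arch1 <- assignTraitArchitecture(s$popA, s$popB, cfg1)
  ratio <- arch1$effects[, 2] / arch1$effects[, 1]
  expect_lt(diff(range(ratio)), 1e-8)
  QA <- dosages(haplotypesToGenotypes(s$popA))[, arch1$qtlIdx]
  expect_equal(cor(drop(QA %*% arch1$effects[, 1]),
                   drop(QA %*% arch1$effects[, 2])), 1, tolerance = 1e-10)
  # TBV variance equals h2 in each population
  expect_equal(var(s$arch$tbv$A), s$cfg@h2, tolerance = 1e-10)
  expect_equal(var(s$arch$tbv$B), s$cfg@h2, tolerance = 1e-10)
  expect_error(assignTraitArchitecture(s$popA, s$popB,
                                       {c2 <- s$cfg; c2@rG <- 1.5; c2}))

  # rG = 0.8 recovery: realized correlation of the two traits' TBV on
  # shared genotypes, averaged over seeds
  real <- vapply(1:10, function(k) {
    ss <- smallSim(400 + k, nMarkers = 80, sizes = c(200, 200), nQtl = 50)
    Q <- dosages(haplotypesToGenotypes(ss$popA))[, ss$arch$qtlIdx]
    cor(drop(Q %*% ss$arch$effects[, 1]), drop(Q %*% ss$arch$effects[, 2]))
  }, numeric(1))
  expect_lt(abs(mean(real) - 0.8), 0.1)
})

test_that("TBV recomputes exactly from QTL dosages and effects", {
  s <- smallSim(37)
  Q <- dosages(haplotypesToGenotypes(s$popA))[, s$arch$qtlIdx, drop = FALSE]
  expect_equal(unname(computeTbv(s$popA, s$arch, 1L)),
               drop(Q %*% s$arch$effects[, 1]))
})

test_that("family structure respects sizes, sires and the trend switch", {
  s <- smallSim(41, sizes = c(200, 100))
  fam <- buildFamilyStructure(s$popA, s$arch, s$cfg, nBulls = 12, nSires = 4,
                              nCows = 120, familySizeRange = c(10, 60),
                              bullYears = 2000:2004, cowYears = 2005:2006)
  ped <- fam$pedigree
  cows <- ped[ped$role == "cow", ]
  sires <- unique(cows$sire_id)
  expect_length(sires, 4L)
  expect_true(all(sires %in% ped$animal_id[ped$role == "bull"]))
  sizes <- table(cows$sire_id)
  expect_true(all(sizes >= 10 & sizes <= 60))
  expect_identical(sum(sizes), 120L)

  one <- buildFamilyStructure(s$popA, s$arch, s$cfg, nBulls = 3, nSires = 1,
                              nCows = 10, familySizeRange = c(1, 50),
                              bullYears = 2000:2001, cowYears = 2002)
  expect_identical(nrow(one$pedigree[one$pedigree$role == "cow", ]), 10L)
  expect_length(unique(one$pedigree$sire_id[one$pedigree$role == "cow"]), 1L)

  expect_error(buildFamilyStructure(s$popA, s$arch, s$cfg, nBulls = 5,
                                    nSires = 2, nCows = 10,
                                    familySizeRange = c(20, 30)),
               "exceed")

  # trendPerYear = 0: no selection, bull TBV slope on birth year is null
  tstats <- vapply(1:10, function(k) {
    cfg0 <- s$cfg; cfg0@trendPerYear <- 0
    f <- buildFamilyStructure(s$popA, s$arch, cfg0, nBulls = 40, nSires = 3,
                              nCows = 60, familySizeRange = c(10, 30),
                              bullYears = 2000:2007, cowYears = 2008,
                              seed = 500 + k)
    p <- f$pedigree[f$pedigree$role == "bull", ]
    tbv <- computeTbv(f$haplotypes, s$arch, 1L)[p$animal_id]
    summary(lm(tbv ~ p$birth_year))$coefficients[2, 3]
  }, numeric(1))
  expect_gte(sum(abs(tstats) < 3), 9)

  # positive trend under selection
  cfg1 <- s$cfg; cfg1@trendPerYear <- 0.3
  f1 <- buildFamilyStructure(s$popA, s$arch, cfg1, nBulls = 60, nSires = 3,
                             nCows = 60, familySizeRange = c(10, 30),
                             bullYears = 2000:2007, cowYears = 2008,
                             seed = 99)
  p1 <- f1$pedigree[f1$pedigree$role == "bull", ]
  tbv1 <- computeTbv(f1$haplotypes, s$arch, 1L)[p1$animal_id]
  expect_gt(coef(lm(tbv1 ~ p1$birth_year))[2], 0)
})

test_that("DRP noise is calibrated so Cor^2(DRP, TBV) equals the reliability", {
  set.seed(1)
  tbv <- rnorm(5000)
  names(tbv) <- paste0("a", seq_along(tbv))
  drp <- generateDrp(tbv, 0.5, sigma2g = 1, seed = 2)
  expect_gt(cor(drp$drp, tbv)^2, 0.45)
  expect_lt(cor(drp$drp, tbv)^2, 0.55)

  exact <- generateDrp(tbv, 1, sigma2g = 1, seed = 3)
  expect_identical(exact$drp, unname(tbv))

  # error-variance monotonicity: r2 = 0.9 bulls vs 0.3 cows
  eBull <- generateDrp(tbv, 0.9, 1, seed = 4)$drp - tbv
  eCow <- generateDrp(tbv, 0.3, 1, seed = 5)$drp - tbv
  expect_lt(var(eBull), var(eCow))
  expect_equal(var(eBull), 1 / 9, tolerance = 0.05)
  expect_equal(var(eCow), 7 / 3, tolerance = 0.25)

  expect_error(generateDrp(tbv, 0, 1), "reliabilit")
  expect_error(generateDrp(tbv, 1.2, 1), "reliabilit")
})

test_that("random mating keeps Hardy-Weinberg and drift erodes heterozygosity", {
  cfg <- simConfig(nChromosomes = 1, nMarkersPerChrom = 500, Ne = 50,
                   nBurninGenerations = 60, splitSizes = c(10, 10),
                   nQtl = 10, seed = 61)
  base <- simulateBasePopulation(cfg)
  h <- haplotypes(base)
  d <- h[seq(1, nrow(h), 2), ] + h[seq(2, nrow(h), 2), ]
  p <- colMeans(h)
  keep <- p > 0.1 & p < 0.9
  hetObs <- colMeans(d[, keep] == 1L)
  hetExp <- 2 * p[keep] * (1 - p[keep])
  # HWE: observed heterozygote fraction tracks 2pq on average
  expect_equal(mean(hetObs / hetExp), 1, tolerance = 0.1)
  # heterozygosity decay ~ (1 - 1/(2Ne))^g from the U(0.05, 0.95) start
  he0 <- 0.5 - (0.25 + 0.9^2 / 12)   # E[2pq] under the initialization
  heExp <- 2 * he0 * (1 - 1 / (2 * 50))^60
  expect_gt(mean(2 * p * (1 - p)), heExp * 0.7)
  expect_lt(mean(2 * p * (1 - p)), heExp * 1.4)
})
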