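test_that("bull split excludes candidates by their maximum relationship", {
  G <- diag(4) * 0 + 1e-6
  G <- G + diag(1, 4)
  G[1, 2] <- G[2, 1] <- 0.9    # candidate a2 is near-clone of reference a1
  G[1, 3] <- G[3, 1] <- 0.1
  grm <- new("GRM", animalIds = paste0("a", 1:4), mat = G, p = numeric(0),
             ridge = 0)
  sp <- makeBullSplit(c("a2", "a3", "a4"), "a1", grm, relationshipMax = 0.45)
  expect_identical(sp$test, c("a3", "a4"))
  expect_identical(sp$excluded, "a2")
  # +Inf retains everyone
  spAll <- makeBullSplit(c("a2", "a3", "a4"), "a1", grm,
                         relationshipMax = Inf)
  expect_length(spAll$test, 3L)
  expect_warning(makeBullSplit(c("a2"), "a1", grm, relationshipMax = 0.1),
                 "empty")
})

test_that("relationship threshold 0.45 separates first-degree kin from unrelated bulls", {
  # Cattle-like genome (30 x 1 Morgan, 6k markers) so realized
  # parent-offspring relationships concentrate near their pedigree
  # expectation. With contemporary-frequency GRMs that expectation is
  # ~0.48 with SD ~0.03 (first-degree relationships straddle 0.45, the
  # same range seen on a real 54K chip), so the 0.45 filter removes most
  # but not all kin while leaving unrelated candidates untouched.
  hits <- vapply(1:6, function(k) {
    cfg <- simConfig(nChromosomes = 30, chromLengthMorgans = 1,
                     nMarkersPerChrom = 200, Ne = 80,
                     nBurninGenerations = 25, nDivergenceGenerations = 2,
                     splitSizes = c(300, 40), nQtl = 30, h2 = 0.3,
                     rG = 0.8, trendPerYear = 0, seed = 600 + k)
    pops <- splitAndDiverge(simulateBasePopulation(cfg), cfg)
    arch <- assignTraitArchitecture(pops$popA, pops$popB, cfg)
    fam <- buildFamilyStructure(pops$popA, arch, cfg, nBulls = 8, nSires = 2,
                                nCows = 20, familySizeRange = c(5, 15),
                                bullYears = 2000:2001, cowYears = 2002)
    ped <- fam$pedigree
    cows <- ped[ped$role == "cow", ]           # first-degree kin of sires
    unrelated <- ped$animal_id[ped$role == "base"][1:20]
    sires <- unique(cows$sire_id)
    keep <- c(ped$animal_id[ped$role != "base"], unrelated)
    pBase <- alleleFrequencies(haplotypesToGenotypes(pops$popA))
    grm <- buildGrm(haplotypesToGenotypes(
      subsetHaplotypes(fam$haplotypes, ids = keep)), p = pBase)
    # warning expected when every kin candidate is filtered out
    spd <- suppressWarnings(
      makeBullSplit(cows$animal_id, sires, grm, relationshipMax = 0.45))
    spu <- makeBullSplit(unrelated, sires, grm, relationshipMax = 0.45)
    c(length(spd$excluded) / nrow(cows), length(spu$excluded) / 20)
  }, numeric(2))
  expect_gte(mean(hits[1, ]), 0.75)  # most first-degree kin excluded
  expect_lte(mean(hits[2, ]), 0.1)   # unrelated candidates retained
  expect_gt(mean(hits[1, ]) - mean(hits[2, ]), 0.6)
})

test_that("cow folds assign whole families and partition the cow set", {
  set.seed(60)
  fams <- rep(paste0("f", 1:13), times = sample(60:150, 13, TRUE))
  cows <- data.frame(animal_id = paste0("c", seq_along(fams)), family = fams)
  folds <- makeCowFolds(cows, bulls = paste0("b", 1:5), kFolds = 5, seed = 2)
  counts <- sort(vapply(folds, function(f) length(f$testFamilies), integer(1)))
  expect_identical(counts, c(2L, 2L, 3L, 3L, 3L))
  testSets <- lapply(folds, `[[`, "test")
  expect_identical(sort(unlist(testSets)), sort(cows$animal_id))
  expect_identical(anyDuplicated(unlist(testSets)), 0L)
  # no family split across test folds
  for (f in folds)
    expect_true(all(cows$family[cows$animal_id %in% f$test] %in% f$testFamilies))
  # reference = bulls + all non-test cows
  expect_identical(sort(folds[[1]]$reference),
                   sort(c(paste0("b", 1:5),
                          setdiff(cows$animal_id, folds[[1]]$test))))

  # balanced case: 10 equal families of 100 over 5 folds -> 200 each
  cows2 <- data.frame(animal_id = paste0("x", 1:1000),
                      family = rep(paste0("g", 1:10), each = 100))
  folds2 <- makeCowFolds(cows2, bulls = character(0), kFolds = 5, seed = 3)
  expect_true(all(vapply(folds2, function(f) length(f$test), integer(1)) == 200L))

  expect_error(makeCowFolds(cows2[cows2$family %in% paste0("g", 1:3), ],
                            character(0), kFolds = 5), "at least")
})

test_that("detrending removes linear birth-year structure", {
  yrs <- rep(2000:2009, each = 5)
  expect_equal(detrend(2 * yrs - 100, yrs), rep(0, 50), tolerance = 1e-10)
  set.seed(61)
  v <- rnorm(50)
  expect_equal(detrend(v, yrs), residuals(lm(v ~ yrs)), ignore_attr = TRUE)
  expect_warning(out <- detrend(v, rep(2000, 50)), "identical")
  expect_identical(out, v)
})

test_that("trend correction deflates trend-inflated validation correlations", {
  gaps <- vapply(1:10, function(k) {
    set.seed(70 + k)
    yrs <- rep(1:10, each = 30)
    nn <- length(yrs)
    trueCor2 <- function(trend) {
      u <- trend * yrs + rnorm(nn, 0, 1)          # genetic signal
      gebv <- 0.5 * u + rnorm(nn, 0, 1)
      drp <- u + rnorm(nn, 0, 1)
      c(raw = cor(gebv, drp)^2,
        det = cor(detrend(gebv, yrs), detrend(drp, yrs))^2)
    }
    withTrend <- trueCor2(0.3)
    noTrend <- trueCor2(0)
    # raw correlation is inflated by the shared trend; detrending brings it
    # back toward the no-trend control
    (withTrend["raw"] - noTrend["raw"]) -
      abs(withTrend["det"] - noTrend["det"])
  }, numeric(1))
  expect_gt(mean(gaps), 0)
  expect_gte(sum(gaps > 0), 8)
})

test_that("validation reliability follows its defining formula", {
  set.seed(62)
  g <- rnorm(100)
  expect_equal(validationReliability(g, g, rep(0.5, 100)), 2.0)
  # affine invariance
  d <- g + rnorm(100, 0, 0.5)
  expect_equal(validationReliability(3 * g - 1, d, rep(0.5, 100)),
               validationReliability(g, d, rep(0.5, 100)))
  # independence -> ~0
  big <- rnorm(20000)
  expect_lt(validationReliability(big, rnorm(20000), rep(0.5, 20000)), 0.01)
  expect_error(validationReliability(g[1:2], g[1:2], c(0.5, 0.5)), "at least 3")
  expect_error(validationReliability(rep(1, 10), rnorm(10), rep(0.5, 10)),
               "zero variance")
})

test_that("validation reliability tracks Cor^2(GEBV, TBV) when r2_DRP is correct", {
  vals <- vapply(1:20, function(k) {
    set.seed(80 + k)
    n <- 400
    tbv <- rnorm(n)
    gebv <- 0.6 * tbv + rnorm(n, 0, 0.6)     # an imperfect predictor
    r2 <- 0.5
    drp <- tbv + rnorm(n, 0, sqrt((1 - r2) / r2))
    validationReliability(gebv, drp, rep(r2, n)) - cor(gebv, tbv)^2
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.1)
})

test_that("expected reliability reproduces the worked value and its monotonicities", {
  expect_equal(round(goddardExpectedReliability(30, 100, 1500, 0.5), 3), 0.175)
  r1500 <- goddardExpectedReliability(30, 100, 1500, 0.5)
  rBig <- goddardExpectedReliability(30, 100, 1e6, 0.5)
  expect_gt(rBig, 0.9)
  expect_gt(rBig, r1500)
  r1 <- goddardExpectedReliability(30, 100, 1, 0.5)
  expect_gt(r1, 0)
  expect_lt(r1, r1500)
  # grids: increasing in N and h2, decreasing in Ne, always within (0, 1)
  Ns <- c(10, 100, 1000, 10000, 1e5)
  vN <- vapply(Ns, function(N) goddardExpectedReliability(30, 100, N, 0.5),
               numeric(1))
  expect_true(all(diff(vN) > 0))
  h2s <- seq(0.1, 1, by = 0.1)
  vH <- vapply(h2s, function(h) goddardExpectedReliability(30, 100, 1500, h),
               numeric(1))
  expect_true(all(diff(vH) > 0))
  Nes <- c(10, 50, 100, 500, 1000)
  vNe <- vapply(Nes, function(ne) goddardExpectedReliability(30, ne, 1500, 0.5),
                numeric(1))
  expect_true(all(diff(vNe) < 0))
  expect_true(all(c(vN, vH, vNe) > 0 & c(vN, vH, vNe) < 1))
  expect_error(goddardExpectedReliability(-1, 100, 1500, 0.5), "invalid")
  expect_error(goddardExpectedReliability(30, 100, 1500, 0), "h2")
})
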