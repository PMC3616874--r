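## End-to-end experiment orchestration: simulate two related populations,
## QC, LD consistency, single-reference GBLUP, joint-reference two-trait
## GBLUP, validation report. Every stage reseeds deterministically from the
## root seed and persists its intermediates, so stages can be re-run and
## every reported number re-derived from files.

#' Configure a scenario run
#'
#' The default sizes mirror the study system (population A: 80 bulls of
#' which 13 sire ~1.6k cows; population B: ~4.4k bulls). Reduced sizes for
#' quick experimentation are available via `smallScenarioConfig()`.
#'
#' @param sim a [SimConfig-class].
#' @param nBulls,nSires,nCows population-A structure (see
#'   [buildFamilyStructure()]).
#' @param nPopBBulls genotyped/phenotyped bulls sampled from population B.
#' @param bullR2,cowR2 DRP reliabilities for bulls and cows.
#' @param mafMin,markerCallrateMin,animalMissingMax QC thresholds
#'   ([qcFilter()]).
#' @param excludeQtlFromPanel drop QTL loci from the genotyping panel so
#'   prediction acts through marker-QTL LD (default TRUE).
#' @param relationshipMax bull test-set exclusion threshold
#'   ([makeBullSplit()]).
#' @param kFolds,doCowCv cow cross-validation settings.
#' @param familySizeRange,bullYears,cowYears passed to
#'   [buildFamilyStructure()].
#' @param independentPopB simulate population B from an independent base
#'   population (negative control: no shared ancestry).
#' @param remlTol,remlMaxIter AI-REML settings for the scenario fits.
#' @param ridge GRM diagonal ridge.
#' @param outDir directory for persisted intermediates (default a fresh
#'   tempdir subdirectory).
#' @param seed root seed; all stage seeds derive from it.
#' @return A `ScenarioConfig` list.
#' @export
scenarioConfig <- function(sim = simConfig(), nBulls = 80, nSires = 13,
                           nCows = 1572, nPopBBulls = 4398,
                           bullR2 = 0.90, cowR2 = 0.35,
                           mafMin = 0.01, markerCallrateMin = 0.90,
                           animalMissingMax = 0.10,
                           excludeQtlFromPanel = TRUE,
                           relationshipMax = 0.45, kFolds = 5L,
                           doCowCv = TRUE,
                           familySizeRange = c(63, 358),
                           bullYears = 1993:2002, cowYears = 2001:2006,
                           independentPopB = FALSE,
                           remlTol = 1e-6, remlMaxIter = 50L,
                           ridge = 1e-6, outDir = NULL, seed = 1L) {
  cfg <- as.list(environment())
  cfg$sim@seed <- as.integer(seed)
  validObject(cfg$sim)
  structure(cfg, class = "ScenarioConfig")
}

#' Reduced-size scenario for quick runs
#'
#' Same structure as [scenarioConfig()] at roughly 1/4 linear scale:
#' population A of 50 bulls (3 sires) and 390 cows, population B of 500
#' bulls, 2 chromosomes x 300 loci. Used by the package's own validation
#' experiments so a full scenario completes in tens of seconds.
#'
#' @param seed root seed.
#' @param ... overrides passed to [scenarioConfig()].
#' @return A `ScenarioConfig` list.
#' @export
smallScenarioConfig <- function(seed = 1L, ...) {
  scenarioConfig(
    sim = simConfig(nChromosomes = 2, chromLengthMorgans = 1,
                    nMarkersPerChrom = 300, Ne = 100,
                    nBurninGenerations = 150, nDivergenceGenerations = 5,
                    splitSizes = c(500, 600), nQtl = 100, h2 = 0.3,
                    rG = 0.8, trendPerYear = 0.1, seed = seed),
    nBulls = 50, nSires = 3, nCows = 390, nPopBBulls = 500,
    doCowCv = FALSE, seed = seed, ...)
}

## Simulation stage: returns haplotypes, pedigree, architecture, DRP.
.simStage <- function(cfg) {
  sim <- cfg$sim
  base <- simulateBasePopulation(sim)
  pops <- splitAndDiverge(base, sim)
  popB <- pops$popB
  if (isTRUE(cfg$independentPopB)) {
    sim2 <- sim
    sim2@seed <- as.integer(childSeed(sim@seed, 11L))
    base2 <- simulateBasePopulation(sim2)
    popB <- splitAndDiverge(base2, sim2)$popB
  }
  arch <- assignTraitArchitecture(pops$popA, popB, sim)
  fam <- buildFamilyStructure(pops$popA, arch, sim, nBulls = cfg$nBulls,
                              nSires = cfg$nSires, nCows = cfg$nCows,
                              bullYears = cfg$bullYears,
                              cowYears = cfg$cowYears,
                              familySizeRange = cfg$familySizeRange)
  set.seed(childSeed(sim@seed, 5L))
  bIdx <- sort(sample(length(popB@animalIds), cfg$nPopBBulls))
  popB <- subsetHaplotypes(popB, ids = popB@animalIds[bIdx])
  ped <- fam$pedigree
  hapsA <- subsetHaplotypes(fam$haplotypes,
                            ids = ped$animal_id[ped$role != "base"])
  tbvA <- computeTbv(hapsA, arch, 1L)
  tbvB <- computeTbv(popB, arch, 2L)
  pedA <- ped[ped$role != "base", , drop = FALSE]
  isBull <- pedA$role == "bull"
  r2A <- ifelse(isBull, cfg$bullR2, cfg$cowR2)
  drpA <- generateDrp(tbvA, r2A, sim@h2, trait = "traitA",
                      seed = childSeed(sim@seed, 6L))
  drpB <- generateDrp(tbvB, cfg$bullR2, sim@h2, trait = "traitB",
                      seed = childSeed(sim@seed, 7L))
  list(hapsA = hapsA, popB = popB, pedigree = pedA, arch = arch,
       tbvA = tbvA, tbvB = tbvB, drpA = drpA, drpB = drpB,
       sigmaG = fam$sigmaG)
}

## Genotype stage: panel construction, QC, harmonization.
.genoStage <- function(cfg, sim) {
  panelMarkers <- sim$hapsA@map$id
  if (isTRUE(cfg$excludeQtlFromPanel))
    panelMarkers <- setdiff(panelMarkers, sim$hapsA@map$id[sim$arch$qtlIdx])
  hA <- subsetHaplotypes(sim$hapsA, markers = panelMarkers)
  hB <- subsetHaplotypes(sim$popB, markers = panelMarkers)
  gA <- haplotypesToGenotypes(hA)
  gB <- haplotypesToGenotypes(hB)
  qcA <- qcFilter(gA, cfg$mafMin, cfg$markerCallrateMin, cfg$animalMissingMax)
  qcB <- qcFilter(gB, cfg$mafMin, cfg$markerCallrateMin, cfg$animalMissingMax)
  harm <- harmonizeAlleles(qcA$genotypes, qcB$genotypes)
  shared <- harm$a@map$id
  list(gA = harm$a, gB = harm$b,
       hA = subsetHaplotypes(hA, markers = shared),
       hB = subsetHaplotypes(hB, markers = shared),
       qcReports = list(A = qcA$report, B = qcB$report))
}

## Bull validation at fixed splits for one reference design.
.bullReliability <- function(gebvRes, trait, split, drp, ped) {
  g <- gebvRes$gebv
  g <- g[g$trait == trait, , drop = FALSE]
  idx <- match(split$test, g$animal_id)
  di <- match(split$test, drp$animal_id)
  yi <- match(split$test, ped$animal_id)
  validationReliability(g$gebv[idx], drp$drp[di], drp$r2_drp[di],
                        birthYears = ped$birth_year[yi])
}

#' Run the full scenario
#'
#' Stages: simulate -> genotype QC/harmonization -> LD consistency ->
#' single-reference single-trait GBLUP -> joint-reference two-trait GBLUP
#' -> bull validation (and optionally half-sib-family cow cross-validation).
#' All intermediates are persisted under `config$outDir`; the run is fully
#' deterministic given `config$seed`.
#'
#' @param config a `ScenarioConfig` from [scenarioConfig()] or
#'   [smallScenarioConfig()].
#' @return A `ScenarioReport` list: `ldConsistency`, `vcSingle`, `vcJoint`,
#'   `bull` (single/joint reliability and increase), `cow` (when cow CV is
#'   run), `outDir`, `meta`.
#' @export
runScenario <- function(config) {
  t0 <- proc.time()[3]
  outDir <- config$outDir %||% file.path(tempdir(),
                                         sprintf("scenario_seed%d", config$seed))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  timings <- c()
  tick <- function(name) {
    timings[name] <<- proc.time()[3] - t0
  }

  sim <- .simStage(config)
  writeTable(sim$pedigree, file.path(outDir, "pedigree.tsv"))
  writeTable(sim$drpA, file.path(outDir, "drp_popA.tsv"))
  writeTable(sim$drpB, file.path(outDir, "drp_popB.tsv"))
  writeTable(data.frame(animal_id = names(sim$tbvA), tbv = sim$tbvA),
             file.path(outDir, "tbv_popA.tsv"))
  tick("simulate")

  geno <- .genoStage(config, sim)
  writeGenotypes(geno$gA, file.path(outDir, "popA"), "tsv")
  writeGenotypes(geno$gB, file.path(outDir, "popB"), "tsv")
  tick("genotypes")

  ldA <- adjacentLd(geno$hA)
  ldB <- adjacentLd(geno$hB)
  cons <- ldConsistency(ldA, ldB)
  writeTable(ldA, file.path(outDir, "ld_popA.tsv"))
  writeTable(ldB, file.path(outDir, "ld_popB.tsv"))
  tick("ld")

  grmJoint <- buildGrm(list(geno$gA, geno$gB), ridge = config$ridge)
  grmA <- buildGrm(geno$gA, ridge = config$ridge)
  writeGrm(grmA, file.path(outDir, "grm_popA"))
  tick("grm")

  ped <- sim$pedigree
  bulls <- ped$animal_id[ped$role == "bull"]
  cows <- ped$animal_id[ped$role == "cow"]
  sires <- unique(ped$family[ped$role == "cow"])
  candidates <- setdiff(bulls, sires)
  split <- makeBullSplit(candidates, sires, grmA,
                         relationshipMax = config$relationshipMax)
  writeSplit(split, file.path(outDir, "bull_split.tsv"))

  refIds <- c(sires, cows)
  drpA <- residualWeights(sim$drpA)
  drpB <- residualWeights(sim$drpB)
  recSingle <- drpA[drpA$animal_id %in% refIds, , drop = FALSE]
  specSingle <- modelSpec(recSingle, grmA)
  fitSingle <- singleTraitGblup(specSingle, tol = config$remlTol,
                                maxIter = config$remlMaxIter)
  writeTable(fitSingle$gebv$gebv, file.path(outDir, "gebv_single.tsv"))
  tick("gblup_single")

  recJoint <- rbind(recSingle, drpB)
  specJoint <- modelSpec(recJoint, grmJoint)
  fitJoint <- twoTraitGblup(specJoint, tol = config$remlTol,
                            maxIter = config$remlMaxIter)
  writeTable(fitJoint$gebv$gebv, file.path(outDir, "gebv_joint.tsv"))
  tick("gblup_joint")

  relSingle <- .bullReliability(fitSingle$gebv, "traitA", split, sim$drpA, ped)
  relJoint <- .bullReliability(fitJoint$gebv, "traitA", split, sim$drpA, ped)
  bull <- data.frame(group = "bulls", reliability_single = relSingle,
                     reliability_joint = relJoint,
                     increase = relJoint - relSingle)

  cow <- NULL
  if (isTRUE(config$doCowCv)) {
    folds <- makeCowFolds(ped[ped$role == "cow", c("animal_id", "family")],
                          bulls, kFolds = config$kFolds,
                          seed = childSeed(config$seed, 8L))
    writeSplit(folds, file.path(outDir, "cow_folds.tsv"))
    pool <- function(joint) {
      out <- numeric(0)
      for (f in folds) {
        rec <- if (joint)
          rbind(drpA[drpA$animal_id %in% f$reference, , drop = FALSE], drpB)
        else drpA[drpA$animal_id %in% f$reference, , drop = FALSE]
        spec <- modelSpec(rec, if (joint) grmJoint else grmA)
        vc <- if (joint) fitJoint$vc else fitSingle$vc
        res <- solveMme(buildMme(spec, vc))
        g <- res$gebv
        g <- g[g$trait == "traitA", ]
        out <- c(out, structure(g$gebv[match(f$test, g$animal_id)],
                                names = f$test))
      }
      out
    }
    gebvCvS <- pool(FALSE)
    gebvCvJ <- pool(TRUE)
    di <- match(names(gebvCvS), sim$drpA$animal_id)
    relCowS <- validationReliability(gebvCvS, sim$drpA$drp[di],
                                     sim$drpA$r2_drp[di])
    relCowJ <- validationReliability(gebvCvJ[names(gebvCvS)],
                                     sim$drpA$drp[di], sim$drpA$r2_drp[di])
    cow <- data.frame(group = "cows", reliability_single = relCowS,
                      reliability_joint = relCowJ,
                      increase = relCowJ - relCowS)
    tick("cow_cv")
  }

  report <- structure(list(
    ldConsistency = cons, vcSingle = fitSingle$vc, vcJoint = fitJoint$vc,
    bull = bull, cow = cow, split = split, qcReports = geno$qcReports,
    outDir = outDir,
    meta = list(seed = config$seed, timings = timings,
                nTestBulls = length(split$test),
                nReferenceRecords = nrow(recSingle),
                nJointRecords = nrow(recJoint))),
    class = "ScenarioReport")
  tab <- rbind(bull, cow)
  writeTable(tab, file.path(outDir, "report.tsv"))
  report
}

#' @export
print.ScenarioReport <- function(x, ...) {
  cat(sprintf("ScenarioReport (seed %d, %d test bulls)\n",
              x$meta$seed, x$meta$nTestBulls))
  cat(sprintf("  LD consistency: %.3f; mean r2 A %.3f, B %.3f\n",
              x$ldConsistency$meanConsistency,
              x$ldConsistency$meanR2["a"], x$ldConsistency$meanR2["b"]))
  cat(sprintf("  rG (two-trait): %.3f\n", x$vcJoint@rG))
  tab <- rbind(x$bull, x$cow)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Re-run the single-reference prediction with part of the cows removed
#'
#' Quantifies the information cows contribute to a bull-reference-poor
#' population: removes a random fraction of cow records from the reference,
#' refits the single-trait model and recomputes the bull validation
#' reliability.
#'
#' @param config a `ScenarioConfig`.
#' @param cowFractionRemoved fraction in [0, 1).
#' @param report optional baseline `ScenarioReport` from [runScenario()]
#'   with the same config (rerun when NULL).
#' @return data.frame: baseline and reduced reliability and their
#'   difference, plus the reference sizes.
#' @export
compareReducedReference <- function(config, cowFractionRemoved,
                                    report = NULL) {
  if (cowFractionRemoved < 0 || cowFractionRemoved >= 1)
    stop("cowFractionRemoved must be in [0, 1)")
  if (is.null(report)) report <- runScenario(config)
  outDir <- report$outDir
  ped <- readTable(file.path(outDir, "pedigree.tsv"))
  drpA <- residualWeights(readTable(file.path(outDir, "drp_popA.tsv")))
  grmA <- readGrm(file.path(outDir, "grm_popA"))
  grmA@ridge <- config$ridge
  cows <- ped$animal_id[ped$role == "cow"]
  sires <- unique(ped$family[ped$role == "cow"])
  set.seed(childSeed(config$seed, 9L))
  keepCows <- sample(cows, round(length(cows) * (1 - cowFractionRemoved)))
  refIds <- c(sires, keepCows)
  rec <- drpA[drpA$animal_id %in% refIds, , drop = FALSE]
  if (nrow(rec) < 10L)
    stop("fewer than 10 reference records after cow removal")
  fit <- singleTraitGblup(modelSpec(rec, grmA), tol = config$remlTol,
                          maxIter = config$remlMaxIter)
  rel <- .bullReliability(fit$gebv, "traitA", report$split, drpA, ped)
  data.frame(reliability_baseline = report$bull$reliability_single,
             reliability_reduced = rel,
             change = rel - report$bull$reliability_single,
             n_reference_baseline = report$meta$nReferenceRecords,
             n_reference_reduced = nrow(rec))
}
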