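## Forward-in-time simulator of two related dairy-cattle-like populations:
## drift-generated LD in a finite base population, a split with subsequent
## divergence, correlated trait architectures across the populations,
## half-sib family structure with selection-induced genetic trend, and DRP
## phenotypes with a prescribed reliability.

#' Construct a simulation configuration
#'
#' Defaults emulate the study system: two Holstein-like populations sharing
#' ancestry a few generations back, a small mixed population A (80 bulls plus
#' ~1.6k cows in half-sib families) and a large bull population B (~4.4k),
#' with 54K-chip-like marker density scaled down to 2 chromosomes x 500 loci,
#' milk-yield-like heritability 0.3 and a cross-population genetic
#' correlation of 0.8.
#'
#' @param nChromosomes,chromLengthMorgans,nMarkersPerChrom genome layout;
#'   loci are equally spaced in Morgans and mapped to bp at 1 Mb/cM.
#' @param Ne diploid size of the randomly mating base population.
#' @param nBurninGenerations random-mating generations before the split
#'   (builds drift-recombination LD; ~2*Ne approaches equilibrium).
#' @param nDivergenceGenerations generations of separate random mating after
#'   the split.
#' @param splitSizes diploid sizes of populations A and B after the split.
#' @param nQtl number of loci given additive trait effects.
#' @param h2 heritability of the trait in (0, 1].
#' @param rG target cross-population genetic correlation.
#' @param trendPerYear genetic trend among bull cohorts, in genetic-SD
#'   units per birth year; 0 disables sire selection.
#' @param seed integer seed for all simulator randomness.
#' @return A [SimConfig-class] object.
#' @export
simConfig <- function(nChromosomes = 2, chromLengthMorgans = 1,
                      nMarkersPerChrom = 500, Ne = 100,
                      nBurninGenerations = 200, nDivergenceGenerations = 5,
                      splitSizes = c(2000, 4398), nQtl = 100, h2 = 0.3,
                      rG = 0.8, trendPerYear = 0.1, seed = 1) {
  new("SimConfig",
      nChromosomes = as.integer(nChromosomes),
      chromLengthMorgans = as.numeric(chromLengthMorgans),
      nMarkersPerChrom = as.integer(nMarkersPerChrom),
      Ne = as.integer(Ne),
      nBurninGenerations = as.integer(nBurninGenerations),
      nDivergenceGenerations = as.integer(nDivergenceGenerations),
      splitSizes = as.integer(splitSizes),
      nQtl = as.integer(nQtl), h2 = as.numeric(h2), rG = as.numeric(rG),
      trendPerYear = as.numeric(trendPerYear), seed = as.integer(seed))
}

# Marker map for a SimConfig: loci equally spaced in Morgans, bp at 1 Mb/cM
# (1 Morgan = 1e8 bp), 1-based positions.
simMap <- function(config) {
  M <- config@nMarkersPerChrom
  L <- config@chromLengthMorgans
  morgan <- if (M == 1L) 0 else (seq_len(M) - 1L) * L / (M - 1L)
  do.call(rbind, lapply(seq_len(config@nChromosomes), function(ch) {
    data.frame(chrom = ch, pos = as.integer(round(morgan * 1e8)) + 1L,
               id = sprintf("m%d_%d", ch, seq_len(M)))
  }))
}

# Per-chromosome recombination fractions between adjacent markers:
# Haldane map function r = (1 - exp(-2d)) / 2 at map distance d Morgans
# (bp -> Morgans at 1e8 bp/Morgan), no interference.
recombFractions <- function(map) {
  lapply(split(map$pos, map$chrom), function(pos) {
    d <- diff(pos) / 1e8
    0.5 * (1 - exp(-2 * d))
  })
}

# One round of meioses. hap: (2 x P) x M parental haplotypes; parentIdx:
# parent index (1..P) per gamete. Strand choice is a Markov walk along each
# chromosome: start strand Bernoulli(1/2), switch between adjacent markers
# with the Haldane recombination fraction.
.meiosis <- function(hap, map, rfrac, parentIdx) {
  G <- length(parentIdx)
  out <- matrix(0L, G, ncol(hap))
  chroms <- unique(map$chrom)
  for (ci in seq_along(chroms)) {
    cols <- which(map$chrom == chroms[ci])
    M <- length(cols)
    r <- rfrac[[ci]]
    s0 <- rbinom(G, 1L, 0.5)
    if (M > 1L) {
      sw <- matrix(rbinom(G * (M - 1L), 1L, rep(r, each = G)), G, M - 1L)
      strand <- (s0 + cbind(0L, t(apply(sw, 1L, cumsum)))) %% 2L
    } else {
      strand <- matrix(s0, G, 1L)
    }
    rowIdx <- 2L * (parentIdx - 1L) + 1L + strand            # G x M
    idx <- cbind(as.vector(rowIdx), rep(cols, each = G))
    out[, cols] <- matrix(hap[idx], G, M)
  }
  out
}

# One generation of random mating: N offspring, each from two distinct
# parents drawn uniformly; returns a (2 x N) x M haplotype matrix.
.nextGeneration <- function(hap, map, rfrac, N) {
  P <- nrow(hap) %/% 2L
  sires <- sample.int(P, N, replace = TRUE)
  dams <- sample.int(P, N, replace = TRUE)
  clash <- which(dams == sires)
  while (length(clash) && P > 1L) {
    dams[clash] <- sample.int(P, length(clash), replace = TRUE)
    clash <- clash[dams[clash] == sires[clash]]
  }
  g1 <- .meiosis(hap, map, rfrac, sires)
  g2 <- .meiosis(hap, map, rfrac, dams)
  out <- matrix(0L, 2L * N, ncol(hap))
  out[seq(1L, 2L * N, 2L), ] <- g1
  out[seq(2L, 2L * N, 2L), ] <- g2
  out
}

.newHaplotypeSet <- function(popId, hap, map, animalIds) {
  rownames(hap) <- NULL
  new("HaplotypeSet", popId = popId, animalIds = animalIds,
      map = map[, c("chrom", "pos", "id", intersect("low_maf", names(map)))],
      haplo = hap)
}

#' Simulate the randomly mating base population
#'
#' Initializes allele frequencies from U(0.05, 0.95), draws `2 * Ne`
#' independent haplotypes, then runs `nBurninGenerations` of random mating
#' with recombination (Haldane map function, no interference) so that
#' drift builds linkage disequilibrium towards the drift-recombination
#' equilibrium E(r^2) ~ 1 / (1 + 4 Ne c). Markers with final MAF < 0.01 are
#' flagged in the map column `low_maf`.
#'
#' @param config a [SimConfig-class].
#' @return A [HaplotypeSet-class] with `Ne` animals.
#' @export
simulateBasePopulation <- function(config) {
  validObject(config)
  if (config@Ne < 2L) stop("invalid config: Ne must be >= 2")
  map <- simMap(config)
  if (nrow(map) == 0L) stop("invalid config: zero markers")
  set.seed(childSeed(config@seed, 1L))
  rfrac <- recombFractions(map)
  M <- nrow(map)
  p0 <- runif(M, 0.05, 0.95)
  hap <- matrix(rbinom(2L * config@Ne * M, 1L, rep(p0, each = 2L * config@Ne)),
                2L * config@Ne, M)
  for (g in seq_len(config@nBurninGenerations))
    hap <- .nextGeneration(hap, map, rfrac, config@Ne)
  p <- colMeans(hap)
  map$low_maf <- pmin(p, 1 - p) < 0.01
  .newHaplotypeSet("base", hap, map,
                   sprintf("base_%d", seq_len(config@Ne)))
}

#' Split the base population and let the branches diverge
#'
#' Founds populations A and B from samples of the base population (disjoint
#' by default; `founderOverlap` > 0 lets a fraction of A's founders also
#' found B) and mates each branch separately for `nDivergenceGenerations`
#' at sizes `splitSizes`. With zero divergence generations the populations
#' are the founder samples themselves — two draws from one gene pool.
#'
#' @param base [HaplotypeSet-class] from [simulateBasePopulation()].
#' @param config a [SimConfig-class].
#' @param founderOverlap fraction of shared founders in [0, 1).
#' @param founderSizes number of base animals founding each branch; default
#'   splits the base evenly.
#' @return List with elements `popA` and `popB`, both [HaplotypeSet-class].
#' @export
splitAndDiverge <- function(base, config, founderOverlap = 0,
                            founderSizes = NULL) {
  stopifnot(is(base, "HaplotypeSet"))
  nBase <- length(base@animalIds)
  if (nBase == 0L) stop("base population is empty")
  if (any(config@splitSizes < 1L))
    stop("degenerate split: both split sizes must be >= 1")
  if (is.null(founderSizes)) {
    founderSizes <- c(nBase %/% 2L, nBase - nBase %/% 2L)
  }
  nShared <- floor(founderOverlap * min(founderSizes))
  if (founderSizes[1] + founderSizes[2] - nShared > nBase)
    stop("split sizes exceed available founders")
  set.seed(childSeed(config@seed, 2L))
  idxA <- sample.int(nBase, founderSizes[1])
  poolB <- setdiff(seq_len(nBase), idxA)
  idxB <- c(sample(idxA, nShared),
            sample(poolB, founderSizes[2] - nShared))
  rfrac <- recombFractions(base@map)
  grow <- function(founderIdx, size, popId) {
    rows <- as.vector(rbind(2L * founderIdx - 1L, 2L * founderIdx))
    hap <- base@haplo[rows, , drop = FALSE]
    gens <- config@nDivergenceGenerations
    if (gens == 0L) {
      ids <- base@animalIds[founderIdx]
    } else {
      for (g in seq_len(gens)) hap <- .nextGeneration(hap, base@map, rfrac, size)
      ids <- sprintf("%s_%d", popId, seq_len(size))
    }
    .newHaplotypeSet(popId, hap, base@map, ids)
  }
  list(popA = grow(idxA, config@splitSizes[1], "A"),
       popB = grow(idxB, config@splitSizes[2], "B"))
}

#' Assign a correlated trait architecture to two populations
#'
#' Samples `nQtl` QTL positions among the simulated loci and, per QTL, a
#' pair of additive effects (one per population-trait) from a bivariate
#' normal with correlation `rG`, so that the same biological trait behaves
#' as two correlated traits across populations. Effects are scaled within
#' each population so the true-breeding-value (TBV) variance equals `h2`
#' on a unit total-variance scale.
#'
#' @param popA,popB [HaplotypeSet-class] objects sharing one marker map.
#' @param config a [SimConfig-class] (uses `nQtl`, `h2`, `rG`).
#' @param seed integer; defaults to a sub-stream of `config@seed`.
#' @return A `TraitArchitecture` list: `qtlIdx` (column indices of QTL),
#'   `effects` (nQtl x 2 matrix), `tbv` (list `A`, `B` of named TBV
#'   vectors), `h2`, `rG`.
#' @export
assignTraitArchitecture <- function(popA, popB, config, seed = NULL) {
  if (abs(config@rG) > 1) stop("|rG| must be <= 1")
  M <- nrow(popA@map)
  if (config@nQtl > M) stop("nQtl exceeds marker count")
  set.seed(if (is.null(seed)) childSeed(config@seed, 3L) else seed)
  qtl <- sort(sample.int(M, config@nQtl))
  a1 <- rnorm(config@nQtl)
  a2 <- config@rG * a1 + sqrt(1 - config@rG^2) * rnorm(config@nQtl)
  QA <- haploToDosage(popA@haplo)[, qtl, drop = FALSE]
  QB <- haploToDosage(popB@haplo)[, qtl, drop = FALSE]
  sA <- drop(QA %*% a1); sB <- drop(QB %*% a2)
  vA <- var(sA); vB <- var(sB)
  if (vA <= 0 || vB <= 0)
    stop("all sampled QTL are monomorphic; cannot scale effects")
  eff <- cbind(A = a1 * sqrt(config@h2 / vA), B = a2 * sqrt(config@h2 / vB))
  tbvA <- drop(QA %*% eff[, 1]); names(tbvA) <- popA@animalIds
  tbvB <- drop(QB %*% eff[, 2]); names(tbvB) <- popB@animalIds
  structure(list(qtlIdx = qtl, effects = eff,
                 tbv = list(A = tbvA, B = tbvB),
                 h2 = config@h2, rG = config@rG),
            class = "TraitArchitecture")
}

#' Recompute true breeding values from a trait architecture
#'
#' @param haps a [HaplotypeSet-class].
#' @param arch a `TraitArchitecture` from [assignTraitArchitecture()].
#' @param trait 1 for the population-A trait, 2 for the population-B trait.
#' @return Named numeric vector of TBV.
#' @export
computeTbv <- function(haps, arch, trait = 1L) {
  Q <- haploToDosage(haps@haplo)[, arch$qtlIdx, drop = FALSE]
  tbv <- drop(Q %*% arch$effects[, trait])
  names(tbv) <- haps@animalIds
  tbv
}

# Truncation-selection proportion whose selection intensity yields the
# requested per-year gain with sire-side selection only:
# deltaG = i(p) * sigma_g / 2, accuracy 1 on TBV.
.selProportionFor <- function(trendPerYear) {
  if (trendPerYear <= 0) return(1)
  target_i <- 2 * trendPerYear
  f <- function(p) dnorm(qnorm(1 - p)) / p - target_i
  if (f(0.99) > 0) return(0.99)
  if (f(0.01) < 0) return(0.01)
  uniroot(f, c(0.01, 0.99))$root
}

# Draw half-sib family sizes summing to nCows within [lo, hi]: translated
# exponential draws (right-skewed, as observed daughter counts are), then
# unit adjustments on random families to hit the total exactly.
.familySizes <- function(nSires, nCows, lo, hi) {
  if (nSires * lo > nCows)
    stop("requested daughters exceed population size: ",
         nSires, " families of >= ", lo, " cows need more than ", nCows)
  if (nSires * hi < nCows)
    stop("family-size upper bound too small for ", nCows, " cows")
  mu <- nCows / nSires
  sizes <- pmin(hi, lo + round(rexp(nSires, 1 / max(mu - lo, 1e-9))))
  guard <- 0L
  while (sum(sizes) != nCows && (guard <- guard + 1L) < 100000L) {
    if (sum(sizes) < nCows) {
      k <- which(sizes < hi); i <- if (length(k) == 1L) k else sample(k, 1L)
      sizes[i] <- sizes[i] + 1L
    } else {
      k <- which(sizes > lo); i <- if (length(k) == 1L) k else sample(k, 1L)
      sizes[i] <- sizes[i] - 1L
    }
  }
  if (sum(sizes) != nCows) stop("could not balance family sizes")
  sizes
}

#' Build bull cohorts and half-sib cow families in population A
#'
#' Designates bull cohorts across birth years (later cohorts are bred from
#' sires truncation-selected on TBV, producing a positive genetic trend when
#' `trendPerYear > 0`), then generates cows as daughters of `nSires` of the
#' bulls in half-sib families whose sizes are drawn within
#' `familySizeRange`. Daughter haplotypes are produced by meiosis from the
#' sire and a dam drawn from population-A females, so genomic relationships
#' (daughter-sire ~0.5, half-sibs ~0.25) are realized in the marker data.
#'
#' @param popA [HaplotypeSet-class] for population A.
#' @param arch `TraitArchitecture` (TBV are needed for selection).
#' @param config [SimConfig-class] (uses `trendPerYear`, `seed`).
#' @param nBulls,nSires,nCows cohort sizes; defaults mirror a small national
#'   population: 80 bulls, 13 of them sires of 1572 cows.
#' @param bullYears,cowYears birth-year ranges.
#' @param familySizeRange inclusive bounds on daughters per sire.
#' @param selProportion proportion of bulls selected as sires of the next
#'   cohort; default calibrated from `trendPerYear`.
#' @param seed integer; defaults to a sub-stream of `config@seed`.
#' @return List: `haplotypes` ([HaplotypeSet-class] over popA base animals,
#'   bulls and cows) and `pedigree` (data.frame with `animal_id`, `sire_id`,
#'   `dam_id`, `birth_year`, `sex`, `population`, `family`, `role`).
#' @export
buildFamilyStructure <- function(popA, arch, config,
                                 nBulls = 80, nSires = 13, nCows = 1572,
                                 bullYears = 1993:2002, cowYears = 2001:2006,
                                 familySizeRange = c(63, 358),
                                 selProportion = NULL, seed = NULL) {
  stopifnot(is(popA, "HaplotypeSet"))
  nA <- length(popA@animalIds)
  if (nBulls > nA) stop("not enough population-A animals for ", nBulls, " bulls")
  set.seed(if (is.null(seed)) childSeed(config@seed, 4L) else seed)
  if (is.null(selProportion)) selProportion <- .selProportionFor(config@trendPerYear)
  rfrac <- recombFractions(popA@map)
  sex <- sample(rep(c("M", "F"), length.out = nA))
  males <- which(sex == "M"); females <- which(sex == "F")
  if (length(males) == 0L || length(females) == 0L)
    stop("population A must contain both sexes")

  nYears <- length(bullYears)
  perYear <- diff(round(seq(0, nBulls, length.out = nYears + 1)))
  hap <- popA@haplo
  ids <- popA@animalIds
  ped <- data.frame(animal_id = ids, sire_id = "0", dam_id = "0",
                    birth_year = NA_integer_, sex = sex, population = "A",
                    family = NA_character_, role = "base",
                    stringsAsFactors = FALSE)
  tbv <- computeTbv(popA, arch, 1L)
  sigmaG <- sd(tbv)

  bullIdx <- integer(0)                      # indices into hap-animal order
  addAnimals <- function(newHap, newIds, sires, dams, year, sx, role, fam = NA) {
    hap <<- rbind(hap, newHap)
    ids <<- c(ids, newIds)
    ped <<- rbind(ped, data.frame(
      animal_id = newIds, sire_id = sires, dam_id = dams,
      birth_year = year, sex = sx, population = "A",
      family = fam, role = role, stringsAsFactors = FALSE))
    newTbv <- drop(haploToDosage(newHap)[, arch$qtlIdx, drop = FALSE] %*%
                     arch$effects[, 1])
    names(newTbv) <- newIds
    tbv <<- c(tbv, newTbv)
  }

  for (t in seq_len(nYears)) {
    n_t <- perYear[t]
    if (n_t == 0L) next
    if (t == 1L || length(bullIdx) == 0L) {
      pick <- sample(males, n_t)
      bullIdx <- c(bullIdx, pick)
      ped$birth_year[pick] <- bullYears[t]
      ped$role[pick] <- "bull"
    } else {
      cand <- bullIdx
      nSel <- max(1L, ceiling(selProportion * length(cand)))
      sel <- if (config@trendPerYear > 0) {
        cand[order(tbv[ids[cand]], decreasing = TRUE)[seq_len(nSel)]]
      } else sample(cand, nSel)
      sirePick <- sel[sample.int(length(sel), n_t, replace = TRUE)]
      damPick <- females[sample.int(length(females), n_t, replace = TRUE)]
      g1 <- .meiosis(hap, popA@map, rfrac, sirePick)
      g2 <- .meiosis(hap, popA@map, rfrac, damPick)
      newHap <- matrix(0L, 2L * n_t, ncol(hap))
      newHap[seq(1L, 2L * n_t, 2L), ] <- g1
      newHap[seq(2L, 2L * n_t, 2L), ] <- g2
      newIds <- sprintf("bull_%d_%d", bullYears[t], seq_len(n_t))
      addAnimals(newHap, newIds, ids[sirePick], ids[damPick],
                 bullYears[t], "M", "bull")
      bullIdx <- c(bullIdx, match(newIds, ids))
    }
  }

  bullIds <- ids[bullIdx]
  sireIds <- sample(bullIds, nSires)
  sizes <- .familySizes(nSires, nCows, familySizeRange[1], familySizeRange[2])
  sireOfCow <- rep(match(sireIds, ids), sizes)
  damPick <- females[sample.int(length(females), nCows, replace = TRUE)]
  g1 <- .meiosis(hap, popA@map, rfrac, sireOfCow)
  g2 <- .meiosis(hap, popA@map, rfrac, damPick)
  cowHap <- matrix(0L, 2L * nCows, ncol(hap))
  cowHap[seq(1L, 2L * nCows, 2L), ] <- g1
  cowHap[seq(2L, 2L * nCows, 2L), ] <- g2
  cowIds <- sprintf("cow_%d", seq_len(nCows))
  addAnimals(cowHap, cowIds, ids[sireOfCow], ids[damPick],
             sample(cowYears, nCows, replace = TRUE), "F", "cow",
             fam = ids[sireOfCow])

  list(haplotypes = .newHaplotypeSet("A", hap, popA@map, ids),
       pedigree = ped, sigmaG = sigmaG)
}

#' Generate deregressed proofs from true breeding values
#'
#' DRP_i = TBV_i + eps_i with Var(eps_i) = sigma2g * (1 - r2_i) / r2_i, so
#' the squared correlation between DRP and TBV equals the prescribed
#' reliability r2_i in expectation. `r2 = 1` gives DRP identical to TBV.
#'
#' @param tbv named numeric vector of true breeding values.
#' @param reliability scalar or per-animal vector of DRP reliabilities in
#'   (0, 1].
#' @param sigma2g additive genetic variance on the TBV scale.
#' @param trait trait label for the output table.
#' @param seed optional integer seed.
#' @return data.frame with columns `animal_id`, `trait`, `drp`, `r2_drp`.
#' @export
generateDrp <- function(tbv, reliability, sigma2g, trait = "trait1",
                        seed = NULL) {
  r2 <- rep_len(reliability, length(tbv))
  if (any(r2 <= 0 | r2 > 1)) stop("reliabilities must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  noiseSd <- sqrt(sigma2g * (1 - r2) / r2)
  data.frame(animal_id = names(tbv), trait = trait,
             drp = as.numeric(tbv) + rnorm(length(tbv), 0, noiseSd),
             r2_drp = r2, stringsAsFactors = FALSE)
}
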