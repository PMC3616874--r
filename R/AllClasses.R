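#' @import methods
#' @importFrom stats rnorm runif rbinom rexp cor var lm residuals coef sd
#' @importFrom stats dnorm qnorm uniroot
#' @importFrom utils read.table write.table head
NULL

## Central S4 containers. Marker maps are plain data.frames with columns
## chrom (integer), pos (1-based bp), id (character) and, for GenotypeSet,
## counted_allele (character): the allele whose copies the dosage counts.

.validMap <- function(map, need_allele = FALSE) {
  need <- c("chrom", "pos", "id")
  if (need_allele) need <- c(need, "counted_allele")
  if (!is.data.frame(map) || !all(need %in% names(map)))
    return(paste0("marker map must have columns ", paste(need, collapse = ", ")))
  if (anyDuplicated(map$id)) return("duplicate marker ids in map")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (length(p) > 1 && any(diff(p) <= 0))
      return(sprintf("positions not strictly increasing on chromosome %s", ch))
  }
  TRUE
}

#' GenotypeSet: allele-count genotypes with a marker map
#'
#' Holds biallelic SNP genotypes for one named population as counted-allele
#' dosages in \{0, 1, 2, NA\}, together with the marker map (chromosome,
#' 1-based bp position, marker id, counted allele label).
#'
#' @slot popId single population label.
#' @slot animalIds character vector, one per row of `dosage`.
#' @slot map data.frame with columns `chrom`, `pos`, `id`, `counted_allele`,
#'   sorted by (chrom, pos), positions strictly increasing within chromosome.
#' @slot dosage integer matrix, animals x markers, values 0/1/2/NA.
#' @export
setClass("GenotypeSet", representation(
  popId = "character", animalIds = "character",
  map = "data.frame", dosage = "matrix"))

setValidity("GenotypeSet", function(object) {
  msgs <- character()
  ok <- .validMap(object@map, need_allele = TRUE)
  if (!isTRUE(ok)) msgs <- c(msgs, ok)
  if (nrow(object@dosage) != length(object@animalIds))
    msgs <- c(msgs, "dosage rows != number of animals")
  if (ncol(object@dosage) != nrow(object@map))
    msgs <- c(msgs, "dosage columns != number of mapped markers")
  v <- object@dosage[!is.na(object@dosage)]
  if (length(v) && !all(v %in% 0:2))
    msgs <- c(msgs, "dosages must be 0, 1, 2 or NA")
  if (anyDuplicated(object@animalIds))
    msgs <- c(msgs, "duplicate animal ids")
  if (length(msgs)) msgs else TRUE
})

#' HaplotypeSet: phased 0/1 haplotypes with a marker map
#'
#' Phased haplotypes for one population: two haplotype rows per animal
#' (maternal and paternal), alleles coded 0/1, over a shared marker map.
#' Rows `2i - 1` and `2i` belong to animal `i`.
#'
#' @slot popId population label.
#' @slot animalIds character, one per animal.
#' @slot map data.frame with `chrom`, `pos`, `id`.
#' @slot haplo integer matrix, (2 x animals) x markers, values 0/1.
#' @export
setClass("HaplotypeSet", representation(
  popId = "character", animalIds = "character",
  map = "data.frame", haplo = "matrix"))

setValidity("HaplotypeSet", function(object) {
  msgs <- character()
  ok <- .validMap(object@map)
  if (!isTRUE(ok)) msgs <- c(msgs, ok)
  if (nrow(object@haplo) != 2L * length(object@animalIds))
    msgs <- c(msgs, "haplotype rows must be exactly 2 per animal")
  if (ncol(object@haplo) != nrow(object@map))
    msgs <- c(msgs, "haplotype columns != number of mapped markers")
  if (length(object@haplo) && !all(object@haplo %in% 0:1))
    msgs <- c(msgs, "haplotype alleles must be 0/1")
  if (length(msgs)) msgs else TRUE
})

#' GRM: genomic relationship matrix
#'
#' Symmetric genomic relationship matrix over an ordered animal list, built
#' by VanRaden's method 1, storing the allele frequencies used and the ridge
#' added to the diagonal.
#'
#' @slot animalIds ordered animal ids (row/column names of `mat`).
#' @slot mat numeric symmetric matrix.
#' @slot p allele frequencies used for centering/scaling.
#' @slot ridge value added to the diagonal.
#' @export
setClass("GRM", representation(
  animalIds = "character", mat = "matrix", p = "numeric", ridge = "numeric"))

setValidity("GRM", function(object) {
  msgs <- character()
  n <- length(object@animalIds)
  if (!all(dim(object@mat) == c(n, n)))
    msgs <- c(msgs, "matrix dimension != number of animals")
  else if (max(abs(object@mat - t(object@mat))) > 1e-10)
    msgs <- c(msgs, "matrix not symmetric within 1e-10")
  if (length(msgs)) msgs else TRUE
})

#' SimConfig: configuration of the two-population simulator
#'
#' @slot nChromosomes,chromLengthMorgans,nMarkersPerChrom genome layout;
#'   markers are equally spaced in Morgans, bp assigned at 1 Mb/cM.
#' @slot Ne effective (census) size of the randomly mating base population.
#' @slot nBurninGenerations generations of random mating before the split.
#' @slot nDivergenceGenerations generations after the split.
#' @slot splitSizes diploid sizes of populations A and B after the split.
#' @slot nQtl number of loci carrying trait effects.
#' @slot h2 trait heritability in (0, 1].
#' @slot rG target cross-population genetic correlation in [-1, 1].
#' @slot trendPerYear genetic trend in genetic-SD units per birth year
#'   (0 disables sire selection).
#' @slot seed integer seed; all simulator randomness derives from it.
#' @export
setClass("SimConfig", representation(
  nChromosomes = "integer", chromLengthMorgans = "numeric",
  nMarkersPerChrom = "integer", Ne = "integer",
  nBurninGenerations = "integer", nDivergenceGenerations = "integer",
  splitSizes = "integer", nQtl = "integer", h2 = "numeric",
  rG = "numeric", trendPerYear = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msgs <- character()
  cnt <- c(nChromosomes = object@nChromosomes,
           nMarkersPerChrom = object@nMarkersPerChrom,
           Ne = object@Ne, splitSizes = object@splitSizes,
           nQtl = object@nQtl)
  if (any(cnt < 1L)) msgs <- c(msgs, "all counts must be >= 1")
  if (object@Ne < 2L) msgs <- c(msgs, "Ne must be >= 2")
  if (object@nBurninGenerations < 0L || object@nDivergenceGenerations < 0L)
    msgs <- c(msgs, "generation counts must be >= 0")
  if (object@chromLengthMorgans <= 0) msgs <- c(msgs, "chromosome length must be > 0")
  if (object@h2 <= 0 || object@h2 > 1) msgs <- c(msgs, "h2 must be in (0, 1]")
  if (abs(object@rG) > 1) msgs <- c(msgs, "|rG| must be <= 1")
  if (object@nQtl > object@nChromosomes * object@nMarkersPerChrom)
    msgs <- c(msgs, "nQtl exceeds total marker count")
  if (length(msgs)) msgs else TRUE
})

#' VarianceComponents: (co)variance estimates of a GBLUP model
#'
#' Per-trait additive genetic and residual variances; for the two-trait
#' across-population model also the genetic covariance and the derived
#' genetic correlation rG = sigma_g12 / sqrt(sigma2_g1 * sigma2_g2).
#'
#' @slot traits trait labels (length 1 or 2).
#' @slot sigma2g additive genetic variance per trait.
#' @slot sigmaG12 genetic covariance between the two population-traits
#'   (NA for single-trait models).
#' @slot sigma2e residual variance per trait.
#' @slot rG derived genetic correlation (NA for single-trait models).
#' @slot se asymptotic standard errors from the inverse average-information
#'   matrix, ordered (sigma2g1, [sigmaG12,] [sigma2g2,] sigma2e1,
#'   [sigma2e2]); empty when not estimated.
#' @slot converged logical convergence flag.
#' @slot logLik restricted log-likelihood at the estimates.
#' @slot iterations iterations used.
#' @export
setClass("VarianceComponents", representation(
  traits = "character", sigma2g = "numeric", sigmaG12 = "numeric",
  sigma2e = "numeric", rG = "numeric", se = "numeric", converged = "logical",
  logLik = "numeric", iterations = "integer"))

setValidity("VarianceComponents", function(object) {
  msgs <- character()
  nt <- length(object@traits)
  if (length(object@sigma2g) != nt || length(object@sigma2e) != nt)
    msgs <- c(msgs, "one genetic and one residual variance per trait required")
  if (any(object@sigma2g < 0) || any(object@sigma2e < 0))
    msgs <- c(msgs, "variances must be >= 0")
  if (nt == 2L && !is.na(object@sigmaG12)) {
    den <- sqrt(prod(object@sigma2g))
    if (den > 0 && abs(object@sigmaG12) > den + 1e-8)
      msgs <- c(msgs, "genetic covariance implies |rG| > 1")
  }
  if (length(msgs)) msgs else TRUE
})

## ---- show methods -------------------------------------------------------

setMethod("show", "GenotypeSet", function(object) {
  cat(sprintf("GenotypeSet '%s': %d animals x %d markers on %d chromosome(s)\n",
              object@popId, length(object@animalIds), nrow(object@map),
              length(unique(object@map$chrom))))
  nm <- sum(is.na(object@dosage))
  cat(sprintf("  missing calls: %d (%.2f%%)\n", nm,
              100 * nm / max(1, length(object@dosage))))
})

setMethod("show", "HaplotypeSet", function(object) {
  cat(sprintf("HaplotypeSet '%s': %d animals (%d haplotypes) x %d markers on %d chromosome(s)\n",
              object@popId, length(object@animalIds), nrow(object@haplo),
              nrow(object@map), length(unique(object@map$chrom))))
})

setMethod("show", "GRM", function(object) {
  n <- length(object@animalIds)
  cat(sprintf("GRM: %d x %d, mean diagonal %.3f, ridge %g\n",
              n, n, mean(diag(object@mat)), object@ridge))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0("SimConfig: %d chrom x %d markers (%.2f M each), Ne=%d, ",
                     "burn-in %d, divergence %d, split (%d, %d)\n",
                     "  nQtl=%d, h2=%.2f, rG=%.2f, trend %.3f SD/yr, seed %d\n"),
              object@nChromosomes, object@nMarkersPerChrom,
              object@chromLengthMorgans, object@Ne,
              object@nBurninGenerations, object@nDivergenceGenerations,
              object@splitSizes[1], object@splitSizes[2], object@nQtl,
              object@h2, object@rG, object@trendPerYear, object@seed))
})

setMethod("show", "VarianceComponents", function(object) {
  cat("VarianceComponents (", if (object@converged) "converged" else "NOT converged",
      ", ", object@iterations, " iterations, logLik ",
      sprintf("%.4f", object@logLik), ")\n", sep = "")
  for (i in seq_along(object@traits))
    cat(sprintf("  %s: sigma2_g = %.4f, sigma2_e = %.4f\n",
                object@traits[i], object@sigma2g[i], object@sigma2e[i]))
  if (length(object@traits) == 2L && !is.na(object@rG))
    cat(sprintf("  genetic covariance = %.4f, rG = %.4f\n",
                object@sigmaG12, object@rG))
})

## ---- accessors ----------------------------------------------------------

#' Accessors for the core containers
#'
#' `animalIds()` returns the ordered animal ids; `markerMap()` the marker map
#' data.frame; `dosages()` the animals x markers dosage matrix of a
#' [GenotypeSet]; `haplotypes()` the (2 x animals) x markers 0/1 matrix of a
#' [HaplotypeSet]; `grmMatrix()` the relationship matrix of a [GRM].
#'
#' @param x a GenotypeSet, HaplotypeSet or GRM.
#' @return See the per-accessor description.
#' @name accessors
#' @aliases animalIds markerMap dosages haplotypes grmMatrix popId
NULL

#' @rdname accessors
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))
#' @rdname accessors
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))
#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("haplotypes", function(x) standardGeneric("haplotypes"))
#' @rdname accessors
#' @export
setGeneric("grmMatrix", function(x) standardGeneric("grmMatrix"))
#' @rdname accessors
#' @export
setGeneric("popId", function(x) standardGeneric("popId"))

#' @rdname accessors
setMethod("animalIds", "GenotypeSet", function(x) x@animalIds)
#' @rdname accessors
setMethod("animalIds", "HaplotypeSet", function(x) x@animalIds)
#' @rdname accessors
setMethod("animalIds", "GRM", function(x) x@animalIds)
#' @rdname accessors
setMethod("markerMap", "GenotypeSet", function(x) x@map)
#' @rdname accessors
setMethod("markerMap", "HaplotypeSet", function(x) x@map)
#' @rdname accessors
setMethod("dosages", "GenotypeSet", function(x) x@dosage)
#' @rdname accessors
setMethod("haplotypes", "HaplotypeSet", function(x) x@haplo)
#' @rdname accessors
setMethod("grmMatrix", "GRM", function(x) x@mat)
#' @rdname accessors
setMethod("popId", "GenotypeSet", function(x) x@popId)
#' @rdname accessors
setMethod("popId", "HaplotypeSet", function(x) x@popId)
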