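## Pairwise linkage disequilibrium from phased haplotypes, adjacent-pair LD
## tables, marker-distance summaries, the cross-population LD-consistency
## statistic, and an EM fallback for unphased genotypes.

#' Haplotype and allele frequencies for a marker pair
#'
#' Counts over all pooled haplotypes (maternal and paternal, 2 per animal).
#' "A"/"B" denote the 1-coded allele at the first/second marker.
#'
#' @param haps a [HaplotypeSet-class].
#' @param i,j marker column indices.
#' @return List: `fAB` frequency of the 1-1 haplotype, `fA`, `fB` allele-1
#'   frequencies, `n` number of haplotypes counted.
#' @export
haplotypeFrequencies <- function(haps, i, j) {
  M <- ncol(haps@haplo)
  if (any(c(i, j) < 1L) || any(c(i, j) > M))
    stop("marker index out of range (1..", M, ")")
  hi <- haps@haplo[, i]; hj <- haps@haplo[, j]
  list(fAB = mean(hi == 1L & hj == 1L), fA = mean(hi), fB = mean(hj),
       n = length(hi))
}

#' Signed LD correlation between two loci
#'
#' r = (f(AB) - f(A) f(B)) / sqrt(f(A) f(a) f(B) f(b)). Undefined (NA) when
#' either locus is monomorphic; never coerced to 0.
#'
#' @param fAB haplotype frequency of the A-B haplotype.
#' @param fA,fB allele frequencies. All arguments are vectorized.
#' @return Numeric vector of signed r values (NA where undefined).
#' @export
rLd <- function(fAB, fA, fB) {
  den <- fA * (1 - fA) * fB * (1 - fB)
  out <- (fAB - fA * fB) / sqrt(den)
  out[den <= 0] <- NA_real_
  out
}

#' LD between adjacent marker pairs
#'
#' One record per adjacent pair within each chromosome (never across
#' chromosomes); pairs with a monomorphic member get `r = NA`. A map with m
#' markers over c chromosomes yields exactly m - c records.
#'
#' @param haps a [HaplotypeSet-class] with at least 2 markers on some
#'   chromosome.
#' @return data.frame with columns `chrom`, `id1`, `id2`, `distance_bp`,
#'   `fAB`, `fA`, `fB`, `r`, `r2`.
#' @export
adjacentLd <- function(haps) {
  h <- haps@haplo
  map <- haps@map
  out <- lapply(unique(map$chrom), function(ch) {
    cols <- which(map$chrom == ch)
    if (length(cols) < 2L) return(NULL)
    i <- cols[-length(cols)]; j <- cols[-1L]
    fA <- colMeans(h[, i, drop = FALSE])
    fB <- colMeans(h[, j, drop = FALSE])
    fAB <- colMeans(h[, i, drop = FALSE] * h[, j, drop = FALSE])
    r <- rLd(fAB, fA, fB)
    data.frame(chrom = ch, id1 = map$id[i], id2 = map$id[j],
               distance_bp = map$pos[j] - map$pos[i],
               fAB = fAB, fA = fA, fB = fB, r = r, r2 = r^2,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cross-population consistency of LD
#'
#' Pearson correlation, per chromosome, of the signed r of adjacent marker
#' pairs between two populations, over pairs defined (non-monomorphic) in
#' both. The overall consistency is the unweighted mean across chromosomes.
#' Inputs must come from allele-harmonized marker sets
#' ([harmonizeAlleles()]), otherwise systematic allele flips reverse the
#' sign of r in one population.
#'
#' @param a,b adjacent-LD tables from [adjacentLd()] for the two
#'   populations.
#' @param minPairs chromosomes with fewer usable pairs are omitted with a
#'   warning (default 3).
#' @return A `ConsistencySummary` list: `perChrom` (chrom, n_pairs,
#'   consistency), `meanConsistency`, `meanR2` (per population, over pairs
#'   defined in each).
#' @export
ldConsistency <- function(a, b, minPairs = 3L) {
  m <- merge(a, b, by = c("chrom", "id1", "id2"), suffixes = c("_a", "_b"))
  usable <- is.finite(m$r_a) & is.finite(m$r_b)
  m <- m[usable, , drop = FALSE]
  rows <- lapply(sort(unique(m$chrom)), function(ch) {
    mc <- m[m$chrom == ch, , drop = FALSE]
    if (nrow(mc) < minPairs) {
      warning("chromosome ", ch, " omitted: fewer than ", minPairs,
              " usable pairs")
      return(NULL)
    }
    data.frame(chrom = ch, n_pairs = nrow(mc),
               consistency = cor(mc$r_a, mc$r_b))
  })
  perChrom <- do.call(rbind, rows)
  structure(list(
    perChrom = perChrom,
    meanConsistency = if (is.null(perChrom)) NA_real_
                      else mean(perChrom$consistency),
    meanR2 = c(a = mean(a$r2, na.rm = TRUE), b = mean(b$r2, na.rm = TRUE))),
    class = "ConsistencySummary")
}

#' @export
print.ConsistencySummary <- function(x, ...) {
  cat("LD consistency (signed r of adjacent pairs):\n")
  if (!is.null(x$perChrom)) print(x$perChrom, row.names = FALSE)
  cat(sprintf("mean consistency: %.4f; mean r2: %.4f (a), %.4f (b)\n",
              x$meanConsistency, x$meanR2["a"], x$meanR2["b"]))
  invisible(x)
}

#' Per-chromosome marker-distance summary
#'
#' Mean gap per chromosome is span / (n - 1), where the span is the reported
#' chromosome length when supplied and the covered range max(pos) - min(pos)
#' otherwise. The overall mean gap is the unweighted average of the
#' per-chromosome means.
#'
#' @param map data.frame with `chrom` and `pos` (bp), sorted within
#'   chromosome.
#' @param lengths optional numeric vector of chromosome lengths in bp, named
#'   by chromosome.
#' @param gapThresholdBp gaps larger than this are counted as "large"
#'   (default 200 kb).
#' @return List: `perChrom` data.frame (`chrom`, `length_bp`, `n_markers`,
#'   `mean_gap_bp`, `min_gap_bp`, `max_gap_bp`, `frac_large_gaps`),
#'   `meanGapBp` (unweighted chromosome average) and `fracLargeGaps`
#'   (over all gaps).
#' @export
distanceSummary <- function(map, lengths = NULL, gapThresholdBp = 2e5) {
  chroms <- unique(map$chrom)
  rows <- lapply(chroms, function(ch) {
    pos <- sort(map$pos[map$chrom == ch])
    n <- length(pos)
    span <- if (!is.null(lengths) && as.character(ch) %in% names(lengths))
      lengths[[as.character(ch)]] else if (n > 1) max(pos) - min(pos) else NA
    gaps <- if (n > 1) diff(pos) else numeric(0)
    data.frame(chrom = ch, length_bp = span, n_markers = n,
               mean_gap_bp = if (n > 1) span / (n - 1) else NA_real_,
               min_gap_bp = if (n > 1) min(gaps) else NA_real_,
               max_gap_bp = if (n > 1) max(gaps) else NA_real_,
               frac_large_gaps = if (n > 1) mean(gaps > gapThresholdBp)
                                 else NA_real_)
  })
  perChrom <- do.call(rbind, rows)
  allGaps <- unlist(lapply(chroms, function(ch)
    diff(sort(map$pos[map$chrom == ch]))))
  list(perChrom = perChrom,
       meanGapBp = mean(perChrom$mean_gap_bp, na.rm = TRUE),
       fracLargeGaps = if (length(allGaps)) mean(allGaps > gapThresholdBp)
                       else NA_real_)
}

#' EM estimate of a two-locus haplotype frequency from unphased genotypes
#'
#' Fallback when phased haplotypes are unavailable: estimates f(AB) under
#' Hardy-Weinberg and random mating. Only double heterozygotes are phase
#' ambiguous; all other genotype pairs contribute determined haplotype
#' counts. Missing genotypes are excluded pairwise.
#'
#' @param gi,gj dosage vectors (0/1/2/NA) at the two loci, counting the
#'   "A"/"B" allele respectively.
#' @param tol convergence tolerance on the change in f(AB) (default 1e-8).
#' @param maxIter iteration cap (default 1000).
#' @return List: `fAB`, `fA`, `fB`, `n` (animals used), `iterations`.
#'   `fAB` is NA when either locus is monomorphic.
#' @export
emPairwiseHaplotypeFreq <- function(gi, gj, tol = 1e-8, maxIter = 1000L) {
  ok <- !is.na(gi) & !is.na(gj)
  gi <- gi[ok]; gj <- gj[ok]
  n <- length(gi)
  if (n == 0L) stop("no jointly non-missing genotype pairs")
  fA <- mean(gi) / 2; fB <- mean(gj) / 2
  if (fA %in% c(0, 1) || fB %in% c(0, 1))
    return(list(fAB = NA_real_, fA = fA, fB = fB, n = n, iterations = 0L))
  # determined haplotype counts; c[a, b] counts haplotype (allele a, allele b)
  cnt <- matrix(0, 2, 2, dimnames = list(c("1", "0"), c("1", "0")))
  dh <- gi == 1L & gj == 1L
  nDh <- sum(dh)
  di <- gi[!dh]; dj <- gj[!dh]
  addHap <- function(ai, aj, k) {
    cnt[2L - ai, 2L - aj] <<- cnt[2L - ai, 2L - aj] + k
  }
  for (a1 in 0:2) for (a2 in 0:2) {
    if (a1 == 1L && a2 == 1L) next
    k <- sum(di == a1 & dj == a2)
    if (!k) next
    al1 <- c(as.integer(a1 >= 1L), as.integer(a1 == 2L))   # two alleles, locus i
    al2 <- c(as.integer(a2 >= 1L), as.integer(a2 == 2L))
    if (a1 == 1L) {            # locus j fixed, alleles at i differ
      addHap(1L, al2[1], k); addHap(0L, al2[1], k)
    } else if (a2 == 1L) {     # locus i fixed, alleles at j differ
      addHap(al1[1], 1L, k); addHap(al1[1], 0L, k)
    } else {
      addHap(al1[1], al2[1], 2 * k)
    }
  }
  tot <- 2 * n
  f11 <- fA * fB   # start at linkage equilibrium
  it <- 0L
  repeat {
    it <- it + 1L
    f10 <- fA - f11; f01 <- fB - f11; f00 <- 1 - fA - fB + f11
    q <- if (nDh) {
      num <- f11 * f00
      den <- num + f10 * f01
      if (den <= 0) 0.5 else num / den
    } else 0
    f11new <- (cnt["1", "1"] + nDh * q) / tot
    if (abs(f11new - f11) < tol || it >= maxIter) { f11 <- f11new; break }
    f11 <- f11new
  }
  list(fAB = f11, fA = fA, fB = fB, n = n, iterations = it)
}
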