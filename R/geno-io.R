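## Readers and writers for genotype, haplotype, pedigree and phenotype
## tables; quality-control filters; allele harmonization across populations.
##
## Supported genotype dialects:
##   * native TSV pair  <prefix>.dosage.tsv (animals x markers) +
##     <prefix>.markers.tsv (chrom, pos, id, counted_allele, other_allele)
##     — full-fidelity round trip;
##   * PLINK-style text .ped/.map, alleles as letters (the .map carries no
##     allele designation, so the counted allele is re-derived on read);
##   * VCF, biallelic SNP records only (via vcfR), ALT is the counted allele.

#' Construct a GenotypeSet
#'
#' Markers are sorted by (chromosome, position); dosage columns are
#' reordered accordingly.
#'
#' @param popId population label.
#' @param animalIds character vector of animal ids.
#' @param map data.frame with `chrom`, `pos`, `id`, `counted_allele` and
#'   optionally `other_allele`.
#' @param dosage animals x markers matrix with values 0/1/2/NA.
#' @return A [GenotypeSet-class].
#' @export
genotypeSet <- function(popId, animalIds, map, dosage) {
  dosage <- as.matrix(dosage)
  mode(dosage) <- "integer"
  o <- order(map$chrom, map$pos)
  map <- map[o, , drop = FALSE]
  rownames(map) <- NULL
  dosage <- dosage[, o, drop = FALSE]
  dimnames(dosage) <- NULL
  new("GenotypeSet", popId = as.character(popId),
      animalIds = as.character(animalIds), map = map, dosage = dosage)
}

#' Collapse phased haplotypes to a GenotypeSet
#'
#' Allele 1 becomes the counted allele (labelled "B"), allele 0 the other
#' allele ("A").
#'
#' @param haps a [HaplotypeSet-class].
#' @return A [GenotypeSet-class].
#' @export
haplotypesToGenotypes <- function(haps) {
  map <- haps@map[, c("chrom", "pos", "id")]
  map$counted_allele <- "B"
  map$other_allele <- "A"
  genotypeSet(haps@popId, haps@animalIds, map, haploToDosage(haps@haplo))
}

## ---- native TSV ---------------------------------------------------------

.writeTsvGenotypes <- function(g, prefix) {
  d <- g@dosage
  dimnames(d) <- list(g@animalIds, g@map$id)
  df <- data.frame(animal_id = rownames(d), d, check.names = FALSE)
  write.table(df, paste0(prefix, ".dosage.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  map <- g@map
  if (is.null(map$other_allele)) map$other_allele <- NA
  write.table(cbind(population = g@popId, map), paste0(prefix, ".markers.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

.readTsvGenotypes <- function(prefix) {
  map <- read.table(paste0(prefix, ".markers.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  df <- read.table(paste0(prefix, ".dosage.tsv"), header = TRUE, sep = "\t",
                   check.names = FALSE, stringsAsFactors = FALSE)
  popId <- as.character(map$population[1])
  keep <- setdiff(names(map), "population")
  dos <- as.matrix(df[, map$id, drop = FALSE])
  genotypeSet(popId, df$animal_id, map[, keep, drop = FALSE], dos)
}

## ---- PLINK-style .ped/.map ----------------------------------------------

.writePedGenotypes <- function(g, prefix) {
  map <- data.frame(chrom = g@map$chrom, id = g@map$id, cm = 0, pos = g@map$pos)
  write.table(map, paste0(prefix, ".map"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  counted <- g@map$counted_allele
  other <- g@map$other_allele %||% rep("A", nrow(g@map))
  other[is.na(other)] <- "A"
  n <- length(g@animalIds); M <- nrow(g@map)
  al <- matrix("0", n, 2L * M)
  for (j in seq_len(M)) {
    x <- g@dosage[, j]
    a1 <- ifelse(is.na(x), "0", ifelse(x >= 1L, counted[j], other[j]))
    a2 <- ifelse(is.na(x), "0", ifelse(x == 2L, counted[j], other[j]))
    al[, 2L * j - 1L] <- a1
    al[, 2L * j] <- a2
  }
  lines <- paste(g@popId, g@animalIds, 0, 0, 0, -9,
                 apply(al, 1L, paste, collapse = " "))
  writeLines(lines, paste0(prefix, ".ped"))
}

.readPedGenotypes <- function(prefix, countedAllele = NULL) {
  map <- read.table(paste0(prefix, ".map"), header = FALSE,
                    col.names = c("chrom", "id", "cm", "pos"),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(map$id))
    stop("duplicate marker id in ", prefix, ".map: ",
         map$id[anyDuplicated(map$id)])
  M <- nrow(map)
  lines <- readLines(paste0(prefix, ".ped"))
  lines <- lines[nzchar(trimws(lines))]
  tok <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(tok) != 6L + 2L * M)
  if (length(bad))
    stop(sprintf("malformed .ped line %d: expected %d fields, got %d",
                 bad[1], 6L + 2L * M, lengths(tok)[bad[1]]))
  tokm <- do.call(rbind, tok)
  popId <- tokm[1, 1]; animalIds <- tokm[, 2]
  a1 <- tokm[, 6L + 2L * seq_len(M) - 1L, drop = FALSE]
  a2 <- tokm[, 6L + 2L * seq_len(M), drop = FALSE]
  counted <- character(M); other <- rep(NA_character_, M)
  dos <- matrix(NA_integer_, length(animalIds), M)
  for (j in seq_len(M)) {
    obs <- setdiff(unique(c(a1[, j], a2[, j])), "0")
    if (length(obs) > 2L)
      stop("marker ", map$id[j], " has more than two alleles")
    cj <- if (!is.null(countedAllele)) countedAllele[j]
          else if (length(obs)) max(sort(obs)) else "B"
    counted[j] <- cj
    oth <- setdiff(obs, cj)
    if (length(oth)) other[j] <- oth
    miss <- a1[, j] == "0" | a2[, j] == "0"
    dos[, j] <- (a1[, j] == cj) + (a2[, j] == cj)
    dos[miss, j] <- NA_integer_
  }
  gmap <- data.frame(chrom = as.integer(map$chrom), pos = as.integer(map$pos),
                     id = map$id, counted_allele = counted,
                     other_allele = other, stringsAsFactors = FALSE)
  genotypeSet(popId, animalIds, gmap, dos)
}

## ---- VCF ----------------------------------------------------------------

.readVcfGenotypes <- function(path, popId = "vcf") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- if (is.matrix(fix)) fix else t(as.matrix(fix))
  biall <- !grepl(",", fix[, "ALT"]) & nchar(fix[, "REF"]) == 1L &
    nchar(fix[, "ALT"]) == 1L
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biall, , drop = FALSE]
  fix <- fix[biall, , drop = FALSE]
  if (nrow(fix) == 0L) stop("no biallelic SNP records in ", path)
  id <- fix[, "ID"]
  noid <- is.na(id) | id == "."
  id[noid] <- paste0(fix[noid, "CHROM"], "_", fix[noid, "POS"])
  if (anyDuplicated(id)) stop("duplicate marker id in ", path)
  countAlt <- function(s) {
    out <- rep(NA_integer_, length(s))
    ok <- !is.na(s) & grepl("^[01]([/|][01])?$", s)
    out[ok] <- vapply(strsplit(s[ok], "[/|]"),
                      function(a) sum(a == "1"), integer(1))
    out
  }
  dos <- t(apply(gt, 1L, countAlt))
  if (ncol(gt) == 1L) dos <- matrix(as.integer(dos), ncol = 1L)
  map <- data.frame(chrom = as.integer(fix[, "CHROM"]),
                    pos = as.integer(fix[, "POS"]), id = id,
                    counted_allele = fix[, "ALT"],
                    other_allele = fix[, "REF"], stringsAsFactors = FALSE)
  genotypeSet(popId, colnames(gt), map, t(dos))
}

#' Read genotypes
#'
#' @param path file prefix for `"tsv"` (expects `<path>.dosage.tsv` and
#'   `<path>.markers.tsv`) and `"ped"` (expects `<path>.ped` / `<path>.map`),
#'   or a file path for `"vcf"`.
#' @param format one of `"tsv"`, `"ped"`, `"vcf"`.
#' @param countedAllele optional per-marker counted-allele vector for
#'   `"ped"`, whose map format does not record it; by default the
#'   lexicographically larger observed allele is counted.
#' @param popId population label for `"vcf"` input.
#' @return A [GenotypeSet-class]; markers sorted by (chromosome, position).
#' @export
readGenotypes <- function(path, format = c("tsv", "ped", "vcf"),
                          countedAllele = NULL, popId = "vcf") {
  format <- match.arg(format)
  switch(format,
         tsv = .readTsvGenotypes(path),
         ped = .readPedGenotypes(path, countedAllele),
         vcf = .readVcfGenotypes(path, popId))
}

#' Write genotypes
#'
#' @param g a [GenotypeSet-class].
#' @param prefix output file prefix.
#' @param format `"tsv"` (native, full fidelity) or `"ped"`.
#' @return Invisibly, the files written.
#' @export
writeGenotypes <- function(g, prefix, format = c("tsv", "ped")) {
  format <- match.arg(format)
  switch(format,
         tsv = .writeTsvGenotypes(g, prefix),
         ped = .writePedGenotypes(g, prefix))
  ext <- if (format == "tsv") c(".dosage.tsv", ".markers.tsv") else c(".ped", ".map")
  invisible(paste0(prefix, ext))
}

## ---- haplotype / pedigree / phenotype tables ----------------------------

#' Read or write phased haplotypes as TSV (two rows per animal)
#'
#' The haplotype file has columns `animal_id`, `hap` (1 or 2) and one 0/1
#' column per marker id; the marker map travels in `<prefix>.markers.tsv`.
#'
#' @param haps a [HaplotypeSet-class].
#' @param prefix file prefix.
#' @return `writeHaplotypes()` the files written (invisibly);
#'   `readHaplotypes()` a [HaplotypeSet-class].
#' @export
writeHaplotypes <- function(haps, prefix) {
  h <- haps@haplo
  df <- data.frame(animal_id = rep(haps@animalIds, each = 2L),
                   hap = rep(1:2, length(haps@animalIds)), h,
                   check.names = FALSE)
  names(df)[-(1:2)] <- haps@map$id
  write.table(df, paste0(prefix, ".haplo.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cbind(population = haps@popId, haps@map[, c("chrom", "pos", "id")]),
              paste0(prefix, ".markers.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paste0(prefix, c(".haplo.tsv", ".markers.tsv")))
}

#' @rdname writeHaplotypes
#' @export
readHaplotypes <- function(prefix) {
  map <- read.table(paste0(prefix, ".markers.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  df <- read.table(paste0(prefix, ".haplo.tsv"), header = TRUE, sep = "\t",
                   check.names = FALSE, stringsAsFactors = FALSE)
  h <- as.matrix(df[, map$id, drop = FALSE])
  mode(h) <- "integer"
  dimnames(h) <- NULL
  new("HaplotypeSet", popId = as.character(map$population[1]),
      animalIds = df$animal_id[df$hap == 1L],
      map = map[, c("chrom", "pos", "id")], haplo = h)
}

#' Read/write pedigree and DRP tables as TSV with header
#'
#' @param x data.frame (pedigree: `animal_id`, `sire_id`, `dam_id`,
#'   `birth_year`, `sex`, `population`, ...; DRP: `animal_id`, `trait`,
#'   `drp`, `r2_drp`, ...).
#' @param path file path.
#' @return The data.frame read, or the path written (invisibly).
#' @export
writeTable <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTable
#' @export
readTable <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

## ---- quality control ----------------------------------------------------

#' Quality-control filter on markers and animals
#'
#' Removes markers with minor allele frequency strictly below `mafMin`
#' (computed on non-missing calls) or call rate strictly below
#' `markerCallrateMin`, then animals whose missing-call fraction strictly
#' exceeds `animalMissingMax`. Boundary values are retained on all three
#' rules. The default call-rate threshold is 0.90 — the threshold is an
#' explicit parameter and is never hard-coded.
#'
#' @param g a [GenotypeSet-class].
#' @param mafMin minimum minor allele frequency (default 0.01).
#' @param markerCallrateMin minimum marker call rate (default 0.90).
#' @param animalMissingMax maximum per-animal missing fraction (default 0.10).
#' @return List with `genotypes` (filtered [GenotypeSet-class]) and
#'   `report` (a `QCReport` list: axis counts in/out and per-rule removal
#'   counts, attributed to the first rule violated).
#' @export
qcFilter <- function(g, mafMin = 0.01, markerCallrateMin = 0.90,
                     animalMissingMax = 0.10) {
  stopifnot_scalar_prob(mafMin, "mafMin")
  stopifnot_scalar_prob(markerCallrateMin, "markerCallrateMin")
  stopifnot_scalar_prob(animalMissingMax, "animalMissingMax")
  d <- g@dosage
  nA <- nrow(d); nM <- ncol(d)
  called <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * pmax(called, 1L))
  maf <- pmin(p, 1 - p)
  callrate <- called / nA
  badMaf <- maf < mafMin | called == 0L
  badCall <- callrate < markerCallrateMin & !badMaf
  keepM <- !(badMaf | badCall)
  if (!any(keepM)) warning("QC removed every marker")
  d2 <- d[, keepM, drop = FALSE]
  missFrac <- if (ncol(d2)) rowMeans(is.na(d2)) else rep(0, nA)
  keepA <- missFrac <= animalMissingMax
  report <- structure(list(
    n_markers_in = nM, n_markers_out = sum(keepM),
    n_animals_in = nA, n_animals_out = sum(keepA),
    removed_maf = sum(badMaf), removed_callrate = sum(badCall),
    removed_missing_animals = sum(!keepA)), class = "QCReport")
  out <- genotypeSet(g@popId, g@animalIds[keepA],
                     g@map[keepM, , drop = FALSE],
                     d2[keepA, , drop = FALSE])
  list(genotypes = out, report = report)
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf("QC: markers %d -> %d (MAF %d, call rate %d); animals %d -> %d (missingness %d)\n",
              x$n_markers_in, x$n_markers_out, x$removed_maf,
              x$removed_callrate, x$n_animals_in, x$n_animals_out,
              x$removed_missing_animals))
  invisible(x)
}

## ---- allele harmonization -----------------------------------------------

#' Harmonize counted alleles across two GenotypeSets
#'
#' Restricts both sets to their shared markers (in set `a`'s map order) and,
#' where the two sets count different alleles of the same pair, recodes set
#' `b` (dosage x -> 2 - x, labels swapped) so both count the same allele.
#' Markers whose allele pairs cannot be reconciled by a swap (e.g. A/C in
#' one set, A/G in the other) are dropped with a warning. Mandatory before
#' comparing signed LD across populations.
#'
#' @param a,b [GenotypeSet-class] objects with `other_allele` in their maps.
#' @return List `a`, `b` (harmonized, identical marker order) and `flipped`
#'   (character vector of marker ids recoded in `b`).
#' @export
harmonizeAlleles <- function(a, b) {
  shared <- intersect(a@map$id, b@map$id)
  if (!length(shared)) stop("no shared marker ids")
  ia <- match(shared, a@map$id); ib <- match(shared, b@map$id)
  mapA <- a@map[ia, , drop = FALSE]
  mapB <- b@map[ib, , drop = FALSE]
  ca <- mapA$counted_allele; oa <- mapA$other_allele %||% rep(NA, length(ia))
  cb <- mapB$counted_allele; ob <- mapB$other_allele %||% rep(NA, length(ib))
  same <- cb == ca
  flip <- !same & cb == ifelse(is.na(oa), cb, oa) &
    (is.na(ob) | ob == ca)
  drop <- !(same | flip)
  if (any(drop))
    warning(sum(drop), " marker(s) dropped: allele pairs not resolvable by swap")
  keep <- which(!drop)
  dA <- a@dosage[, ia[keep], drop = FALSE]
  dB <- b@dosage[, ib[keep], drop = FALSE]
  fl <- flip[keep]
  dB[, fl] <- 2L - dB[, fl]
  mapB2 <- mapB[keep, , drop = FALSE]
  mapB2$counted_allele[fl] <- ca[keep][fl]
  if (!is.null(mapB2$other_allele))
    mapB2$other_allele[fl] <- cb[keep][fl]
  list(a = genotypeSet(a@popId, a@animalIds, mapA[keep, , drop = FALSE], dA),
       b = genotypeSet(b@popId, b@animalIds, mapB2, dB),
       flipped = mapB$id[keep][fl])
}

## ---- container subsetting -----------------------------------------------

#' Subset a HaplotypeSet by animals and/or markers
#'
#' @param haps a [HaplotypeSet-class].
#' @param ids animal ids to keep (default all).
#' @param markers marker ids to keep (default all; map order preserved).
#' @return A [HaplotypeSet-class].
#' @export
subsetHaplotypes <- function(haps, ids = NULL, markers = NULL) {
  ai <- if (is.null(ids)) seq_along(haps@animalIds)
        else match(ids, haps@animalIds)
  if (anyNA(ai)) stop("unknown animal id(s)")
  mi <- if (is.null(markers)) seq_len(nrow(haps@map))
        else sort(match(markers, haps@map$id))
  if (anyNA(mi)) stop("unknown marker id(s)")
  rows <- as.vector(rbind(2L * ai - 1L, 2L * ai))
  map <- haps@map[mi, , drop = FALSE]
  rownames(map) <- NULL
  new("HaplotypeSet", popId = haps@popId, animalIds = haps@animalIds[ai],
      map = map, haplo = haps@haplo[rows, mi, drop = FALSE])
}

#' Subset a GenotypeSet by animals and/or markers
#'
#' @param g a [GenotypeSet-class].
#' @param ids animal ids to keep (default all).
#' @param markers marker ids to keep (default all; map order preserved).
#' @return A [GenotypeSet-class].
#' @export
subsetGenotypes <- function(g, ids = NULL, markers = NULL) {
  ai <- if (is.null(ids)) seq_along(g@animalIds) else match(ids, g@animalIds)
  if (anyNA(ai)) stop("unknown animal id(s)")
  mi <- if (is.null(markers)) seq_len(nrow(g@map))
        else sort(match(markers, g@map$id))
  if (anyNA(mi)) stop("unknown marker id(s)")
  genotypeSet(g@popId, g@animalIds[ai], g@map[mi, , drop = FALSE],
              g@dosage[ai, mi, drop = FALSE])
}
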