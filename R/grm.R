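## Genomic relationship matrix, VanRaden method 1: G = MM' / sum(2 p_i q_i)
## with M the column-centered dosage coding (0 - 2p, 1 - 2p, 2 - 2p), and
## relationship-based group summaries used in validation design.

#' Allele frequencies of the counted allele
#'
#' p_i = mean dosage / 2 over non-missing calls. When several populations
#' are supplied, their animals are pooled (concatenated) before averaging,
#' so the result is the size-weighted mean of within-population frequencies.
#'
#' @param ... one or more [GenotypeSet-class] objects over the same markers
#'   (same map order).
#' @return Numeric vector of allele frequencies, one per marker.
#' @export
alleleFrequencies <- function(...) {
  sets <- list(...)
  d <- do.call(rbind, lapply(sets, dosages))
  called <- colSums(!is.na(d))
  if (any(called == 0L))
    stop("all calls missing at marker(s): ",
         paste(sets[[1]]@map$id[called == 0L], collapse = ", "))
  colSums(d, na.rm = TRUE) / (2 * called)
}

#' Build a genomic relationship matrix (VanRaden method 1)
#'
#' G = MM' / sum(2 p_i (1 - p_i)), where column i of M holds dosages
#' centered by 2 p_i. Missing dosages are replaced by 2 p_i (zero after
#' centering). A small ridge is added to the diagonal for numerical
#' invertibility of downstream mixed-model equations.
#'
#' @param g a [GenotypeSet-class], or a list of them over identical markers
#'   (animals are stacked; ids must be unique).
#' @param p allele frequencies used for centering and scaling; default
#'   computed from `g` itself (pooled when `g` is a list).
#' @param ridge value added to the diagonal (default 1e-6).
#' @return A [GRM-class].
#' @export
buildGrm <- function(g, p = NULL, ridge = 1e-6) {
  sets <- if (is(g, "GenotypeSet")) list(g) else g
  if (is.null(p)) p <- do.call(alleleFrequencies, sets)
  d <- do.call(rbind, lapply(sets, dosages))
  ids <- unlist(lapply(sets, animalIds))
  if (anyDuplicated(ids)) stop("duplicate animal ids across sets")
  if (length(p) != ncol(d)) stop("length(p) != number of markers")
  denom <- sum(2 * p * (1 - p))
  if (denom <= 0) stop("zero denominator: all markers monomorphic at supplied p")
  M <- sweep(d, 2L, 2 * p, `-`)
  M[is.na(M)] <- 0
  G <- tcrossprod(M) / denom
  G <- (G + t(G)) / 2
  diag(G) <- diag(G) + ridge
  dimnames(G) <- list(ids, ids)
  new("GRM", animalIds = ids, mat = G, p = as.numeric(p),
      ridge = as.numeric(ridge))
}

#' Subset a GRM to a set of animals
#'
#' @param grm a [GRM-class].
#' @param ids animal ids to keep, in the requested order.
#' @return A [GRM-class] over `ids`.
#' @export
subsetGrm <- function(grm, ids) {
  idx <- match(ids, grm@animalIds)
  if (anyNA(idx)) stop("ids not in GRM: ", paste(ids[is.na(idx)][1:3], collapse = ", "))
  new("GRM", animalIds = as.character(ids),
      mat = grm@mat[idx, idx, drop = FALSE], p = grm@p, ridge = grm@ridge)
}

#' Between-group relationship summary
#'
#' For each animal in `groupA`, counts its relationships to `groupB` animals
#' exceeding `threshold` (pairs involving the same animal are excluded).
#' Mirrors the kind of relatedness audit used when explaining why one group
#' predicts better than another.
#'
#' @param grm a [GRM-class].
#' @param groupA,groupB character vectors of animal ids present in the GRM.
#' @param threshold relationship threshold (e.g. 0.2).
#' @return List: `perA` data.frame (`animal_id`, `n_above`, `any_above`),
#'   `fractionWithPartner` (share of A with at least one B above threshold),
#'   `meanCount` (mean number of such B partners per A animal).
#' @export
relationshipSummary <- function(grm, groupA, groupB, threshold) {
  ia <- match(groupA, grm@animalIds); ib <- match(groupB, grm@animalIds)
  if (anyNA(ia) || anyNA(ib)) stop("group ids missing from GRM")
  sub <- grm@mat[ia, ib, drop = FALSE]
  same <- outer(groupA, groupB, `==`)
  sub[same] <- -Inf
  nAbove <- rowSums(sub > threshold)
  perA <- data.frame(animal_id = groupA, n_above = nAbove,
                     any_above = nAbove > 0L, stringsAsFactors = FALSE)
  list(perA = perA, fractionWithPartner = mean(perA$any_above),
       meanCount = mean(perA$n_above))
}

#' Write / read a GRM in the 3-column exchange format
#'
#' Lower triangle (including diagonal) as `i j value` with 1-based indices
#' into an accompanying id index file `<prefix>.ids.tsv`.
#'
#' @param grm a [GRM-class].
#' @param prefix output file prefix.
#' @return `writeGrm()` the files written (invisibly); `readGrm()` a
#'   [GRM-class] (allele frequencies are not part of the exchange format
#'   and come back empty).
#' @export
writeGrm <- function(grm, prefix) {
  n <- length(grm@animalIds)
  idx <- which(lower.tri(grm@mat, diag = TRUE), arr.ind = TRUE)
  df <- data.frame(i = idx[, 1], j = idx[, 2], value = grm@mat[idx])
  write.table(df, paste0(prefix, ".grm.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(index = seq_len(n), animal_id = grm@animalIds),
              paste0(prefix, ".ids.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paste0(prefix, c(".grm.tsv", ".ids.tsv")))
}

#' @rdname writeGrm
#' @export
readGrm <- function(prefix) {
  ids <- read.table(paste0(prefix, ".ids.tsv"), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  tri <- read.table(paste0(prefix, ".grm.tsv"), header = TRUE, sep = "\t")
  n <- nrow(ids)
  G <- matrix(0, n, n)
  G[cbind(tri$i, tri$j)] <- tri$value
  G[cbind(tri$j, tri$i)] <- tri$value
  dimnames(G) <- list(ids$animal_id, ids$animal_id)
  new("GRM", animalIds = ids$animal_id, mat = G, p = numeric(0), ridge = 0)
}
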