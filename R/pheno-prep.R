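## DRP residual weights and the parentage-consistency filter applied before
## genomic prediction.

#' Attach residual weights to a DRP table
#'
#' d_i = (1 - r2_i) / r2_i: the standard deregressed-proof weight, making a
#' record's residual precision in the mixed-model equations proportional to
#' its effective information (d = 1 at r2 = 0.5, d = 1/9 at r2 = 0.9).
#' r2 = 1 would give d = 0 (an exact record); it is floored at 1e-8 with a
#' warning so the equations stay finite.
#'
#' @param t data.frame with a `r2_drp` column in (0, 1].
#' @return The table with a `weight` column added/overwritten.
#' @export
residualWeights <- function(t) {
  r2 <- t$r2_drp
  if (is.null(r2)) stop("table has no 'r2_drp' column")
  if (any(is.na(r2)) || any(r2 <= 0) || any(r2 > 1))
    stop("reliabilities must be in (0, 1]; r2 = 0 implies infinite weight")
  d <- (1 - r2) / r2
  if (any(d == 0)) {
    warning("r2_drp = 1 gives weight 0; floored at 1e-8")
    d[d == 0] <- 1e-8
  }
  t$weight <- d
  t
}

#' Verify paternity by opposing homozygotes
#'
#' A marker is in conflict when the putative sire is homozygous for one
#' allele and the daughter homozygous for the other (dosages 0 vs 2).
#' Pairs reaching `conflictThreshold` conflicts ("five or more" by default)
#' fail. Missing genotypes at a marker skip that marker. Conflict counts
#' are invariant to allele relabeling.
#'
#' @param daughters,sires [GenotypeSet-class] objects over the same marker
#'   map (sires may contain more animals than referenced).
#' @param pairs data.frame with `daughter_id`, `sire_id`.
#' @param panel marker ids to use; default a random subset of
#'   `panelSize` markers (seeded by `seed`).
#' @param panelSize default panel size, 255 markers.
#' @param conflictThreshold conflicts at or above this fail the pair
#'   (default 5).
#' @param seed seed for the default panel draw.
#' @return data.frame: `daughter_id`, `sire_id`, `n_markers_used`,
#'   `n_conflicts`, `pass`.
#' @export
parentageCheck <- function(daughters, sires, pairs, panel = NULL,
                           panelSize = 255L, conflictThreshold = 5L,
                           seed = 1L) {
  if (is.null(panel)) {
    ids <- intersect(daughters@map$id, sires@map$id)
    if (!length(ids)) stop("no shared panel markers")
    set.seed(seed)
    panel <- if (length(ids) > panelSize) sort(sample(ids, panelSize)) else ids
  }
  jd <- match(panel, daughters@map$id)
  js <- match(panel, sires@map$id)
  if (anyNA(jd) || anyNA(js)) stop("panel markers missing from a genotype set")
  dd <- daughters@dosage[, jd, drop = FALSE]
  ds <- sires@dosage[, js, drop = FALSE]
  id <- match(pairs$daughter_id, daughters@animalIds)
  is <- match(pairs$sire_id, sires@animalIds)
  if (anyNA(id) || anyNA(is)) stop("pair ids missing from genotype sets")
  res <- vapply(seq_len(nrow(pairs)), function(k) {
    gd <- dd[id[k], ]; gs <- ds[is[k], ]
    ok <- !is.na(gd) & !is.na(gs)
    conf <- (gd == 0L & gs == 2L) | (gd == 2L & gs == 0L)
    c(sum(ok), sum(conf & ok))
  }, numeric(2))
  data.frame(daughter_id = pairs$daughter_id, sire_id = pairs$sire_id,
             n_markers_used = res[1, ], n_conflicts = res[2, ],
             pass = res[2, ] < conflictThreshold, stringsAsFactors = FALSE)
}

#' Drop records of daughters that failed parentage verification
#'
#' @param t DRP data.frame with `animal_id`.
#' @param check output of [parentageCheck()] (or any data.frame with
#'   `daughter_id` and logical `pass`).
#' @return The filtered table; counts are reported via a message, and a
#'   warning is raised if nothing survives.
#' @export
applyExclusions <- function(t, check) {
  failed <- unique(check$daughter_id[!check$pass])
  out <- t[!(t$animal_id %in% failed), , drop = FALSE]
  message(sprintf("parentage exclusions: %d of %d records removed (%d animals)",
                  nrow(t) - nrow(out), nrow(t), length(failed)))
  if (nrow(out) == 0L) warning("all records excluded by parentage check")
  out
}
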