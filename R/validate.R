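## Validation designs (relationship-filtered bull test set, half-sib-family
## cross-validation), the validation-reliability statistic with
## genetic-trend correction, and the deterministic expected reliability of
## genomic prediction.

#' Bull test-set split filtered on genomic relationship
#'
#' The test set holds candidate bulls whose maximum genomic relationship to
#' any reference bull stays below `relationshipMax`; closely related
#' candidates are excluded (they would inflate validation reliability).
#'
#' @param candidates character ids of candidate test bulls (bulls without
#'   genotyped daughters).
#' @param referenceBulls character ids of the reference bulls.
#' @param grm a [GRM-class] covering all ids.
#' @param relationshipMax exclusion threshold (default 0.45, between
#'   first-degree relationships ~0.5 and half-sib relationships ~0.25).
#' @return A `ValidationSplit` list: `name`, `reference`, `test`,
#'   `excluded` (candidates dropped for high relationship).
#' @export
makeBullSplit <- function(candidates, referenceBulls, grm,
                          relationshipMax = 0.45) {
  ic <- match(candidates, grm@animalIds)
  ir <- match(referenceBulls, grm@animalIds)
  if (anyNA(ic) || anyNA(ir)) stop("ids missing from GRM")
  rel <- grm@mat[ic, ir, drop = FALSE]
  rel[outer(candidates, referenceBulls, `==`)] <- -Inf
  maxRel <- apply(rel, 1L, max)
  keep <- maxRel < relationshipMax
  if (!any(keep)) warning("empty test set: every candidate is highly related")
  structure(list(name = "bull_test", reference = referenceBulls,
                 test = candidates[keep], excluded = candidates[!keep]),
            class = "ValidationSplit")
}

#' Half-sib-family cross-validation folds for cows
#'
#' Whole half-sib families are assigned to folds (families are never split
#' across test sets, so a test cow cannot have a large half-sib group in the
#' reference). Family counts per fold differ by at most one and fold sizes
#' are balanced greedily by descending family size. The reference of each
#' fold is all non-test cows plus all bulls.
#'
#' @param cows data.frame with `animal_id` and `family` (sire label).
#' @param bulls character ids always kept in the reference.
#' @param kFolds number of folds (default 5).
#' @param seed seed for the family shuffle.
#' @return List of `ValidationSplit` objects, one per fold, each with
#'   `fold`, `testFamilies`, `reference`, `test`.
#' @export
makeCowFolds <- function(cows, bulls, kFolds = 5L, seed = 1L) {
  fams <- split(cows$animal_id, cows$family)
  if (length(fams) < kFolds)
    stop("need at least ", kFolds, " families for ", kFolds, " folds")
  set.seed(seed)
  ord <- sample(length(fams))   # shuffle, then greedy-balance by size
  fams <- fams[ord]
  fams <- fams[order(-lengths(fams))]
  foldOf <- integer(length(fams))
  foldSize <- numeric(kFolds)
  foldCount <- integer(kFolds)
  maxFam <- ceiling(length(fams) / kFolds)
  for (i in seq_along(fams)) {
    open <- which(foldCount < maxFam)
    k <- open[which.min(foldSize[open])]
    foldOf[i] <- k
    foldSize[k] <- foldSize[k] + length(fams[[i]])
    foldCount[k] <- foldCount[k] + 1L
  }
  lapply(seq_len(kFolds), function(k) {
    testIds <- unlist(fams[foldOf == k], use.names = FALSE)
    structure(list(name = sprintf("cow_fold_%d", k), fold = k,
                   testFamilies = names(fams)[foldOf == k],
                   reference = c(bulls, setdiff(cows$animal_id, testIds)),
                   test = testIds),
              class = "ValidationSplit")
  })
}

#' Remove a linear genetic trend
#'
#' Ordinary least-squares regression of the values on birth year; returns
#' the residuals. Selection-induced trend inflates the naive GEBV-DRP
#' correlation when test animals span many birth years.
#'
#' @param values numeric vector.
#' @param birthYears numeric vector of the same length.
#' @return Residual values (identity with a warning when all birth years
#'   are equal).
#' @export
detrend <- function(values, birthYears) {
  if (length(unique(birthYears)) < 2L) {
    warning("all birth years identical; returning values unchanged")
    return(values)
  }
  unname(residuals(lm(values ~ birthYears)))
}

#' Validation reliability of genomic predictions
#'
#' Cor^2(GEBV, DRP) / mean(r2_DRP) over the test animals. When birth years
#' are supplied, both GEBV and DRP are detrended first. The statistic is a
#' contract, not a probability: it can exceed 1 (it equals
#' 1 / mean(r2_DRP) when GEBV and DRP coincide) and is invariant to affine
#' transformations of GEBV.
#'
#' @param gebv,drp numeric vectors over the test animals.
#' @param r2Drp DRP reliabilities of the test animals.
#' @param birthYears optional; triggers genetic-trend correction.
#' @return The reliability (single numeric).
#' @export
validationReliability <- function(gebv, drp, r2Drp, birthYears = NULL) {
  if (length(gebv) < 3L) stop("need at least 3 test animals")
  if (!is.null(birthYears)) {
    gebv <- detrend(gebv, birthYears)
    drp <- detrend(drp, birthYears)
  }
  if (sd(gebv) == 0 || sd(drp) == 0)
    stop("zero variance in GEBV or DRP; reliability undefined")
  mr2 <- mean(r2Drp)
  if (mr2 <= 0) stop("mean DRP reliability must be > 0")
  cor(gebv, drp)^2 / mr2
}

#' Deterministic expected reliability of genomic prediction
#'
#' Evaluates E(r^2_GEBV) = 1 - lambda / (2 N sqrt(a)) *
#' ln((1 + a + 2 sqrt(a)) / (1 + a - 2 sqrt(a))), with a = 1 + 2 lambda / N,
#' lambda = Me k / h2, Me = 2 Ne L and k = 1 / ln(2 Ne). Natural logarithms
#' are used throughout (both in k and in the main term). h2 is the squared
#' accuracy of the reference phenotypes; with DRP phenotypes their
#' reliability plays this role.
#'
#' @param L genome length in Morgans.
#' @param Ne effective population size (>= 2).
#' @param N reference population size.
#' @param h2 squared accuracy of reference phenotypes in (0, 1].
#' @return Expected reliability in (0, 1).
#' @export
goddardExpectedReliability <- function(L, Ne, N, h2) {
  if (L <= 0 || Ne < 2 || N < 1) stop("invalid parameters: need L > 0, Ne >= 2, N >= 1")
  stopifnot_scalar_prob(h2, "h2", open0 = TRUE)
  Me <- 2 * Ne * L
  k <- 1 / log(2 * Ne)
  lambda <- Me * k / h2
  a <- 1 + 2 * lambda / N
  if (a <= 1 || (1 + a - 2 * sqrt(a)) <= 0)
    stop("parameters outside the formula's domain")
  1 - lambda / (2 * N * sqrt(a)) * log((1 + a + 2 * sqrt(a)) / (1 + a - 2 * sqrt(a)))
}

#' Write a validation split as a long TSV
#'
#' @param split a `ValidationSplit` (or list of them).
#' @param path file path.
#' @return The path, invisibly.
#' @export
writeSplit <- function(split, path) {
  splits <- if (inherits(split, "ValidationSplit")) list(split) else split
  df <- do.call(rbind, lapply(splits, function(s)
    data.frame(split = s$name, fold = s$fold %||% NA,
               animal_id = c(s$reference, s$test),
               role = rep(c("reference", "test"),
                          c(length(s$reference), length(s$test))),
               stringsAsFactors = FALSE)))
  writeTable(df, path)
}
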