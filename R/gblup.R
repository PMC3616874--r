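## Single-trait weighted GBLUP and the two-trait across-population model:
## y = 1*mu + Z g + e with g ~ N(0, Sigma_g (x) G) and e ~ N(0, D sigma2_e),
## D a diagonal matrix of per-record residual weights. Variance components
## by AI-REML on the dense V-formulation; breeding values from Henderson's
## mixed-model equations, which carry GEBV for every animal in the GRM
## (test animals enter with no records and are predicted through G).

#' Construct a GBLUP model specification
#'
#' Records are phenotype (DRP) rows; the animal list is the GRM's, so
#' animals without records are prediction targets. In a two-trait model the
#' traits are population-exclusive: no animal may carry records for both.
#'
#' @param records data.frame with `animal_id`, `trait`, `drp` and either
#'   `weight` (residual weight d_i > 0) or `r2_drp` (converted via
#'   d = (1 - r2) / r2, see [residualWeights()]).
#' @param grm a [GRM-class] covering at least all record animals.
#' @return A `ModelSpec` list: `records` (with `trait_idx`, `animal_idx`,
#'   `weight`), `traits`, `grm`.
#' @export
modelSpec <- function(records, grm) {
  stopifnot(is.data.frame(records), is(grm, "GRM"))
  if (is.null(records$weight)) {
    if (is.null(records$r2_drp))
      stop("records need a 'weight' or 'r2_drp' column")
    records <- residualWeights(records)
  }
  if (any(records$weight <= 0)) stop("residual weights must be > 0")
  traits <- unique(records$trait)
  if (length(traits) > 2L) stop("at most two traits supported")
  records$trait_idx <- match(records$trait, traits)
  records$animal_idx <- match(records$animal_id, grm@animalIds)
  if (anyNA(records$animal_idx))
    stop("record animal(s) not in GRM: ",
         paste(head(records$animal_id[is.na(records$animal_idx)], 3),
               collapse = ", "))
  if (length(traits) == 2L) {
    both <- intersect(records$animal_id[records$trait_idx == 1L],
                      records$animal_id[records$trait_idx == 2L])
    if (length(both))
      stop("two-trait model requires population-exclusive traits; animals with both: ",
           paste(head(both, 3), collapse = ", "))
  }
  records <- records[order(records$trait_idx), , drop = FALSE]
  structure(list(records = records, traits = traits, grm = grm),
            class = "ModelSpec")
}

#' Construct variance components
#'
#' @param traits trait labels (length 1 or 2).
#' @param sigma2g,sigma2e per-trait genetic and residual variances.
#' @param sigmaG12 genetic covariance (two-trait only).
#' @param se asymptotic standard errors (inverse AI matrix), in the order
#'   (sigma2g1, [sigmaG12, sigma2g2,] sigma2e...).
#' @param converged,logLik,iterations fit diagnostics.
#' @return A [VarianceComponents-class].
#' @export
varianceComponents <- function(traits, sigma2g, sigma2e, sigmaG12 = NA_real_,
                               se = numeric(0), converged = TRUE,
                               logLik = NA_real_, iterations = 0L) {
  rG <- if (length(traits) == 2L && !is.na(sigmaG12) && all(sigma2g > 0))
    sigmaG12 / sqrt(prod(sigma2g)) else NA_real_
  new("VarianceComponents", traits = as.character(traits),
      sigma2g = as.numeric(sigma2g), sigmaG12 = as.numeric(sigmaG12),
      sigma2e = as.numeric(sigma2e), rG = rG, se = as.numeric(se),
      converged = converged, logLik = as.numeric(logLik),
      iterations = as.integer(iterations))
}

## Genetic covariance matrix of a VarianceComponents.
.sigmaG <- function(vc) {
  t <- length(vc@traits)
  if (t == 1L) matrix(vc@sigma2g, 1, 1)
  else matrix(c(vc@sigma2g[1], vc@sigmaG12, vc@sigmaG12, vc@sigma2g[2]), 2, 2)
}

#' Build Henderson's mixed-model equations
#'
#' Fixed effects are one mean per trait; random effects are breeding values
#' for ALL animals in the GRM and every trait. Record residual precision is
#' 1 / (d_i sigma2_e_trait).
#'
#' @param spec a `ModelSpec` from [modelSpec()].
#' @param vc a [VarianceComponents-class].
#' @return List: `C` coefficient matrix, `rhs`, `nFixed`, `traits`,
#'   `animalIds`.
#' @export
buildMme <- function(spec, vc) {
  rec <- spec$records
  t <- length(spec$traits)
  if (length(vc@traits) != t) stop("vc traits do not match spec")
  q <- length(spec$grm@animalIds)
  n <- nrow(rec)
  w <- 1 / (rec$weight * vc@sigma2e[rec$trait_idx])
  y <- rec$drp
  # column index of each record's breeding value: (trait-1)*q + animal
  zcol <- (rec$trait_idx - 1L) * q + rec$animal_idx
  dimC <- t + t * q
  C <- matrix(0, dimC, dimC)
  rhs <- numeric(dimC)
  for (k in seq_len(t)) {
    rk <- which(rec$trait_idx == k)
    C[k, k] <- sum(w[rk])
    rhs[k] <- sum(w[rk] * y[rk])
    idx <- t + zcol[rk]
    # X'R^-1 Z and Z'R^-1 Z are sums over records sharing an animal
    zx <- tapply(w[rk], idx, sum)
    cols <- as.integer(names(zx))
    C[k, cols] <- C[k, cols] + as.numeric(zx)
    C[cols, k] <- C[k, cols]
    zy <- tapply(w[rk] * y[rk], idx, sum)
    rhs[as.integer(names(zy))] <- rhs[as.integer(names(zy))] + as.numeric(zy)
    dg <- tapply(w[rk], idx, sum)
    di <- as.integer(names(dg))
    C[cbind(di, di)] <- C[cbind(di, di)] + as.numeric(dg)
  }
  Ginv <- tryCatch(chol2inv(chol(spec$grm@mat)),
                   error = function(e) stop(
                     "G is numerically singular; increase the GRM ridge",
                     call. = FALSE))
  Sinv <- tryCatch(solve(.sigmaG(vc)),
                   error = function(e) stop(
                     "genetic covariance matrix singular; cannot build MME",
                     call. = FALSE))
  for (k in seq_len(t)) for (l in seq_len(t)) {
    rows <- t + (k - 1L) * q + seq_len(q)
    cols <- t + (l - 1L) * q + seq_len(q)
    C[rows, cols] <- C[rows, cols] + Sinv[k, l] * Ginv
  }
  list(C = C, rhs = rhs, nFixed = t, traits = spec$traits,
       animalIds = spec$grm@animalIds)
}

#' Solve mixed-model equations
#'
#' Direct Cholesky factorization with a relative-residual check.
#'
#' @param system output of [buildMme()].
#' @param tolRel maximum acceptable relative residual (default 1e-10).
#' @return A `GEBVResult` list: `mu` (fixed means per trait), `gebv`
#'   (data.frame `animal_id`, `trait`, `gebv`), `diagnostics`.
#' @export
solveMme <- function(system, tolRel = 1e-10) {
  C <- system$C
  ch <- tryCatch(chol(C), error = function(e)
    stop("MME coefficient matrix is not positive definite; ",
         "increase the GRM ridge", call. = FALSE))
  sol <- backsolve(ch, forwardsolve(t(ch), system$rhs))
  relres <- sqrt(sum((C %*% sol - system$rhs)^2)) /
    max(sqrt(sum(system$rhs^2)), .Machine$double.eps)
  if (!is.finite(relres) || relres > max(tolRel, 1e-8))
    stop(sprintf("MME solve ill-conditioned: relative residual %.3e", relres))
  t <- system$nFixed
  q <- length(system$animalIds)
  gebv <- do.call(rbind, lapply(seq_len(t), function(k)
    data.frame(animal_id = system$animalIds, trait = system$traits[k],
               gebv = sol[t + (k - 1L) * q + seq_len(q)],
               stringsAsFactors = FALSE)))
  structure(list(mu = sol[seq_len(t)], gebv = gebv,
                 diagnostics = list(method = "cholesky",
                                    relResidual = relres)),
            class = "GEBVResult")
}

## ---- AI-REML ------------------------------------------------------------

## Internal: dense REML machinery on the V parameterization. Records must
## be sorted by trait. Blocks of G restricted to record animals are
## precomputed; V and all score/AI quantities are assembled blockwise, so
## cost per iteration is a Cholesky and an inverse of the n x n V.
.remlEval <- function(theta, env) {
  t <- env$t; n <- env$n
  V <- matrix(0, n, n)
  if (t == 1L) {
    V <- theta[1] * env$G11
    diag(V) <- diag(V) + theta[2] * env$d
  } else {
    i1 <- env$i1; i2 <- env$i2
    V[i1, i1] <- theta[1] * env$G11
    V[i1, i2] <- theta[2] * env$G12
    V[i2, i1] <- t(V[i1, i2])
    V[i2, i2] <- theta[3] * env$G22
    dg <- diag(V)
    dg[i1] <- dg[i1] + theta[4] * env$d[i1]
    dg[i2] <- dg[i2] + theta[5] * env$d[i2]
    diag(V) <- dg
  }
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  Vinv <- chol2inv(ch)
  W <- Vinv %*% env$X
  XtVX <- crossprod(env$X, W)
  XtVXi <- tryCatch(solve(XtVX), error = function(e) NULL)
  if (is.null(XtVXi)) return(NULL)
  P <- Vinv - W %*% XtVXi %*% t(W)
  Py <- drop(P %*% env$y)
  ll <- -0.5 * (2 * sum(log(diag(ch))) + determinant(XtVX)$modulus[1] +
                  sum(env$y * Py))
  list(ll = ll, P = P, Py = Py)
}

.remlScoreAI <- function(ev, env) {
  P <- ev$P; Py <- ev$Py
  t <- env$t
  if (t == 1L) {
    u <- list(drop(env$G11 %*% Py), env$d * Py)
    trPV <- c(sum(P * env$G11), sum(diag(P) * env$d))
  } else {
    i1 <- env$i1; i2 <- env$i2
    Py1 <- Py[i1]; Py2 <- Py[i2]
    z1 <- numeric(env$n); z2 <- numeric(env$n); z3 <- numeric(env$n)
    z4 <- numeric(env$n); z5 <- numeric(env$n)
    z1[i1] <- drop(env$G11 %*% Py1)
    z2[i1] <- drop(env$G12 %*% Py2); z2[i2] <- drop(crossprod(env$G12, Py1))
    z3[i2] <- drop(env$G22 %*% Py2)
    z4[i1] <- env$d[i1] * Py1
    z5[i2] <- env$d[i2] * Py2
    u <- list(z1, z2, z3, z4, z5)
    dP <- diag(P)
    trPV <- c(sum(P[i1, i1] * env$G11),
              2 * sum(P[i1, i2] * env$G12),
              sum(P[i2, i2] * env$G22),
              sum(dP[i1] * env$d[i1]),
              sum(dP[i2] * env$d[i2]))
  }
  np <- length(u)
  score <- numeric(np)
  for (i in seq_len(np)) score[i] <- -0.5 * (trPV[i] - sum(Py * u[[i]]))
  AI <- matrix(0, np, np)
  Pu <- lapply(u, function(ui) drop(P %*% ui))
  for (i in seq_len(np)) for (j in i:np) {
    AI[i, j] <- 0.5 * sum(u[[i]] * Pu[[j]])
    AI[j, i] <- AI[i, j]
  }
  list(score = score, AI = AI)
}

## theta <-> phi transform. Single trait: phi = log(sigma2g, sigma2e).
## Two traits: phi = (log s2g1, log s2g2, atanh rG, log s2e1, log s2e2),
## theta = (s2g1, sG12, s2g2, s2e1, s2e2).
.phiToTheta <- function(phi, t) {
  if (t == 1L) return(exp(phi))
  s2g1 <- exp(phi[1]); s2g2 <- exp(phi[2]); r <- tanh(phi[3])
  c(s2g1, r * sqrt(s2g1 * s2g2), s2g2, exp(phi[4]), exp(phi[5]))
}

.thetaToPhi <- function(theta, t) {
  if (t == 1L) return(log(theta))
  r <- theta[2] / sqrt(theta[1] * theta[3])
  c(log(theta[1]), log(theta[3]), atanh(max(-0.999, min(0.999, r))),
    log(theta[4]), log(theta[5]))
}

.phiJacobian <- function(phi, t) {
  # J[i, j] = d theta_i / d phi_j
  if (t == 1L) return(diag(exp(phi), 2))
  s2g1 <- exp(phi[1]); s2g2 <- exp(phi[2]); r <- tanh(phi[3])
  sg12 <- r * sqrt(s2g1 * s2g2)
  J <- matrix(0, 5, 5)
  J[1, 1] <- s2g1
  J[2, 1] <- 0.5 * sg12
  J[2, 2] <- 0.5 * sg12
  J[2, 3] <- (1 - r^2) * sqrt(s2g1 * s2g2)
  J[3, 2] <- s2g2
  J[4, 4] <- exp(phi[4])
  J[5, 5] <- exp(phi[5])
  J
}

#' Estimate variance components by AI-REML
#'
#' Average-information REML on the dense V-formulation, updating
#' log-variances and (two-trait) the atanh genetic correlation so the
#' estimates respect their bounds, with step-halving so accepted steps
#' never decrease the restricted log-likelihood. The two-trait residual
#' covariance is structurally zero (the traits are population-exclusive).
#'
#' @param spec a `ModelSpec` from [modelSpec()].
#' @param start optional [VarianceComponents-class] start values; default
#'   assigns half the weighted phenotypic variance to each component per
#'   trait and starts the genetic covariance at
#'   0.5 * sqrt(sigma2g1 * sigma2g2).
#' @param tol convergence tolerance on the relative parameter change
#'   (default 1e-8).
#' @param maxIter iteration cap (default 100); on hitting it the best
#'   estimates are returned with `converged = FALSE`.
#' @return A [VarianceComponents-class].
#' @export
aiReml <- function(spec, start = NULL, tol = 1e-8, maxIter = 100L) {
  rec <- spec$records
  t <- length(spec$traits)
  n <- nrow(rec)
  if (n < 2L) stop("need at least 2 records")
  if (t == 2L && any(table(factor(rec$trait_idx, levels = 1:2)) < 2L))
    stop("each trait needs at least 2 records")
  env <- new.env(parent = emptyenv())
  env$t <- t; env$n <- n
  env$y <- rec$drp
  env$d <- rec$weight
  env$X <- matrix(0, n, t)
  env$X[cbind(seq_len(n), rec$trait_idx)] <- 1
  a <- rec$animal_idx
  G <- spec$grm@mat
  if (t == 1L) {
    env$G11 <- G[a, a, drop = FALSE]
  } else {
    env$i1 <- which(rec$trait_idx == 1L)
    env$i2 <- which(rec$trait_idx == 2L)
    env$G11 <- G[a[env$i1], a[env$i1], drop = FALSE]
    env$G12 <- G[a[env$i1], a[env$i2], drop = FALSE]
    env$G22 <- G[a[env$i2], a[env$i2], drop = FALSE]
  }

  vw <- vapply(seq_len(t), function(k) {
    idx <- rec$trait_idx == k
    w <- 1 / rec$weight[idx]
    yk <- rec$drp[idx]
    m <- sum(w * yk) / sum(w)
    sum(w * (yk - m)^2) / sum(w)
  }, numeric(1))
  floorVar <- pmax(1e-8 * vw, 1e-12)
  if (any(vw <= 0)) {
    warning("phenotypes have zero variance; returning floor estimates")
    return(varianceComponents(spec$traits, floorVar + 1e-12, floorVar + 1e-12,
                              sigmaG12 = if (t == 2L) 0 else NA_real_,
                              converged = FALSE, logLik = NA_real_))
  }
  theta <- if (!is.null(start)) {
    if (t == 1L) c(start@sigma2g, start@sigma2e)
    else c(start@sigma2g[1], start@sigmaG12, start@sigma2g[2],
           start@sigma2e[1], start@sigma2e[2])
  } else if (t == 1L) c(vw / 2, vw / 2)
  else c(vw[1] / 2, 0.5 * sqrt(vw[1] * vw[2]) / 2, vw[2] / 2,
         vw[1] / 2, vw[2] / 2)
  phi <- .thetaToPhi(theta, t)
  ev <- .remlEval(.phiToTheta(phi, t), env)
  if (is.null(ev)) stop("start values give a singular V; supply 'start'")
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    sa <- .remlScoreAI(ev, env)
    J <- .phiJacobian(phi, t)
    g_phi <- drop(crossprod(J, sa$score))
    AI_phi <- crossprod(J, sa$AI %*% J)
    step <- tryCatch(solve(AI_phi + diag(1e-8, length(phi)), g_phi),
                     error = function(e) g_phi / max(abs(g_phi), 1))
    accepted <- FALSE
    for (h in 0:25) {
      phiNew <- phi + step / 2^h
      phiNew <- pmin(pmax(phiNew, -30), 30)
      if (t == 2L) phiNew[3] <- max(-5, min(5, phiNew[3]))
      evNew <- .remlEval(.phiToTheta(phiNew, t), env)
      if (!is.null(evNew) && is.finite(evNew$ll) &&
          evNew$ll >= ev$ll - 1e-10) {
        accepted <- TRUE
        break
      }
    }
    if (!accepted) break
    thetaNew <- .phiToTheta(phiNew, t)
    relChange <- max(abs(thetaNew - .phiToTheta(phi, t)) /
                       (abs(.phiToTheta(phi, t)) + 1e-8))
    phi <- phiNew
    ev <- evNew
    if (relChange < tol) { converged <- TRUE; break }
  }
  theta <- .phiToTheta(phi, t)
  saFinal <- .remlScoreAI(ev, env)
  se <- tryCatch(sqrt(diag(solve(saFinal$AI))), error = function(e)
    rep(NA_real_, length(theta)))
  if (t == 1L) {
    varianceComponents(spec$traits, max(theta[1], floorVar),
                       max(theta[2], floorVar), se = se,
                       converged = converged, logLik = ev$ll, iterations = it)
  } else {
    varianceComponents(spec$traits, pmax(theta[c(1, 3)], floorVar),
                       pmax(theta[4:5], floorVar), sigmaG12 = theta[2],
                       se = se, converged = converged, logLik = ev$ll,
                       iterations = it)
  }
}

#' Restricted log-likelihood at given variance components
#'
#' @param spec a `ModelSpec`.
#' @param vc a [VarianceComponents-class].
#' @return The restricted log-likelihood (up to the usual constant).
#' @export
remlLogLik <- function(spec, vc) {
  rec <- spec$records
  t <- length(spec$traits)
  env <- new.env(parent = emptyenv())
  env$t <- t; env$n <- nrow(rec)
  env$y <- rec$drp; env$d <- rec$weight
  env$X <- matrix(0, env$n, t)
  env$X[cbind(seq_len(env$n), rec$trait_idx)] <- 1
  a <- rec$animal_idx
  G <- spec$grm@mat
  if (t == 1L) {
    env$G11 <- G[a, a, drop = FALSE]
    theta <- c(vc@sigma2g, vc@sigma2e)
  } else {
    env$i1 <- which(rec$trait_idx == 1L)
    env$i2 <- which(rec$trait_idx == 2L)
    env$G11 <- G[a[env$i1], a[env$i1], drop = FALSE]
    env$G12 <- G[a[env$i1], a[env$i2], drop = FALSE]
    env$G22 <- G[a[env$i2], a[env$i2], drop = FALSE]
    theta <- c(vc@sigma2g[1], vc@sigmaG12, vc@sigma2g[2], vc@sigma2e)
  }
  ev <- .remlEval(theta, env)
  if (is.null(ev)) stop("V not positive definite at these components")
  ev$ll
}

#' Single-trait GBLUP: variance components and GEBV
#'
#' @param spec a single-trait `ModelSpec`.
#' @param vc optional fixed [VarianceComponents-class]; estimated by
#'   [aiReml()] when NULL.
#' @param ... passed to [aiReml()].
#' @return List: `vc` and `gebv` (a `GEBVResult`, GEBV for every GRM
#'   animal).
#' @export
singleTraitGblup <- function(spec, vc = NULL, ...) {
  if (length(spec$traits) != 1L) stop("spec is not single-trait")
  if (is.null(vc)) vc <- aiReml(spec, ...)
  res <- solveMme(buildMme(spec, vc))
  list(vc = vc, gebv = res)
}

#' Two-trait across-population GBLUP
#'
#' One biological trait is treated as two correlated traits, one per
#' population, over a shared GRM spanning both; the residual covariance is
#' structurally zero. Trait-1 GEBV for all animals are the joint-reference
#' predictions for population-A targets.
#'
#' @param spec a two-trait `ModelSpec` (trait 1: population A records,
#'   trait 2: population B records).
#' @param vc optional fixed [VarianceComponents-class]; estimated by
#'   [aiReml()] when NULL.
#' @param ... passed to [aiReml()].
#' @return List: `vc` and `gebv` (a `GEBVResult` over all animals and both
#'   traits).
#' @export
twoTraitGblup <- function(spec, vc = NULL, ...) {
  if (length(spec$traits) != 2L) stop("spec is not two-trait")
  if (is.null(vc)) vc <- aiReml(spec, ...)
  res <- solveMme(buildMme(spec, vc))
  list(vc = vc, gebv = res)
}
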