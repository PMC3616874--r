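# Independent oracles and small fixture builders. Everything here is
# deliberately written from first principles (dense algebra, direct
# counting), not via the package's own computational paths.

# Minimal HaplotypeSet from a raw 0/1 matrix (2 rows per animal).
makeHaps <- function(h, chrom = rep(1L, ncol(h)), pos = NULL, popId = "t") {
  if (is.null(pos)) pos <- as.integer(unlist(lapply(split(seq_along(chrom), chrom),
                                                    seq_along)))
  mode(h) <- "integer"
  new("HaplotypeSet", popId = popId,
      animalIds = sprintf("%s%d", popId, seq_len(nrow(h) / 2)),
      map = data.frame(chrom = as.integer(chrom), pos = pos,
                       id = sprintf("s%d", seq_along(chrom))),
      haplo = h)
}

# Minimal GenotypeSet from a dosage matrix.
makeGeno <- function(d, chrom = rep(1L, ncol(d)), pos = seq_len(ncol(d)),
                     popId = "t", counted = rep("B", ncol(d)),
                     other = rep("A", ncol(d)), ids = NULL) {
  genotypeSet(popId, ids %||% sprintf("%s%d", popId, seq_len(nrow(d))),
              data.frame(chrom = as.integer(chrom), pos = as.integer(pos),
                         id = sprintf("s%d", seq_len(ncol(d))),
                         counted_allele = counted, other_allele = other),
              d)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Brute-force VanRaden G: element-by-element double loop.
bruteForceGrm <- function(dos, p) {
  n <- nrow(dos)
  den <- sum(2 * p * (1 - p))
  G <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    xi <- dos[i, ] - 2 * p
    xj <- dos[j, ] - 2 * p
    xi[is.na(xi)] <- 0; xj[is.na(xj)] <- 0
    G[i, j] <- sum(xi * xj) / den
  }
  G
}

# Dense GLS/BLUP oracle for the (possibly two-trait) GBLUP model.
# rec: data.frame(animal_idx, trait_idx, drp, weight); G over all animals.
# Returns list(mu, gebv matrix q x t).
glsOracle <- function(rec, G, sigma2g, sigma2e, sigmaG12 = 0) {
  t <- max(rec$trait_idx)
  n <- nrow(rec)
  q <- nrow(G)
  Sg <- if (t == 1L) matrix(sigma2g[1], 1, 1)
        else matrix(c(sigma2g[1], sigmaG12, sigmaG12, sigma2g[2]), 2, 2)
  # V = sum_kl Sg[k,l] * Zk G Zl' + diag(d * sigma2e_trait)
  V <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    V[i, j] <- Sg[rec$trait_idx[i], rec$trait_idx[j]] *
      G[rec$animal_idx[i], rec$animal_idx[j]]
  }
  diag(V) <- diag(V) + rec$weight * sigma2e[rec$trait_idx]
  X <- matrix(0, n, t)
  X[cbind(seq_len(n), rec$trait_idx)] <- 1
  Vi <- solve(V)
  mu <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% rec$drp)
  resid <- rec$drp - X %*% mu
  # Cov(g_trait_k(all animals), y_j) = Sg[k, trait_j] * G[, animal_j]
  gebv <- matrix(0, q, t)
  for (k in seq_len(t)) {
    C <- matrix(0, q, n)
    for (j in seq_len(n))
      C[, j] <- Sg[k, rec$trait_idx[j]] * G[, rec$animal_idx[j]]
    gebv[, k] <- C %*% Vi %*% resid
  }
  list(mu = drop(mu), gebv = gebv)
}

# Independent single-trait EM-REML via the P-matrix formulation:
# theta_i <- theta_i + theta_i^2 / w_i * (y'P Vi P y - tr(P Vi)).
emRemlOracle <- function(y, X, G, d, start = c(1, 1), tol = 1e-12,
                         maxIter = 100000L) {
  n <- length(y)
  Vg <- G
  theta <- start
  for (it in seq_len(maxIter)) {
    V <- theta[1] * Vg + diag(theta[2] * d, n)
    Vi <- solve(V)
    P <- Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X, t(X) %*% Vi)
    Py <- P %*% y
    newTheta <- c(
      theta[1] + theta[1]^2 / n * (sum(Py * (Vg %*% Py)) - sum(P * Vg)),
      theta[2] + theta[2]^2 / n * (sum(Py * (d * Py)) - sum(diag(P) * d)))
    newTheta <- pmax(newTheta, 1e-10)
    if (max(abs(newTheta - theta)) < tol) return(list(theta = newTheta, iter = it))
    theta <- newTheta
  }
  list(theta = theta, iter = maxIter)
}

# SNP-BLUP (ridge-regression) oracle: y = 1 mu + W a + e over reference
# rows; Var(a) = sigma2g / s, s = sum 2 p q; returns GEBV = W_all %*% a_hat.
snpBlupOracle <- function(dosAll, refRows, y, d, p, sigma2g, sigma2e) {
  W <- sweep(dosAll, 2, 2 * p, `-`)
  Wr <- W[refRows, , drop = FALSE]
  s <- sum(2 * p * (1 - p))
  Rinv <- diag(1 / (d * sigma2e), length(y))
  m <- ncol(W)
  C <- rbind(
    cbind(sum(Rinv), t(rep(1, length(y))) %*% Rinv %*% Wr),
    cbind(t(Wr) %*% Rinv %*% rep(1, length(y)),
          t(Wr) %*% Rinv %*% Wr + diag(s / sigma2g, m)))
  rhs <- c(sum(Rinv %*% y), t(Wr) %*% Rinv %*% y)
  sol <- solve(C, rhs)
  drop(W %*% sol[-1])
}

# Build a small two-population simulated system for model tests.
smallSim <- function(seed, nMarkers = 100, Ne = 60, burnin = 60,
                     divergence = 3, sizes = c(150, 150), nQtl = 30,
                     h2 = 0.3, rG = 0.8) {
  cfg <- simConfig(nChromosomes = 2, chromLengthMorgans = 1,
                   nMarkersPerChrom = nMarkers, Ne = Ne,
                   nBurninGenerations = burnin,
                   nDivergenceGenerations = divergence,
                   splitSizes = sizes, nQtl = nQtl, h2 = h2, rG = rG,
                   trendPerYear = 0, seed = seed)
  pops <- splitAndDiverge(simulateBasePopulation(cfg), cfg)
  arch <- assignTraitArchitecture(pops$popA, pops$popB, cfg)
  list(cfg = cfg, popA = pops$popA, popB = pops$popB, arch = arch)
}

# Acceptance scenario runs are shared between test blocks (rG recovery and
# the joint-vs-single directional check use the same fits). Cached per
# session.
.accEnv <- new.env(parent = emptyenv())
acceptanceScenarios <- function(seeds = 1:10) {
  key <- paste0("s", paste(seeds, collapse = "_"))
  if (is.null(.accEnv[[key]]))
    .accEnv[[key]] <- lapply(seeds, function(s)
      runScenario(smallScenarioConfig(seed = s)))
  .accEnv[[key]]
}
acceptanceControls <- function(seeds = 1:10) {
  key <- paste0("c", paste(seeds, collapse = "_"))
  if (is.null(.accEnv[[key]]))
    .accEnv[[key]] <- lapply(seeds, function(s) {
      cfg <- smallScenarioConfig(seed = s, independentPopB = TRUE)
      cfg$sim@rG <- 0
      runScenario(cfg)
    })
  .accEnv[[key]]
}
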