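# Independent oracles and small fixture builders shared across test files.

# Naive dense evaluation of the r-score criterion: forms every matrix of the
# defining trace expressions explicitly, with no precomputation. This is the
# reference the optimized implementation is checked against.
naiveRScore <- function(X0, Xt, lambda = 1) {
  n0 <- nrow(X0)
  nt <- nrow(Xt)
  Cmat <- diag(n0) - matrix(1 / n0, n0, n0)
  Theta <- t(X0) %*% Cmat %*% X0
  A <- t(Xt) %*% solve(Xt %*% t(Xt) + lambda * diag(nt))
  q12 <- sum(diag(Theta %*% A %*% Xt))
  q1 <- (n0 - 1) + sum(diag(Theta))
  q2 <- sum(diag(t(A) %*% Theta %*% A)) +
    sum(diag(t(Xt) %*% t(A) %*% Theta %*% A %*% Xt))
  q12 / sqrt(q1 * q2)
}

# Wrap an arbitrary score matrix as a valid PCScores object (tests that
# exercise the optimizer only need the scores slot).
makePC <- function(L) {
  if (is.null(rownames(L))) rownames(L) <- sprintf("i%03d", seq_len(nrow(L)))
  r <- ncol(L)
  Q <- qr.Q(qr(matrix(stats::rnorm((r + 1) * r), r + 1, r)))
  new("PCScores", scores = L, eigenvalues = as.numeric(seq(r, 1)),
      loadings = Q)
}

# Ridge-regression (rrBLUP) fitted genotypic values with a known intercept:
# g_hat = X beta_hat, beta_hat = X'(XX' + lambda* I)^-1 (y - mu 1).
ridgeFit <- function(X, y, lambdaStar, mu) {
  n <- nrow(X)
  drop(X %*% crossprod(X, solve(X %*% t(X) + lambdaStar * diag(n), y - mu)))
}

# One shared mid-sized structured panel, built once per test run.
.fixtures <- new.env(parent = emptyenv())

panel300 <- function() {
  if (is.null(.fixtures$panel300)) {
    cfg <- simConfig(nIndividuals = 300L, nMarkers = 1000L, nClusters = 3L,
                     divergence = 0.15, missingRate = 0.02, h2 = 0.5,
                     nQtl = 100L, seed = 424241L)
    sim <- simulateGenotypes(cfg)
    g <- imputeMean(sim$genotypes)
    pc <- suppressWarnings(pcScores(standardizeMarkers(g)))
    .fixtures$panel300 <- list(cfg = cfg, genotypes = g, pc = pc,
                               clusters = sim$clusters)
  }
  .fixtures$panel300
}

# Small unstructured panel for fast pipeline-level tests.
panel120 <- function() {
  if (is.null(.fixtures$panel120)) {
    cfg <- simConfig(nIndividuals = 120L, nMarkers = 300L, nClusters = 1L,
                     divergence = 0, missingRate = 0, h2 = 0.5, nQtl = 60L,
                     seed = 77L)
    sim <- simulateGenotypes(cfg)
    g <- imputeMean(sim$genotypes)
    pc <- suppressWarnings(pcScores(standardizeMarkers(g)))
    .fixtures$panel120 <- list(cfg = cfg, genotypes = g, pc = pc,
                               clusters = sim$clusters)
  }
  .fixtures$panel120
}
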