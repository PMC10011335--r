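#' @include AllClasses.R AllGenerics.R markers.R
NULL

#' Construct a simulation configuration
#'
#' Defaults emulate the structured diversity panels the size-determination
#' procedure targets: a few hundred individuals, thousands of SNPs, a handful
#' of subpopulations with moderate allele-frequency divergence, a lightly
#' missing genotype matrix and a moderately heritable polygenic trait.
#'
#' @param nIndividuals,nMarkers panel dimensions.
#' @param nClusters number of subpopulations.
#' @param divergence Balding-Nichols F governing between-cluster
#'   allele-frequency spread, in \[0, 1).
#' @param mafRange interval for ancestral minor allele frequencies.
#' @param missingRate completely-at-random missing call rate.
#' @param h2 narrow-sense heritability of the simulated trait.
#' @param nQtl number of causal markers.
#' @param seed integer seed.
#' @return a [SimConfig-class].
#' @export
simConfig <- function(nIndividuals = 300L, nMarkers = 1000L, nClusters = 3L,
                      divergence = 0.15, mafRange = c(0.05, 0.5),
                      missingRate = 0.02, h2 = 0.5, nQtl = 100L, seed = 1L) {
  new("SimConfig", nIndividuals = as.integer(nIndividuals),
      nMarkers = as.integer(nMarkers), nClusters = as.integer(nClusters),
      divergence = as.numeric(divergence), mafRange = as.numeric(mafRange),
      missingRate = as.numeric(missingRate), h2 = as.numeric(h2),
      nQtl = as.integer(nQtl), seed = as.integer(seed))
}

#' Simulate a structured SNP genotype panel
#'
#' Ancestral minor-allele frequencies are drawn uniformly in `mafRange`;
#' per-cluster frequencies are perturbed by a Balding-Nichols draw
#' Beta(p (1-F)/F, (1-p)(1-F)/F) with F = `divergence` (F = 0 leaves
#' frequencies unperturbed, one unstructured population). Diploid genotypes
#' are sampled per individual and coded -1/0/1 by the per-locus major allele;
#' missingness is applied completely at random at `missingRate`.
#'
#' @param cfg a [SimConfig-class].
#' @return list with elements `genotypes` (a [GenotypeMatrix-class]) and
#'   `clusters` (named character vector of cluster labels).
#' @export
simulateGenotypes <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  withr::with_seed(cfg@seed, {
    n <- cfg@nIndividuals
    p <- cfg@nMarkers
    k <- cfg@nClusters
    ## near-equal cluster sizes
    sizes <- diff(round(seq(0, n, length.out = k + 1L)))
    labels <- rep(paste0("C", seq_len(k)), times = sizes)
    anc <- stats::runif(p, cfg@mafRange[1], cfg@mafRange[2])
    freq <- matrix(anc, nrow = k, ncol = p, byrow = TRUE)
    if (cfg@divergence > 0) {
      F <- cfg@divergence
      for (ck in seq_len(k))
        freq[ck, ] <- stats::rbeta(p, anc * (1 - F) / F,
                                   (1 - anc) * (1 - F) / F)
      freq <- pmin(pmax(freq, 1e-4), 1 - 1e-4)
    }
    ## allele dose of the ancestral-minor allele; coded by the major allele
    scores <- matrix(NA_real_, n, p,
                     dimnames = list(sprintf("ind%03d", seq_len(n)),
                                     sprintf("snp%05d", seq_len(p))))
    row0 <- 0L
    for (ck in seq_len(k)) {
      rows <- row0 + seq_len(sizes[ck])
      dose <- matrix(stats::rbinom(length(rows) * p, 2L,
                                   rep(freq[ck, ], each = length(rows))),
                     nrow = length(rows))
      scores[rows, ] <- 1 - dose   # 0 minor copies -> +1 (major homozygote)
      row0 <- row0 + sizes[ck]
    }
    if (cfg@missingRate > 0) {
      drop <- stats::runif(n * p) < cfg@missingRate
      scores[drop] <- NA_real_
    }
    ## guard: markers that lost every call are refilled at one random cell
    empty <- which(colSums(!is.na(scores)) == 0L)
    for (j in empty) scores[sample.int(n, 1L), j] <- 0
    list(genotypes = newGenotypeMatrix(scores),
         clusters = stats::setNames(labels, rownames(scores)))
  })
}

#' Simulate heritable phenotypes from a genotype panel
#'
#' Draws `nQtl` causal markers with standard-normal effects, forms genetic
#' values g = X beta from the imputed coded scores, and adds Gaussian noise
#' scaled so that the realized Var(g)/Var(y) targets `h2` (for `h2 = 0` the
#' phenotype is pure noise; for `h2 = 1` it is the genetic value).
#'
#' @param g an imputed [GenotypeMatrix-class].
#' @param h2 target heritability in \[0, 1\].
#' @param nQtl number of causal markers.
#' @param seed integer seed.
#' @return list with `phenotypes` (named numeric), `effects` (named by causal
#'   marker), `geneticValues`, and `realizedH2`.
#' @export
simulatePhenotypes <- function(g, h2, nQtl, seed = 1L) {
  stopifnot(is(g, "GenotypeMatrix"))
  if (anyNA(scoreMatrix(g))) stop("genotypes must be imputed first")
  if (h2 < 0 || h2 > 1) stop("h2 must be in [0, 1]")
  withr::with_seed(as.integer(seed), {
    X <- scoreMatrix(g)
    nQtl <- as.integer(nQtl)
    if (nQtl < 1L || nQtl > ncol(X)) stop("nQtl out of range")
    qtl <- sort(sample.int(ncol(X), nQtl))
    beta <- stats::rnorm(nQtl)
    gv <- drop(X[, qtl, drop = FALSE] %*% beta)
    vg <- stats::var(gv)
    if (h2 == 1 && vg <= 0)
      stop("h2 = 1 requested but genetic variance is zero")
    y <- if (h2 == 0) {
      stats::rnorm(nrow(X))
    } else if (h2 == 1) {
      gv
    } else {
      eps <- stats::rnorm(nrow(X), sd = sqrt(vg * (1 - h2) / h2))
      gv + eps
    }
    names(y) <- rownames(X)
    realized <- if (h2 == 0) 0 else vg / stats::var(y)
    list(phenotypes = y, effects = stats::setNames(beta, colnames(X)[qtl]),
         geneticValues = stats::setNames(gv, rownames(X)),
         realizedH2 = realized)
  })
}
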