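#' @include AllClasses.R AllGenerics.R
NULL

#' Genomic kinship from PC scores
#'
#' K = (1/n) L L' restricted to the requested rows/columns, with n the total
#' dataset size by default (configurable for sensitivity checks).
#'
#' @param pc a [PCScores-class] for the whole dataset.
#' @param rows,cols index vectors into the dataset.
#' @param divisor kinship divisor; defaults to the total number of
#'   individuals.
#' @return numeric kinship matrix.
#' @export
kinshipMatrix <- function(pc, rows, cols = rows,
                          divisor = nrow(scoreMatrix(pc))) {
  L <- scoreMatrix(pc)
  tcrossprod(L[rows, , drop = FALSE], L[cols, , drop = FALSE]) / divisor
}

remlRatio <- function(y, K) {
  ## REML for y = mu 1 + g + e, g ~ N(0, s2g K), e ~ N(0, s2e I), over the
  ## ratio r = s2e / s2g: coarse log-grid, then golden-section refinement.
  n <- length(y)
  eg <- eigen(K, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  yt <- crossprod(eg$vectors, y)
  xt <- crossprod(eg$vectors, rep(1, n))
  negRestLL <- function(logr) {
    r <- exp(logr)
    w <- d + r                      # V = s2g (K + r I) up to scale
    xtwx <- sum(xt^2 / w)
    bhat <- sum(xt * yt / w) / xtwx
    resid2 <- sum((yt - xt * bhat)^2 / w)
    s2g <- resid2 / (n - 1)
    ## -2 restricted loglik up to constants
    (n - 1) * log(s2g) + sum(log(w)) + log(xtwx)
  }
  grid <- seq(log(1e-4), log(1e4), length.out = 41L)
  vals <- vapply(grid, negRestLL, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  exp(stats::optimize(negRestLL, c(lo, hi), tol = 1e-8)$minimum)
}

#' Fit the GBLUP model on a training set
#'
#' Solves Henderson's mixed-model equations for y = mu 1 + g + e with
#' g ~ N(0, sigma2_g K_t), in the equivalent generalized-least-squares form
#' mu_hat = (1' V^-1 1)^-1 1' V^-1 y and g_hat = K (K + r I)^-1 (y - mu_hat 1)
#' with r = sigma2_e / sigma2_g (identical solutions, no K inverse needed).
#' With `varianceRatio = "reml"` the ratio is estimated by maximizing the
#' restricted likelihood over a log-grid refined by golden-section search.
#'
#' @param yTrain training phenotypes.
#' @param KTrain training kinship (from [kinshipMatrix()]).
#' @param varianceRatio positive scalar sigma2_e / sigma2_g, or `"reml"`.
#' @param divisorN the dataset size used as kinship divisor (bookkeeping).
#' @return a [GBLUPModel-class].
#' @export
fitGBLUP <- function(yTrain, KTrain, varianceRatio = "reml",
                     divisorN = nrow(KTrain)) {
  yTrain <- as.numeric(yTrain)
  KTrain <- as.matrix(KTrain)
  if (length(yTrain) != nrow(KTrain) || nrow(KTrain) != ncol(KTrain))
    stop("phenotype / kinship dimensions do not match")
  if (!isTRUE(all.equal(KTrain, t(KTrain), tolerance = 1e-8)))
    stop("kinship must be symmetric")
  ratio <- if (identical(varianceRatio, "reml")) remlRatio(yTrain, KTrain)
           else as.numeric(varianceRatio)
  if (!is.finite(ratio) || ratio <= 0) stop("variance ratio must be positive")
  n <- length(yTrain)
  V <- KTrain
  diag(V) <- diag(V) + ratio
  ch <- tryCatch(chol(V), error = function(e)
    stop("singular mixed-model system (rank-deficient K + ratio*I): ",
         conditionMessage(e)))
  Vi1 <- backsolve(ch, forwardsolve(t(ch), rep(1, n)))
  Viy <- backsolve(ch, forwardsolve(t(ch), yTrain))
  muHat <- sum(Vi1 * yTrain) / sum(Vi1)
  gHat <- drop(KTrain %*% (Viy - Vi1 * muHat))
  new("GBLUPModel", muHat = muHat, gHatTrain = gHat, KTrain = KTrain,
      varianceRatio = ratio, divisorN = as.integer(divisorN))
}

#' Predict GEBVs for a test set by Henderson projection
#'
#' g0_hat = K0 K_t^-1 g_t_hat; the returned GEBVs are g0_hat + mu_hat. If
#' K_t is numerically singular a logged ridge jitter of 1e-8 tr(K_t)/n_t is
#' added before inverting.
#'
#' @param model a [GBLUPModel-class].
#' @param KCross test-by-training kinship (same divisor as the model's K_t).
#' @return numeric vector of GEBVs for the test individuals.
#' @export
predictGEBV <- function(model, KCross) {
  stopifnot(is(model, "GBLUPModel"))
  KCross <- as.matrix(KCross)
  if (ncol(KCross) != nrow(model@KTrain))
    stop("KCross column dimension must match the training set")
  Kt <- model@KTrain
  sol <- tryCatch(solve(Kt, model@gHatTrain), error = function(e) NULL)
  if (is.null(sol)) {
    jit <- 1e-8 * sum(diag(Kt)) / nrow(Kt)
    message(sprintf("predictGEBV: K_t singular, adding ridge jitter %.3g", jit))
    diag(Kt) <- diag(Kt) + jit
    sol <- solve(Kt, model@gHatTrain)
  }
  drop(KCross %*% sol) + model@muHat
}

#' Prediction ability
#'
#' Pearson correlation between GEBVs and observed phenotypes.
#'
#' @param gebv predicted GEBVs.
#' @param yObserved observed phenotypes.
#' @return scalar correlation.
#' @export
predictionAbility <- function(gebv, yObserved) {
  if (length(gebv) != length(yObserved)) stop("length mismatch")
  if (length(gebv) < 3L) stop("need at least 3 pairs")
  if (stats::sd(gebv) == 0 || stats::sd(yObserved) == 0)
    stop("undefined correlation: constant input")
  stats::cor(gebv, yObserved)
}

#' Relative prediction ability REpa
#'
#' Ratio of the prediction ability achieved with the optimized training set
#' to that achieved with the whole candidate set. Reported unclamped: values
#' above 1 mean the optimized subset out-predicted the full candidate set.
#'
#' @param rT prediction ability r(n_t*) of the optimized training set.
#' @param rC prediction ability r(n_c) of the full candidate set.
#' @return scalar REpa.
#' @export
repa <- function(rT, rC) {
  if (rC == 0) stop("candidate-set prediction ability is zero; REpa undefined")
  rT / rC
}

#' Assess a chosen training set against the candidate set
#'
#' Fits GBLUP on the optimized training set and on the full candidate set,
#' predicts GEBVs for the test set from each, and reports both prediction
#' abilities and their ratio REpa.
#'
#' @param pc a [PCScores-class] for the whole dataset.
#' @param phenotypes numeric phenotype vector for the whole dataset.
#' @param trainingIndices indices of the optimized training set S_t*.
#' @param candidateIndices indices of the candidate set S_c.
#' @param testIndices indices of the test set S_0.
#' @param varianceRatio passed to [fitGBLUP()].
#' @return a [PredictionAssessment-class].
#' @export
assessPrediction <- function(pc, phenotypes, trainingIndices,
                             candidateIndices, testIndices,
                             varianceRatio = "reml") {
  n <- nrow(scoreMatrix(pc))
  gebvFor <- function(train) {
    Kt <- kinshipMatrix(pc, train, divisor = n)
    K0 <- kinshipMatrix(pc, testIndices, train, divisor = n)
    model <- fitGBLUP(phenotypes[train], Kt, varianceRatio, divisorN = n)
    predictGEBV(model, K0)
  }
  gebvT <- gebvFor(trainingIndices)
  gebvC <- gebvFor(candidateIndices)
  y0 <- phenotypes[testIndices]
  rT <- predictionAbility(gebvT, y0)
  rC <- predictionAbility(gebvC, y0)
  new("PredictionAssessment", gebvTest = gebvT, rTrainingSet = rT,
      rCandidateSet = rC, repa = repa(rT, rC))
}
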