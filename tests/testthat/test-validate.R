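test_that("an overwhelming noise ratio shrinks the BLUP to the mean", {
  set.seed(71)
  X <- matrix(rnorm(6 * 10), 6, 10)
  K <- tcrossprod(X) / 10
  y <- rnorm(6, mean = 3)
  m <- fitGBLUP(y, K, varianceRatio = 1e8)
  expect_lt(max(abs(m@gHatTrain)), 1e-5)
  expect_equal(m@muHat, mean(y), tolerance = 1e-4)
})

test_that("GBLUP reproduces rrBLUP fitted values under the matched mapping", {
  # K = XX'/p and sigma2_g = p sigma2_beta make the two models identical:
  # the GBLUP ratio is lambda*/p for ridge shrinkage lambda*.
  set.seed(72)
  for (i in 1:20) {
    n <- sample(5:9, 1)
    p <- sample(8:15, 1)
    lambdaStar <- sample(c(0.5, 1, 4), 1)
    X <- matrix(rnorm(n * p), n, p)
    y <- rnorm(n)
    K <- tcrossprod(X) / p
    m <- fitGBLUP(y, K, varianceRatio = lambdaStar / p)
    gRidge <- ridgeFit(X, y, lambdaStar, m@muHat)
    expect_equal(m@gHatTrain, gRidge, tolerance = 1e-8)
  }
})

test_that("Henderson projection reduces to identity on the training set", {
  set.seed(73)
  X <- matrix(rnorm(8 * 12), 8, 12)
  K <- tcrossprod(X) / 12
  y <- rnorm(8)
  m <- fitGBLUP(y, K, varianceRatio = 1.3)
  expect_equal(predictGEBV(m, K), m@gHatTrain + m@muHat, tolerance = 1e-8)
  # a test individual identical to a training one gets that individual's GEBV
  Kcross <- K[c(2L, 5L), , drop = FALSE]
  expect_equal(predictGEBV(m, Kcross),
               m@gHatTrain[c(2L, 5L)] + m@muHat, tolerance = 1e-8)
  expect_error(predictGEBV(m, K[, 1:3]), "dimension")
})

test_that("projection matches a direct joint-BLUP computation", {
  # cov(g0, y_t) = s2g K0 gives g0_hat = K0 (K_t + r I)^-1 (y - mu 1); the
  # K0 K_t^-1 g_t route must agree.
  set.seed(74)
  n <- 10
  p <- 25
  X <- matrix(rnorm((n + 4) * p), n + 4, p)
  K <- tcrossprod(X) / p
  Kt <- K[1:n, 1:n]
  K0 <- K[n + 1:4, 1:n]
  y <- rnorm(n)
  r <- 0.8
  m <- fitGBLUP(y, Kt, varianceRatio = r)
  direct <- drop(K0 %*% solve(Kt + r * diag(n), y - m@muHat)) + m@muHat
  expect_equal(predictGEBV(m, K0), direct, tolerance = 1e-6)
})

test_that("REML recovers the variance ratio order of magnitude", {
  set.seed(75)
  hits <- 0
  for (i in 1:25) {
    cfg <- simConfig(nIndividuals = 400L, nMarkers = 600L, nClusters = 1L,
                     divergence = 0, missingRate = 0, h2 = 0.5, nQtl = 150L,
                     seed = 9000L + i)
    sim <- simulateGenotypes(cfg)
    g <- imputeMean(sim$genotypes)
    ph <- simulatePhenotypes(g, 0.5, 150L, seed = 100L + i)
    pc <- suppressWarnings(pcScores(standardizeMarkers(g)))
    K <- kinshipMatrix(pc, seq_len(400L))
    m <- fitGBLUP(ph$phenotypes, K, varianceRatio = "reml")
    # h2 = 0.5 means var(eps)/var(g) = 1; K is scaled so tr(K)/n ~ p/n,
    # putting the matched ratio at (1 - h2)/h2 * tr(K)/n
    truth <- sum(diag(K)) / 400
    hits <- hits + (m@varianceRatio > truth / 2 && m@varianceRatio < truth * 2)
  }
  expect_gte(hits, 20)   # >= 80% of 25 replicates
})

test_that("prediction ability is the Pearson correlation with guards", {
  g <- c(0.3, 1.2, -0.5, 0.8, 0.1)
  y <- c(0.5, 1.0, -0.2, 1.1, -0.3)
  expect_equal(predictionAbility(g, g), 1)
  expect_equal(predictionAbility(g, -g), -1)
  # hand computation of r for the 5-pair table
  num <- sum((g - mean(g)) * (y - mean(y)))
  den <- sqrt(sum((g - mean(g))^2) * sum((y - mean(y))^2))
  expect_equal(predictionAbility(g, y), num / den, tolerance = 1e-12)
  expect_error(predictionAbility(rep(1, 5), y), "constant")
  expect_error(predictionAbility(g[1:2], y[1:2]), "at least 3")
})

test_that("REpa is the unclamped prediction-ability ratio", {
  expect_equal(repa(0.6, 0.6), 1)
  expect_equal(repa(0.5, 0.4), 1.25)
  expect_gt(repa(0.7, 0.6), 1)     # values above 1 are meaningful
  expect_error(repa(0.5, 0), "undefined")
})

test_that("assessPrediction wires kinship, GBLUP and REpa together", {
  p120 <- panel120()
  ph <- simulatePhenotypes(p120$genotypes, 0.5, 60L, seed = 5L)
  test <- 81:120   # 40 test individuals keep the correlation estimate stable
  cand <- 1:80
  train <- seq(1, 80, by = 2)
  a <- assessPrediction(p120$pc, ph$phenotypes, train, cand, test,
                        varianceRatio = "reml")
  expect_length(a@gebvTest, 40L)
  expect_equal(a@repa, a@rTrainingSet / a@rCandidateSet, tolerance = 1e-12)
  expect_gt(a@rCandidateSet, 0.2)  # h2 = 0.5 must yield real signal
})
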