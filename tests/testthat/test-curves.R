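test_that("noiseless logistic data recover the generating parameters", {
  x <- seq(25, 300, by = 25)
  y <- 0.875 / (1 + exp(-2.29 - 0.015 * x))
  fit <- fitLogistic(x, y)
  expect_true(fit@converged)
  expect_equal(fit@alpha, 0.875, tolerance = 1e-6)
  expect_equal(fit@beta, -2.29, tolerance = 1e-6)
  expect_equal(fit@gamma, 0.015, tolerance = 1e-6)
  expect_lt(fit@residualSS, 1e-12)
  expect_equal(predict(fit, x), y, tolerance = 1e-8)
})

test_that("degenerate or underdetermined profiles are rejected", {
  expect_error(fitLogistic(c(10, 20, 30), c(0.1, 0.2, 0.3)), "4 distinct")
  expect_error(fitLogistic(c(10, 20, 30, 40), rep(0.5, 4)), "degenerate fit")
  expect_error(fitWeibull(c(10, 20, 30, 40), c(0.1, 0.2, 0.3, 0.35)),
               "5 distinct")
  expect_error(fitLogistic(c(10, 20, 30, NA), c(0.1, 0.2, 0.3, 0.4)),
               "non-finite")
})

test_that("noiseless Weibull-type data recover the generating parameters", {
  x <- seq(20, 300, by = 20)
  y <- 0.88 - 0.85 * exp(-0.01 * x)   # theta = 1: shifted exponential
  fit <- fitWeibull(x, y)
  expect_true(fit@converged)
  expect_equal(fit@alpha, 0.88, tolerance = 1e-5)
  expect_equal(fit@beta, 0.85, tolerance = 1e-5)
  expect_equal(fit@gamma, 0.01, tolerance = 1e-5)
  expect_equal(fit@theta, 1, tolerance = 1e-4)
})

test_that("the 4-parameter family fits at least as well as the logistic", {
  set.seed(8)
  x <- seq(25, 250, by = 25)
  y <- 0.9 / (1 + exp(-1.8 - 0.02 * x)) + rnorm(length(x), sd = 0.005)
  lg <- fitLogistic(x, y)
  wb <- fitWeibull(x, y, initFrom = lg)
  expect_lte(wb@residualSS, lg@residualSS + 1e-10)
})

test_that("the operating curve has its defining identities", {
  fit <- new("GrowthCurveFit", family = "logistic", alpha = 0.9, beta = 2,
             gamma = 0.01, theta = NA_real_, residualSS = 0, nPoints = 10L,
             converged = TRUE)
  nc <- 200                       # beta - gamma * nc = 0
  expect_equal(rers(fit, nc, nc), 1)
  ntHalf <- (2 - log(3)) / 0.01   # beta - gamma * nt = ln 3 -> RErs = 2/4
  expect_equal(rers(fit, ntHalf, nc), 0.5, tolerance = 1e-12)
  grid <- seq(5, nc, by = 5)
  expect_true(all(diff(rers(fit, grid, nc)) > 0))   # monotone for gamma > 0
  expect_error(rers(fit, 300, nc), "exceed")
})

test_that("closed-form inversion meets its target with the ceiling convention", {
  fit <- new("GrowthCurveFit", family = "logistic", alpha = 0.875,
             beta = -2.2867, gamma = 0.0152, theta = NA_real_,
             residualSS = 0, nPoints = 12L, converged = TRUE)
  nc <- 317L
  atMin <- rers(fit, 25L, nc)
  for (t in seq(atMin + 0.005, 0.995, length.out = 10)) {
    d <- invertRers(fit, t, nc, nMin = 25L)
    expect_gte(d@achievedRers, t)
    expect_gte(rers(fit, d@nTarget, nc), t)
    if (d@nTarget > 25L)
      expect_lt(rers(fit, d@nTarget - 1L, nc), t)
    # closed form agrees with an independent bisection within one size unit
    root <- uniroot(function(n) rers(fit, n, nc) - t, c(25, nc),
                    tol = 1e-10)$root
    expect_lt(abs(d@nContinuous - root), 1 + 1e-6)
  }
  expect_identical(invertRers(fit, 1, nc, 25L)@nTarget, nc)
  expect_error(invertRers(fit, atMin - 0.1, nc, nMin = 25L),
               "attainable range")
  expect_error(invertRers(fit, 1.2, nc), "in \\(0, 1\\]")
})

test_that("Weibull-type inversion by bisection meets its target too", {
  x <- seq(20, 300, by = 20)
  y <- 0.88 - 0.85 * exp(-0.012 * x)
  fit <- fitWeibull(x, y)
  nc <- 300L
  d <- invertRers(fit, 0.95, nc, nMin = 20L)
  expect_gte(d@achievedRers, 0.95)
  expect_lt(rers(fit, d@nTarget - 1L, nc), 0.95)
  expect_identical(invertRers(fit, 1, nc, 20L)@nTarget, nc)
})

test_that("gamma survives moderate noise across seeded replicates", {
  # a profile with a visible S-shape over the grid (rising 0.21 -> 0.83)
  set.seed(55)
  x <- seq(25, 300, by = 25)
  true <- c(alpha = 0.875, beta = 1.5, gamma = 0.015)
  relErr <- replicate(50, {
    y <- true["alpha"] / (1 + exp(true["beta"] - true["gamma"] * x)) +
      rnorm(length(x), sd = 0.01)
    fit <- fitLogistic(x, y)
    abs(fit@gamma - true["gamma"]) / true["gamma"]
  })
  expect_lt(median(relErr), 0.10)
})
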