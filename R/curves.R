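#' @include AllClasses.R AllGenerics.R
NULL

logisticFun <- function(x, alpha, beta, gamma) alpha / (1 + exp(beta - gamma * x))
weibullFun <- function(x, alpha, beta, gamma, theta) alpha - beta * exp(-gamma * x^theta)

#' Predicted curve values
#'
#' @param object a [GrowthCurveFit-class].
#' @param x sizes at which to evaluate the fitted curve.
#' @param ... ignored.
#' @return numeric vector of fitted r-scores.
#' @export
setMethod("predict", "GrowthCurveFit", function(object, x, ...) {
  if (object@family == "logistic")
    logisticFun(x, object@alpha, object@beta, object@gamma)
  else
    weibullFun(x, object@alpha, object@beta, object@gamma, object@theta)
})

checkCurveData <- function(sizes, scores, minDistinct) {
  if (length(sizes) != length(scores)) stop("sizes and scores lengths differ")
  if (!all(is.finite(sizes)) || !all(is.finite(scores)))
    stop("non-finite curve data")
  if (length(unique(sizes)) < minDistinct)
    stop("need at least ", minDistinct, " distinct sizes")
  if (stats::sd(scores) < 1e-10 * max(1, max(abs(scores))))
    stop("degenerate fit: scores are (near-)constant, growth rate unidentifiable")
}

nlsFit <- function(formula, data, start, lower = NULL) {
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12, ptol = 1e-12)
  tryCatch({
    fit <- if (is.null(lower))
      minpack.lm::nlsLM(formula, data = data, start = start, control = ctrl)
    else
      minpack.lm::nlsLM(formula, data = data, start = start, control = ctrl,
                        lower = lower)
    list(coef = stats::coef(fit), rss = sum(stats::residuals(fit)^2),
         converged = fit$convInfo$isConv)
  }, error = function(e) NULL)
}

#' Fit the logistic growth curve to an r-score profile
#'
#' Nonlinear least squares for y = alpha / (1 + exp(beta - gamma x)).
#' Default initialization: alpha0 = 1.02 max(y); gamma0 from the log-odds
#' slope between the first and last points (ordered by size); beta0 from the
#' first point. If that start fails to converge, a coarse grid of gamma0
#' values is retried before failing.
#'
#' @param sizes training set sizes (>= 4 distinct values).
#' @param scores r-scores at those sizes.
#' @param init optional named triple `c(alpha=, beta=, gamma=)` overriding the
#'   default start.
#' @return a [GrowthCurveFit-class].
#' @export
fitLogistic <- function(sizes, scores, init = NULL) {
  checkCurveData(sizes, scores, 4L)
  ord <- order(sizes)
  x <- as.numeric(sizes)[ord]
  y <- as.numeric(scores)[ord]
  data <- data.frame(x = x, y = y)

  starts <- list()
  if (!is.null(init)) {
    starts <- list(as.list(init[c("alpha", "beta", "gamma")]))
  } else {
    a0 <- 1.02 * max(y)
    z1 <- log(a0 / y[1L] - 1)
    zn <- log(a0 / y[length(y)] - 1)
    if (is.finite(z1) && is.finite(zn)) {
      g0 <- (z1 - zn) / (x[length(x)] - x[1L])
      starts <- list(list(alpha = a0, beta = z1 + g0 * x[1L], gamma = g0))
    }
    for (g0 in c(0.001, 0.005, 0.01, 0.02, 0.05, 0.1)) {
      b0 <- if (is.finite(z1)) z1 + g0 * x[1L] else g0 * x[1L]
      starts <- c(starts, list(list(alpha = a0, beta = b0, gamma = g0)))
    }
  }
  best <- NULL
  for (s in starts) {
    f <- nlsFit(y ~ alpha / (1 + exp(beta - gamma * x)), data, s)
    if (!is.null(f) && (is.null(best) || f$rss < best$rss)) best <- f
    if (!is.null(best) && best$converged && is.null(init)) break
  }
  if (is.null(best))
    stop("logistic curve fit failed to converge for all starting values")
  cf <- best$coef
  new("GrowthCurveFit", family = "logistic", alpha = unname(cf["alpha"]),
      beta = unname(cf["beta"]), gamma = unname(cf["gamma"]),
      theta = NA_real_, residualSS = best$rss,
      nPoints = length(y), converged = isTRUE(best$converged))
}

#' Fit the Weibull-type growth curve to an r-score profile
#'
#' Nonlinear least squares for y = alpha - beta exp(-gamma x^theta), the
#' four-parameter family used when the logistic curve underfits near the
#' profile maximum. Initialization is a multi-start over a (gamma0, theta0)
#' grid (including the sign-flipped branch), with the asymptote seeded from a
#' supplied logistic fit when available.
#'
#' @param sizes training set sizes (>= 5 distinct values).
#' @param scores r-scores at those sizes.
#' @param initFrom optional logistic [GrowthCurveFit-class] whose asymptote
#'   seeds alpha0.
#' @return a [GrowthCurveFit-class].
#' @export
fitWeibull <- function(sizes, scores, initFrom = NULL) {
  checkCurveData(sizes, scores, 5L)
  ord <- order(sizes)
  x <- as.numeric(sizes)[ord]
  y <- as.numeric(scores)[ord]
  data <- data.frame(x = x, y = y)
  a0 <- if (!is.null(initFrom) && is(initFrom, "GrowthCurveFit") &&
            initFrom@family == "logistic" && initFrom@converged)
    max(initFrom@alpha, 1.001 * max(y)) else 1.02 * max(y)

  best <- NULL
  for (g0 in c(0.0005, 0.002, 0.01, 0.05, -0.002, -0.02)) {
    for (t0 in c(0.5, 1, 1.5, -0.5)) {
      b0 <- (a0 - y[1L]) * exp(g0 * x[1L]^t0)
      if (!is.finite(b0)) next
      s <- list(alpha = a0, beta = b0, gamma = g0, theta = t0)
      f <- nlsFit(y ~ alpha - beta * exp(-gamma * x^theta), data, s)
      if (!is.null(f) && isTRUE(f$converged) &&
          (is.null(best) || f$rss < best$rss)) best <- f
    }
  }
  if (is.null(best))
    stop("Weibull-type curve fit failed to converge over the multi-start grid")
  cf <- best$coef
  new("GrowthCurveFit", family = "weibull", alpha = unname(cf["alpha"]),
      beta = unname(cf["beta"]), gamma = unname(cf["gamma"]),
      theta = unname(cf["theta"]), residualSS = best$rss,
      nPoints = length(y), converged = TRUE)
}

#' Relative operating curve RErs
#'
#' Fitted r-score at size `nT` relative to the fitted r-score at the
#' candidate set size `nC`. For the logistic family this is the closed form
#' (1 + exp(beta - gamma nC)) / (1 + exp(beta - gamma nT)); for the
#' Weibull-type family the generic ratio fitted(nT) / fitted(nC) (which
#' reduces to the same expression in the logistic case).
#'
#' @param fit a converged [GrowthCurveFit-class].
#' @param nT training set size(s); vectorized.
#' @param nC candidate set size.
#' @return RErs value(s) in (0, 1] for nT <= nC.
#' @export
rers <- function(fit, nT, nC) {
  stopifnot(is(fit, "GrowthCurveFit"))
  if (!fit@converged) stop("curve fit did not converge")
  if (any(nT > nC)) stop("nT must not exceed nC")
  if (fit@family == "logistic") {
    (1 + exp(fit@beta - fit@gamma * nC)) / (1 + exp(fit@beta - fit@gamma * nT))
  } else {
    denom <- predict(fit, nC)
    if (denom <= 0) stop("fitted value at nC is not positive")
    predict(fit, nT) / denom
  }
}

#' Invert the operating curve at a target relative accuracy
#'
#' Finds the smallest integer size whose RErs meets `target`. The logistic
#' family is inverted in closed form; the Weibull-type family by monotone
#' bisection on \[nMin, nC\]. The integer recommendation is the ceiling of
#' the continuous solution, clamped to \[nMin, nC\], so the target is always
#' met.
#'
#' @param fit a converged [GrowthCurveFit-class].
#' @param target target RErs in (RErs(nMin), 1].
#' @param nC candidate set size.
#' @param nMin smallest size considered (lower end of the profiling grid).
#' @return a [SampleSizeDecision-class].
#' @export
invertRers <- function(fit, target, nC, nMin = 1L) {
  stopifnot(is(fit, "GrowthCurveFit"))
  if (target > 1 || target <= 0) stop("target must be in (0, 1]")
  atMin <- rers(fit, nMin, nC)
  if (target < atMin)
    stop(sprintf(
      "target %.4f is below the operating curve at nMin (RErs(%d) = %.4f); attainable range is [%.4f, 1]",
      target, as.integer(nMin), atMin, atMin))
  cont <- if (fit@family == "logistic") {
    arg <- (1 + exp(fit@beta - fit@gamma * nC)) / target - 1
    (fit@beta - log(arg)) / fit@gamma
  } else {
    f <- function(n) rers(fit, n, nC) - target
    if (f(nC) < 0) nC else stats::uniroot(f, c(nMin, nC), tol = 1e-8)$root
  }
  cont <- min(max(cont, nMin), nC)
  nStar <- as.integer(min(max(ceiling(cont - 1e-9), nMin), nC))
  new("SampleSizeDecision", targetRers = as.numeric(target), nTarget = nStar,
      nContinuous = cont, achievedRers = rers(fit, nStar, nC),
      nC = as.integer(nC), nMin = as.integer(nMin))
}

curveFitToList <- function(fit) {
  list(family = fit@family,
       parameters = as.list(curveCoefficients(fit)),
       residual_ss = fit@residualSS, n_points = fit@nPoints,
       converged = fit@converged)
}
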