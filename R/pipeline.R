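#' @include AllClasses.R AllGenerics.R rscore.R optimizer.R curves.R
NULL

#' Build a candidate/test scenario
#'
#' Fixed-candidate: `nC` candidates are drawn at random first, then `n0` test
#' individuals from the remainder. Non-fixed-candidate: the `n0` test
#' individuals are drawn first and all remaining individuals form the
#' candidate set (so n_c = nTotal - n0).
#'
#' @param nTotal number of individuals in the dataset.
#' @param kind `"fixed-candidate"` or `"non-fixed-candidate"`.
#' @param method `"targeted"` or `"untargeted"`.
#' @param nC candidate set size (fixed-candidate only).
#' @param n0 test set size.
#' @param seed integer seed.
#' @return a [Scenario-class].
#' @export
buildScenario <- function(nTotal, kind = c("fixed-candidate",
                                           "non-fixed-candidate"),
                          method = c("targeted", "untargeted"),
                          nC = NULL, n0, seed = 1L) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  nTotal <- as.integer(nTotal)
  n0 <- as.integer(n0)
  seed <- as.integer(seed)
  if (kind == "fixed-candidate") {
    nC <- as.integer(nC)
    if (is.na(nC) || nC < 2L) stop("fixed-candidate scenario needs nC >= 2")
    if (nC + n0 > nTotal)
      stop("infeasible sizes: nC + n0 = ", nC + n0, " > nTotal = ", nTotal)
    idx <- withr::with_seed(seed, {
      cand <- sort(sample.int(nTotal, nC))
      test <- sort(sample(setdiff(seq_len(nTotal), cand), n0))
      list(cand = cand, test = test)
    })
  } else {
    if (n0 >= nTotal) stop("infeasible sizes: n0 must be < nTotal")
    idx <- withr::with_seed(seed, {
      test <- sort(sample.int(nTotal, n0))
      list(cand = setdiff(seq_len(nTotal), test), test = test)
    })
  }
  new("Scenario", kind = kind, method = method,
      candidates = as.integer(idx$cand), testSet = as.integer(idx$test),
      seed = seed)
}

#' Construct a search grid
#'
#' @param nMin,nMax smallest and largest profiled size.
#' @param delta size increment.
#' @param m optimal training sets generated per size.
#' @param includeNcPoint append the single full-candidate-set point at n_c.
#' @return a [SearchGrid-class].
#' @export
searchGrid <- function(nMin = 25L, nMax = 225L, delta = 25L, m = 10L,
                       includeNcPoint = TRUE) {
  new("SearchGrid", nMin = as.integer(nMin), nMax = as.integer(nMax),
      delta = as.integer(delta), m = as.integer(m),
      includeNcPoint = isTRUE(includeNcPoint))
}

gridSizes <- function(grid) seq(grid@nMin, grid@nMax, by = grid@delta)

referenceContext <- function(pc, scenario, lambda) {
  refIdx <- if (scenario@method == "targeted") scenario@testSet
            else scenario@candidates
  if (scenario@method == "targeted" && !length(refIdx))
    stop("targeted method requires a non-empty test set")
  buildRScoreContext(scoreMatrix(pc)[refIdx, , drop = FALSE], lambda = lambda)
}

scenarioAllocation <- function(scenario, clusters, nT) {
  if (is.null(clusters)) return(NULL)
  candLabels <- as.character(clusters[scenario@candidates])
  basis <- if (scenario@method == "targeted")
    as.character(clusters[scenario@testSet]) else candLabels
  mode <- if (scenario@method == "targeted") "targeted-proportional"
          else "untargeted-proportional"
  allocateClusters(basis, nT, mode, available = table(candLabels),
                   candidateLabels = candLabels)
}

#' Profile optimal r-scores over the size grid
#'
#' For every size on the grid, runs `m` independently seeded training-set
#' optimizations and records their achieved r-scores; optionally appends the
#' single available point at n_t = n_c (the full candidate set). Per-run
#' seeds are derived from the master seed by a counter scheme, so the runs
#' are reproducible individually.
#'
#' @param pc a [PCScores-class] for the whole dataset.
#' @param scenario a [Scenario-class].
#' @param grid a [SearchGrid-class].
#' @param lambda shrinkage of the r-score criterion.
#' @param clusters optional named cluster labels for the whole dataset,
#'   activating the cluster-proportional sampling rule.
#' @param seed master seed.
#' @param restarts optimizer restarts per run.
#' @return data.frame with columns `size`, `rep`, `rScore`, `seed`.
#' @export
generateScoreProfile <- function(pc, scenario, grid, lambda = 1,
                                 clusters = NULL, seed = 1L, restarts = 1L) {
  stopifnot(is(pc, "PCScores"), is(scenario, "Scenario"),
            is(grid, "SearchGrid"))
  nC <- length(scenario@candidates)
  if (grid@nMax > nC) stop("grid nMax exceeds the candidate set size")
  ctx <- referenceContext(pc, scenario, lambda)
  sizes <- gridSizes(grid)
  rows <- vector("list", length(sizes) * grid@m + grid@includeNcPoint)
  k <- 0L
  for (si in seq_along(sizes)) {
    nT <- sizes[si]
    alloc <- scenarioAllocation(scenario, clusters, nT)
    for (rep in seq_len(grid@m)) {
      runSeed <- deriveSeed(seed, (si - 1L) * grid@m + rep)
      res <- optimizeTrainingSet(pc, scenario@candidates, nT, ctx,
                                 allocation = alloc, seed = runSeed,
                                 restarts = restarts)
      k <- k + 1L
      rows[[k]] <- data.frame(size = nT, rep = rep, rScore = rsValue(res),
                              seed = runSeed)
    }
  }
  if (grid@includeNcPoint) {
    res <- optimizeTrainingSet(pc, scenario@candidates, nC, ctx,
                               seed = deriveSeed(seed, 0L))
    k <- k + 1L
    rows[[k]] <- data.frame(size = nC, rep = 1L, rScore = rsValue(res),
                            seed = deriveSeed(seed, 0L))
  }
  do.call(rbind, rows)
}

#' Run the full sample size determination procedure
#'
#' Profiles optimal r-scores over the grid, fits the growth curve, inverts
#' the RErs operating curve at each target, and optimizes the final training
#' set S_t* at each recommended size. When the logistic fit shows lack of
#' fit (residual SS per point above `lackOfFitThreshold`) and `family` is
#' `"logistic"`, a Weibull-type refit is attempted and used if it converges
#' with a smaller residual SS.
#'
#' @inheritParams generateScoreProfile
#' @param targets relative accuracies to invert at, each in (0, 1].
#' @param family `"logistic"` (with automatic Weibull escalation) or
#'   `"weibull"`.
#' @param lackOfFitThreshold residual-SS-per-point threshold that triggers
#'   the Weibull refit.
#' @return an [SSDReport-class].
#' @export
runSSD <- function(pc, scenario, grid, targets = c(0.95, 0.99), lambda = 1,
                   family = c("logistic", "weibull"), clusters = NULL,
                   seed = 1L, restarts = 1L, lackOfFitThreshold = 5e-4) {
  family <- match.arg(family)
  if (any(targets <= 0 | targets > 1)) stop("targets must be in (0, 1]")
  nC <- length(scenario@candidates)
  profile <- generateScoreProfile(pc, scenario, grid, lambda = lambda,
                                  clusters = clusters, seed = seed,
                                  restarts = restarts)
  fits <- list()
  fits$logistic <- tryCatch(fitLogistic(profile$size, profile$rScore),
                            error = function(e) e)
  if (is(fits$logistic, "error") && family == "logistic")
    stop("logistic curve fit failed (profile retained in the error object); ",
         "consider family = 'weibull': ", conditionMessage(fits$logistic))
  useFamily <- family
  if (family == "logistic") {
    rssPerPoint <- fits$logistic@residualSS / fits$logistic@nPoints
    if (rssPerPoint > lackOfFitThreshold) {
      wb <- tryCatch(fitWeibull(profile$size, profile$rScore,
                                initFrom = fits$logistic),
                     error = function(e) NULL)
      if (!is.null(wb) && wb@residualSS < fits$logistic@residualSS) {
        fits$weibull <- wb
        useFamily <- "weibull"
        message("runSSD: logistic lack of fit (RSS/point = ",
                signif(rssPerPoint, 3), "), switched to the Weibull-type curve")
      }
    }
  } else {
    fits$weibull <- fitWeibull(profile$size, profile$rScore,
                               initFrom = if (is(fits$logistic, "error")) NULL
                                          else fits$logistic)
  }
  fit <- fits[[useFamily]]

  ctx <- referenceContext(pc, scenario, lambda)
  decs <- list()
  finals <- list()
  for (t in targets) {
    d <- invertRers(fit, t, nC = nC, nMin = grid@nMin)
    alloc <- scenarioAllocation(scenario, clusters, d@nTarget)
    f <- optimizeTrainingSet(pc, scenario@candidates, d@nTarget, ctx,
                             allocation = alloc,
                             seed = deriveSeed(seed, 900000L + round(1000 * t)),
                             restarts = restarts)
    key <- sprintf("%.2f", t)
    decs[[key]] <- d
    finals[[key]] <- f
  }
  if (is(fits$logistic, "error")) fits$logistic <- NULL
  new("SSDReport", profile = profile, fits = fits, family = useFamily,
      decisions = decs, finalSets = finals, scenario = scenario, grid = grid,
      lambda = lambda, seed = as.integer(seed),
      provenance = list(timestamp = format(Sys.time(), tz = "UTC"),
                        restarts = restarts, targets = targets))
}

#' Serialize an SSD report to JSON
#'
#' @param report an [SSDReport-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeReportJson <- function(report, path) {
  stopifnot(is(report, "SSDReport"))
  sc <- report@scenario
  out <- list(
    config = list(kind = sc@kind, method = sc@method,
                  n_c = length(sc@candidates), n_0 = length(sc@testSet),
                  n_min = report@grid@nMin, n_max = report@grid@nMax,
                  delta = report@grid@delta, m = report@grid@m,
                  lambda = report@lambda, family = report@family,
                  seed = report@seed),
    profile = report@profile,
    fits = lapply(report@fits, curveFitToList),
    decisions = lapply(report@decisions, function(d)
      list(target_rers = d@targetRers, n_t_star = d@nTarget,
           continuous = d@nContinuous, achieved_rers = d@achievedRers,
           n_c = d@nC)),
    final_training_sets = lapply(report@finalSets, function(f)
      list(indices = f@selected, r_score = f@score@value, seed = f@seed)),
    provenance = report@provenance)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' Write the r-score profile as TSV
#'
#' @param report an [SSDReport-class] (or a profile data.frame).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeProfileTsv <- function(report, path) {
  prof <- if (is(report, "SSDReport")) report@profile else report
  utils::write.table(prof, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot the fitted growth and operating curves
#'
#' Draws the (size, r-score) profile with the fitted curve, and the RErs
#' operating curve with the decision points. Writes an SVG when `file` is
#' given, otherwise draws on the current device.
#'
#' @param report an [SSDReport-class].
#' @param file optional SVG output path.
#' @return `file` (or `NULL`), invisibly.
#' @export
plotSSD <- function(report, file = NULL) {
  stopifnot(is(report, "SSDReport"))
  if (!is.null(file)) {
    grDevices::svg(file, width = 9, height = 4.5)
    on.exit(grDevices::dev.off())
  }
  fit <- report@fits[[report@family]]
  nC <- length(report@scenario@candidates)
  xs <- seq(min(report@profile$size), nC, length.out = 200L)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  plot(report@profile$size, report@profile$rScore, pch = 16, cex = 0.6,
       xlab = "training set size", ylab = "r-score",
       main = sprintf("%s fit", report@family))
  graphics::lines(xs, predict(fit, xs), col = "firebrick", lwd = 2)
  plot(xs, rers(fit, xs, nC), type = "l", lwd = 2, col = "steelblue",
       xlab = "training set size", ylab = "RErs", main = "operating curve")
  for (d in report@decisions) {
    graphics::abline(h = d@targetRers, lty = 3)
    graphics::points(d@nTarget, d@achievedRers, pch = 17, col = "firebrick")
  }
  invisible(file)
}
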