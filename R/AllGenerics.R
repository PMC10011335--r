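#' @include AllClasses.R
NULL

#' Accessors for ssdGP containers
#'
#' Small accessor generics so user code never touches slots directly.
#'
#' @param x an ssdGP S4 object.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname accessors
#' @export
setGeneric("markerIds", function(x) standardGeneric("markerIds"))

#' @rdname accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))

#' @rdname accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname accessors
#' @export
setGeneric("isImputed", function(x) standardGeneric("isImputed"))

#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname accessors
#' @export
setGeneric("pcLoadings", function(x) standardGeneric("pcLoadings"))

#' @rdname accessors
#' @export
setGeneric("rsValue", function(x) standardGeneric("rsValue"))

#' @rdname accessors
#' @export
setGeneric("selectedIndices", function(x) standardGeneric("selectedIndices"))

#' @rdname accessors
#' @export
setGeneric("curveFamily", function(x) standardGeneric("curveFamily"))

#' @rdname accessors
#' @export
setGeneric("curveCoefficients", function(x) standardGeneric("curveCoefficients"))

#' @rdname accessors
#' @export
setGeneric("decisions", function(x) standardGeneric("decisions"))

#' @rdname accessors
#' @export
setGeneric("scoreProfileTable", function(x) standardGeneric("scoreProfileTable"))

## -- methods ---------------------------------------------------------------

#' @rdname accessors
setMethod("individualIds", "GenotypeMatrix", function(x) rownames(x@scores))
#' @rdname accessors
setMethod("individualIds", "PCScores", function(x) rownames(x@scores))
#' @rdname accessors
setMethod("markerIds", "GenotypeMatrix", function(x) colnames(x@scores))
#' @rdname accessors
setMethod("scoreMatrix", "GenotypeMatrix", function(x) x@scores)
#' @rdname accessors
setMethod("scoreMatrix", "StandardizedGenotypes", function(x) x@values)
#' @rdname accessors
setMethod("scoreMatrix", "PCScores", function(x) x@scores)
#' @rdname accessors
setMethod("missingMask", "GenotypeMatrix", function(x) x@missing)
#' @rdname accessors
setMethod("isImputed", "GenotypeMatrix", function(x) x@imputed)
#' @rdname accessors
setMethod("eigenvalues", "PCScores", function(x) x@eigenvalues)
#' @rdname accessors
setMethod("pcLoadings", "PCScores", function(x) x@loadings)
#' @rdname accessors
setMethod("rsValue", "RScoreValue", function(x) x@value)
#' @rdname accessors
setMethod("rsValue", "OptimizationResult", function(x) x@score@value)
#' @rdname accessors
setMethod("selectedIndices", "OptimizationResult", function(x) x@selected)
#' @rdname accessors
setMethod("curveFamily", "GrowthCurveFit", function(x) x@family)
#' @rdname accessors
setMethod("curveCoefficients", "GrowthCurveFit", function(x) {
  cf <- c(alpha = x@alpha, beta = x@beta, gamma = x@gamma)
  if (x@family == "weibull") cf <- c(cf, theta = x@theta)
  cf
})
#' @rdname accessors
setMethod("decisions", "SSDReport", function(x) x@decisions)
#' @rdname accessors
setMethod("scoreProfileTable", "SSDReport", function(x) x@profile)

## -- show ------------------------------------------------------------------

setMethod("show", "GenotypeMatrix", function(object) {
  s <- object@scores
  cat(sprintf("GenotypeMatrix: %d individuals x %d markers (%s)\n",
              nrow(s), ncol(s),
              if (object@imputed) "imputed" else
                sprintf("%.2f%% missing", 100 * mean(object@missing))))
})

setMethod("show", "PCScores", function(object) {
  cat(sprintf("PCScores: %d individuals, %d components (top eigenvalue %.4g)\n",
              nrow(object@scores), ncol(object@scores),
              if (length(object@eigenvalues)) object@eigenvalues[1] else NA))
})

setMethod("show", "RScoreContext", function(object) {
  cat(sprintf("RScoreContext: n0 = %d, q1 = %.6g, lambda = %g\n",
              object@n0, object@q1, object@lambda))
})

setMethod("show", "RScoreValue", function(object) {
  cat(sprintf("r-score %.6f (q12 = %.6g, q1 = %.6g, q2 = %.6g, n_t = %d)\n",
              object@value, object@q12, object@q1, object@q2, object@nTrain))
})

setMethod("show", "OptimizationResult", function(object) {
  cat(sprintf(
    "OptimizationResult: n_t = %d, r-score %.6f, %d evaluations%s\n",
    length(object@selected), object@score@value, object@nEvaluations,
    if (object@converged) "" else " (not converged)"))
})

setMethod("show", "GrowthCurveFit", function(object) {
  cf <- curveCoefficients(object)
  cat(sprintf("GrowthCurveFit [%s]: %s; RSS %.4g over %d points%s\n",
              object@family,
              paste(sprintf("%s = %.5g", names(cf), cf), collapse = ", "),
              object@residualSS, object@nPoints,
              if (object@converged) "" else " (not converged)"))
})

setMethod("show", "SampleSizeDecision", function(object) {
  cat(sprintf(
    "SampleSizeDecision: target RErs %.3f -> n_t* = %d (continuous %.2f, achieved %.4f, n_c = %d)\n",
    object@targetRers, object@nTarget, object@nContinuous,
    object@achievedRers, object@nC))
})

setMethod("show", "Scenario", function(object) {
  cat(sprintf("Scenario: %s, %s; n_c = %d, n_0 = %d\n", object@kind,
              object@method, length(object@candidates), length(object@testSet)))
})

setMethod("show", "SSDReport", function(object) {
  cat(sprintf("SSDReport (%s family, lambda = %g)\n", object@family,
              object@lambda))
  show(object@scenario)
  cat(sprintf("  profile: %d points over sizes %d..%d\n", nrow(object@profile),
              min(object@profile$size), max(object@profile$size)))
  for (d in object@decisions) { cat("  "); show(d) }
})

setMethod("show", "GBLUPModel", function(object) {
  cat(sprintf(
    "GBLUPModel: n_t = %d, mu_hat = %.4f, variance ratio %.4g (K divisor n = %d)\n",
    length(object@gHatTrain), object@muHat, object@varianceRatio,
    object@divisorN))
})

setMethod("show", "PredictionAssessment", function(object) {
  cat(sprintf(
    "PredictionAssessment: r(train) = %.4f, r(candidates) = %.4f, REpa = %.4f\n",
    object@rTrainingSet, object@rCandidateSet, object@repa))
})
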