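#' @import methods
NULL

## Central containers. Individuals are always rows; markers / PCs are columns.
## Identifiers live in dimnames so subsetting keeps them aligned.

#' GenotypeMatrix: coded SNP scores
#'
#' Holds an individuals-by-markers grid of SNP scores coded -1 (homozygote of
#' the minor allele), 0 (heterozygote) and 1 (homozygote of the major allele).
#' Before imputation entries are exactly -1/0/1 or `NA`; after mean imputation
#' no `NA` remains and imputed cells may be fractional in \[-1, 1\]. The
#' original missingness pattern is kept in `missing`.
#'
#' @slot scores numeric matrix, individuals x markers, with row/column names.
#' @slot missing logical matrix of the same shape flagging originally missing
#'   calls.
#' @slot imputed logical scalar; `TRUE` once missing cells have been filled.
#' @export
setClass("GenotypeMatrix",
         representation(scores = "matrix", missing = "matrix",
                        imputed = "logical"))

setValidity("GenotypeMatrix", function(object) {
  s <- object@scores
  msk <- object@missing
  msgs <- character()
  if (!is.numeric(s)) msgs <- c(msgs, "'scores' must be numeric")
  if (nrow(s) < 2L) msgs <- c(msgs, "need at least 2 individuals")
  if (ncol(s) < 1L) msgs <- c(msgs, "need at least 1 marker")
  if (is.null(rownames(s)) || anyDuplicated(rownames(s)))
    msgs <- c(msgs, "individual ids must be present and unique")
  if (is.null(colnames(s)) || anyDuplicated(colnames(s)))
    msgs <- c(msgs, "marker ids must be present and unique")
  if (!identical(dim(s), dim(msk)) || !is.logical(msk))
    msgs <- c(msgs, "'missing' must be a logical matrix matching 'scores'")
  if (length(object@imputed) != 1L || is.na(object@imputed))
    msgs <- c(msgs, "'imputed' must be TRUE or FALSE")
  if (length(msgs) == 0L) {
    if (isTRUE(object@imputed)) {
      if (anyNA(s)) msgs <- c(msgs, "imputed matrix must contain no NA")
      else if (any(s < -1 - 1e-12 | s > 1 + 1e-12))
        msgs <- c(msgs, "imputed scores must lie in [-1, 1]")
    } else {
      obs <- s[!is.na(s)]
      if (length(obs) && !all(obs %in% c(-1, 0, 1)))
        msgs <- c(msgs, "observed scores must be -1, 0 or 1")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' StandardizedGenotypes: column-standardized marker matrix
#'
#' The matrix M with m_ij = (x_ij - xbar_j) / s_j, using the n-1 denominator
#' for s_j. Zero-variance columns are dropped at construction time.
#'
#' @slot values numeric matrix, individuals x retained markers.
#' @slot columnMeans,columnSds per-retained-marker centering and scaling used.
#' @export
setClass("StandardizedGenotypes",
         representation(values = "matrix", columnMeans = "numeric",
                        columnSds = "numeric"))

setValidity("StandardizedGenotypes", function(object) {
  v <- object@values
  msgs <- character()
  if (nrow(v) < 2L) msgs <- c(msgs, "need at least 2 individuals")
  if (length(object@columnMeans) != ncol(v) ||
      length(object@columnSds) != ncol(v))
    msgs <- c(msgs, "columnMeans/columnSds must match the number of columns")
  if (ncol(v) > 0L) {
    if (max(abs(colMeans(v))) > 1e-10)
      msgs <- c(msgs, "columns must have mean 0")
    sds <- apply(v, 2L, stats::sd)
    if (max(abs(sds - 1)) > 1e-10)
      msgs <- c(msgs, "columns must have sd 1 (n-1 denominator)")
  }
  if (length(msgs)) msgs else TRUE
})

#' PCScores: principal-component score matrix
#'
#' L = M Q from the spectral decomposition M'M = sum u_i q_i q_i', keeping as
#' many components as individuals minus numerically null ones. L L' equals
#' M M', so all inner products among individuals are preserved.
#'
#' @slot scores numeric matrix (individuals x components), the matrix L.
#' @slot eigenvalues non-increasing positive eigenvalues u_i of M'M.
#' @slot loadings p x components matrix Q with orthonormal columns.
#' @export
setClass("PCScores",
         representation(scores = "matrix", eigenvalues = "numeric",
                        loadings = "matrix"))

setValidity("PCScores", function(object) {
  msgs <- character()
  r <- ncol(object@scores)
  if (length(object@eigenvalues) != r)
    msgs <- c(msgs, "one eigenvalue per score column required")
  if (ncol(object@loadings) != r)
    msgs <- c(msgs, "one loading column per score column required")
  if (r > 0L) {
    ev <- object@eigenvalues
    if (any(ev <= 0)) msgs <- c(msgs, "eigenvalues must be positive")
    if (is.unsorted(rev(ev))) msgs <- c(msgs, "eigenvalues must be non-increasing")
  }
  if (is.null(rownames(object@scores)))
    msgs <- c(msgs, "individual ids (rownames) required")
  if (length(msgs)) msgs else TRUE
})

#' RScoreContext: precomputed reference-set quantities for the r-score
#'
#' Caches the centered Gram matrix Theta = X0' (I - Jbar) X0 and
#' q1 = (n0 - 1) + Tr(Theta) of the reference set (test set for the targeted
#' method, candidate set for the untargeted method), so that scoring a
#' proposed training set only involves training-set-sized algebra.
#'
#' @slot reference reference-set PC score matrix X0 (n0 x p).
#' @slot theta p x p centered Gram matrix of the reference set.
#' @slot q1 scalar (n0 - 1) + Tr(Theta); depends on the reference set only.
#' @slot n0 reference set size.
#' @slot lambda ridge shrinkage used in the criterion (1 by default).
#' @export
setClass("RScoreContext",
         representation(reference = "matrix", theta = "matrix", q1 = "numeric",
                        n0 = "integer", lambda = "numeric"))

setValidity("RScoreContext", function(object) {
  msgs <- character()
  if (object@n0 < 2L) msgs <- c(msgs, "reference set needs at least 2 rows")
  if (!isTRUE(all.equal(object@theta, t(object@theta), tolerance = 1e-8)))
    msgs <- c(msgs, "theta must be symmetric")
  if (length(object@q1) != 1L || !is.finite(object@q1) || object@q1 <= 0)
    msgs <- c(msgs, "q1 must be a positive scalar")
  if (length(object@lambda) != 1L || !is.finite(object@lambda) ||
      object@lambda <= 0)
    msgs <- c(msgs, "lambda must be a positive scalar")
  if (length(msgs)) msgs else TRUE
})

#' RScoreValue: one evaluation of the r-score criterion
#'
#' @slot value the r-score q12 / sqrt(q1 * q2).
#' @slot q12,q2,q1 the constituent traces.
#' @slot nTrain training set size n_t.
#' @export
setClass("RScoreValue",
         representation(value = "numeric", q12 = "numeric", q2 = "numeric",
                        q1 = "numeric", nTrain = "integer"))

setValidity("RScoreValue", function(object) {
  rec <- object@q12 / sqrt(object@q1 * object@q2)
  if (abs(rec - object@value) > 1e-12 * max(1, abs(object@value)))
    "value must equal q12/sqrt(q1*q2)" else TRUE
})

#' ClusterAllocation: per-cluster training-set quotas
#'
#' Largest-remainder apportionment of n_t over clusters, proportional to the
#' cluster shares of the basis set (test set for targeted, candidate set for
#' untargeted sampling), capped at per-cluster availability.
#'
#' @slot labels per-candidate cluster label (parallel to the candidate pool).
#' @slot quota named integer vector of per-cluster counts, summing to n_t.
#' @slot mode "targeted-proportional", "untargeted-proportional" or "none".
#' @export
setClass("ClusterAllocation",
         representation(labels = "character", quota = "integer",
                        mode = "character"))

#' OptimizationResult: an optimized training set
#'
#' @slot selected ordered candidate indices (into the full PC score matrix).
#' @slot score the achieved [RScoreValue-class].
#' @slot trace best exact score after each accepted exchange (non-decreasing).
#' @slot nEvaluations number of criterion evaluations performed.
#' @slot seed integer seed that produced this result.
#' @slot converged TRUE if the exchange search stopped with no improving swap.
#' @export
setClass("OptimizationResult",
         representation(selected = "integer", score = "RScoreValue",
                        trace = "numeric", nEvaluations = "numeric",
                        seed = "integer", converged = "logical"))

#' GrowthCurveFit: fitted S-shaped curve for r-score versus size
#'
#' Logistic family: y = alpha / (1 + exp(beta - gamma x)). Weibull-type
#' family: y = alpha - beta exp(-gamma x^theta).
#'
#' @slot family "logistic" or "weibull".
#' @slot alpha,beta,gamma,theta fitted parameters (`theta` is `NA` for the
#'   logistic family).
#' @slot residualSS residual sum of squares at the solution.
#' @slot nPoints number of (size, score) pairs fitted.
#' @slot converged logical convergence flag from the optimizer.
#' @export
setClass("GrowthCurveFit",
         representation(family = "character", alpha = "numeric",
                        beta = "numeric", gamma = "numeric", theta = "numeric",
                        residualSS = "numeric", nPoints = "integer",
                        converged = "logical"))

setValidity("GrowthCurveFit", function(object) {
  msgs <- character()
  if (!object@family %in% c("logistic", "weibull"))
    msgs <- c(msgs, "family must be 'logistic' or 'weibull'")
  if (object@residualSS < -1e-12) msgs <- c(msgs, "residualSS must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' SampleSizeDecision: inverted operating curve at one target
#'
#' @slot targetRers requested relative r-score in (0, 1].
#' @slot nTarget recommended integer size n_t* (ceiling of the continuous
#'   solution, clamped to \[nMin, nC\]).
#' @slot nContinuous continuous solution of RErs(n) = target.
#' @slot achievedRers RErs evaluated at `nTarget`.
#' @slot nC candidate set size; @slot nMin smallest size considered.
#' @export
setClass("SampleSizeDecision",
         representation(targetRers = "numeric", nTarget = "integer",
                        nContinuous = "numeric", achievedRers = "numeric",
                        nC = "integer", nMin = "integer"))

#' Scenario: candidate/test split of a dataset
#'
#' Fixed-candidate: S_c is drawn first, S_0 from the remainder.
#' Non-fixed-candidate: S_0 is drawn first, S_c is everything else.
#'
#' @slot kind "fixed-candidate" or "non-fixed-candidate".
#' @slot method "targeted" or "untargeted".
#' @slot candidates indices of S_c; @slot testSet indices of S_0.
#' @slot seed the seed that produced the split.
#' @export
setClass("Scenario",
         representation(kind = "character", method = "character",
                        candidates = "integer", testSet = "integer",
                        seed = "integer"))

setValidity("Scenario", function(object) {
  msgs <- character()
  if (!object@kind %in% c("fixed-candidate", "non-fixed-candidate"))
    msgs <- c(msgs, "kind must be 'fixed-candidate' or 'non-fixed-candidate'")
  if (!object@method %in% c("targeted", "untargeted"))
    msgs <- c(msgs, "method must be 'targeted' or 'untargeted'")
  if (length(intersect(object@candidates, object@testSet)))
    msgs <- c(msgs, "candidate and test sets must be disjoint")
  if (anyDuplicated(object@candidates) || anyDuplicated(object@testSet))
    msgs <- c(msgs, "index sets must not contain duplicates")
  if (length(msgs)) msgs else TRUE
})

#' SearchGrid: sizes at which optimal training sets are profiled
#'
#' @slot nMin,nMax grid end points; @slot delta increment; @slot m optimal
#'   training sets generated per size; @slot includeNcPoint add the single
#'   full-candidate-set point at n_c.
#' @export
setClass("SearchGrid",
         representation(nMin = "integer", nMax = "integer", delta = "integer",
                        m = "integer", includeNcPoint = "logical"))

setValidity("SearchGrid", function(object) {
  msgs <- character()
  if (object@nMin < 1L) msgs <- c(msgs, "nMin must be >= 1")
  if (object@nMin >= object@nMax) msgs <- c(msgs, "nMin must be < nMax")
  if (object@delta < 1L) msgs <- c(msgs, "delta must be >= 1")
  if ((object@nMax - object@nMin) %% object@delta != 0L)
    msgs <- c(msgs, "(nMax - nMin) must be divisible by delta")
  if (object@m < 1L) msgs <- c(msgs, "m must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' SSDReport: full record of one sample size determination run
#'
#' @slot profile data.frame with columns size, rep, rScore, seed.
#' @slot fits named list of [GrowthCurveFit-class] (at least the family used
#'   for the decisions).
#' @slot family curve family the decisions are based on.
#' @slot decisions list of [SampleSizeDecision-class], one per target.
#' @slot finalSets list of [OptimizationResult-class], one per decision.
#' @slot scenario,grid the [Scenario-class] and [SearchGrid-class] used.
#' @slot lambda shrinkage used throughout.
#' @slot seed master seed; @slot provenance free-form run metadata.
#' @export
setClass("SSDReport",
         representation(profile = "data.frame", fits = "list",
                        family = "character", decisions = "list",
                        finalSets = "list", scenario = "Scenario",
                        grid = "SearchGrid", lambda = "numeric",
                        seed = "integer", provenance = "list"))

#' GBLUPModel: Henderson mixed-model fit of y = mu 1 + g + e
#'
#' @slot muHat BLUE of the intercept.
#' @slot gHatTrain BLUP of training genotypic values.
#' @slot KTrain training kinship K_t = (1/n) L_t L_t'.
#' @slot varianceRatio sigma2_e / sigma2_g used in the solve.
#' @slot divisorN the n used in the kinship divisor.
#' @export
setClass("GBLUPModel",
         representation(muHat = "numeric", gHatTrain = "numeric",
                        KTrain = "matrix", varianceRatio = "numeric",
                        divisorN = "integer"))

setValidity("GBLUPModel", function(object) {
  msgs <- character()
  if (!all(is.finite(object@gHatTrain)) || !is.finite(object@muHat))
    msgs <- c(msgs, "predictions must be finite")
  if (nrow(object@KTrain) != length(object@gHatTrain))
    msgs <- c(msgs, "KTrain dimension must match training set")
  if (length(msgs)) msgs else TRUE
})

#' PredictionAssessment: prediction ability and REpa for one run
#'
#' @slot gebvTest GEBVs (g0_hat + mu_hat) of test individuals.
#' @slot rTrainingSet Pearson correlation using the optimized training set.
#' @slot rCandidateSet Pearson correlation using the whole candidate set.
#' @slot repa rTrainingSet / rCandidateSet, unclamped.
#' @export
setClass("PredictionAssessment",
         representation(gebvTest = "numeric", rTrainingSet = "numeric",
                        rCandidateSet = "numeric", repa = "numeric"))

#' SimConfig: synthetic genotype/phenotype generator settings
#'
#' @slot nIndividuals,nMarkers,nClusters panel dimensions.
#' @slot divergence between-cluster allele-frequency divergence in \[0, 1)
#'   (the F of a Balding-Nichols draw).
#' @slot mafRange interval the ancestral minor allele frequencies are drawn
#'   from.
#' @slot missingRate completely-at-random missing call rate.
#' @slot h2 narrow-sense heritability of the simulated trait.
#' @slot nQtl number of markers with nonzero effects.
#' @slot seed integer seed.
#' @export
setClass("SimConfig",
         representation(nIndividuals = "integer", nMarkers = "integer",
                        nClusters = "integer", divergence = "numeric",
                        mafRange = "numeric", missingRate = "numeric",
                        h2 = "numeric", nQtl = "integer", seed = "integer"))

setValidity("SimConfig", function(object) {
  msgs <- character()
  if (object@nIndividuals < 2L) msgs <- c(msgs, "need >= 2 individuals")
  if (object@nMarkers < 1L) msgs <- c(msgs, "need >= 1 marker")
  if (object@nClusters < 1L) msgs <- c(msgs, "need >= 1 cluster")
  if (object@divergence < 0 || object@divergence >= 1)
    msgs <- c(msgs, "divergence must be in [0, 1)")
  if (length(object@mafRange) != 2L || object@mafRange[1] <= 0 ||
      object@mafRange[2] > 0.5 || object@mafRange[1] > object@mafRange[2])
    msgs <- c(msgs, "mafRange must be an interval within (0, 0.5]")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msgs <- c(msgs, "missingRate must be in [0, 1)")
  if (object@h2 < 0 || object@h2 > 1) msgs <- c(msgs, "h2 must be in [0, 1]")
  if (object@nQtl < 1L || object@nQtl > object@nMarkers)
    msgs <- c(msgs, "nQtl must be in [1, nMarkers]")
  if (length(msgs)) msgs else TRUE
})
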