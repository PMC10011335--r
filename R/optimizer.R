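#' @include AllClasses.R AllGenerics.R rscore.R
NULL

#' Derive a reproducible child seed from a master seed
#'
#' Counter-based derivation so that changing the number of repetitions or the
#' grid does not reshuffle unrelated runs. The result stays inside the
#' 32-bit signed integer range.
#'
#' @param master integer master seed.
#' @param counter non-negative integer counter.
#' @return an integer seed.
#' @export
deriveSeed <- function(master, counter) {
  m <- as.numeric(master) %% 2147483647
  as.integer((m * 48271 + 10007 * as.numeric(counter)) %% 2147483646) + 1L
}

#' Cluster-proportional training-set quotas
#'
#' Apportions `nT` over clusters proportionally to the cluster shares of the
#' basis set (the test set for the targeted method, the candidate set for the
#' untargeted method), by the largest-remainder rule. Quotas are capped at
#' the per-cluster candidate availability; any shortfall is redistributed to
#' the clusters with the largest remaining remainders that still have spare
#' candidates.
#'
#' @param labelsOfBasis character/factor vector of cluster labels of the
#'   basis set.
#' @param nT requested training set size.
#' @param mode one of `"targeted-proportional"`, `"untargeted-proportional"`,
#'   `"none"`.
#' @param available named integer vector of per-cluster candidate counts.
#' @param candidateLabels optional per-candidate labels stored alongside the
#'   quota (used by the optimizer to constrain swaps).
#' @return a [ClusterAllocation-class].
#' @export
allocateClusters <- function(labelsOfBasis, nT,
                             mode = c("targeted-proportional",
                                      "untargeted-proportional", "none"),
                             available, candidateLabels = character()) {
  mode <- match.arg(mode)
  labelsOfBasis <- as.character(labelsOfBasis)
  if (!length(labelsOfBasis)) stop("empty basis set")
  nT <- as.integer(nT)
  if (sum(available) < nT)
    stop("requested training size ", nT, " exceeds total availability ",
         sum(available))
  share <- table(labelsOfBasis) / length(labelsOfBasis)
  clusters <- union(names(share), names(available))
  avail <- stats::setNames(integer(length(clusters)), clusters)
  avail[names(available)] <- as.integer(available)
  raw <- stats::setNames(numeric(length(clusters)), clusters)
  raw[names(share)] <- nT * as.numeric(share)
  quota <- pmin(floor(raw), avail)
  remainder <- raw - floor(raw)
  ## hand out the leftover seats by largest remainder, capped at availability
  while (sum(quota) < nT) {
    spare <- avail - quota
    elig <- names(which(spare > 0))
    if (!length(elig)) stop("internal: no spare capacity left")
    ord <- elig[order(-remainder[elig], elig)]
    pick <- ord[1L]
    quota[pick] <- quota[pick] + 1L
    remainder[pick] <- remainder[pick] - 1   # de-prioritize after a grant
  }
  new("ClusterAllocation", labels = as.character(candidateLabels),
      quota = stats::setNames(as.integer(quota), names(quota)), mode = mode)
}

## Deterministic greedy forward-selection start: grow the set one candidate
## at a time, always adding the candidate that maximizes the criterion,
## within clusters that still have unfilled quota. Used as the first restart
## for small target sizes, where the exchange landscape is most rugged.
greedyInit <- function(mats, q1, lambda, candLabels, quota, nT, nCand) {
  sel <- integer(0)
  filled <- if (is.null(quota)) NULL else stats::setNames(
    integer(length(quota)), names(quota))
  for (step in seq_len(nT)) {
    open <- setdiff(seq_len(nCand), sel)
    if (!is.null(quota)) {
      ok <- names(which(filled < quota))
      open <- open[candLabels[open] %in% ok]
    }
    vals <- vapply(open, function(b) {
      sc <- tryCatch(cpp_subset_score(mats$K, mats$R, q1, lambda,
                                      sort(c(sel, b)) - 1L),
                     error = function(e) NULL)
      if (is.null(sc)) -Inf else sc$value
    }, numeric(1))
    pick <- open[which.max(vals)]
    sel <- c(sel, pick)
    if (!is.null(quota)) {
      cl <- candLabels[pick]
      filled[cl] <- filled[cl] + 1L
    }
  }
  sort(sel)
}

stratifiedInit <- function(candLabels, quota, nT, nCand) {
  if (is.null(quota)) return(sort(sample.int(nCand, nT)))
  sel <- integer(0)
  for (cl in names(quota)) {
    if (quota[[cl]] == 0L) next
    members <- which(candLabels == cl)
    if (length(members) < quota[[cl]])
      stop("cluster '", cl, "' has ", length(members),
           " candidate(s) but quota ", quota[[cl]])
    sel <- c(sel, members[sample.int(length(members), quota[[cl]])])
  }
  sort(sel)
}

poolMatrices <- function(pc, candidateIndices, ctx) {
  Xc <- scoreMatrix(pc)[candidateIndices, , drop = FALSE]
  list(K = tcrossprod(Xc), R = Xc %*% ctx@theta %*% t(Xc))
}

countSubsets <- function(nC, nT, candLabels, quota) {
  if (is.null(quota)) return(choose(nC, nT))
  q <- quota[quota > 0L]
  prod(vapply(names(q), function(cl)
    choose(sum(candLabels == cl), q[[cl]]), numeric(1)))
}

enumerateSubsets <- function(nC, nT, candLabels, quota) {
  if (is.null(quota)) return(utils::combn(nC, nT, simplify = FALSE))
  q <- quota[quota > 0L]
  perCluster <- lapply(names(q), function(cl) {
    members <- which(candLabels == cl)
    utils::combn(members, q[[cl]], simplify = FALSE)
  })
  Reduce(function(acc, nxt) {
    unlist(lapply(acc, function(a) lapply(nxt, function(b) c(a, b))),
           recursive = FALSE)
  }, perCluster[-1L], init = perCluster[[1L]])
}

bestBySubsetScan <- function(mats, ctx, subsets) {
  bestVal <- -Inf
  bestIdx <- NULL
  bestSc <- NULL
  for (s in subsets) {
    s <- sort(s)
    sc <- tryCatch(cpp_subset_score(mats$K, mats$R, ctx@q1, ctx@lambda,
                                    s - 1L),
                   error = function(e) NULL)
    if (!is.null(sc) && sc$value > bestVal) {
      bestVal <- sc$value
      bestIdx <- s
      bestSc <- sc
    }
  }
  if (is.null(bestIdx)) stop("no admissible subset could be scored")
  list(idx = bestIdx, sc = bestSc, n = as.numeric(length(subsets)))
}

#' Optimize a training set of a given size under the r-score
#'
#' Tiny problems (at most `exactLimit` admissible subsets) are solved exactly
#' by enumeration. Larger ones use a seeded exchange search: sweep over the
#' selected positions, for each position screen every admissible replacement
#' candidate (within the same cluster when quotas are active) and apply the
#' best strictly improving exchange; stop when a full sweep yields no
#' improvement or after `maxSweeps` sweeps. The search is restarted
#' `restarts` times and the best result is returned. For target sizes up to
#' `greedyLimit` the first restart uses a deterministic greedy
#' forward-selection start (the most rugged criterion landscapes occur at
#' small sizes); all other restarts use stratified-random starts.
#' Deterministic given `seed`.
#'
#' @param pc a [PCScores-class] for the whole dataset.
#' @param candidateIndices indices (rows of `pc`) forming the candidate set.
#' @param nT training set size.
#' @param ctx an [RScoreContext-class] built on the scenario's reference set.
#' @param allocation a [ClusterAllocation-class] or `NULL`.
#' @param seed integer seed.
#' @param restarts number of random restarts.
#' @param maxSweeps sweep cap per restart.
#' @param greedyLimit largest target size for which the greedy-forward start
#'   is used.
#' @param exactLimit largest number of admissible subsets solved by exact
#'   enumeration instead of the exchange search (0 disables enumeration).
#' @return an [OptimizationResult-class]; `selected` holds indices into the
#'   full dataset (i.e. values of `candidateIndices`).
#' @export
optimizeTrainingSet <- function(pc, candidateIndices, nT, ctx,
                                allocation = NULL, seed = 1L, restarts = 3L,
                                maxSweeps = 50L, greedyLimit = 50L,
                                exactLimit = 3000L) {
  stopifnot(is(pc, "PCScores"), is(ctx, "RScoreContext"))
  candidateIndices <- as.integer(candidateIndices)
  nC <- length(candidateIndices)
  nT <- as.integer(nT)
  if (nT < 1L) stop("training set size must be >= 1")
  if (nT > nC) stop("training set size exceeds the candidate pool")
  mats <- poolMatrices(pc, candidateIndices, ctx)

  if (nT == nC) {
    ## only one training set available at n_t = n_c: no search
    sc <- cpp_subset_score(mats$K, mats$R, ctx@q1, ctx@lambda,
                           seq_len(nC) - 1L)
    val <- new("RScoreValue", value = sc$value, q12 = sc$q12, q2 = sc$q2,
               q1 = ctx@q1, nTrain = nT)
    return(new("OptimizationResult", selected = candidateIndices, score = val,
               trace = sc$value, nEvaluations = 1, seed = as.integer(seed),
               converged = TRUE))
  }

  quota <- NULL
  clusterVec <- integer(0)
  candLabels <- NULL
  if (!is.null(allocation) && allocation@mode != "none") {
    stopifnot(is(allocation, "ClusterAllocation"))
    if (length(allocation@labels) != nC)
      stop("allocation labels must match the candidate pool")
    candLabels <- allocation@labels
    quota <- allocation@quota
    if (sum(quota) != nT) stop("allocation quotas must sum to nT")
    clusterVec <- as.integer(factor(candLabels,
                                    levels = sort(unique(candLabels)))) - 1L
  }

  ## tiny pools are solved exactly: enumerating a few thousand subsets is
  ## cheaper and stronger than any heuristic there
  nSubsets <- countSubsets(nC, nT, candLabels, quota)
  if (nSubsets <= exactLimit) {
    bs <- bestBySubsetScan(mats, ctx, enumerateSubsets(nC, nT, candLabels,
                                                       quota))
    val <- new("RScoreValue", value = bs$sc$value, q12 = bs$sc$q12,
               q2 = bs$sc$q2, q1 = ctx@q1, nTrain = nT)
    return(new("OptimizationResult",
               selected = candidateIndices[bs$idx], score = val,
               trace = bs$sc$value, nEvaluations = bs$n,
               seed = as.integer(seed), converged = TRUE))
  }

  best <- NULL
  totEval <- 0
  useGreedy <- nT <= greedyLimit
  for (r in seq_len(restarts)) {
    restartSeed <- deriveSeed(seed, r - 1L)
    init <- if (r == 1L && useGreedy) {
      totEval <- totEval + sum(nC - seq_len(nT) + 1L)
      greedyInit(mats, ctx@q1, ctx@lambda, candLabels, quota, nT, nC)
    } else {
      withr::with_seed(restartSeed,
                       stratifiedInit(candLabels, quota, nT, nC))
    }
    res <- cpp_exchange(mats$K, mats$R, ctx@q1, ctx@lambda, init - 1L,
                        clusterVec, as.integer(maxSweeps), 1e-10)
    totEval <- totEval + res$n_eval
    if (is.null(best) || res$value > best$value) best <- res
  }
  val <- new("RScoreValue", value = best$value, q12 = best$q12, q2 = best$q2,
             q1 = ctx@q1, nTrain = nT)
  new("OptimizationResult",
      selected = candidateIndices[sort(best$idx + 1L)], score = val,
      trace = best$trace, nEvaluations = totEval, seed = as.integer(seed),
      converged = isTRUE(best$converged))
}

#' Exhaustive training-set search (test oracle)
#'
#' Enumerates every quota-respecting subset of the candidate pool of size
#' `nT` and returns the global r-score optimum. Intended for verifying the
#' exchange optimizer on small instances.
#'
#' @inheritParams optimizeTrainingSet
#' @param maxSubsets combinatorial safety budget.
#' @return an [OptimizationResult-class].
#' @export
exhaustiveBest <- function(pc, candidateIndices, nT, ctx, allocation = NULL,
                           maxSubsets = 1e5) {
  stopifnot(is(pc, "PCScores"), is(ctx, "RScoreContext"))
  candidateIndices <- as.integer(candidateIndices)
  nC <- length(candidateIndices)
  nT <- as.integer(nT)
  mats <- poolMatrices(pc, candidateIndices, ctx)

  candLabels <- NULL
  quota <- NULL
  if (!is.null(allocation) && allocation@mode != "none") {
    candLabels <- allocation@labels
    quota <- allocation@quota
  }
  counts <- countSubsets(nC, nT, candLabels, quota)
  if (counts > maxSubsets) stop("combinatorial budget exceeded: ", counts)
  bs <- bestBySubsetScan(mats, ctx,
                         enumerateSubsets(nC, nT, candLabels, quota))
  val <- new("RScoreValue", value = bs$sc$value, q12 = bs$sc$q12,
             q2 = bs$sc$q2, q1 = ctx@q1, nTrain = nT)
  new("OptimizationResult", selected = candidateIndices[bs$idx], score = val,
      trace = bs$sc$value, nEvaluations = bs$n,
      seed = NA_integer_, converged = TRUE)
}
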