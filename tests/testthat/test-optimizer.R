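test_that("cluster quotas follow the largest-remainder apportionment", {
  # exact proportionality, no rounding needed
  a <- allocateClusters(rep(c("A", "B"), c(30, 20)), 25,
                        "targeted-proportional",
                        available = c(A = 100, B = 100))
  expect_identical(a@quota, c(A = 15L, B = 10L))

  # single cluster takes everything
  b <- allocateClusters(rep("A", 12), 7, "untargeted-proportional",
                        available = c(A = 30))
  expect_identical(b@quota, c(A = 7L))

  # basis {A:2, B:1}, n_t = 2: raw (1.33, 0.67) -> largest remainder {1, 1}
  c1 <- allocateClusters(c("A", "A", "B"), 2, "targeted-proportional",
                         available = c(A = 5, B = 5))
  expect_identical(c1@quota, c(A = 1L, B = 1L))

  # capping: cluster A can only supply 2, shortfall goes to B
  d <- allocateClusters(rep(c("A", "B"), c(30, 20)), 25,
                        "targeted-proportional", available = c(A = 2, B = 40))
  expect_identical(d@quota, c(A = 2L, B = 23L))
  expect_identical(sum(d@quota), 25L)

  expect_error(allocateClusters(c("A", "B"), 10, "none",
                                available = c(A = 3, B = 3)),
               "exceeds total availability")
  expect_error(allocateClusters(character(0), 1, "none", c(A = 3)),
               "empty basis")
})

test_that("exhaustive enumeration counts subsets exactly", {
  set.seed(11)
  L <- matrix(rnorm(6 * 4), 6, 4)
  pc <- makePC(L)
  ctx <- buildRScoreContext(matrix(rnorm(3 * 4), 3, 4))
  ex <- exhaustiveBest(pc, 1:6, 2, ctx)
  expect_identical(ex@nEvaluations, 15)    # choose(6, 2)
  expect_true(ex@converged)

  # quota {A:1, B:1} over 3 + 3 candidates enumerates the 3 x 3 product
  alloc <- new("ClusterAllocation", labels = rep(c("A", "B"), each = 3),
               quota = c(A = 1L, B = 1L), mode = "targeted-proportional")
  ex2 <- exhaustiveBest(pc, 1:6, 2, ctx, allocation = alloc)
  expect_identical(ex2@nEvaluations, 9)
  lab <- rep(c("A", "B"), each = 3)[ex2@selected]
  expect_identical(sort(lab), c("A", "B"))

  expect_error(exhaustiveBest(pc, 1:6, 3, ctx, maxSubsets = 10),
               "budget exceeded")
})

test_that("the exchange search attains the exhaustive optimum on small instances", {
  # spec-sized seeded instance: 10 candidates, n_t = 3, p = 4 -> 120 subsets
  set.seed(1234)
  L <- matrix(rnorm(10 * 4), 10, 4)
  pc <- makePC(L)
  ctx <- buildRScoreContext(matrix(rnorm(4 * 4), 4, 4))
  opt <- optimizeTrainingSet(pc, 1:10, 3, ctx, seed = 1)
  ex <- exhaustiveBest(pc, 1:10, 3, ctx)
  expect_equal(rsValue(opt), rsValue(ex), tolerance = 1e-10)
  expect_setequal(selectedIndices(opt), selectedIndices(ex))

  # and beats 100 random subsets on a fresh instance
  set.seed(99)
  L2 <- matrix(rnorm(20 * 5), 20, 5)
  pc2 <- makePC(L2)
  ctx2 <- buildRScoreContext(matrix(rnorm(6 * 5), 6, 5))
  opt2 <- optimizeTrainingSet(pc2, 1:20, 6, ctx2, seed = 7)
  rand <- replicate(100, {
    s <- sort(sample(1:20, 6))
    rsValue(rScore(ctx2, L2[s, , drop = FALSE]))
  })
  expect_gte(rsValue(opt2), max(rand))
})

test_that("n_t = n_c returns the full candidate set without searching", {
  set.seed(21)
  L <- matrix(rnorm(8 * 3), 8, 3)
  pc <- makePC(L)
  ctx <- buildRScoreContext(matrix(rnorm(3 * 3), 3, 3))
  res <- optimizeTrainingSet(pc, 2:7, 6, ctx, seed = 5)
  expect_identical(selectedIndices(res), 2:7)
  expect_identical(res@nEvaluations, 1)
  expect_true(res@converged)
  expect_equal(rsValue(res), rsValue(rScore(ctx, L[2:7, ])), tolerance = 1e-10)
})

test_that("optimization is deterministic and its trace is non-decreasing", {
  set.seed(41)
  L <- matrix(rnorm(30 * 6), 30, 6)
  pc <- makePC(L)
  ctx <- buildRScoreContext(matrix(rnorm(8 * 6), 8, 6))
  r1 <- optimizeTrainingSet(pc, 1:30, 8, ctx, seed = 42)
  r2 <- optimizeTrainingSet(pc, 1:30, 8, ctx, seed = 42)
  expect_identical(selectedIndices(r1), selectedIndices(r2))
  expect_identical(r1@trace, r2@trace)
  expect_identical(rsValue(r1), rsValue(r2))
  expect_true(all(diff(r1@trace) > 0))
  # reported score is the exact criterion value of the returned subset
  expect_equal(rsValue(r1), rsValue(rScore(ctx, L[selectedIndices(r1), ])),
               tolerance = 1e-8)
  r3 <- optimizeTrainingSet(pc, 1:30, 8, ctx, seed = 43)
  expect_true(r3@converged)
})

test_that("cluster quotas are honored by the final selection", {
  set.seed(61)
  L <- matrix(rnorm(24 * 5), 24, 5)
  pc <- makePC(L)
  labels <- rep(c("A", "B", "C"), each = 8)
  ctx <- buildRScoreContext(matrix(rnorm(6 * 5), 6, 5))
  alloc <- allocateClusters(rep(c("A", "B", "C"), c(3, 2, 1)), 6,
                            "targeted-proportional", available = table(labels),
                            candidateLabels = labels)
  expect_identical(alloc@quota, c(A = 3L, B = 2L, C = 1L))
  res <- optimizeTrainingSet(pc, 1:24, 6, ctx, allocation = alloc, seed = 3)
  got <- table(labels[selectedIndices(res)])
  expect_identical(as.integer(got[c("A", "B", "C")]), c(3L, 2L, 1L))
  # quota-respecting exhaustive search agrees on the quota structure
  ex <- exhaustiveBest(pc, 1:24, 6, ctx, allocation = alloc, maxSubsets = 2e4)
  expect_gte(rsValue(ex) + 1e-10, rsValue(res))
})

test_that("the exchange heuristic itself matches enumeration on 20 seeded instances", {
  # exactLimit = 0 forces the greedy + exchange path even on tiny pools, so
  # this genuinely exercises the heuristic against the enumeration oracle
  set.seed(123)
  for (i in 1:20) {
    n <- sample(7:10, 1)
    p <- sample(3:8, 1)
    nt <- sample(2:4, 1)
    L <- matrix(rnorm(n * p), n, p)
    pc <- makePC(L)
    ctx <- buildRScoreContext(matrix(rnorm(5 * p), 5, p))
    opt <- optimizeTrainingSet(pc, seq_len(n), nt, ctx, seed = i,
                               exactLimit = 0L)
    ex <- exhaustiveBest(pc, seq_len(n), nt, ctx)
    expect_equal(rsValue(opt), rsValue(ex), tolerance = 1e-9,
                 info = sprintf("instance %d", i))
  }
})

test_that("the heuristic matches enumeration above the exact-solve cutoff", {
  # choose(25, 4) = 12650 > exactLimit, so the exchange path is used
  set.seed(321)
  L <- matrix(rnorm(25 * 6), 25, 6)
  pc <- makePC(L)
  ctx <- buildRScoreContext(matrix(rnorm(8 * 6), 8, 6))
  opt <- optimizeTrainingSet(pc, 1:25, 4, ctx, seed = 9)
  expect_gt(opt@nEvaluations, 0)
  ex <- exhaustiveBest(pc, 1:25, 4, ctx)
  expect_identical(ex@nEvaluations, 12650)
  expect_equal(rsValue(opt), rsValue(ex), tolerance = 1e-9)
})

test_that("child seeds stay in integer range and differ across counters", {
  s <- vapply(0:1000, function(k) deriveSeed(987654321, k), integer(1))
  expect_true(all(s > 0))
  expect_true(all(s < 2^31))
  expect_identical(anyDuplicated(s), 0L)
  expect_identical(deriveSeed(5, 3), deriveSeed(5, 3))
})
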