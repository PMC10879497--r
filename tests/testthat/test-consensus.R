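test_that("agreement matrix counts co-assignment fractions", {
  p1 <- partition(c(1, 1, 2, 2))
  p2 <- partition(c(1, 1, 2, 2))
  D <- agreementMatrix(list(p1, p2))
  v <- agreementValues(D)
  expect_equal(v[1, 2], 1)
  expect_equal(v[1, 3], 0)
  expect_equal(diag(v), rep(1, 4))
  # one disagreeing pair -> 0.5
  p3 <- partition(c(1, 2, 2, 2))
  v2 <- agreementValues(agreementMatrix(list(p1, p3)))
  expect_equal(v2[1, 2], 0.5)
  expect_true(isSymmetric(v2))
  # label permutation leaves agreement unchanged
  p1r <- partition(c(2, 2, 1, 1))
  expect_equal(agreementValues(agreementMatrix(list(p1, p1r))), v)
  expect_error(agreementMatrix(list()), "empty")
})

test_that("consensus of a binary block agreement returns the blocks", {
  v <- matrix(0, 6, 6)
  v[1:3, 1:3] <- 1
  v[4:6, 4:6] <- 1
  D <- new("AgreementMatrix", values = v, nRepetitions = 10L)
  p <- consensusPartition(D, gamma = 1, seed = 1)
  expect_equal(oracleNmi(moduleLabels(p), rep(1:2, each = 3)), 1)
})

test_that("subject consensus recovers a planted 6-module graph", {
  W <- plantedSubjectMatrix(seed = 301)
  sc <- subjectConsensus(W, gamma = 1.2, nReps = 100, seed = 5)
  truth <- rep(1:6, each = 12)
  expect_equal(nmi(sc$partition, partition(truth)), 1)
  # consensus Q on the original W is at least the median single-run Q
  qCons <- modularityScore(W, moduleLabels(sc$partition), gamma = 1.2)
  qMed <- median(vapply(sc$reps, modularityQ, 1.0))
  expect_gte(qCons, qMed - 1e-9)
})

test_that("group consensus is majority-driven and order-invariant", {
  truth <- rep(1:4, each = 6)
  set.seed(77)
  noisy <- lapply(1:12, function(i) {
    l <- truth
    flip <- sample(24, 2)                  # ~10% label noise
    l[flip] <- sample(4, 2, replace = TRUE)
    partition(l)
  })
  g1 <- groupConsensus(noisy, gamma = 1, seed = 3)
  expect_equal(oracleNmi(moduleLabels(g1), truth), 1)
  g2 <- groupConsensus(rev(noisy), gamma = 1, seed = 3)
  expect_equal(moduleLabels(g1), moduleLabels(g2))
  # all subjects identical -> that partition comes straight back
  same <- lapply(1:5, function(i) partition(truth))
  g3 <- groupConsensus(same, gamma = 1, seed = 1)
  expect_equal(oracleNmi(moduleLabels(g3), truth), 1)
})

test_that("nmi follows the arithmetic-mean normalization", {
  a <- partition(c(1, 1, 2, 2))
  expect_equal(nmi(a, a), 1)
  expect_equal(nmi(a, partition(c(2, 2, 1, 1))), 1)   # relabeling
  expect_equal(nmi(a, partition(c(1, 2, 1, 2))), 0)   # independent margins
  # zero-entropy conventions
  one <- partition(rep(1, 4))
  expect_equal(nmi(one, one), 1)
  expect_equal(nmi(one, a), 0)
  # cross-check against igraph and the contingency oracle on random labels
  canon <- netaging:::.canonicalLabels
  set.seed(123)
  for (i in 1:20) {
    l1 <- sample(3, 30, replace = TRUE)
    l2 <- sample(4, 30, replace = TRUE)
    v <- nmi(partition(l1), partition(l2))
    expect_equal(v, oracleNmi(canon(l1), canon(l2)), tolerance = 1e-12)
    expect_equal(v, igraph::compare(canon(l1), canon(l2), method = "nmi"),
                 tolerance = 1e-9)
  }
})

test_that("gamma sweep selects by mean pairwise NMI with low-gamma ties", {
  mats <- lapply(1:4, function(s) plantedSubjectMatrix(seed = 400 + s))
  sw <- gammaSweep(mats, gammas = c(1, 1.3, 1.6), nReps = 60, seed = 11)
  # strongly modular data: all gammas agree, tie resolved to the smallest
  expect_equal(sw$selectedGamma, 1)
  expect_true(isSymmetric(sw$nmiTable))
  expect_equal(diag(sw$nmiTable), rep(1, 3), ignore_attr = TRUE)
  expect_equal(nmi(sw$selectedPartition, partition(rep(1:6, each = 12))), 1)
})

test_that("hungarian assignment equals exhaustive permutation search", {
  set.seed(5)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    }
    out
  }
  for (rep in 1:20) {
    k <- sample(2:5, 1)
    cost <- matrix(runif(k * k), k, k)
    got <- netaging:::.hungarian(cost)
    best <- min(vapply(perms(seq_len(k)), function(p) {
      sum(cost[cbind(seq_len(k), p)])
    }, 1.0))
    expect_equal(sum(cost[cbind(seq_len(k), got)]), best, tolerance = 1e-12)
  }
})

test_that("classification consistency counts matched assignments per node", {
  cons <- partition(rep(1:2, each = 4))
  repsSame <- lapply(1:10, function(i) partition(rep(c(2, 1), each = 4)))
  cc <- classificationConsistency(repsSame, cons)
  expect_equal(unname(cc), rep(1, 8))      # relabeled copies still match
  # node 1 misassigned in 2 of 10 reps -> 0.8
  flip <- lapply(1:10, function(i) {
    l <- rep(1:2, each = 4)
    if (i <= 2) l[1] <- 2L
    partition(l)
  })
  cc2 <- classificationConsistency(flip, cons)
  expect_equal(unname(cc2[1]), 0.8)
  expect_equal(unname(cc2[2]), 1)
})

test_that("boundary nodes score lower consistency than core nodes", {
  # two 5-cliques plus node 6 tied equally to every node of both modules:
  # its assignment depends on the randomized sweep order
  W <- matrix(0, 11, 11)
  W[1:5, 1:5] <- 0.8
  W[7:11, 7:11] <- 0.8
  W[6, c(1:5, 7:11)] <- 0.4
  W[c(1:5, 7:11), 6] <- 0.4
  diag(W) <- 0
  reps <- repeatedPartitions(W, gamma = 1, nReps = 200, seed = 17)
  cons <- consensusPartition(agreementMatrix(reps), gamma = 1, seed = 1)
  cc <- classificationConsistency(reps, cons)
  expect_lt(cc[6], min(cc[c(1:5, 7:11)]))
})

test_that("module flow across timepoints conserves node counts", {
  pA <- partition(rep(1:2, each = 6))
  pB <- partition(c(rep(1, 6), rep(2, 3), rep(3, 3)))  # module 2 splits
  res <- matchModulesAcrossTimepoints(list(t1 = pA, t2 = pB))
  f <- res$flows
  # flows out of each source module sum to the module size
  out1 <- sum(f$n_shared_nodes[f$module_from == 1])
  out2 <- sum(f$n_shared_nodes[f$module_from == 2])
  expect_equal(out1, 6)
  expect_equal(out2, 6)
  expect_equal(sort(f$module_to[f$module_from == 2]), c(2, 3))
  # identical partitions: diagonal flow with Jaccard 1
  res2 <- matchModulesAcrossTimepoints(list(a = pA, b = pA))
  expect_true(all(res2$dominant$jaccard == 1))
  expect_equal(res2$dominant$module_from, res2$dominant$module_to)
})

test_that("reliable-module selection ranks by mean consistency", {
  cons <- partition(rep(1:3, each = 4))
  reps <- lapply(1:10, function(i) {
    l <- rep(1:3, each = 4)
    if (i <= 5) l[9] <- 1L       # module 3 is half-inconsistent at node 9
    partition(l)
  })
  mc <- moduleConsistency(reps, cons)
  expect_equal(mc[1], 1)
  expect_lt(mc[3], 1)
  expect_equal(selectReliableModules(reps, cons, k = 2), c(1L, 2L))
})
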