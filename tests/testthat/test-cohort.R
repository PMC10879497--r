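test_that("cohort design enumerates surviving subject/timepoint/session rows", {
  spec <- cohortSpec(nSubjectsPerCell = 3L, cohorts = c(A = "Y", B = "X"),
                     dropoutProb = 0)
  d <- buildCohortDesign(spec, seed = 7)$design
  # 2 cohorts x 2 sexes x 3 subjects x 3 timepoints x 2 sessions
  expect_equal(nrow(d), 12 * 3 * 2)
  expect_setequal(unique(d$group), c("X", "Y"))
  expect_equal(length(unique(d$subject_id)), 12)
  # ages jittered at most 14 days around targets, constant across sessions
  byTp <- split(d$age_days, d$timepoint_label)
  expect_true(all(abs(byTp$`12mo` - 365) <= 14))
  expect_true(all(abs(byTp$`24mo` - 730) <= 14))
  perKey <- tapply(d$age_days, paste(d$subject_id, d$timepoint_label),
                   function(x) length(unique(x)))
  expect_true(all(perKey == 1))
})

test_that("cohort design is deterministic given the seed", {
  spec <- cohortSpec(nSubjectsPerCell = 2L)
  a <- buildCohortDesign(spec, seed = 11)
  b <- buildCohortDesign(spec, seed = 11)
  expect_identical(a, b)
  c <- buildCohortDesign(spec, seed = 12)
  expect_false(identical(a$design$age_days, c$design$age_days))
})

test_that("dropout produces the expected binomial survival", {
  spec <- cohortSpec(nSubjectsPerCell = 250L, cohorts = c(A = "Y", B = "X"),
                     dropoutProb = 0.5, sessionsPerTimepoint = 1L)
  d <- buildCohortDesign(spec, seed = 3)$design
  n0 <- sum(d$timepoint_label == "12mo")
  n2 <- sum(d$timepoint_label == "24mo")
  expect_equal(n0, 1000)
  # survival to 3rd timepoint ~ Binomial(1000, 0.25); 4 sd tolerance
  expect_lt(abs(n2 / n0 - 0.25), 4 * sqrt(0.25 * 0.75 / 1000))
})

test_that("invalid cohort specs are rejected with the field named", {
  expect_error(cohortSpec(dropoutProb = 1.2), "dropoutProb")
  expect_error(cohortSpec(withinR0 = 0.2, betweenR0 = 0.4), "betweenR0")
  expect_error(cohortSpec(timepointsDays = c(365, 365, 730)),
               "strictly increasing")
  expect_error(cohortSpec(nRois = 71L), "even|nRois")
  expect_error(cohortSpec(plantedPartition = c(1, 2, rep(1, 70))),
               "mirror-symmetric")
})

test_that("target correlation matrices have the planted block structure", {
  labels <- rep(1:2, each = 3)
  m <- targetCorrelationMatrix(labels, 0.5, 0.1)
  expect_equal(diag(m), rep(1, 6))
  expect_equal(m[1, 2], 0.5)
  expect_equal(m[1, 4], 0.1)
  expect_false(attr(m, "repaired"))
  # compound symmetry: within == between is PD for n = 72
  cs <- targetCorrelationMatrix(rep(1:6, each = 12), 0.3, 0.3)
  expect_equal(max(abs(cs[row(cs) != col(cs)] - 0.3)), 0)
  expect_gt(min(eigen(cs, symmetric = TRUE, only.values = TRUE)$values), 0)
  # 6 equal modules: all eigenvalues positive (eigendecomposition oracle)
  m6 <- targetCorrelationMatrix(rep(1:6, each = 12), 0.5, 0.1)
  expect_gt(min(eigen(m6, symmetric = TRUE, only.values = TRUE)$values), 0)
  # degenerate corner: all-zero correlations give the identity
  id <- targetCorrelationMatrix(rep(1:2, each = 2), 0, 0)
  expect_equal(unname(id[, ]), diag(4), ignore_attr = TRUE)
  expect_error(targetCorrelationMatrix(labels, 1.0, 0.1), "withinR")
})

test_that("non-PD targets are repaired by eigenvalue flooring", {
  # a 3-node 'correlation' matrix that is not PD
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  ev <- eigen(bad, only.values = TRUE)$values
  expect_lt(min(ev), 0)
  # repair path exercised through the same flooring rule
  e <- eigen(bad)
  fixed <- stats::cov2cor(e$vectors %*% diag(pmax(e$values, 1e-6)) %*% t(e$vectors))
  expect_gt(min(eigen(fixed, only.values = TRUE)$values), 0)
})

test_that("simulated time series reproduce the target correlation", {
  tgt <- diag(6)
  ts <- simulateTimeseries(tgt, 100000, seed = 4)
  r <- cor(t(ts))
  expect_lt(max(abs(r[upper.tri(r)])), 0.02)   # ~3/sqrt(n) bound

  tgt2 <- targetCorrelationMatrix(rep(1:2, each = 3), 0.5, 0.5)
  ts2 <- simulateTimeseries(tgt2, 100000, seed = 5)
  r2 <- cor(t(ts2))
  expect_lt(abs(r2[1, 2] - 0.5), 0.01)         # Fisher-z SE scale

  expect_identical(simulateTimeseries(tgt, 50, seed = 9),
                   simulateTimeseries(tgt, 50, seed = 9))
  notPd <- matrix(c(1, 1.2, 1.2, 1), 2, 2)
  expect_error(simulateTimeseries(notPd, 100, seed = 1), "positive definite")
  expect_error(simulateTimeseries(tgt, 5, seed = 1), "nVolumes")
})

test_that("AR(1) series keep unit variance and the target cross-correlation", {
  tgt <- targetCorrelationMatrix(rep(1:2, each = 2), 0.6, 0.0)
  ts <- simulateTimeseries(tgt, 50000, seed = 6, arCoef = 0.5)
  expect_lt(abs(sd(ts[1, ]) - 1), 0.05)
  expect_lt(abs(cor(ts[1, ], ts[2, ]) - 0.6), 0.05)
  a1 <- cor(ts[1, -1], ts[1, -ncol(ts)])
  expect_lt(abs(a1 - 0.5), 0.05)
})

test_that("aging effects are linear in days and match the SI formula", {
  spec <- cohortSpec()
  base <- agingEffect(spec, "X", 365)
  expect_equal(unname(base), c(0.5, 0.1))
  # flat group stays at baseline at any age
  expect_equal(agingEffect(spec, "Y", 365), agingEffect(spec, "Y", 730))
  # -1e-4/day over 365 days drops the correlation by 0.0365
  spec2 <- cohortSpec(withinSlope = c(X = -1e-4, Y = 0))
  w <- agingEffect(spec2, "X", 730)[["within"]]
  expect_equal(w, 0.5 - 0.0365, tolerance = 1e-12)
  # ground-truth SI equals segregationIndex on the noiseless z target
  d <- buildCohortDesign(cohortSpec(nSubjectsPerCell = 1L), seed = 2)
  tr <- d$groundTruth$trajectories[1, ]
  tgt <- targetCorrelationMatrix(spec@plantedPartition, tr$within_r,
                                 tr$between_r)
  diag(tgt) <- 0
  z <- atanh(tgt)
  si <- segregationIndex(z, spec@plantedPartition)
  expect_equal(si$si, tr$si, tolerance = 1e-12)
})

test_that("full cohort simulation is a pure function of (spec, seed)", {
  spec <- cohortSpec(nSubjectsPerCell = 1L, nRois = 12L,
                     plantedPartition = rep(1:2, each = 6),
                     nVolumes = 40L, sessionsPerTimepoint = 1L,
                     timepointsDays = c(365, 548))
  a <- simulateCohort(spec, seed = 21)
  b <- simulateCohort(spec, seed = 21)
  expect_identical(a, b)
  expect_equal(names(a$sessions), a$design$session_id)
  expect_equal(dim(a$sessions[[1]]), c(12, 40))
})
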