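simulateLongitudinal <- function(nSubj = 30, slopePerDay = -0.001,
                                 interceptSd = 0.5, residSd = 0.2,
                                 seed = 1, factor = FALSE) {
  set.seed(seed)
  ages <- c(365, 548, 730)
  b <- rnorm(nSubj, 0, interceptSd)
  d <- do.call(rbind, lapply(seq_len(nSubj), function(i) {
    data.frame(subject_id = sprintf("s%03d", i), age_days = ages,
               sex = ifelse(i %% 2 == 0, "M", "F"),
               group = ifelse(i %% 2 == 0, "Y", "X"))
  }))
  d$si <- 2 + slopePerDay * d$age_days + b[match(d$subject_id,
                                                 sprintf("s%03d", 1:nSubj))] +
    rnorm(nrow(d), 0, residSd)
  d
}

test_that("the mixed model recovers a known age slope", {
  d <- simulateLongitudinal(seed = 5)
  res <- fitLME(d, outcome = "si", factor = "none")
  co <- res$coefficients
  i <- which(co$term == ".age")
  expect_lt(abs(co$estimate_per_day[i] - (-0.001)),
            3 * co$se[i] / res$ageScale)
  expect_equal(co$t[i], co$estimate[i] / co$se[i], tolerance = 1e-8)
  expect_equal(res$df, res$nObservations - nrow(co))
  expect_true(res$converged)
})

test_that("ML fit with zero random-effect variance matches OLS", {
  d <- simulateLongitudinal(nSubj = 20, interceptSd = 0, residSd = 0.3,
                            seed = 9)
  res <- suppressMessages(fitLME(d, outcome = "si", factor = "none"))
  ols <- lm(si ~ I((age_days - mean(age_days)) / 30.44), data = d)
  i <- which(res$coefficients$term == ".age")
  expect_equal(res$coefficients$estimate[i], unname(coef(ols)[2]),
               tolerance = 1e-6)
  expect_equal(res$coefficients$estimate[1], unname(coef(ols)[1]),
               tolerance = 1e-6)
})

test_that("pooled no-factor model equals the factor design without interaction columns", {
  d <- simulateLongitudinal(seed = 3)
  resNone <- fitLME(d, outcome = "si", factor = "none")
  # with identical slopes/intercepts per level, the factor model's age
  # estimate converges to the pooled one; here: design matrix identity only
  X <- model.matrix(~1 + age_days, d)
  expect_equal(ncol(X), 2)
  expect_equal(nrow(resNone$coefficients), 2)
  resSex <- fitLME(d, outcome = "si", factor = "sex")
  expect_equal(nrow(resSex$coefficients), 4)
  expect_true(any(grepl("sexM", resSex$coefficients$term)))
})

test_that("type-I error of the age test sits at the nominal level", {
  hits <- vapply(1:120, function(r) {
    d <- simulateLongitudinal(nSubj = 20, slopePerDay = 0, seed = 4000 + r)
    res <- suppressMessages(fitLME(d, outcome = "si", factor = "none"))
    i <- which(res$coefficients$term == ".age")
    res$coefficients$p[i] < 0.05
  }, logical(1))
  rate <- mean(hits)
  expect_lt(abs(rate - 0.05), 4 * sqrt(0.05 * 0.95 / 120))
})

test_that("the time contrast averages the slope over factor levels", {
  d <- simulateLongitudinal(seed = 12, slopePerDay = -0.001)
  # build sex-dependent slopes: +s for M, -s for F around zero mean
  d2 <- d
  s <- 0.0008
  d2$si <- 2 + ifelse(d2$sex == "M", s, -s) * d2$age_days +
    rnorm(nrow(d2), 0, 0.05)
  res <- fitLME(d2, outcome = "si", factor = "sex")
  tc <- timeContrast(res)
  co <- res$coefficients
  # equal contrast = age + 0.5 interaction
  iAge <- which(co$term == ".age")
  iInt <- grep(":", co$term)
  expect_equal(tc$estimate, co$estimate[iAge] + 0.5 * co$estimate[iInt],
               tolerance = 1e-12)
  # c' Sigma c oracle
  cvec <- numeric(nrow(co))
  cvec[iAge] <- 1; cvec[iInt] <- 0.5
  expect_equal(tc$se, sqrt(drop(t(cvec) %*% res$vcov %*% cvec)),
               tolerance = 1e-12)
  # symmetric slopes cancel in the equal contrast
  expect_lt(abs(tc$estimate_per_day), 1e-4)
  # zero interaction: contrast equals the age coefficient
  d3 <- simulateLongitudinal(seed = 13)
  res3 <- fitLME(d3, outcome = "si", factor = "sex")
  tc3 <- timeContrast(res3)
  co3 <- res3$coefficients
  expect_equal(tc3$estimate,
               co3$estimate[co3$term == ".age"] +
                 0.5 * co3$estimate[grep(":", co3$term)], tolerance = 1e-12)
  expect_error(timeContrast(fitLME(d3, outcome = "si", factor = "none")),
               "interaction")
})

test_that("BH correction matches the brute-force step-up oracle", {
  set.seed(21)
  for (r in 1:50) {
    m <- sample(c(1, 2, 5, 20, 100), 1)
    p <- runif(m)^sample(c(1, 2), 1)
    expect_equal(p.adjust(p, method = "BH"), oracleBH(p), tolerance = 1e-12)
  }
  # massUnivariateLME output invariants on a constructed table
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_equal(oracleBH(p), rep(0.04, 4))
  expect_equal(p.adjust(p, method = "BH"), rep(0.04, 4))
})

test_that("KS statistic equals ECDF enumeration on all small pairs", {
  vals <- 1:4
  for (na in 1:3) for (nb in 1:3) {
    combsA <- expand.grid(rep(list(vals), na))
    combsB <- expand.grid(rep(list(vals), nb))
    for (i in seq_len(min(nrow(combsA), 20))) {
      for (j in seq_len(min(nrow(combsB), 20))) {
        a <- as.numeric(combsA[i, ])
        b <- as.numeric(combsB[j, ])
        expect_equal(ksCompare(a, b)$statistic, oracleKs(a, b),
                     tolerance = 1e-12)
      }
    }
  }
  expect_equal(ksCompare(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  expect_equal(ksCompare(c(1, 2), c(5, 6))$statistic, 1)
  expect_equal(ksCompare(c(1, 2, 3), c(2, 3, 4))$statistic, 1 / 3)
})

test_that("mass-univariate fits control FDR and emit both masks", {
  set.seed(31)
  nUnits <- 40
  base <- simulateLongitudinal(nSubj = 12, slopePerDay = 0, seed = 99)
  tab <- do.call(rbind, lapply(seq_len(nUnits), function(u) {
    d <- base
    d$unit <- sprintf("u%02d", u)
    # give 5 units a real slope
    sl <- if (u <= 5) -0.002 else 0
    set.seed(1000 + u)
    d$value <- 1 + sl * d$age_days + rnorm(nrow(d), 0, 0.1)
    d
  }))
  res <- massUnivariateLME(tab, factor = "none", alpha = 0.05)
  expect_equal(nrow(res), nUnits)
  expect_true(all(res$q >= res$p - 1e-12))
  expect_equal(res$q, p.adjust(res$p, method = "BH"))
  # the 5 signal units dominate the discoveries
  sig <- res$unit[res$sig_fdr]
  expect_true(all(sprintf("u%02d", 1:5) %in% sig))
  expect_lte(length(setdiff(sig, sprintf("u%02d", 1:5))), 3)
})

test_that("stratified SI trajectory analysis recovers group-dependent slopes", {
  d <- simulateLongitudinal(nSubj = 20, slopePerDay = 0, seed = 61,
                            residSd = 0.05, interceptSd = 0.1)
  # group X declines, group Y flat
  d$si <- d$si + ifelse(d$group == "X", -0.0008, 0) * (d$age_days - 365)
  d$cohort <- ifelse(d$group == "X", "B", "A")
  tab <- siTrajectoryAnalysis(d)
  x <- tab[tab$stratum == "group" & tab$level == "X", ]
  y <- tab[tab$stratum == "group" & tab$level == "Y", ]
  expect_lt(x$slope_per_day, 0)
  expect_lt(x$p, 0.05)
  expect_gt(y$p, 0.05)
  expect_true("overall" %in% tab$stratum)
  # excluded subjects are dropped before fitting
  d$excluded_flag <- d$subject_id %in% c("s001", "s002")
  tab2 <- siTrajectoryAnalysis(d)
  expect_equal(tab2$n_subjects[tab2$stratum == "overall"], 18)
})
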