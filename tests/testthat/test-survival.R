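test_that("MELD score follows the log-linear formula and dialysis rule", {
  expect_equal(computeMELD(1, 1, 1, FALSE), 6.43)
  expect_equal(computeMELD(1, 1, 1, TRUE), 6.43 + 9.57 * log(4))
  expect_equal(computeMELD(exp(1), exp(1), exp(1)),
               9.57 + 3.78 + 11.2 + 6.43)
  expect_equal(computeMELD(c(1, exp(1)), 1, 1), c(6.43, 6.43 + 3.78))
  expect_error(computeMELD(0, 1, 1), "positive")
  expect_error(computeMELD(1, -2, 1), "positive")
})

test_that("clinical imputation applies median and constant rules", {
  tab <- data.frame(weight = c(70, NA, 90), height = c(NA, 160, 180),
                    ca19_9 = c(NA, 2, 4), ldh = c(1, NA, 3),
                    days_diagnosis_to_surgery = c(10, NA, 30),
                    biliary_stent = c(NA, 1, 0),
                    perineural_invasion = c(0, NA, 1),
                    uicc_stage = c(NA, 2, 3), V = c(NA, 1, 0),
                    L = c(0, NA, 1), T = c(NA, 2, 3), G = c(1, NA, 3))
  out <- imputeClinical(tab)
  expect_equal(out$weight[2], 80)          # median
  expect_equal(out$T[1], 0)                # T grading -> 0
  expect_equal(out$G[2], 2)                # G grading -> 2
  expect_equal(out$biliary_stent[1], 0)
  expect_false(anyNA(out))
  flags <- attr(out, "imputed")
  expect_true(flags$weight[2] && !flags$weight[1])

  ## medians come from training rows only
  out2 <- imputeClinical(tab, trainIdx = c(1, 2))
  expect_equal(out2$weight[2], 70)
  expect_error(imputeClinical(tab[, -1]), "missing column")
})

test_that("univariable screen is calibrated under the null and powered", {
  ## null: an unrelated covariate is flagged at roughly the alpha rate
  flagged <- 0L; nrep <- 100L
  for (r in seq_len(nrep)) {
    X <- matrix(stats::rnorm(80), 80, 1)
    coh <- generateCohort(cohortSpec(80, beta = 0, baselineHazard = 0.1,
                                     censorRate = 0.02, seed = 7000 + r), X)
    sc <- univariableCoxScreen(data.frame(x = X[, 1]), coh)
    flagged <- flagged + sc$flagged[1]
  }
  expect_gte(flagged / nrep, 0.005)
  expect_lte(flagged / nrep, 0.13)

  ## power: HR = 3 at n = 200 is flagged essentially always
  hits <- 0L
  for (r in 1:50) {
    X <- matrix(stats::rnorm(200), 200, 1)
    coh <- generateCohort(cohortSpec(200, beta = log(3),
                                     baselineHazard = 0.1,
                                     censorRate = 0.02, seed = 8000 + r), X)
    sc <- univariableCoxScreen(data.frame(x = X[, 1]), coh)
    hits <- hits + sc$flagged[1]
  }
  expect_gte(hits, 48L)

  expect_warning(univariableCoxScreen(
    data.frame(c1 = rep(1, 50), x = stats::rnorm(50)),
    generateCohort(cohortSpec(50, beta = numeric(), seed = 1),
                   matrix(numeric(0), 50, 0))), "constant covariate")
})

test_that("screen drops IHM and R2 patients before fitting", {
  X <- matrix(stats::rnorm(100), 100, 1)
  coh <- generateCohort(cohortSpec(100, beta = 1, baselineHazard = 0.1,
                                   censorRate = 0.02, seed = 3), X)
  coh$in_hospital_death <- rep(c(TRUE, FALSE), 50)
  keep <- survivalInclusion(coh)
  expect_identical(sum(keep), 50L)
  sc <- univariableCoxScreen(data.frame(x = X[, 1]), coh)
  scAll <- univariableCoxScreen(data.frame(x = X[, 1]), coh,
                                applyExclusions = FALSE)
  expect_false(isTRUE(all.equal(sc$p, scAll$p)))
})

test_that("backward selection retains true effects and prunes collinear copies", {
  set.seed(11)
  X <- matrix(stats::rnorm(200), 200, 1, dimnames = list(NULL, "x1"))
  coh <- generateCohort(cohortSpec(200, beta = 1.2, baselineHazard = 0.1,
                                   censorRate = 0.02, seed = 5), X)
  tab <- data.frame(x1 = X[, 1])
  mv <- multivariableCox(tab, coh, "x1")
  expect_identical(mv$covariate, "x1")

  ## near-collinear duplicate: exactly one of the pair survives
  tab2 <- data.frame(x1 = X[, 1], x2 = X[, 1] + stats::rnorm(200, 0, 0.01))
  mv2 <- multivariableCox(tab2, coh, c("x1", "x2"))
  expect_identical(nrow(mv2), 1L)
  expect_true(mv2$covariate %in% c("x1", "x2"))

  ## pure noise: an empty model is a valid outcome, not an error
  cohN <- generateCohort(cohortSpec(200, beta = 0, baselineHazard = 0.1,
                                    censorRate = 0.02, seed = 6), X)
  mvN <- multivariableCox(data.frame(z = stats::rnorm(200)), cohN, "z")
  expect_true(nrow(mvN) %in% c(0L, 1L))

  ## selection recovery: true effects among noise retained most of the time
  recovered <- 0L
  for (r in 1:10) {
    set.seed(300 + r)
    Xr <- matrix(stats::rnorm(200 * 6), 200, 6,
                 dimnames = list(NULL, paste0("v", 1:6)))
    cohR <- generateCohort(cohortSpec(200, beta = c(1, 1, 0, 0, 0, 0),
                                      baselineHazard = 0.1,
                                      censorRate = 0.02, seed = 400 + r), Xr)
    mvR <- multivariableCox(as.data.frame(Xr), cohR, paste0("v", 1:6))
    recovered <- recovered + all(c("v1", "v2") %in% mvR$covariate)
  }
  expect_gte(recovered, 6L)
})

test_that("KM estimator and log-rank match hand product-limit arithmetic", {
  ## 6-patient toy, distinct times, one censored per group
  time <- c(2, 4, 6, 3, 5, 7)
  event <- c(1, 0, 1, 1, 1, 0)
  risk <- c(10, 9, 8, 3, 2, 1)   # split: first three high, last three low
  out <- data.frame(time = time, event = event)
  res <- kmLogrankSplit(risk, out)
  expect_identical(as.character(res$groups),
                   c("high", "high", "high", "low", "low", "low"))

  ## oracle product-limit per group
  for (g in c("low", "high")) {
    sel <- res$groups == g
    orc <- kmOracle(time[sel], event[sel])
    got <- res$km[res$km$group == g, ]
    expect_equal(got$time, orc$time)
    expect_equal(got$survival, orc$survival, tolerance = 1e-9)
  }
  ## oracle log-rank chi-square
  expect_equal(res$logrank$chisq,
               logrankOracle(time, event, res$groups), tolerance = 1e-9)

  ## risks = negated event times, no censoring: perfect ranking, and the
  ## KM estimate equals the empirical survival function exactly
  t2 <- 1:8
  res2 <- kmLogrankSplit(-t2, data.frame(time = t2, event = rep(1, 8)))
  km2 <- res2$km[res2$km$group == "high", ]
  expect_equal(km2$time, 1:4)
  expect_equal(km2$survival, 1 - (1:4) / 4, tolerance = 1e-12)
  expect_equal(res2$concordance, 1.0)

  ## identical groups by construction: log-rank statistic ~ 0
  td <- rep(c(3, 5, 8), 2); ed <- rep(c(1, 1, 0), 2)
  rk <- c(1, 1, 1, 2, 2, 2)
  resd <- kmLogrankSplit(rk, data.frame(time = td, event = ed))
  expect_lt(resd$logrank$chisq, 1e-9)

  expect_error(kmLogrankSplit(rep(1, 6), out), "impossible")
})

test_that("concordance equals brute-force pair counting on small cohorts", {
  set.seed(21)
  for (r in 1:20) {
    n <- 10
    time <- sample(1:50, n)            # distinct times
    event <- stats::rbinom(n, 1, 0.7)
    if (sum(event) == 0) event[1] <- 1
    risk <- stats::rnorm(n)
    expect_equal(concordanceIndex(risk, time, event),
                 concordanceOracle(risk, time, event), tolerance = 1e-12)
  }
})

test_that("risk model bootstrap is deterministic and validates inputs", {
  set.seed(2)
  X <- matrix(stats::rnorm(60 * 3), 60, 3)
  coh <- generateCohort(cohortSpec(60, beta = c(1, 0, 0),
                                   baselineHazard = 0.1, censorRate = 0.02,
                                   seed = 4), X)
  a <- fitRiskModel(X, coh, nBoot = 1L, seed = 3)
  b <- fitRiskModel(X, coh, nBoot = 1L, seed = 3)
  expect_identical(riskScores(a), riskScores(b))
  expect_identical(concordanceIndices(a), concordanceIndices(b))

  cohC <- coh; cohC$event <- 0
  expect_error(fitRiskModel(X, cohC, nBoot = 2L), "censored")
  expect_error(fitRiskModel(X[1:10, ], coh), "row-aligned")

  ## hyperparameter search stays in the declared space and runs end-to-end
  hp <- sampleHyperparams(20, seed = 5)
  expect_true(all(hp$nrounds >= 50 & hp$nrounds <= 500))
  expect_true(all(hp$max_depth %in% 1:4))
  expect_true(all(hp$eta >= 0.01 & hp$eta <= 0.3))
  expect_true(all(hp$subsample >= 0.5 & hp$subsample <= 1))
  fitH <- fitRiskModel(X, coh, nBoot = 3L, hpoBudget = 2L, hpoRounds = 2L,
                       seed = 3)
  expect_true(fitH@bestParams$max_depth %in% 1:4)
})

test_that("impurity importances are normalized and rank true signals first", {
  set.seed(8)
  X <- matrix(stats::rnorm(120 * 4), 120, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  coh <- generateCohort(cohortSpec(120, beta = c(2, 0, 0, 0),
                                   baselineHazard = 0.1, censorRate = 0.02,
                                   seed = 9), X)
  fit <- fitRiskModel(X, coh, nBoot = 20L, seed = 2)
  imp <- importanceSamples(fit)
  expect_equal(unname(rowSums(imp)), rep(1, 20), tolerance = 1e-9)
  fi <- featureImportanceDistribution(fit)$summary
  expect_identical(fi$feature[which.max(fi$median)], "f1")

  ## single feature: importance 1 every round
  X1 <- X[, 1, drop = FALSE]
  fit1 <- fitRiskModel(X1, coh, nBoot = 5L, seed = 2)
  expect_equal(unname(importanceSamples(fit1)[, 1]), rep(1, 5))

  ## pure noise: importances roughly exchangeable
  cohN <- generateCohort(cohortSpec(120, beta = rep(0, 4),
                                    baselineHazard = 0.1, censorRate = 0.02,
                                    seed = 10), X)
  fitN <- fitRiskModel(X, cohN, nBoot = 50L, seed = 2)
  med <- apply(importanceSamples(fitN), 2, stats::median)
  expect_lt(max(med) / min(med), 3)
})

test_that("validation scores come from out-of-bag patients only", {
  set.seed(5)
  X <- matrix(stats::rnorm(40 * 2), 40, 2)
  coh <- generateCohort(cohortSpec(40, beta = c(1, 0), baselineHazard = 0.1,
                                   censorRate = 0.02, seed = 6), X)
  fit <- fitRiskModel(X, coh, nBoot = 30L, seed = 7)
  sc <- riskScores(fit)
  tr <- sc[sc$split == "train", ]
  ## a training patient is out-of-bag in ~ (1-1/n)^n ~ 37% of rounds
  expect_true(all(tr$n_rounds < 30))
  expect_true(all(sc$n_rounds[sc$split == "test"] == 30))
})
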