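## Gradient-boosted Cox survival modelling (xgboost, objective
## "survival:cox") with patient-level bootstrap resampling: per round the
## training patients are resampled with replacement, the ensemble is fitted,
## and the round's out-of-bag patients ("validation") plus the fixed
## held-out test patients are scored; per-patient risks are averaged over
## rounds and per-round concordance indices recorded.

## xgboost survival:cox encodes censored observations as negative times.
coxLabel <- function(time, event) ifelse(event == 1, time, -time)

fitBoostRound <- function(X, time, event, params, nrounds, seed) {
  dtrain <- xgboost::xgb.DMatrix(X, label = coxLabel(time, event),
                                 nthread = 1)
  xgboost::xgb.train(
    params = c(params, list(objective = "survival:cox", nthread = 1,
                            seed = seed)),
    data = dtrain, nrounds = nrounds, verbose = 0)
}

predictRisk <- function(bst, X) {
  ## log-hazard margin: higher = higher risk
  predict(bst, xgboost::xgb.DMatrix(X, nthread = 1), outputmargin = TRUE)
}

## Normalized impurity (gain) importance over all feature columns.
roundImportance <- function(bst, featureNames) {
  imp <- tryCatch(xgboost::xgb.importance(model = bst),
                  error = function(e) NULL)
  out <- stats::setNames(numeric(length(featureNames)), featureNames)
  if (!is.null(imp) && nrow(imp)) {
    out[imp$Feature] <- imp$Gain
    out / sum(out)
  } else {
    ## ensemble made no splits: importance is uninformative, spread evenly
    out + 1 / length(out)
  }
}

safeConcordance <- function(risk, time, event) {
  if (length(risk) < 2 || sum(event) < 1 || length(unique(risk)) < 1)
    return(NA_real_)
  tryCatch(concordanceIndex(risk, time, event), error = function(e) NA_real_)
}

#' Hyperparameter search space for the boosted Cox model
#'
#' Random candidates over trees 50-500, depth 1-4, learning rate
#' 0.01-0.3 and subsample 0.5-1.0.
#' @param n number of candidates.
#' @param seed RNG seed.
#' @return data.frame of candidate settings.
#' @export
sampleHyperparams <- function(n, seed = 1L) {
  withSeed(subSeed(seed, 91L), data.frame(
    nrounds = sample(seq(50L, 500L, by = 50L), n, replace = TRUE),
    max_depth = sample(1:4, n, replace = TRUE),
    eta = stats::runif(n, 0.01, 0.3),
    subsample = stats::runif(n, 0.5, 1.0)))
}

#' Fit the bootstrap-averaged gradient-boosted Cox risk model
#'
#' Splits patients into a fixed held-out test set and a training set
#' (by patient; either explicit `testIds` or a seeded fraction). An
#' optional random hyperparameter search (`hpoBudget` candidates, each
#' scored by mean out-of-bag concordance over `hpoRounds` bootstrap
#' rounds) precedes the final pass of `nBoot` bootstrap rounds. Per
#' round, training patients are resampled with replacement, a boosted
#' Cox tree ensemble is fitted, and the round's out-of-bag patients and
#' the test patients are scored; risks are averaged per patient across
#' rounds (training patients over their out-of-bag rounds only) and
#' per-round concordance indices and normalized impurity importances are
#' recorded.
#'
#' @param features numeric matrix or data.frame (patients x features):
#'   clinical covariates, reduced slide features, or both.
#' @param outcomes aligned data.frame with `patient_id`, `time`, `event`.
#' @param nBoot bootstrap rounds (canonical 1000).
#' @param testIds patient_ids held out for testing; if NULL a seeded
#'   `testFraction` sample is drawn.
#' @param testFraction fraction of patients held out when `testIds` is
#'   NULL (canonical split: 27 of 142).
#' @param hpoBudget hyperparameter candidates (0 = use `params`).
#' @param hpoRounds bootstrap rounds per hyperparameter candidate.
#' @param params boosted-tree settings used when `hpoBudget = 0`:
#'   list(nrounds, max_depth, eta, subsample).
#' @param seed integer RNG seed for the split, resampling and boosting.
#' @return A [RiskScoreSet-class].
#' @export
fitRiskModel <- function(features, outcomes, nBoot = 1000L, testIds = NULL,
                         testFraction = 27 / 142, hpoBudget = 0L,
                         hpoRounds = 10L,
                         params = list(nrounds = 100L, max_depth = 2L,
                                       eta = 0.1, subsample = 0.8),
                         seed = 1L) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) colnames(X) <- paste0("f", seq_len(ncol(X)))
  storage.mode(X) <- "double"
  stopIfNot(nrow(X) == nrow(outcomes),
            "features must be row-aligned with outcomes")
  ids <- as.character(outcomes$patient_id)
  if (is.null(testIds)) {
    nTest <- max(1L, round(testFraction * length(ids)))
    testIds <- withSeed(subSeed(seed, 92L), sample(ids, nTest))
  }
  isTest <- ids %in% testIds
  trIdx <- which(!isTest); teIdx <- which(isTest)
  stopIfNot(length(trIdx) >= 4, "too few training patients")
  if (sum(outcomes$event[trIdx]) == 0)
    stop("all training outcomes are censored: Cox loss undefined",
         call. = FALSE)

  runRounds <- function(prm, rounds, seedOffset) {
    nTr <- length(trIdx)
    riskSum <- numeric(nrow(X)); riskCnt <- integer(nrow(X))
    valC <- numeric(rounds); testC <- numeric(rounds)
    imp <- matrix(0, rounds, ncol(X), dimnames = list(NULL, colnames(X)))
    for (b in seq_len(rounds)) {
      rs <- subSeed(seed, seedOffset + b)
      bag <- withSeed(rs, sample(trIdx, nTr, replace = TRUE))
      oob <- setdiff(trIdx, bag)
      bst <- fitBoostRound(X[bag, , drop = FALSE], outcomes$time[bag],
                           outcomes$event[bag],
                           params = list(max_depth = prm$max_depth,
                                         eta = prm$eta,
                                         subsample = prm$subsample),
                           nrounds = prm$nrounds, seed = rs)
      if (length(oob)) {
        rOob <- predictRisk(bst, X[oob, , drop = FALSE])
        riskSum[oob] <- riskSum[oob] + rOob
        riskCnt[oob] <- riskCnt[oob] + 1L
        valC[b] <- safeConcordance(rOob, outcomes$time[oob],
                                   outcomes$event[oob])
      } else valC[b] <- NA_real_
      if (length(teIdx)) {
        rTe <- predictRisk(bst, X[teIdx, , drop = FALSE])
        riskSum[teIdx] <- riskSum[teIdx] + rTe
        riskCnt[teIdx] <- riskCnt[teIdx] + 1L
        testC[b] <- safeConcordance(rTe, outcomes$time[teIdx],
                                    outcomes$event[teIdx])
      } else testC[b] <- NA_real_
      imp[b, ] <- roundImportance(bst, colnames(X))
    }
    list(riskSum = riskSum, riskCnt = riskCnt, valC = valC, testC = testC,
         imp = imp)
  }

  prm <- params
  if (hpoBudget > 0) {
    cand <- sampleHyperparams(hpoBudget, seed)
    score <- vapply(seq_len(hpoBudget), function(i) {
      res <- runRounds(as.list(cand[i, ]), hpoRounds,
                       seedOffset = 5000L + 100L * i)
      mean(res$valC, na.rm = TRUE)
    }, numeric(1))
    prm <- as.list(cand[which.max(score), ])
  }

  res <- runRounds(prm, nBoot, seedOffset = 10000L)
  risk <- ifelse(res$riskCnt > 0, res$riskSum / pmax(res$riskCnt, 1L),
                 NA_real_)
  scores <- data.frame(patient_id = ids,
                       split = ifelse(isTest, "test", "train"),
                       risk = risk, n_rounds = res$riskCnt)
  ## patients never out-of-bag in any round carry no averaged risk; drop
  scores <- scores[!is.na(scores$risk), , drop = FALSE]
  new("RiskScoreSet", scores = scores, valConcordance = res$valC,
      testConcordance = res$testC, importance = res$imp,
      bestParams = prm, nRounds = as.integer(nBoot))
}

#' Distribution of impurity-based feature importances across rounds
#'
#' Per bootstrap round the total impurity (gain) reduction attributed to
#' each feature, normalized to sum 1; the across-round distribution is
#' what the violin plot of clinical-feature importances shows.
#'
#' @param fit a [RiskScoreSet-class] from [fitRiskModel()].
#' @return List with `samples` (rounds x features matrix) and `summary`
#'   (data.frame: feature, median, q25, q75).
#' @export
featureImportanceDistribution <- function(fit) {
  stopIfNot(is(fit, "RiskScoreSet"), "unsupported model object")
  imp <- importanceSamples(fit)
  qs <- apply(imp, 2, stats::quantile, probs = c(0.25, 0.5, 0.75))
  list(samples = imp,
       summary = data.frame(feature = colnames(imp), median = qs[2, ],
                            q25 = qs[1, ], q75 = qs[3, ],
                            row.names = NULL))
}
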