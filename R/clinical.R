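#' MELD score (Model for End-stage Liver Disease)
#'
#' `9.57 * ln(creatinine) + 3.78 * ln(bilirubin) + 11.2 * ln(INR) + 6.43`,
#' with creatinine in mg/dL, bilirubin in mg/dL. If the patient received
#' dialysis (at least twice) in the last week, the creatinine value is set
#' to 4.0 before evaluation.
#'
#' @param bilirubin total bilirubin in mg/dL (> 0).
#' @param creatinine serum creatinine in mg/dL (> 0).
#' @param inr International Normalized Ratio (> 0).
#' @param dialysisLastWeek logical; dialysis in the week before the labs.
#' @return MELD points (vectorized over the inputs).
#' @examples
#' computeMELD(1, 1, 1)          # 6.43, the additive constant
#' computeMELD(1, 1, 1, TRUE)    # dialysis rule adds 9.57 * log(4)
#' @export
computeMELD <- function(bilirubin, creatinine, inr,
                        dialysisLastWeek = FALSE) {
  n <- max(length(bilirubin), length(creatinine), length(inr),
           length(dialysisLastWeek))
  bilirubin <- rep_len(bilirubin, n); creatinine <- rep_len(creatinine, n)
  inr <- rep_len(inr, n); dialysisLastWeek <- rep_len(dialysisLastWeek, n)
  stopIfNot(all(bilirubin > 0) && all(creatinine > 0) && all(inr > 0),
            "laboratory values must be positive")
  creatinine[dialysisLastWeek] <- 4.0
  9.57 * log(creatinine) + 3.78 * log(bilirubin) + 11.2 * log(inr) + 6.43
}

#' Default clinical imputation rules
#'
#' Continuous variables (CA19-9, LDH, weight, height, days from diagnosis
#' to surgery) are imputed with the column median; biliary stent,
#' perineural invasion, UICC stage, vascular invasion (V), lymphatic
#' invasion (L) and T grading with 0; G grading with 2 (the most common
#' grade for this tumor).
#'
#' @return Named list mapping column names to `"median"` or a constant.
#' @export
defaultImputationRules <- function() {
  list(ca19_9 = "median", ldh = "median", weight = "median",
       height = "median", days_diagnosis_to_surgery = "median",
       biliary_stent = 0, perineural_invasion = 0, uicc_stage = 0,
       V = 0, L = 0, T = 0, G = 2)
}

#' Impute missing clinical covariates
#'
#' Applies per-column rules (`"median"` or a constant). Medians are
#' computed on training rows only (`trainIdx`), so held-out patients
#' never influence the imputation. Imputation flags are attached as the
#' `"imputed"` attribute (logical data.frame).
#'
#' @param table clinical data.frame.
#' @param rules named list as from [defaultImputationRules()]; only rules
#'   whose column exists are required to be present — a rule naming a
#'   missing column is a configuration error.
#' @param trainIdx row indices used to compute medians (default: all).
#' @return The table with no missing values in the ruled columns.
#' @export
imputeClinical <- function(table, rules = defaultImputationRules(),
                           trainIdx = seq_len(nrow(table))) {
  flags <- as.data.frame(matrix(FALSE, nrow(table), length(rules),
                                dimnames = list(NULL, names(rules))))
  for (field in names(rules)) {
    if (!field %in% names(table))
      stop("imputation rule for missing column: ", field, call. = FALSE)
    miss <- is.na(table[[field]])
    if (!any(miss)) next
    rule <- rules[[field]]
    value <- if (identical(rule, "median")) {
      trainVals <- table[[field]][intersect(trainIdx, which(!miss))]
      if (!length(trainVals))
        stop("column ", field, " has no observed training values",
             call. = FALSE)
      stats::median(trainVals)
    } else as.numeric(rule)
    table[[field]][miss] <- value
    flags[[field]] <- miss
  }
  attr(table, "imputed") <- flags
  table
}

#' Apply the in-hospital-mortality / R2-resection exclusion
#'
#' Drops patients flagged `in_hospital_death` or `r2_resection` before the
#' classical Cox screen, mirroring survival analyses reported "without
#' IHM".
#'
#' @param outcomes data.frame with `time`, `event` and optional
#'   `in_hospital_death`, `r2_resection` flags.
#' @return Logical keep-vector aligned with the rows.
#' @export
survivalInclusion <- function(outcomes) {
  keep <- rep(TRUE, nrow(outcomes))
  if ("in_hospital_death" %in% names(outcomes))
    keep <- keep & !as.logical(outcomes$in_hospital_death)
  if ("r2_resection" %in% names(outcomes))
    keep <- keep & !as.logical(outcomes$r2_resection)
  keep
}

#' Univariable Cox screen over candidate covariates
#'
#' One proportional-hazards fit per covariate; covariates with Wald
#' `P < alpha` (strict inequality) are flagged for the multivariable
#' stage. Constant covariates are skipped with a warning. Patients
#' excluded by [survivalInclusion()] are dropped first.
#'
#' @param table data.frame of covariates.
#' @param outcomes aligned data.frame with `time` and `event` (and
#'   optional exclusion flags).
#' @param alpha significance threshold (default 0.05).
#' @param applyExclusions drop IHM / R2 patients first (default TRUE).
#' @return data.frame: covariate, hr, ci_low, ci_high, p, flagged.
#' @export
univariableCoxScreen <- function(table, outcomes, alpha = 0.05,
                                 applyExclusions = TRUE) {
  stopIfNot(nrow(table) == nrow(outcomes),
            "covariates and outcomes must be row-aligned")
  keep <- if (applyExclusions) survivalInclusion(outcomes) else
    rep(TRUE, nrow(outcomes))
  table <- table[keep, , drop = FALSE]
  outcomes <- outcomes[keep, , drop = FALSE]
  srv <- survival::Surv(outcomes$time, outcomes$event)
  rows <- lapply(names(table), function(nm) {
    x <- table[[nm]]
    if (length(unique(x[!is.na(x)])) < 2) {
      warning("skipping constant covariate: ", nm)
      return(NULL)
    }
    fit <- survival::coxph(srv ~ x, data = data.frame(x = x))
    sm <- summary(fit)
    data.frame(covariate = nm, hr = unname(sm$conf.int[1, "exp(coef)"]),
               ci_low = unname(sm$conf.int[1, "lower .95"]),
               ci_high = unname(sm$conf.int[1, "upper .95"]),
               p = unname(sm$coefficients[1, "Pr(>|z|)"]))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(covariate = character(), hr = numeric(),
                      ci_low = numeric(), ci_high = numeric(), p = numeric(),
                      flagged = logical()))
  out$flagged <- out$p < alpha
  out
}

#' Multivariable Cox model with conditional backward selection
#'
#' Starts from the flagged covariates and iteratively removes the
#' covariate with the largest Wald P-value at or above the removal
#' threshold, refitting after each removal, until all retained covariates
#' have `P < threshold`. An empty model (no covariate survives) is a
#' valid result, not an error.
#'
#' @param table covariate data.frame.
#' @param outcomes aligned data.frame with `time`, `event` (and optional
#'   exclusion flags).
#' @param covariates names of the covariates entering the model.
#' @param threshold removal threshold (default 0.05).
#' @param applyExclusions drop IHM / R2 patients first (default TRUE).
#' @return data.frame of retained covariates: covariate, hr, ci_low,
#'   ci_high, p (0 rows when nothing survives).
#' @export
multivariableCox <- function(table, outcomes, covariates, threshold = 0.05,
                             applyExclusions = TRUE) {
  stopIfNot(length(covariates) >= 1, "need at least one flagged covariate")
  keep <- if (applyExclusions) survivalInclusion(outcomes) else
    rep(TRUE, nrow(outcomes))
  dat <- cbind(outcomes[keep, c("time", "event")],
               table[keep, covariates, drop = FALSE])
  current <- covariates
  while (length(current)) {
    fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                   paste(current, collapse = " + ")))
    fit <- survival::coxph(fml, data = dat)
    sm <- summary(fit)
    ps <- stats::setNames(sm$coefficients[, "Pr(>|z|)"],
                          rownames(sm$coefficients))
    if (max(ps) < threshold) break
    worst <- names(ps)[which.max(ps)]
    ## coefficient names equal covariate names for numeric covariates
    current <- setdiff(current, worst)
  }
  if (!length(current))
    return(data.frame(covariate = character(), hr = numeric(),
                      ci_low = numeric(), ci_high = numeric(),
                      p = numeric()))
  sm <- summary(fit)
  data.frame(covariate = rownames(sm$coefficients),
             hr = unname(sm$conf.int[, "exp(coef)"]),
             ci_low = unname(sm$conf.int[, "lower .95"]),
             ci_high = unname(sm$conf.int[, "upper .95"]),
             p = unname(sm$coefficients[, "Pr(>|z|)"]),
             row.names = NULL)
}

#' Concordance index of a risk score against survival outcomes
#'
#' Probability that, of a comparable patient pair, the patient with the
#' higher predicted risk fails first (Harrell's C via
#' [survival::concordance()]).
#'
#' @param risk numeric risk scores (higher = worse prognosis).
#' @param time,event survival outcome.
#' @return Concordance index in [0, 1].
#' @export
concordanceIndex <- function(risk, time, event) {
  fit <- survival::concordance(survival::Surv(time, event) ~ risk,
                               reverse = TRUE)
  unname(fit$concordance)
}

#' Median risk split, Kaplan-Meier curves and log-rank test
#'
#' Averaged risk scores are split strictly at their median (ties assigned
#' to the low-risk group); the two groups are compared with Kaplan-Meier
#' product-limit curves and the two-sample log-rank test, and the
#' concordance index of the mean risks against the outcomes is reported.
#'
#' @param risk a [RiskScoreSet-class] (its `"test"` split is used via
#'   `split`), or a numeric risk vector aligned with `outcomes`.
#' @param outcomes data.frame with `time` and `event` aligned to the
#'   risks.
#' @param split when `risk` is a [RiskScoreSet-class]: `"test"`,
#'   `"train"`, or `"all"`.
#' @return List with `groups` (factor low/high), `km` (data.frame time,
#'   n_risk, n_event, survival, group), `logrank` (list: chisq, df, p)
#'   and `concordance`.
#' @export
kmLogrankSplit <- function(risk, outcomes,
                           split = c("test", "train", "all")) {
  split <- match.arg(split)
  if (is(risk, "RiskScoreSet")) {
    sc <- riskScores(risk)
    if (split != "all") sc <- sc[sc$split == split, , drop = FALSE]
    stopIfNot(nrow(sc) == nrow(outcomes),
              "outcomes must align with the selected risk split")
    risk <- sc$risk
  }
  stopIfNot(length(risk) == nrow(outcomes),
            "risk vector and outcomes must align")
  med <- stats::median(risk)
  grp <- factor(ifelse(risk <= med, "low", "high"), levels = c("low", "high"))
  if (length(unique(risk)) < 2 || min(table(grp)) < 2)
    stop("median split impossible: risks identical or a group too small",
         call. = FALSE)
  dat <- data.frame(time = outcomes$time, event = outcomes$event, grp = grp)
  sf <- survival::survfit(survival::Surv(time, event) ~ grp, data = dat)
  sm <- summary(sf)
  km <- data.frame(time = sm$time, n_risk = sm$n.risk, n_event = sm$n.event,
                   survival = sm$surv,
                   group = sub("^grp=", "", as.character(sm$strata)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = dat)
  p <- stats::pchisq(sd$chisq, df = length(sd$n) - 1, lower.tail = FALSE)
  list(groups = grp, km = km,
       logrank = list(chisq = unname(sd$chisq), df = length(sd$n) - 1, p = p),
       concordance = concordanceIndex(risk, outcomes$time, outcomes$event))
}
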