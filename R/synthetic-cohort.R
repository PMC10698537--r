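#' Construct a cohort specification
#'
#' @param nPatients number of patients (>= 2).
#' @param beta log-hazard coefficients, one per covariate column.
#' @param baselineHazard baseline event rate per time unit (> 0).
#' @param censorRate independent exponential censoring rate (0 disables
#'   censoring).
#' @param seed integer RNG seed.
#' @return A [CohortSpec-class] object.
#' @export
cohortSpec <- function(nPatients = 150L, beta = numeric(),
                       baselineHazard = 0.1, censorRate = 0.02, seed = 1L) {
  new("CohortSpec", nPatients = as.integer(nPatients), beta = as.numeric(beta),
      baselineHazard = baselineHazard, censorRate = censorRate,
      seed = as.integer(seed))
}

#' Generate a synthetic survival cohort under proportional hazards
#'
#' Event times are exponential with per-patient rate
#' `baselineHazard * exp(covariates %*% beta)`; censoring times are
#' independent exponential with rate `censorRate` (infinite when the rate
#' is 0). The observed time is the minimum of the two and the event flag is
#' 1 when the event precedes censoring. Exponential times were chosen for
#' closed-form checkability; Weibull times (shape `weibullShape != 1`) are
#' available behind a flag.
#'
#' @param spec a [CohortSpec-class].
#' @param covariates numeric matrix with `nPatients` rows and
#'   `length(beta)` columns.
#' @param weibullShape Weibull shape parameter; 1 (default) gives
#'   exponential times.
#' @return A data.frame with `patient_id`, `time`, `event` and the
#'   covariate columns.
#' @examples
#' X <- matrix(rnorm(300), 150, 2)
#' coh <- generateCohort(cohortSpec(150, beta = c(1, 0), seed = 2), X)
#' head(coh)
#' @export
generateCohort <- function(spec, covariates, weibullShape = 1) {
  validObject(spec)
  covariates <- as.matrix(covariates)
  if (nrow(covariates) != spec@nPatients)
    stop("covariates must have nPatients = ", spec@nPatients, " rows",
         call. = FALSE)
  if (ncol(covariates) != length(spec@beta))
    stop("covariates must have one column per beta coefficient",
         call. = FALSE)
  stopIfNot(weibullShape > 0, "weibullShape must be > 0")
  withSeed(subSeed(spec@seed, 21L), {
    n <- spec@nPatients
    lp <- if (length(spec@beta)) drop(covariates %*% spec@beta) else rep(0, n)
    rate <- spec@baselineHazard * exp(lp)
    u <- stats::runif(n)
    ## inverse-CDF draw; shape 1 reduces to rexp(rate)
    tEvent <- (-log(u) / rate)^(1 / weibullShape)
    tCensor <- if (spec@censorRate > 0)
      stats::rexp(n, rate = spec@censorRate) else rep(Inf, n)
    time <- pmin(tEvent, tCensor)
    event <- as.integer(tEvent <= tCensor)
    out <- data.frame(patient_id = sprintf("pt%04d", seq_len(n)),
                      time = time, event = event)
    if (ncol(covariates)) {
      cn <- colnames(covariates)
      if (is.null(cn)) cn <- paste0("x", seq_len(ncol(covariates)))
      out <- cbind(out, stats::setNames(as.data.frame(covariates), cn))
    }
    out
  })
}

#' Write a cohort table to CSV
#'
#' @param cohort data.frame from [generateCohort()].
#' @param path output CSV path.
#' @return The path, invisibly.
#' @export
writeCohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}
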