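#' Exact Clopper-Pearson binomial confidence interval
#'
#' The exact two-sided interval from beta quantiles:
#' `low = qbeta(alpha/2, s, n - s + 1)` and
#' `high = qbeta(1 - alpha/2, s + 1, n - s)`, with `low = 0` when `s = 0`
#' and `high = 1` when `s = n`.
#'
#' @param successes number of successes (0..trials).
#' @param trials number of trials (>= 1).
#' @param alpha two-sided error rate (default 0.05 for a 95% interval).
#' @return Numeric vector `c(low, high)`.
#' @examples
#' clopperPearson(5, 10)
#' @export
clopperPearson <- function(successes, trials, alpha = 0.05) {
  stopIfNot(isCount(trials, 1), "trials must be a positive integer")
  stopIfNot(isCount(successes, 0) && successes <= trials,
            "successes must be an integer in [0, trials]")
  stopIfNot(isFraction(alpha, 0, 1) && alpha > 0 && alpha < 1,
            "alpha must be in (0, 1)")
  low <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, trials - successes + 1)
  high <- if (successes == trials) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, trials - successes)
  c(low = low, high = high)
}

#' Per-slide pixel classification metrics with exact confidence intervals
#'
#' Compares a predicted binary mask with the ground truth over evaluated
#' pixels (no-data pixels, NA in the prediction, are excluded). Metrics
#' with an empty denominator (e.g. sensitivity when the slide has no truth
#' positives) are reported as NA, never coerced to 0. Clopper-Pearson
#' intervals are attached to each proportion metric (not F1, which is not
#' a binomial proportion).
#'
#' @param pred binary matrix (NA = no-data), e.g. from [binaryMask()].
#' @param truth binary ground-truth matrix of the same shape.
#' @param alpha two-sided error rate for the confidence intervals.
#' @return A list with `counts` (tp, fp, tn, fn), `metrics` (named numeric:
#'   accuracy, specificity, sensitivity, precision, f1) and `ci` (2-row
#'   matrix of interval bounds per metric).
#' @export
slideMetrics <- function(pred, truth, alpha = 0.05) {
  stopIfNot(identical(dim(pred), dim(truth)),
            "pred and truth must have the same shape")
  keep <- !is.na(pred)
  p <- pred[keep]; y <- truth[keep]
  tp <- sum(p == 1 & y == 1); fp <- sum(p == 1 & y == 0)
  tn <- sum(p == 0 & y == 0); fn <- sum(p == 0 & y == 1)
  n <- tp + fp + tn + fn
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  metrics <- c(accuracy = rat(tp + tn, n),
               specificity = rat(tn, tn + fp),
               sensitivity = rat(tp, tp + fn),
               precision = rat(tp, tp + fp))
  ## count form 2tp/(2tp+fp+fn): equals the harmonic mean of precision and
  ## recall when both are defined, and is 0 (not NA) for a slide predicted
  ## entirely wrong -- the representable worst case
  f1 <- rat(2 * tp, 2 * tp + fp + fn)
  metrics <- c(metrics, f1 = unname(f1))
  dens <- c(accuracy = n, specificity = tn + fp, sensitivity = tp + fn,
            precision = tp + fp)
  nums <- c(accuracy = tp + tn, specificity = tn, sensitivity = tp,
            precision = tp)
  ci <- sapply(names(dens), function(m) {
    if (dens[m] > 0) clopperPearson(nums[m], dens[m], alpha) else
      c(low = NA_real_, high = NA_real_)
  })
  ci <- cbind(ci, f1 = c(NA_real_, NA_real_))
  list(counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
       metrics = metrics, ci = ci)
}

#' Pooled ROC curve and AUC across slides
#'
#' All evaluated pixels of all slides are pooled; the ROC curve is traced
#' over the unique predicted probabilities and the AUC computed by
#' trapezoidal integration. Errors if the pooled truth contains a single
#' class (AUC undefined).
#'
#' @param probMaps list of probability matrices (NA pixels excluded) or
#'   [SlideProbabilityMap-class] objects.
#' @param truthMasks list of aligned binary truth matrices.
#' @return A list with `fpr`, `tpr` (ROC points including the (0,0) and
#'   (1,1) endpoints) and `auc`.
#' @export
pooledROC <- function(probMaps, truthMasks) {
  stopIfNot(length(probMaps) == length(truthMasks),
            "need one truth mask per probability map")
  p <- numeric(); y <- numeric()
  for (i in seq_along(probMaps)) {
    pm <- probMaps[[i]]
    if (is(pm, "SlideProbabilityMap")) pm <- probMap(pm)
    stopIfNot(identical(dim(pm), dim(truthMasks[[i]])),
              "probability map and truth shapes differ")
    keep <- !is.na(pm)
    p <- c(p, pm[keep]); y <- c(y, truthMasks[[i]][keep])
  }
  stopIfNot(all(p >= 0 & p <= 1), "probabilities must lie in [0, 1]")
  nPos <- sum(y == 1); nNeg <- sum(y == 0)
  if (nPos == 0 || nNeg == 0)
    stop("pooled truth contains a single class: AUC undefined",
         call. = FALSE)
  ord <- order(p, decreasing = TRUE)
  ys <- y[ord]; ps <- p[ord]
  tps <- cumsum(ys == 1); fps <- cumsum(ys == 0)
  last <- which(diff(ps) != 0)
  idx <- c(last, length(ps))
  tpr <- c(0, tps[idx] / nPos); fpr <- c(0, fps[idx] / nNeg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Render a tumor-probability heatmap with ground-truth overlay
#'
#' Probabilities are mapped on a linear white (low) to red (high) scale;
#' the ground-truth contour is superimposed in green. Optionally the map
#' is binarized at `threshold` first. No-data pixels render white.
#'
#' @param probMap probability matrix or [SlideProbabilityMap-class].
#' @param truthMask binary ground-truth matrix (NULL for no overlay).
#' @param binarize render `prob >= threshold` instead of the raw map.
#' @param threshold threshold used when `binarize = TRUE`.
#' @return RGB array (height x width x 3) in [0, 1].
#' @export
renderHeatmap <- function(probMap, truthMask = NULL, binarize = FALSE,
                          threshold = 0.5) {
  if (is(probMap, "SlideProbabilityMap")) {
    threshold <- probMap@threshold
    probMap <- probMap(probMap)
  }
  p <- probMap
  p[is.na(p)] <- 0
  if (binarize) p <- (p >= threshold) * 1
  img <- array(1, dim = c(nrow(p), ncol(p), 3))
  img[, , 2] <- 1 - p
  img[, , 3] <- 1 - p
  if (!is.null(truthMask)) {
    stopIfNot(identical(dim(p), dim(truthMask)),
              "probability map and truth shapes differ")
    er <- EBImage::imageData(EBImage::erode(
      EBImage::Image(truthMask), EBImage::makeBrush(3, shape = "box")))
    contour <- truthMask == 1 & er == 0
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[contour] <- if (ch == 2) 1 else 0
      img[, , ch] <- plane
    }
  }
  img
}
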