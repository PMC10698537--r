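## Independent oracles used to check the package implementations.
## Each is a direct, brute-force transcription of the defining formula and
## never calls the code path it verifies.

## Clopper-Pearson by inversion of the binomial tail sums: the lower bound
## solves P(X >= s | p) = alpha/2 and the upper bound P(X <= s | p) = alpha/2.
cpOracle <- function(s, n, alpha = 0.05) {
  upperTail <- function(p) sum(stats::dbinom(s:n, n, p))
  lowerTail <- function(p) sum(stats::dbinom(0:s, n, p))
  low <- if (s == 0) 0 else
    stats::uniroot(function(p) upperTail(p) - alpha / 2, c(1e-12, 1 - 1e-12),
                   tol = 1e-12)$root
  high <- if (s == n) 1 else
    stats::uniroot(function(p) lowerTail(p) - alpha / 2, c(1e-12, 1 - 1e-12),
                   tol = 1e-12)$root
  c(low, high)
}

## AUC as the fraction of positive/negative pairs ranked correctly
## (ties count one half).
aucPairsOracle <- function(p, y) {
  pos <- p[y == 1]; neg <- p[y == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

## Harrell's concordance by exhaustive pair comparison: a pair is comparable
## when the shorter observed time ends in an event; the pair is concordant
## when the earlier-failing patient has the higher risk (ties in risk: 1/2).
concordanceOracle <- function(risk, time, event) {
  num <- 0; den <- 0
  n <- length(risk)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      num <- num + (risk[i] > risk[j]) + 0.5 * (risk[i] == risk[j])
    }
  }
  num / den
}

## Two-sample log-rank chi-square from the observed-minus-expected sums
## over distinct event times (hypergeometric variance).
logrankOracle <- function(time, event, group) {
  g1 <- levels(factor(group))[1]
  ts <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    atRisk <- time >= t
    n <- sum(atRisk); n1 <- sum(atRisk & group == g1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

## Product-limit survival estimates at the distinct event times of a group.
kmOracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts)); s <- 1
  for (i in seq_along(ts)) {
    n <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n)
    surv[i] <- s
  }
  data.frame(time = ts, survival = surv)
}

## Otsu threshold by exhaustive search over 256 candidate grey levels,
## maximizing the between-class variance of the split.
otsuOracle <- function(gray) {
  lv <- seq(0, 1, length.out = 256)
  bins <- findInterval(gray, lv, rightmost.closed = TRUE)
  best <- -Inf; bestT <- lv[1]
  for (i in 1:255) {
    thr <- (lv[i] + lv[i + 1]) / 2
    lo <- gray[gray <= thr]; hi <- gray[gray > thr]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(gray); w1 <- 1 - w0
    v <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (v > best) { best <- v; bestT <- thr }
  }
  bestT
}

## Adjusted-free Rand index between two partitions.
randIndex <- function(a, b) {
  n <- length(a)
  cm <- table(a, b)
  sij <- sum(choose(cm, 2))
  si <- sum(choose(rowSums(cm), 2)); sj <- sum(choose(colSums(cm), 2))
  (choose(n, 2) + 2 * sij - si - sj) / choose(n, 2)
}

## Mean silhouette width for a labelled point set (Euclidean).
meanSilhouette <- function(X, labels) {
  d <- as.matrix(stats::dist(X))
  s <- vapply(seq_len(nrow(X)), function(i) {
    own <- labels == labels[i]
    a <- mean(d[i, own & seq_len(nrow(X)) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
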