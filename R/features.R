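#' Concatenation-layer embeddings of tumor patches, per CV model
#'
#' Runs each cross-validation model's embedding hook on the tumor patches
#' of one slide ("tumor" = patches whose annotation mask fraction is at
#' least `tumorMinFraction`, standing in for the pathologist's call).
#' With the canonical backbone each model contributes 2560 features, for
#' `folds * 2560` per patch in total.
#'
#' @param foldModels list of [TrainedFold-class] or [SegModel-class].
#' @param pairs a [PatchPairSet-class] for one slide.
#' @param tumorMinFraction minimum mask fraction for a patch to count as
#'   tumor.
#' @return List of per-model embedding matrices (tumor patches x
#'   embedding dim). If the slide has no tumor patches the matrices have
#'   zero rows and the result carries `attr(, "flagged") = TRUE`.
#' @export
extractPatchEmbeddings <- function(foldModels, pairs,
                                   tumorMinFraction = 0.5) {
  models <- lapply(foldModels, function(m)
    if (is(m, "TrainedFold")) m@model else m)
  fl <- flattenPairs(pairs)
  isTumor <- vapply(fl$mask, function(m) mean(m) >= tumorMinFraction,
                    logical(1))
  sel <- list(focus = fl$focus[isTumor], context = fl$context[isTumor],
              mask = fl$mask[isTumor])
  out <- lapply(models, function(m) segEmbed(m, sel))
  if (!any(isTumor)) attr(out, "flagged") <- TRUE
  out
}

## Squared Euclidean distances between rows of E and rows of C.
sqDist <- function(E, C) {
  outer(rowSums(E^2), rep(1, nrow(C))) - 2 * tcrossprod(E, C) +
    outer(rep(1, nrow(E)), rowSums(C^2))
}

## k-means++ seeding (Arthur & Vassilvitskii) on the current RNG stream.
kmeansPPCenters <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  idx <- sample.int(n, 1)
  centers[1, ] <- X[idx, ]
  if (k > 1) {
    d2 <- sqDist(X, centers[1, , drop = FALSE])[, 1]
    for (j in 2:k) {
      prob <- pmax(d2, 0)
      if (sum(prob) <= 0) prob <- rep(1, n)
      idx <- sample.int(n, 1, prob = prob)
      centers[j, ] <- X[idx, ]
      d2 <- pmin(d2, sqDist(X, centers[j, , drop = FALSE])[, 1])
    }
  }
  centers
}

## Seeded k-means with k-means++ init and multiple restarts (Lloyd).
seededKmeans <- function(X, k, seed, nstart = 10L, iterMax = 100L) {
  best <- NULL
  withSeed(subSeed(seed, 71L), {
    for (s in seq_len(nstart)) {
      cen <- kmeansPPCenters(X, k)
      cen <- cen[!duplicated(cen), , drop = FALSE]
      km <- suppressWarnings(stats::kmeans(X, centers = cen,
                                           iter.max = iterMax,
                                           algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  best
}

#' Elbow scan over candidate codebook sizes
#'
#' Fits one seeded k-means per candidate `k` and reports the inertia
#' (total within-cluster sum of squares); candidates exceeding the sample
#' count are skipped with a warning. Inertia is non-increasing in `k` and
#' zero at `k = n`.
#'
#' @param embeddings numeric matrix (patches x dim).
#' @param kList ascending candidate cluster counts (canonical scan:
#'   5, 10, 50, 100, 200, 500, 1000, 2000, 3000, 5000).
#' @param seed RNG seed.
#' @param nstart k-means restarts per candidate.
#' @return data.frame with columns `k` and `inertia`.
#' @export
elbowScan <- function(embeddings, kList, seed = 1L, nstart = 10L) {
  embeddings <- as.matrix(embeddings)
  stopIfNot(!is.unsorted(kList), "kList must be sorted ascending")
  ok <- kList <= nrow(embeddings)
  if (any(!ok))
    warning("skipping k > number of samples: ",
            paste(kList[!ok], collapse = ", "))
  kList <- kList[ok]
  inertia <- vapply(kList, function(k)
    seededKmeans(embeddings, k, seed = subSeed(seed, k),
                 nstart = nstart)$tot.withinss, numeric(1))
  data.frame(k = kList, inertia = inertia)
}

#' Fit per-model k-means codebooks
#'
#' One codebook per CV model, fitted independently in that model's
#' embedding space on training-slide embeddings pooled across slides
#' (k-means++ seeding, 10 restarts, fixed seed).
#'
#' @param perModelEmbeddings list of matrices (pooled training patches x
#'   dim), one per CV model.
#' @param k number of visual words (canonical 500).
#' @param seed RNG seed.
#' @param nstart restarts per codebook.
#' @return List of [Codebook-class].
#' @export
fitCodebooks <- function(perModelEmbeddings, k = 500L, seed = 1L,
                         nstart = 10L) {
  stopIfNot(isCount(k), "k must be a positive integer")
  lapply(seq_along(perModelEmbeddings), function(i) {
    X <- as.matrix(perModelEmbeddings[[i]])
    if (nrow(X) < k)
      stop("fewer samples (", nrow(X), ") than clusters (", k,
           ") for model ", i, call. = FALSE)
    km <- seededKmeans(X, k, seed = subSeed(seed, 80L + i), nstart = nstart)
    new("Codebook", modelIndex = as.integer(i), centroids = km$centers,
        k = as.integer(k), inertia = km$tot.withinss)
  })
}

#' Assign embeddings to their nearest codebook centroid
#'
#' Ties are broken toward the lowest centroid index.
#'
#' @param embeddings matrix (patches x dim).
#' @param codebook a [Codebook-class].
#' @return Integer vector of 1-based cluster assignments.
#' @export
assignClusters <- function(embeddings, codebook) {
  E <- as.matrix(embeddings)
  if (nrow(E) == 0) return(integer())
  d <- sqDist(E, codebook@centroids)
  max.col(-d, ties.method = "first")
}

## Per-model visual-word count histogram for one slide.
slideCounts <- function(slideEmbPerModel, codebooks) {
  m <- vapply(seq_along(codebooks), function(i) {
    lab <- assignClusters(slideEmbPerModel[[i]], codebooks[[i]])
    tabulate(lab, nbins = codebooks[[i]]@k)
  }, numeric(codebooks[[1]]@k))
  matrix(m, nrow = codebooks[[1]]@k)
}

## Smoothed inverse document frequency: ln((1 + N) / (1 + df)) + 1.
smoothIdf <- function(countsBySlide, nSlides) {
  df <- Reduce(`+`, lapply(countsBySlide, function(cnt) (cnt > 0) * 1))
  log((1 + nSlides) / (1 + df)) + 1
}

#' Fit the slide-level bag-of-visual-words feature model
#'
#' Fits, on training slides only: one k-means codebook per CV model, the
#' smoothed IDF weights of each model's visual-word vocabulary, and the
#' NMF components of the concatenated TF-IDF matrix. Encoding applies
#' TF-IDF per model (raw counts times IDF, L2-normalized per model block)
#' and concatenates the `length(codebooks)` blocks into one
#' `folds * k`-dimensional slide vector (canonical 5 x 500 = 2500), which
#' the NMF reduces to `rank` features (canonical 5).
#'
#' @param trainEmbeddings list over training slides; each element a list
#'   over CV models of embedding matrices (as returned by
#'   [extractPatchEmbeddings()] or [generatePatchEmbeddings()] reshaped).
#' @param k visual words per codebook (canonical 500).
#' @param rank NMF rank (canonical 5).
#' @param seed RNG seed.
#' @param nstart k-means restarts.
#' @return List with `model` (a [BoWFeatureModel-class]), `tfidf`
#'   (training slides x folds*k matrix) and `reduced` (training slides x
#'   rank matrix).
#' @export
fitBoWModel <- function(trainEmbeddings, k = 500L, rank = 5L, seed = 1L,
                        nstart = 10L) {
  nModels <- length(trainEmbeddings[[1]])
  pooled <- lapply(seq_len(nModels), function(i)
    do.call(rbind, lapply(trainEmbeddings, `[[`, i)))
  codebooks <- fitCodebooks(pooled, k = k, seed = seed, nstart = nstart)
  countsBySlide <- lapply(trainEmbeddings, slideCounts, codebooks = codebooks)
  nSlides <- length(trainEmbeddings)
  idf <- lapply(seq_len(nModels), function(i)
    smoothIdf(lapply(countsBySlide, function(m) m[, i]), nSlides))
  tfidf <- t(vapply(countsBySlide, function(cnt)
    tfidfEncode(cnt, idf), numeric(nModels * k)))
  nm <- nmfFit(tfidf, rank = rank, seed = seed)
  model <- new("BoWFeatureModel", codebooks = codebooks, idf = idf,
               nmfComponents = nm$H, k = as.integer(k),
               rank = as.integer(rank), nTrainSlides = as.integer(nSlides),
               seed = as.integer(seed))
  rownames(tfidf) <- names(trainEmbeddings)
  rownames(nm$W) <- names(trainEmbeddings)
  list(model = model, tfidf = tfidf, reduced = nm$W)
}

## TF-IDF encode a k x nModels count matrix into one concatenated vector.
tfidfEncode <- function(cnt, idf) {
  blocks <- lapply(seq_along(idf), function(i) {
    v <- cnt[, i] * idf[[i]]
    nrm <- sqrt(sum(v^2))
    if (nrm > 0) v / nrm else v
  })
  unlist(blocks, use.names = FALSE)
}

#' Encode a slide against a fitted bag-of-visual-words model
#'
#' Assigns each patch embedding to its nearest centroid per model, builds
#' the per-model count histograms, applies the frozen TF-IDF weights and
#' concatenates. The fitted model is never mutated, so held-out slides
#' cannot leak into codebooks, IDF or NMF components. A slide with no
#' tumor patches encodes to the zero vector with `attr(, "flagged")`.
#'
#' @param slideEmbPerModel list over CV models of embedding matrices for
#'   one slide.
#' @param model a fitted [BoWFeatureModel-class].
#' @return Named list with `tfidf` (length folds*k) and `reduced`
#'   (length rank, non-negative).
#' @export
encodeSlide <- function(slideEmbPerModel, model) {
  empty <- all(vapply(slideEmbPerModel, nrow, integer(1)) == 0)
  if (empty) {
    v <- numeric(length(model@codebooks) * model@k)
    red <- numeric(model@rank)
    out <- list(tfidf = v, reduced = red)
    attr(out, "flagged") <- TRUE
    return(out)
  }
  cnt <- slideCounts(slideEmbPerModel, model@codebooks)
  v <- tfidfEncode(cnt, model@idf)
  red <- drop(nmfTransform(matrix(v, 1), model@nmfComponents))
  list(tfidf = v, reduced = red)
}

#' Reduce a TF-IDF matrix to the low-rank slide representation
#'
#' With `model = NULL` fits a fresh NMF (training use); with a fitted
#' [BoWFeatureModel-class] projects onto its frozen components
#' (held-out use).
#'
#' @param tfidf non-negative matrix (slides x folds*k).
#' @param rank NMF rank (ignored when `model` is given).
#' @param model optional fitted [BoWFeatureModel-class].
#' @param seed RNG seed for a fresh fit.
#' @return Matrix (slides x rank), non-negative.
#' @export
reduceFeatures <- function(tfidf, rank = 5L, model = NULL, seed = 1L) {
  if (!is.null(model)) return(nmfTransform(tfidf, model@nmfComponents))
  nmfFit(tfidf, rank = rank, seed = seed)$W
}
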