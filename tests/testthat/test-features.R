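test_that("per-patch feature count is models x embedding width", {
  ## three tiny trained-shape models, embedding 64 -> 192 features per patch
  cfg <- segModelConfig("tiny_cnn", patchPx = 8L, convFilters = 4L,
                        perPathwayEmbedDim = 32L, seed = 3L)
  models <- lapply(1:3, function(i) buildSegModel(cfg))
  sl <- generateSlide(slideGenParams(widthPx = 32, heightPx = 32,
                                     tumorFraction = 0.5,
                                     backgroundFraction = 0, seed = 2))
  pp <- extractPatchPairs(sl, patchGridConfig(patchPx = 8L,
                                              backgroundMaxFraction = 1))
  emb <- extractPatchEmbeddings(models, pp, tumorMinFraction = 0.5)
  expect_length(emb, 3L)
  expect_identical(unique(vapply(emb, ncol, integer(1))), 64L)
  expect_identical(sum(vapply(emb, ncol, integer(1))), 192L)
  ## only tumor-majority patches contribute
  nTumor <- sum(vapply(pp@maskPatch, function(m) mean(m) >= 0.5, logical(1)))
  expect_identical(unique(vapply(emb, nrow, integer(1))), nTumor)

  ## a slide with no tumor patches is flagged with empty matrices
  emb0 <- extractPatchEmbeddings(models, pp, tumorMinFraction = 1.01)
  expect_true(isTRUE(attr(emb0, "flagged")))
  expect_identical(unique(vapply(emb0, nrow, integer(1))), 0L)
})

test_that("elbow scan inertia is monotone and flags the true cluster count", {
  g <- generatePatchEmbeddings(1, 200, 8, 3, clusterSeparation = 12, seed = 9)
  X <- g$embeddings[[1]]
  tab <- elbowScan(X, c(2, 3, 4, 5, 6), seed = 3)
  expect_true(all(diff(tab$inertia) <= 1e-8))
  drops <- -diff(tab$inertia) / utils::head(tab$inertia, -1)
  expect_identical(tab$k[-1][which.max(drops)], 3)

  small <- X[1:10, ]
  full <- elbowScan(small, c(2, 10), seed = 1)
  expect_equal(full$inertia[full$k == 10], 0)
  expect_warning(elbowScan(small, c(2, 50), seed = 1), "skipping")
})

test_that("codebooks are deterministic and recover planted clusters", {
  g <- generatePatchEmbeddings(6, 50, 10, 4, clusterSeparation = 10, seed = 4)
  pooled <- do.call(rbind, g$embeddings)
  cb <- fitCodebooks(list(pooled), k = 4L, seed = 6)[[1]]
  expect_identical(cb@k, 4L)
  lab <- assignClusters(pooled, cb)
  expect_gt(randIndex(lab, unlist(g$labels)), 0.99)
  cb2 <- fitCodebooks(list(pooled), k = 4L, seed = 6)[[1]]
  expect_identical(centroids(cb), centroids(cb2))

  ## k = 1 on duplicated points: centroid is the point, inertia 0
  dup <- matrix(rep(c(1, 2, 3), each = 5), 5, 3)
  cb1 <- fitCodebooks(list(dup), k = 1L, seed = 1)[[1]]
  expect_equal(unname(centroids(cb1)[1, ]), c(1, 2, 3))
  expect_equal(cb1@inertia, 0)
  expect_error(fitCodebooks(list(dup), k = 10L), "fewer samples")
})

test_that("nearest-centroid ties break toward the lowest centroid index", {
  cb <- new("Codebook", modelIndex = 1L,
            centroids = rbind(c(0, 1), c(0, -1)), k = 2L, inertia = 0)
  ## the origin is equidistant from both centroids
  expect_identical(assignClusters(matrix(0, 1, 2), cb), 1L)
})

test_that("TF-IDF encoding matches hand arithmetic on a two-slide corpus", {
  ## one model, k = 3; hand-assigned clusters via unit-distance centroids
  cb <- new("Codebook", modelIndex = 1L,
            centroids = rbind(c(0, 0), c(10, 0), c(0, 10)), k = 3L,
            inertia = 0)
  ## slide A: 3 patches in word 1, 1 in word 2; slide B: 2 in word 2
  embA <- rbind(c(0, 0), c(0.1, 0), c(0, 0.1), c(10, 0))
  embB <- rbind(c(10, 0.1), c(9.9, 0))
  cntA <- c(3, 1, 0); cntB <- c(0, 2, 0)
  df <- c(1, 2, 0)
  idf <- log((1 + 2) / (1 + df)) + 1          # smooth IDF, N = 2 documents
  vA <- cntA * idf; vA <- vA / sqrt(sum(vA^2))  # L2 row normalization
  vB <- cntB * idf; vB <- vB / sqrt(sum(vB^2))
  model <- new("BoWFeatureModel", codebooks = list(cb), idf = list(idf),
               nmfComponents = matrix(1, 1, 3), k = 3L, rank = 1L,
               nTrainSlides = 2L, seed = 1L)
  expect_equal(encodeSlide(list(embA), model)$tfidf, vA, tolerance = 1e-9)
  expect_equal(encodeSlide(list(embB), model)$tfidf, vB, tolerance = 1e-9)
})

test_that("visual-word histograms conserve the patch count", {
  corpus <- makeEmbeddingCorpus(nSlides = 6, patchesPerSlide = 40,
                                nModels = 3)
  fitb <- fitBoWModel(corpus, k = 4L, rank = 2L, seed = 2)
  for (s in seq_along(corpus)) {
    cnt <- SlideSurv:::slideCounts(corpus[[s]], fitb$model@codebooks)
    expect_identical(unname(colSums(cnt)), rep(40, 3))
  }
  ## a slide mapping to a single word has exactly nModels nonzero counts
  onePoint <- lapply(fitb$model@codebooks, function(cb)
    matrix(rep(centroids(cb)[2, ], 5), 5, byrow = TRUE))
  cnt1 <- SlideSurv:::slideCounts(onePoint, fitb$model@codebooks)
  expect_identical(sum(cnt1 > 0), 3L)
})

test_that("the feature cascade has the published dimension arithmetic", {
  corpus <- makeEmbeddingCorpus(nSlides = 8, patchesPerSlide = 30,
                                nModels = 5)
  fitb <- fitBoWModel(corpus, k = 6L, rank = 5L, seed = 3)
  expect_identical(dim(fitb$tfidf), c(8L, 30L))          # folds x k
  expect_identical(dim(fitb$reduced), c(8L, 5L))
  expect_true(all(fitb$tfidf >= 0))
  expect_true(all(fitb$reduced >= 0))
  enc <- encodeSlide(corpus[[3]], fitb$model)
  expect_length(enc$tfidf, 30L)
  expect_length(enc$reduced, 5L)
})

test_that("encoding held-out slides never mutates the fitted model", {
  corpus <- makeEmbeddingCorpus(nSlides = 6, patchesPerSlide = 30,
                                nModels = 2)
  fitb <- fitBoWModel(corpus[1:4], k = 4L, rank = 2L, seed = 2)
  snapshot <- list(cent = lapply(fitb$model@codebooks, centroids),
                   idf = fitb$model@idf, H = fitb$model@nmfComponents)
  enc <- encodeSlide(corpus[[5]], fitb$model)
  expect_identical(lapply(fitb$model@codebooks, centroids), snapshot$cent)
  expect_identical(fitb$model@idf, snapshot$idf)
  expect_identical(fitb$model@nmfComponents, snapshot$H)
  ## empty slide: zero vector plus flag
  emptyEmb <- lapply(1:2, function(i) matrix(0, 0, 16))
  enc0 <- encodeSlide(emptyEmb, fitb$model)
  expect_true(isTRUE(attr(enc0, "flagged")))
  expect_identical(enc0$tfidf, numeric(8))
})

test_that("NMF factorizes exactly at the true rank and improves with rank", {
  set.seed(5)
  ## rank-1 non-negative input factorizes to numerical zero
  X1 <- outer(stats::runif(12), stats::runif(9))
  expect_lt(nmfFit(X1, 1)$loss, 1e-6)

  W0 <- matrix(stats::runif(15 * 3), 15, 3)
  H0 <- matrix(stats::runif(3 * 12), 3, 12)
  X <- W0 %*% H0 + matrix(stats::runif(15 * 12, 0, 0.05), 15, 12)
  losses <- vapply(c(1, 2, 5, 10), function(r) nmfFit(X, r, seed = 1)$loss,
                   numeric(1))
  expect_true(all(diff(losses) <= 1e-8))
  expect_error(nmfFit(X - 1, 2), "non-negative")

  ## transform against frozen components approximates the training W
  fit <- nmfFit(X, 3, seed = 1)
  Wt <- nmfTransform(X, fit$H)
  expect_lt(sqrt(sum((X - Wt %*% fit$H)^2)), fit$loss * 1.05 + 1e-9)
})

test_that("slides with distinct mixture weights separate in reduced space", {
  ## two latent clusters with strongly slide-specific weights
  corpus <- makeEmbeddingCorpus(nSlides = 14, patchesPerSlide = 80,
                                dim = 12, nClusters = 2, separation = 10,
                                nModels = 3, seedBase = 21L)
  gens <- attr(corpus, "generators")
  grp <- gens[[1]]$weights[, 1] > 0.5
  keep <- abs(gens[[1]]$weights[, 1] - 0.5) > 0.15   # strong separation
  fitb <- fitBoWModel(corpus, k = 2L, rank = 2L, seed = 4)
  sil <- meanSilhouette(fitb$reduced[keep, ], grp[keep])
  expect_gt(sil, 0.3)
})
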