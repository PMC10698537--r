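test_that("embedding hook width is twice the per-pathway dimension", {
  canonical <- buildSegModel(segModelConfig("canonical", patchPx = 16L))
  expect_identical(embeddingDim(canonical), 2560L)

  tiny <- buildSegModel(segModelConfig("tiny_cnn", patchPx = 8L,
                                       perPathwayEmbedDim = 32L))
  expect_identical(embeddingDim(tiny), 64L)

  ## probability map stays in [0, 1] for random input
  pair <- list(focus = array(stats::runif(8 * 8 * 3), c(8, 8, 3)),
               context = array(stats::runif(8 * 8 * 3), c(8, 8, 3)),
               mask = matrix(0, 8, 8))
  E <- segEmbed(tiny, list(focus = list(pair$focus),
                           context = list(pair$context),
                           mask = list(pair$mask)))
  expect_identical(dim(E), c(1L, 64L))
  fw <- SlideSurv:::segForward(tiny@weights,
                               SlideSurv:::im2col3(pair$focus, 8L),
                               SlideSurv:::im2col3(pair$context, 8L), 1L, 64L)
  expect_true(all(fw$p >= 0 & fw$p <= 1))
})

test_that("augmentation is deterministic, geometry-consistent and binary-safe", {
  set.seed(3)
  mask <- matrix(0, 8, 8); mask[2, 3] <- 1
  focus <- array(0.2, c(8, 8, 3)); focus[2, 3, ] <- 1  # marker at mask pixel
  pair <- list(focus = focus, context = focus, mask = mask)
  for (sd in c(1L, 5L, 9L, 13L)) {
    aug <- augmentPair(pair, seed = sd)
    expect_true(all(aug$mask %in% c(0, 1)))
    expect_identical(sum(aug$mask), sum(mask))  # flips/rot90 preserve counts
    ## focus and mask undergo the same geometric transform:
    ## the brightest focus pixel sits where the mask's 1 moved
    lum <- (aug$focus[, , 1] + aug$focus[, , 2] + aug$focus[, , 3]) / 3
    expect_identical(which(aug$mask == 1), which.max(lum))
    expect_identical(aug, augmentPair(pair, seed = sd))
  }
})

test_that("class weights follow inverse frequency, normalized to mean 1", {
  Y <- c(rep(0, 80), rep(1, 20))
  cw <- SlideSurv:::segClassWeights(Y, "inverse_frequency")
  expect_equal(cw[2] / cw[1], 4)          # 80% non-tumor -> tumor weight 4x
  expect_equal(80 * cw[1] + 20 * cw[2], 100)  # weighted mean 1
  expect_identical(SlideSurv:::segClassWeights(Y, "fixed"), c(1, 1))
  expect_error(SlideSurv:::segClassWeights(rep(0, 10), "inverse_frequency"),
               "single class")
})

test_that("cross-validation splits slides, not patches, and partitions them", {
  slides <- makeSlideSet(10, widthPx = 48, heightPx = 48)
  pairs <- lapply(slides, extractPatchPairs,
                  config = patchGridConfig(patchPx = 16L))
  cfg <- segModelConfig("tiny_cnn", patchPx = 16L, convFilters = 4L,
                        perPathwayEmbedDim = 8L, learningRate = 0.01,
                        transferEpochs = 1L, finetuneEpochs = 1L, folds = 5L,
                        seed = 2L)
  folds <- trainSegCV(pairs, cfg)
  expect_length(folds, 5L)
  allVal <- unlist(lapply(folds, function(f) f@valSlides))
  expect_setequal(allVal, names(slides))
  expect_identical(anyDuplicated(allVal), 0L)
  for (f in folds) {
    expect_length(intersect(f@trainSlides, f@valSlides), 0L)
    expect_setequal(c(f@trainSlides, f@valSlides), names(slides))
    expect_true(isTrained(f@model))
  }
  expect_error(trainSegCV(pairs[1:3], cfg), "at least as many slides")
})

test_that("training is reproducible under a fixed seed", {
  slides <- makeSlideSet(5, widthPx = 48, heightPx = 48)
  pairs <- lapply(slides, extractPatchPairs,
                  config = patchGridConfig(patchPx = 16L))
  cfg <- segModelConfig("tiny_cnn", patchPx = 16L, convFilters = 4L,
                        perPathwayEmbedDim = 8L, learningRate = 0.01,
                        transferEpochs = 1L, finetuneEpochs = 2L, folds = 5L,
                        seed = 7L)
  a <- trainSegCV(pairs, cfg)
  b <- trainSegCV(pairs, cfg)
  expect_identical(a[[1]]@history, b[[1]]@history)
  expect_identical(a[[1]]@model@weights, b[[1]]@model@weights)
})

test_that("a fold without tumor pixels fails with an explicit message", {
  slides <- makeSlideSet(5, widthPx = 48, heightPx = 48, tumorFraction = 0)
  pairs <- lapply(slides, extractPatchPairs,
                  config = patchGridConfig(patchPx = 16L))
  cfg <- segModelConfig("tiny_cnn", patchPx = 16L, convFilters = 4L,
                        perPathwayEmbedDim = 8L, transferEpochs = 1L,
                        finetuneEpochs = 1L, folds = 5L, seed = 2L)
  expect_error(trainSegCV(pairs, cfg), "single class")
})

test_that("prediction applies the threshold with ties called tumor", {
  sl <- generateSlide(slideGenParams(widthPx = 32, heightPx = 32,
                                     backgroundFraction = 0, seed = 5))
  m7 <- constantProbModel(0.7)
  pm <- predictSlide(m7, sl)
  bm <- binaryMask(pm)
  expect_true(all(bm[!is.na(bm)] == 1))
  expect_equal(unique(probMap(pm)[!is.na(probMap(pm))]), 0.7,
               tolerance = 1e-12)

  ## p exactly at the threshold classifies as tumor (>= convention)
  m5 <- constantProbModel(0.5)
  bm5 <- binaryMask(predictSlide(m5, sl))
  expect_true(all(bm5[!is.na(bm5)] == 1))

  expect_error(predictSlide(buildSegModel(segModelConfig(patchPx = 8L)), sl),
               "not been trained")
})

test_that("probability stitching round-trips patch values exactly", {
  sl <- generateSlide(slideGenParams(widthPx = 64, heightPx = 64,
                                     backgroundFraction = 0, seed = 8))
  pp <- extractPatchPairs(sl, patchGridConfig(patchPx = 16L,
                                              backgroundMaxFraction = 1))
  set.seed(4)
  probs <- lapply(seq_len(nPairs(pp)), function(i)
    matrix(stats::runif(256), 16, 16))
  pm <- stitchProbabilities(pp, probs)
  man <- manifest(pp)
  for (r in which(man$kept)) {
    y <- man$y0[r] + 1:16; x <- man$x0[r] + 1:16
    expect_identical(probMap(pm)[y, x], probs[[man$pair[r]]])
  }
})
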