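## Fixture builders shared across test files. Everything is generated in
## code under fixed seeds; nothing is read from disk.

## A small cohort of synthetic slides for segmentation experiments.
makeSlideSet <- function(n = 20, widthPx = 96, heightPx = 96,
                         tumorFraction = 0.35, textureContrast = 0.7,
                         backgroundFraction = 0.15, seedBase = 100L) {
  slides <- lapply(seq_len(n), function(i)
    generateSlide(slideGenParams(widthPx = widthPx, heightPx = heightPx,
                                 tumorFraction = tumorFraction,
                                 nTumorBlobs = 3L,
                                 textureContrast = textureContrast,
                                 backgroundFraction = backgroundFraction,
                                 seed = seedBase + i)))
  names(slides) <- sprintf("s%02d", seq_len(n))
  slides
}

## Per-slide, per-model embedding corpus with shared latent structure.
makeEmbeddingCorpus <- function(nSlides = 12, patchesPerSlide = 60,
                                dim = 16, nClusters = 4, separation = 10,
                                nModels = 5, seedBase = 5L) {
  gens <- lapply(seq_len(nModels), function(m)
    generatePatchEmbeddings(nSlides, patchesPerSlide, dim, nClusters,
                            separation, seed = seedBase + m))
  out <- lapply(seq_len(nSlides), function(s)
    lapply(gens, function(g) g$embeddings[[s]]))
  names(out) <- sprintf("slide%03d", seq_len(nSlides))
  attr(out, "generators") <- gens
  out
}

## A trained tiny model on a handful of slides (cached per test run).
trainTinyFolds <- local({
  cache <- NULL
  function(slides, folds = 5L, epochs = c(2L, 18L), seed = 11L) {
    if (!is.null(cache)) return(cache)
    grid <- patchGridConfig(patchPx = 16L)
    pairs <- lapply(slides, extractPatchPairs, config = grid)
    cfg <- segModelConfig("tiny_cnn", patchPx = 16L, learningRate = 0.01,
                          transferEpochs = epochs[1],
                          finetuneEpochs = epochs[2],
                          earlyStoppingPatience = 20L, folds = folds,
                          seed = seed)
    cache <<- list(folds = trainSegCV(pairs, cfg), pairs = pairs,
                   grid = grid, cfg = cfg)
    cache
  }
})

## A constant-probability model: all weights zero except the decoder bias.
constantProbModel <- function(p, patchPx = 8L) {
  cfg <- segModelConfig("tiny_cnn", patchPx = patchPx, convFilters = 2L,
                        perPathwayEmbedDim = 2L)
  m <- buildSegModel(cfg)
  W <- lapply(m@weights, function(x) x * 0)
  W$bd <- rep(log(p / (1 - p)), patchPx^2)
  m@weights <- W
  m@trained <- TRUE
  m
}
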