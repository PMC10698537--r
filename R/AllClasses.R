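#' @import methods
NULL

## ---------------------------------------------------------------------------
## Synthetic data
## ---------------------------------------------------------------------------

#' Parameters for the synthetic slide generator
#'
#' Describes one synthetic haematoxylin-eosin-like slide: its pixel
#' dimensions, the fraction of the slide covered by tumor tissue, the number
#' of tumor blobs ("nests"), the texture contrast between tumor and
#' non-tumor tissue, the fraction of near-white glass background, and the
#' RNG seed that makes the slide reproducible.
#'
#' @slot widthPx,heightPx slide dimensions in pixels.
#' @slot tumorFraction target fraction of slide pixels that are tumor.
#' @slot nTumorBlobs number of tumor nests seeded into the slide.
#' @slot textureContrast contrast between tumor and non-tumor texture in
#'   [0, 1]; higher values make the segmentation task easier.
#' @slot backgroundFraction fraction of near-white background pixels.
#' @slot seed integer RNG seed; the same seed yields a bit-identical slide.
#' @exportClass SlideGenParams
setClass("SlideGenParams",
  representation(widthPx = "integer", heightPx = "integer",
                 tumorFraction = "numeric", nTumorBlobs = "integer",
                 textureContrast = "numeric", backgroundFraction = "numeric",
                 seed = "integer"),
  prototype(widthPx = 96L, heightPx = 96L, tumorFraction = 0.35,
            nTumorBlobs = 3L, textureContrast = 0.7,
            backgroundFraction = 0.15, seed = 1L))

setValidity("SlideGenParams", function(object) {
  msg <- character()
  if (!isCount(object@widthPx, 8) || !isCount(object@heightPx, 8))
    msg <- c(msg, "widthPx and heightPx must be integers >= 8")
  if (!isFraction(object@tumorFraction))
    msg <- c(msg, "tumorFraction must be in [0, 1]")
  if (!isFraction(object@backgroundFraction))
    msg <- c(msg, "backgroundFraction must be in [0, 1]")
  if (object@tumorFraction + object@backgroundFraction > 1)
    msg <- c(msg, "tumorFraction + backgroundFraction must be <= 1")
  if (!isFraction(object@textureContrast))
    msg <- c(msg, "textureContrast must be in [0, 1]")
  if (!isCount(object@nTumorBlobs, 0))
    msg <- c(msg, "nTumorBlobs must be a non-negative integer")
  if (length(msg)) msg else TRUE
})

#' A synthetic slide with ground-truth tumor mask
#'
#' @slot image 8-bit RGB array (height x width x 3, values in [0, 1]
#'   quantized to 256 levels).
#' @slot tumorMask binary matrix (same frame); 1 = tumor.
#' @slot params the [SlideGenParams] that generated the slide.
#' @exportClass SyntheticSlide
setClass("SyntheticSlide",
  representation(image = "array", tumorMask = "matrix",
                 params = "SlideGenParams"))

setValidity("SyntheticSlide", function(object) {
  d <- dim(object@image)
  if (length(d) != 3L || d[3] != 3L)
    return("image must be a height x width x 3 RGB array")
  if (!identical(dim(object@tumorMask), d[1:2]))
    return("tumorMask must match the image frame")
  if (!all(object@tumorMask %in% c(0, 1)))
    return("tumorMask must be strictly binary {0, 1}")
  TRUE
})

#' Specification of a synthetic survival cohort
#'
#' Event times are exponential with rate
#' `baselineHazard * exp(X %*% beta)` (a proportional-hazards model);
#' censoring times are independent exponential with rate `censorRate`.
#'
#' @slot nPatients number of patients (>= 2).
#' @slot beta log-hazard coefficient per covariate column.
#' @slot baselineHazard baseline event rate per time unit (> 0).
#' @slot censorRate censoring rate per time unit (0 = no censoring).
#' @slot seed integer RNG seed.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(nPatients = "integer", beta = "numeric",
                 baselineHazard = "numeric", censorRate = "numeric",
                 seed = "integer"),
  prototype(nPatients = 150L, beta = numeric(), baselineHazard = 0.1,
            censorRate = 0.02, seed = 1L))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (!isCount(object@nPatients, 2)) msg <- c(msg, "nPatients must be >= 2")
  if (!(object@baselineHazard > 0)) msg <- c(msg, "baselineHazard must be > 0")
  if (object@censorRate < 0) msg <- c(msg, "censorRate must be >= 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Preprocessing
## ---------------------------------------------------------------------------

#' Patch-grid configuration for dual-resolution tiling
#'
#' Slides are tiled on a non-overlapping grid at the focus magnification
#' (canonically 20x); each kept tile is paired with a context patch
#' (canonically 5x) centered on the same point. With `contextMode = "wide"`
#' the context patch covers a `focusMag / contextMag`-times wider field,
#' resampled to `patchPx`; with `"same"` it covers the identical field.
#' Tiles whose Otsu-background fraction is `>= backgroundMaxFraction`
#' (canonically 0.5) are discarded.
#'
#' @slot patchPx patch side length in pixels at focus magnification.
#' @slot focusMag,contextMag magnification factors, focusMag > contextMag.
#' @slot backgroundMaxFraction maximum tolerated background fraction.
#' @slot stridePx grid stride in pixels (defaults to patchPx).
#' @slot contextMode `"wide"` (default) or `"same"`.
#' @exportClass PatchGridConfig
setClass("PatchGridConfig",
  representation(patchPx = "integer", focusMag = "numeric",
                 contextMag = "numeric", backgroundMaxFraction = "numeric",
                 stridePx = "integer", contextMode = "character"),
  prototype(patchPx = 256L, focusMag = 20, contextMag = 5,
            backgroundMaxFraction = 0.5, stridePx = 256L,
            contextMode = "wide"))

setValidity("PatchGridConfig", function(object) {
  msg <- character()
  if (!isCount(object@patchPx, 2)) msg <- c(msg, "patchPx must be >= 2")
  if (!(object@focusMag > object@contextMag && object@contextMag > 0))
    msg <- c(msg, "need focusMag > contextMag > 0")
  if (!(object@backgroundMaxFraction > 0 && object@backgroundMaxFraction <= 1))
    msg <- c(msg, "backgroundMaxFraction must be in (0, 1]")
  if (!isCount(object@stridePx, 1)) msg <- c(msg, "stridePx must be >= 1")
  if (!object@contextMode %in% c("wide", "same"))
    msg <- c(msg, "contextMode must be 'wide' or 'same'")
  if (length(msg)) msg else TRUE
})

#' A set of co-centered focus/context patch pairs from one slide
#'
#' @slot focus,context,maskPatch lists of arrays, one element per kept pair.
#' @slot manifest data.frame with one row per grid tile (kept or not):
#'   slide_id, row, col, x0, y0 (0-based pixel origin), background_fraction,
#'   kept, pair (index into the patch lists, NA if dropped).
#' @slot config the [PatchGridConfig] used.
#' @slot slideDim height and width of the source slide in pixels.
#' @exportClass PatchPairSet
setClass("PatchPairSet",
  representation(focus = "list", context = "list", maskPatch = "list",
                 manifest = "data.frame", config = "PatchGridConfig",
                 slideDim = "integer"))

setValidity("PatchPairSet", function(object) {
  if (length(object@focus) != length(object@context) ||
      length(object@focus) != length(object@maskPatch))
    return("focus, context and maskPatch must have equal length")
  if (sum(object@manifest$kept) != length(object@focus))
    return("manifest kept count must equal number of stored pairs")
  TRUE
})

## ---------------------------------------------------------------------------
## Segmentation model
## ---------------------------------------------------------------------------

#' Configuration of the dual-pathway segmentation network
#'
#' Two convolutional encoder pathways (focus and context) produce pooled
#' embeddings of `perPathwayEmbedDim` each; their concatenation feeds the
#' decoder head emitting a per-pixel tumor probability map at focus-patch
#' resolution. The canonical backbone reproduces the published embedding
#' width (1280 per pathway, 2560 concatenated); `tiny_cnn` is a scaled-down
#' backbone for desk-scale experiments.
#'
#' @slot backbone `"tiny_cnn"` or `"canonical"`.
#' @slot patchPx input patch side length in pixels.
#' @slot convFilters number of 3x3 convolution filters per pathway.
#' @slot perPathwayEmbedDim pooled embedding width per pathway.
#' @slot learningRate Adam learning rate (canonical 1e-4).
#' @slot lrDecay per-epoch exponential decay factor for the learning rate.
#' @slot transferEpochs epochs with frozen encoders (canonical 11).
#' @slot finetuneEpochs epochs with all weights trained (canonical 120).
#' @slot earlyStoppingPatience epochs without validation improvement before
#'   stopping.
#' @slot classWeightMode `"inverse_frequency"` or `"fixed"` (equal weights).
#' @slot probThreshold probability threshold for the binary mask
#'   (canonical 0.5; ties classified tumor).
#' @slot folds number of cross-validation folds (canonical 5).
#' @slot batchSize minibatch size.
#' @slot seed integer RNG seed for weight init and minibatch order.
#' @exportClass SegModelConfig
setClass("SegModelConfig",
  representation(backbone = "character", patchPx = "integer",
                 convFilters = "integer", perPathwayEmbedDim = "integer",
                 learningRate = "numeric", lrDecay = "numeric",
                 transferEpochs = "integer", finetuneEpochs = "integer",
                 earlyStoppingPatience = "integer",
                 classWeightMode = "character", probThreshold = "numeric",
                 folds = "integer", batchSize = "integer", seed = "integer"),
  prototype(backbone = "tiny_cnn", patchPx = 16L, convFilters = 8L,
            perPathwayEmbedDim = 32L, learningRate = 1e-4, lrDecay = 0.95,
            transferEpochs = 11L, finetuneEpochs = 120L,
            earlyStoppingPatience = 10L,
            classWeightMode = "inverse_frequency", probThreshold = 0.5,
            folds = 5L, batchSize = 64L, seed = 1L))

setValidity("SegModelConfig", function(object) {
  msg <- character()
  if (!object@backbone %in% c("tiny_cnn", "canonical"))
    msg <- c(msg, "backbone must be 'tiny_cnn' or 'canonical'")
  if (!(object@probThreshold > 0 && object@probThreshold < 1))
    msg <- c(msg, "probThreshold must be in (0, 1)")
  if (!isCount(object@folds, 2)) msg <- c(msg, "folds must be >= 2")
  if (!isCount(object@perPathwayEmbedDim, 1) || !isCount(object@convFilters, 1))
    msg <- c(msg, "embedding and filter dims must be positive")
  if (!object@classWeightMode %in% c("inverse_frequency", "fixed"))
    msg <- c(msg, "classWeightMode must be 'inverse_frequency' or 'fixed'")
  if (length(msg)) msg else TRUE
})

#' A dual-pathway segmentation model (weights + configuration)
#'
#' @slot config the [SegModelConfig].
#' @slot weights named list of weight arrays (empty until built).
#' @slot trained logical; set by [trainSegCV()].
#' @slot classWeights numeric length-2 vector (non-tumor, tumor) used in the
#'   weighted cross-entropy loss.
#' @exportClass SegModel
setClass("SegModel",
  representation(config = "SegModelConfig", weights = "list",
                 trained = "logical", classWeights = "numeric"),
  prototype(trained = FALSE, classWeights = c(1, 1)))

#' One trained cross-validation fold
#'
#' @slot foldIndex 1-based fold number.
#' @slot model the trained [SegModel].
#' @slot trainSlides,valSlides slide identifiers (disjoint).
#' @slot history data.frame of per-epoch training/validation loss.
#' @exportClass TrainedFold
setClass("TrainedFold",
  representation(foldIndex = "integer", model = "SegModel",
                 trainSlides = "character", valSlides = "character",
                 history = "data.frame"))

setValidity("TrainedFold", function(object) {
  if (length(intersect(object@trainSlides, object@valSlides)))
    return("training and validation slides must be disjoint")
  TRUE
})

#' Per-pixel tumor probabilities stitched back to the slide frame
#'
#' @slot probs matrix of probabilities in the slide frame; NA marks
#'   no-data pixels (background-filtered or dropped tiles).
#' @slot threshold probability threshold used by [binaryMask()].
#' @exportClass SlideProbabilityMap
setClass("SlideProbabilityMap",
  representation(probs = "matrix", threshold = "numeric"),
  prototype(threshold = 0.5))

## ---------------------------------------------------------------------------
## Feature aggregation
## ---------------------------------------------------------------------------

#' A k-means codebook over one CV model's embedding space
#'
#' @slot modelIndex 1-based index of the CV model the codebook belongs to.
#' @slot centroids k x dim matrix of cluster centers.
#' @slot k number of visual words.
#' @slot inertia sum of squared distances to assigned centroids.
#' @exportClass Codebook
setClass("Codebook",
  representation(modelIndex = "integer", centroids = "matrix",
                 k = "integer", inertia = "numeric"))

setValidity("Codebook", function(object) {
  if (object@k < 1L) return("k must be >= 1")
  if (nrow(object@centroids) != object@k)
    return("centroids must have k rows")
  TRUE
})

#' Fitted slide-level bag-of-visual-words feature model
#'
#' Holds, per CV model, the k-means codebook and the smoothed IDF weights
#' fitted on the training corpus, plus the frozen NMF component matrix used
#' to transform TF-IDF vectors to the reduced representation. Encoding a
#' held-out slide never mutates any of these.
#'
#' @slot codebooks list of [Codebook], one per CV model.
#' @slot idf list of numeric IDF vectors (length k), one per CV model.
#' @slot nmfComponents rank x (nModels * k) non-negative component matrix.
#' @slot k visual words per codebook.
#' @slot rank NMF rank (canonical 5).
#' @slot nTrainSlides number of corpus documents behind the IDF.
#' @slot seed RNG seed used for fitting.
#' @exportClass BoWFeatureModel
setClass("BoWFeatureModel",
  representation(codebooks = "list", idf = "list", nmfComponents = "matrix",
                 k = "integer", rank = "integer", nTrainSlides = "integer",
                 seed = "integer"))

## ---------------------------------------------------------------------------
## Survival
## ---------------------------------------------------------------------------

#' Bootstrap-averaged risk scores and per-round concordance
#'
#' @slot scores data.frame: patient_id, split ("train"/"test"), risk
#'   (mean over bootstrap rounds), n_rounds (rounds contributing; for
#'   training patients only out-of-bag rounds contribute).
#' @slot valConcordance per-round out-of-bag concordance indices.
#' @slot testConcordance per-round held-out test concordance indices.
#' @slot importance rounds x features matrix of normalized impurity
#'   importances (rows sum to 1).
#' @slot bestParams hyperparameters selected by the search.
#' @slot nRounds number of bootstrap rounds.
#' @exportClass RiskScoreSet
setClass("RiskScoreSet",
  representation(scores = "data.frame", valConcordance = "numeric",
                 testConcordance = "numeric", importance = "matrix",
                 bestParams = "list", nRounds = "integer"))

setValidity("RiskScoreSet", function(object) {
  cc <- c(object@valConcordance, object@testConcordance)
  cc <- cc[is.finite(cc)]
  if (length(cc) && (any(cc < 0) || any(cc > 1)))
    return("concordance indices must lie in [0, 1]")
  if (any(!is.finite(object@scores$risk)))
    return("mean risks must be finite")
  TRUE
})
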