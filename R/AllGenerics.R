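#' @include AllClasses.R
NULL

#' Accessors for SlideSurv objects
#'
#' Small accessor generics: `slideImage()` and `tumorMask()` return the RGB
#' array and binary ground-truth mask of a [SyntheticSlide]; `genParams()`
#' its generator parameters; `manifest()` the tile manifest of a
#' [PatchPairSet]; `nPairs()` its number of kept pairs; `embeddingDim()` the
#' concatenated embedding width of a [SegModel]; `isTrained()` whether it
#' has been trained; `probMap()` and `binaryMask()` the probability and
#' thresholded masks of a [SlideProbabilityMap]; `centroids()` the centers
#' of a [Codebook]; `riskScores()` and `concordanceIndices()` the score
#' table and per-round concordances of a [RiskScoreSet];
#' `importanceSamples()` its per-round feature-importance matrix.
#'
#' @param object an object of the documented class.
#' @param ... passed to methods.
#' @return See the method descriptions above.
#' @name accessors
#' @rdname accessors
#' @export
setGeneric("slideImage", function(object, ...) standardGeneric("slideImage"))

#' @rdname accessors
#' @export
setGeneric("tumorMask", function(object, ...) standardGeneric("tumorMask"))

#' @rdname accessors
#' @export
setGeneric("genParams", function(object, ...) standardGeneric("genParams"))

#' @rdname accessors
#' @export
setGeneric("manifest", function(object, ...) standardGeneric("manifest"))

#' @rdname accessors
#' @export
setGeneric("nPairs", function(object, ...) standardGeneric("nPairs"))

#' @rdname accessors
#' @export
setGeneric("embeddingDim", function(object, ...)
  standardGeneric("embeddingDim"))

#' @rdname accessors
#' @export
setGeneric("isTrained", function(object, ...) standardGeneric("isTrained"))

#' @rdname accessors
#' @export
setGeneric("probMap", function(object, ...) standardGeneric("probMap"))

#' @rdname accessors
#' @export
setGeneric("binaryMask", function(object, ...) standardGeneric("binaryMask"))

#' @rdname accessors
#' @export
setGeneric("centroids", function(object, ...) standardGeneric("centroids"))

#' @rdname accessors
#' @export
setGeneric("riskScores", function(object, ...) standardGeneric("riskScores"))

#' @rdname accessors
#' @export
setGeneric("concordanceIndices", function(object, ...)
  standardGeneric("concordanceIndices"))

#' @rdname accessors
#' @export
setGeneric("importanceSamples", function(object, ...)
  standardGeneric("importanceSamples"))

## Methods --------------------------------------------------------------------

#' @rdname accessors
setMethod("slideImage", "SyntheticSlide", function(object, ...) object@image)

#' @rdname accessors
setMethod("tumorMask", "SyntheticSlide", function(object, ...)
  object@tumorMask)

#' @rdname accessors
setMethod("genParams", "SyntheticSlide", function(object, ...) object@params)

#' @rdname accessors
setMethod("manifest", "PatchPairSet", function(object, ...) object@manifest)

#' @rdname accessors
setMethod("nPairs", "PatchPairSet", function(object, ...)
  length(object@focus))

#' @rdname accessors
setMethod("embeddingDim", "SegModel", function(object, ...)
  2L * object@config@perPathwayEmbedDim)

#' @rdname accessors
setMethod("isTrained", "SegModel", function(object, ...) object@trained)

#' @rdname accessors
setMethod("probMap", "SlideProbabilityMap", function(object, ...)
  object@probs)

#' @rdname accessors
#' @param threshold probability threshold; pixels with probability greater
#'   than or equal to it are called tumor.
setMethod("binaryMask", "SlideProbabilityMap",
  function(object, threshold = object@threshold, ...) {
    m <- object@probs
    out <- ifelse(is.na(m), NA_real_, as.numeric(m >= threshold))
    matrix(out, nrow = nrow(m))
  })

#' @rdname accessors
setMethod("centroids", "Codebook", function(object, ...) object@centroids)

#' @rdname accessors
setMethod("riskScores", "RiskScoreSet", function(object, ...) object@scores)

#' @rdname accessors
#' @param split `"validation"` (out-of-bag) or `"test"`.
setMethod("concordanceIndices", "RiskScoreSet",
  function(object, split = c("validation", "test"), ...) {
    split <- match.arg(split)
    if (split == "validation") object@valConcordance else
      object@testConcordance
  })

#' @rdname accessors
setMethod("importanceSamples", "RiskScoreSet", function(object, ...)
  object@importance)

## show methods ---------------------------------------------------------------

setMethod("show", "SyntheticSlide", function(object) {
  d <- dim(object@image)
  cat(sprintf("SyntheticSlide %dx%d px, tumor fraction %.3f (target %.3f)\n",
              d[2], d[1], mean(object@tumorMask),
              object@params@tumorFraction))
})

setMethod("show", "PatchPairSet", function(object) {
  cat(sprintf(
    "PatchPairSet: %d kept / %d grid tiles, patch %d px (%gx focus, %gx context)\n",
    nPairs(object), nrow(object@manifest), object@config@patchPx,
    object@config@focusMag, object@config@contextMag))
})

setMethod("show", "SegModel", function(object) {
  cat(sprintf(
    "SegModel [%s], patch %d px, embedding %d (2 x %d)%s\n",
    object@config@backbone, object@config@patchPx, embeddingDim(object),
    object@config@perPathwayEmbedDim,
    if (object@trained) ", trained" else ", untrained"))
})

setMethod("show", "BoWFeatureModel", function(object) {
  cat(sprintf(
    "BoWFeatureModel: %d codebooks x k=%d -> %d-d TF-IDF, NMF rank %d (fit on %d slides)\n",
    length(object@codebooks), object@k, length(object@codebooks) * object@k,
    object@rank, object@nTrainSlides))
})

setMethod("show", "RiskScoreSet", function(object) {
  cat(sprintf(
    "RiskScoreSet: %d patients, %d bootstrap rounds; mean concordance val %.3f, test %.3f\n",
    nrow(object@scores), object@nRounds,
    mean(object@valConcordance, na.rm = TRUE),
    mean(object@testConcordance, na.rm = TRUE)))
})
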