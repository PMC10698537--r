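#' Construct a patch-grid configuration
#'
#' @param patchPx patch side length in pixels at focus magnification.
#'   The published pipeline does not state a patch size; 256 is the
#'   conventional WSI tile and the default here.
#' @param focusMag,contextMag magnification factors (canonical 20 and 5).
#' @param backgroundMaxFraction tiles with at least this background
#'   fraction are discarded (canonical 0.5).
#' @param stridePx grid stride; defaults to `patchPx` (non-overlapping).
#' @param contextMode `"wide"` (context covers a `focusMag/contextMag`-times
#'   wider field, the default) or `"same"` (identical field at reduced
#'   resolution).
#' @return A [PatchGridConfig-class].
#' @export
patchGridConfig <- function(patchPx = 256L, focusMag = 20, contextMag = 5,
                            backgroundMaxFraction = 0.5, stridePx = patchPx,
                            contextMode = c("wide", "same")) {
  new("PatchGridConfig", patchPx = as.integer(patchPx), focusMag = focusMag,
      contextMag = contextMag,
      backgroundMaxFraction = backgroundMaxFraction,
      stridePx = as.integer(stridePx),
      contextMode = match.arg(contextMode))
}

#' Otsu background mask of a slide
#'
#' The grayscale image (channel mean) is thresholded by Otsu's method on a
#' 256-bin histogram; pixels brighter than the threshold are flagged as
#' background (glass). A constant image has no defined threshold: an
#' all-tissue mask is returned with a warning.
#'
#' @param image RGB array (height x width x 3, values in [0, 1]) or a
#'   grayscale matrix.
#' @return Binary matrix: 1 = background, 0 = tissue.
#' @export
computeBackgroundMask <- function(image) {
  gray <- if (length(dim(image)) == 3L) luminance(image) else image
  stopIfNot(length(gray) > 0, "image must be non-empty")
  if (max(gray) - min(gray) < 1e-12) {
    warning("constant image: Otsu threshold undefined, returning all-tissue")
    return(matrix(0, nrow(gray), ncol(gray)))
  }
  thr <- EBImage::otsu(EBImage::Image(gray), range = c(0, 1), levels = 256)
  (gray > thr) * 1
}

## Crop + bilinear-resample the context field around a focus tile center.
## Regions beyond the slide edge are padded white (glass).
contextPatch <- function(img, y0, x0, patchPx, scale) {
  h <- dim(img)[1]; w <- dim(img)[2]
  if (scale == 1) {
    ## same field at reduced resolution: down- then up-sample
    fp <- img[(y0 + 1):(y0 + patchPx), (x0 + 1):(x0 + patchPx), , drop = FALSE]
    return(fp)
  }
  s <- as.integer(round(patchPx * scale))
  cy <- y0 + patchPx / 2; cx <- x0 + patchPx / 2
  ys <- as.integer(round(cy - s / 2)); xs <- as.integer(round(cx - s / 2))
  big <- array(1, dim = c(s, s, 3))
  yr <- max(1, ys + 1):min(h, ys + s)
  xr <- max(1, xs + 1):min(w, xs + s)
  if (length(yr) && length(xr))
    big[yr - ys, xr - xs, ] <- img[yr, xr, , drop = FALSE]
  big
}

## Downsample an RGB array to patchPx x patchPx (bilinear, EBImage).
resampleTo <- function(arr, patchPx) {
  if (identical(dim(arr)[1:2], c(patchPx, patchPx))) return(arr)
  out <- EBImage::imageData(EBImage::resize(
    EBImage::Image(aperm(arr, c(2, 1, 3)), colormode = "Color"),
    w = patchPx, h = patchPx))
  aperm(out, c(2, 1, 3))
}

#' Extract filtered dual-resolution patch pairs from a slide
#'
#' Tiles the slide on a regular grid at the focus magnification (stride
#' `stridePx`, partial edge tiles dropped), computes the per-slide Otsu
#' background mask, and keeps a tile iff the background fraction of its
#' focus patch is strictly below `backgroundMaxFraction`. Each kept focus
#' patch is paired with a co-centered context patch: in `"wide"` mode the
#' context covers a `focusMag/contextMag`-times wider field resampled to
#' `patchPx` (out-of-slide areas padded white); in `"same"` mode the
#' identical field is down- and re-upsampled to emulate the lower
#' magnification. There is always exactly one context patch per kept focus
#' patch. The annotation mask patch is cut in the focus frame.
#'
#' @param slide a [SyntheticSlide-class], or an RGB array.
#' @param config a [PatchGridConfig-class].
#' @param mask optional binary annotation mask (required when `slide` is a
#'   plain array and mask patches are wanted).
#' @param slideId identifier recorded in the manifest.
#' @return A [PatchPairSet-class]. If the patch size exceeds the slide, an
#'   empty set is returned with a warning.
#' @export
extractPatchPairs <- function(slide, config = patchGridConfig(),
                              mask = NULL, slideId = "slide") {
  validObject(config)
  if (is(slide, "SyntheticSlide")) {
    img <- slide@image
    if (is.null(mask)) mask <- slide@tumorMask
  } else img <- slide
  h <- dim(img)[1]; w <- dim(img)[2]
  P <- config@patchPx
  if (is.null(mask)) mask <- matrix(0, h, w)
  stopIfNot(identical(dim(mask), c(h, w)),
            "annotation mask must match the slide frame")

  emptySet <- function() new("PatchPairSet", focus = list(), context = list(),
                             maskPatch = list(),
                             manifest = data.frame(slide_id = character(),
                                                   row = integer(),
                                                   col = integer(),
                                                   y0 = integer(),
                                                   x0 = integer(),
                                                   background_fraction = numeric(),
                                                   kept = logical(),
                                                   pair = integer()),
                             config = config, slideDim = c(h, w))
  if (P > h || P > w) {
    warning("patch size exceeds slide dimensions; returning empty set")
    return(emptySet())
  }

  bg <- computeBackgroundMask(img)
  y0s <- seq(0L, h - P, by = config@stridePx)
  x0s <- seq(0L, w - P, by = config@stridePx)
  scale <- if (config@contextMode == "wide")
    config@focusMag / config@contextMag else 1

  rows <- list(); focus <- list(); context <- list(); maskP <- list()
  pairIdx <- 0L; i <- 0L
  man <- expand.grid(colIdx = seq_along(x0s), rowIdx = seq_along(y0s))
  n <- nrow(man)
  out <- data.frame(slide_id = rep(slideId, n), row = man$rowIdx - 1L,
                    col = man$colIdx - 1L,
                    y0 = y0s[man$rowIdx], x0 = x0s[man$colIdx],
                    background_fraction = NA_real_, kept = FALSE,
                    pair = NA_integer_)
  for (r in seq_len(n)) {
    y0 <- out$y0[r]; x0 <- out$x0[r]
    bfrac <- mean(bg[(y0 + 1):(y0 + P), (x0 + 1):(x0 + P)])
    out$background_fraction[r] <- bfrac
    if (bfrac < config@backgroundMaxFraction) {
      pairIdx <- pairIdx + 1L
      out$kept[r] <- TRUE
      out$pair[r] <- pairIdx
      focus[[pairIdx]] <- img[(y0 + 1):(y0 + P), (x0 + 1):(x0 + P), ,
                              drop = FALSE]
      ctx <- contextPatch(img, y0, x0, P, scale)
      if (config@contextMode == "same") {
        ## emulate lower magnification of the same field
        low <- as.integer(max(2, round(P * config@contextMag /
                                         config@focusMag)))
        ctx <- resampleTo(resampleTo(ctx, low), P)
      } else ctx <- resampleTo(ctx, P)
      context[[pairIdx]] <- ctx
      maskP[[pairIdx]] <- mask[(y0 + 1):(y0 + P), (x0 + 1):(x0 + P)]
    }
  }
  new("PatchPairSet", focus = focus, context = context, maskPatch = maskP,
      manifest = out, config = config, slideDim = c(h, w))
}

#' Binarize a labeled annotation mask
#'
#' Any annotated (non-zero) label becomes tumor (1); unannotated pixels
#' become non-tumor (0), yielding the binary slide representation used for
#' training.
#'
#' @param annotation labeled matrix (0 = unannotated).
#' @param image optional slide the mask must align with (shape check).
#' @return Binary matrix in {0, 1}.
#' @export
binarizeAnnotation <- function(annotation, image = NULL) {
  if (!is.null(image)) {
    d <- if (length(dim(image)) == 3L) dim(image)[1:2] else dim(image)
    stopIfNot(identical(dim(annotation), d),
              "annotation mask and slide shapes differ")
  }
  (annotation != 0) * 1
}

#' Re-stitch kept focus patches into the slide frame
#'
#' Inverse of the tiling step over kept tiles: pixels covered by a kept
#' focus patch are written back at their grid origin; uncovered pixels are
#' NA. With the default non-overlapping grid this reproduces the kept
#' slide pixels exactly.
#'
#' @param pairs a [PatchPairSet-class].
#' @return An RGB array in the slide frame with NA at uncovered pixels.
#' @export
stitchFocusPatches <- function(pairs) {
  h <- pairs@slideDim[1]; w <- pairs@slideDim[2]
  P <- pairs@config@patchPx
  out <- array(NA_real_, dim = c(h, w, 3))
  man <- pairs@manifest[pairs@manifest$kept, , drop = FALSE]
  for (r in seq_len(nrow(man))) {
    y0 <- man$y0[r]; x0 <- man$x0[r]
    out[(y0 + 1):(y0 + P), (x0 + 1):(x0 + P), ] <-
      pairs@focus[[man$pair[r]]]
  }
  out
}
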