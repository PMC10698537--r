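#' Construct slide-generator parameters
#'
#' Convenience constructor for [SlideGenParams-class] with validity checks.
#'
#' @param widthPx,heightPx slide dimensions in pixels (>= 8).
#' @param tumorFraction target tumor pixel fraction in [0, 1].
#' @param nTumorBlobs number of tumor nests.
#' @param textureContrast tumor/non-tumor texture contrast in [0, 1].
#' @param backgroundFraction near-white background fraction;
#'   `tumorFraction + backgroundFraction` must not exceed 1.
#' @param seed integer RNG seed.
#' @return A [SlideGenParams-class] object.
#' @export
slideGenParams <- function(widthPx = 96L, heightPx = 96L,
                           tumorFraction = 0.35, nTumorBlobs = 3L,
                           textureContrast = 0.7, backgroundFraction = 0.15,
                           seed = 1L) {
  new("SlideGenParams", widthPx = as.integer(widthPx),
      heightPx = as.integer(heightPx), tumorFraction = tumorFraction,
      nTumorBlobs = as.integer(nTumorBlobs),
      textureContrast = textureContrast,
      backgroundFraction = backgroundFraction, seed = as.integer(seed))
}

## Smooth a white-noise field with a Gaussian kernel (EBImage).
smoothNoise <- function(h, w, sigma) {
  z <- matrix(stats::rnorm(h * w), h, w)
  if (sigma > 0) z <- EBImage::imageData(EBImage::gblur(EBImage::Image(z),
                                                        sigma = sigma))
  z
}

#' Generate a synthetic slide with ground-truth tumor mask
#'
#' Emulates a scanned H&E section at the focus magnification: pinkish
#' non-tumor tissue with smooth low-frequency variation, tumor nests with a
#' darker hue and a high-frequency nuclei-like speckle texture, and
#' near-white glass background (luminance > 0.9). Tumor nests are obtained
#' by thresholding a sum of Gaussian bumps plus smoothed noise at the exact
#' quantile that yields `tumorFraction` of the slide, giving irregular
#' blob-shaped regions with a known binary mask. All randomness derives
#' from `params@seed` via fixed substreams, so the same parameters yield a
#' bit-identical slide.
#'
#' @param params a [SlideGenParams-class] object (or arguments forwarded to
#'   [slideGenParams()]).
#' @param ... forwarded to [slideGenParams()] when `params` is missing.
#' @return A [SyntheticSlide-class] with 8-bit RGB `image` (values in
#'   [0, 1], 256 levels) and binary `tumorMask`.
#' @examples
#' sl <- generateSlide(slideGenParams(widthPx = 64, heightPx = 64, seed = 3))
#' mean(tumorMask(sl))
#' @export
generateSlide <- function(params, ...) {
  if (missing(params)) params <- slideGenParams(...)
  validObject(params)
  h <- params@heightPx; w <- params@widthPx; n <- h * w
  seed <- params@seed

  ## background: smoothed noise thresholded at the exact quantile
  bg <- matrix(0, h, w)
  if (params@backgroundFraction > 0) {
    f <- withSeed(subSeed(seed, 1L), smoothNoise(h, w, min(h, w) / 10))
    nbg <- round(params@backgroundFraction * n)
    bg[order(f, decreasing = TRUE)[seq_len(nbg)]] <- 1
  }

  ## tumor nests: Gaussian bumps + smoothed noise, thresholded within tissue
  tumor <- matrix(0, h, w)
  ntum <- round(params@tumorFraction * n)
  if (ntum > 0) {
    field <- withSeed(subSeed(seed, 2L), {
      fld <- 0.6 * smoothNoise(h, w, min(h, w) / 12)
      fld <- fld / max(stats::sd(fld), 1e-12)
      if (params@nTumorBlobs > 0) {
        cy <- stats::runif(params@nTumorBlobs, 0.15 * h, 0.85 * h)
        cx <- stats::runif(params@nTumorBlobs, 0.15 * w, 0.85 * w)
        r  <- sqrt(params@tumorFraction * n /
                     (pi * params@nTumorBlobs)) *
              stats::runif(params@nTumorBlobs, 0.8, 1.2)
        yy <- row(fld); xx <- col(fld)
        for (b in seq_len(params@nTumorBlobs))
          fld <- fld + 2 * exp(-((yy - cy[b])^2 + (xx - cx[b])^2) /
                                 (2 * r[b]^2))
      }
      fld
    })
    tissueIdx <- which(bg == 0)
    ntum <- min(ntum, length(tissueIdx))
    top <- tissueIdx[order(field[tissueIdx], decreasing = TRUE)[seq_len(ntum)]]
    tumor[top] <- 1
  }

  img <- withSeed(subSeed(seed, 3L), {
    ct <- params@textureContrast
    ## non-tumor tissue base (eosin pink) with low-frequency shading
    shade <- 0.05 * smoothNoise(h, w, min(h, w) / 8)
    fine  <- matrix(stats::rnorm(n, sd = 0.02), h, w)
    ## tissue base kept well below glass luminance so the slide's dominant
    ## bimodality is tissue vs glass (what Otsu must find), with the
    ## tumor/non-tumor contrast a second, smaller mode inside tissue
    base <- list(r = 0.72, g = 0.50, b = 0.62)
    ## nuclei-like speckle: sparse dark dots, amplitude scaled by contrast
    speck <- matrix(stats::rbinom(n, 1L, 0.25), h, w) *
      matrix(stats::runif(n, 0.5, 1), h, w)
    glass <- stats::runif(sum(bg == 1), 0.955, 0.995)  # neutral near-white
    im <- array(0, dim = c(h, w, 3))
    drop3 <- c(0.22, 0.20, 0.14)   # hematoxylin-ish shift for tumor
    for (ch in 1:3) {
      plane <- base[[ch]] + shade + fine
      plane <- plane - tumor * (ct * drop3[ch] + ct * 0.25 * speck)
      plane[bg == 1] <- glass
      im[, , ch] <- plane
    }
    im
  })

  new("SyntheticSlide", image = quantize8(img), tumorMask = tumor,
      params = params)
}

#' Write / read a synthetic slide as paired PNGs with a JSON sidecar
#'
#' The image and mask are written as `<basename>.png` and
#' `<basename>_mask.png`; generator parameters go to `<basename>.json`.
#'
#' @param slide a [SyntheticSlide-class].
#' @param dir output directory (created if needed).
#' @param basename file basename without extension.
#' @return `writeSlide` returns the basename invisibly; `readSlide` returns
#'   the reconstructed [SyntheticSlide-class].
#' @export
writeSlide <- function(slide, dir, basename = "slide") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  png::writePNG(slide@image, file.path(dir, paste0(basename, ".png")))
  png::writePNG(slide@tumorMask, file.path(dir, paste0(basename, "_mask.png")))
  p <- slide@params
  jsonlite::write_json(
    list(widthPx = p@widthPx, heightPx = p@heightPx,
         tumorFraction = p@tumorFraction, nTumorBlobs = p@nTumorBlobs,
         textureContrast = p@textureContrast,
         backgroundFraction = p@backgroundFraction, seed = p@seed),
    file.path(dir, paste0(basename, ".json")), auto_unbox = TRUE, digits = NA)
  invisible(basename)
}

#' @rdname writeSlide
#' @export
readSlide <- function(dir, basename = "slide") {
  img <- png::readPNG(file.path(dir, paste0(basename, ".png")))
  msk <- png::readPNG(file.path(dir, paste0(basename, "_mask.png")))
  if (length(dim(msk)) == 3L) msk <- msk[, , 1]
  js <- jsonlite::read_json(file.path(dir, paste0(basename, ".json")),
                            simplifyVector = TRUE)
  new("SyntheticSlide", image = img, tumorMask = round(msk),
      params = slideGenParams(js$widthPx, js$heightPx, js$tumorFraction,
                              js$nTumorBlobs, js$textureContrast,
                              js$backgroundFraction, js$seed))
}
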