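#' Construct a segmentation-model configuration
#'
#' Backbone presets: `"tiny_cnn"` (8 conv filters, 32-d per-pathway
#' embedding) for desk-scale experiments, `"canonical"` (64 filters,
#' 1280-d per pathway, 2560-d concatenated) matching the published
#' dual-pathway embedding width. Any preset value can be overridden.
#'
#' @param backbone `"tiny_cnn"` or `"canonical"`.
#' @param patchPx input patch side in pixels.
#' @param convFilters,perPathwayEmbedDim encoder widths (preset by backbone
#'   when NULL).
#' @param learningRate Adam learning rate (canonical 1e-4).
#' @param lrDecay per-epoch exponential learning-rate decay factor.
#' @param transferEpochs epochs with encoders frozen (canonical 11).
#' @param finetuneEpochs epochs training all weights (canonical 120).
#' @param earlyStoppingPatience epochs without validation-loss improvement
#'   before stopping.
#' @param classWeightMode `"inverse_frequency"` (default) or `"fixed"`.
#' @param probThreshold tumor probability threshold (canonical 0.5).
#' @param folds cross-validation folds (canonical 5).
#' @param batchSize minibatch size.
#' @param seed integer RNG seed.
#' @return A [SegModelConfig-class].
#' @export
segModelConfig <- function(backbone = c("tiny_cnn", "canonical"),
                           patchPx = 16L, convFilters = NULL,
                           perPathwayEmbedDim = NULL, learningRate = 1e-4,
                           lrDecay = 0.95, transferEpochs = 11L,
                           finetuneEpochs = 120L,
                           earlyStoppingPatience = 10L,
                           classWeightMode = c("inverse_frequency", "fixed"),
                           probThreshold = 0.5, folds = 5L, batchSize = 64L,
                           seed = 1L) {
  backbone <- match.arg(backbone)
  if (is.null(convFilters))
    convFilters <- if (backbone == "canonical") 64L else 8L
  if (is.null(perPathwayEmbedDim))
    perPathwayEmbedDim <- if (backbone == "canonical") 1280L else 32L
  new("SegModelConfig", backbone = backbone, patchPx = as.integer(patchPx),
      convFilters = as.integer(convFilters),
      perPathwayEmbedDim = as.integer(perPathwayEmbedDim),
      learningRate = learningRate, lrDecay = lrDecay,
      transferEpochs = as.integer(transferEpochs),
      finetuneEpochs = as.integer(finetuneEpochs),
      earlyStoppingPatience = as.integer(earlyStoppingPatience),
      classWeightMode = match.arg(classWeightMode),
      probThreshold = probThreshold, folds = as.integer(folds),
      batchSize = as.integer(batchSize), seed = as.integer(seed))
}

## ---------------------------------------------------------------------------
## Network internals. The model is a compact dual-pathway CNN implemented
## directly with matrix algebra: per pathway a 3x3 same-padded convolution
## (im2col + matmul) with ReLU, global average pooling and a dense embedding
## layer; the two pooled embeddings are concatenated (the feature-extraction
## hook) and feed a dense per-pixel decoder, plus a 1x1-convolution skip from
## the focus pathway's feature map that restores within-patch localisation.
## ---------------------------------------------------------------------------

## im2col for a P x P x 3 patch, 3x3 kernel, zero padding 1.
## Rows: pixels in column-major order; columns: 27 kernel taps.
im2col3 <- function(img, P) {
  pad <- array(0, dim = c(P + 2L, P + 2L, 3L))
  pad[2:(P + 1), 2:(P + 1), ] <- img
  cols <- matrix(0, P * P, 27L)
  k <- 0L
  for (ch in 1:3) for (dx in 0:2) for (dy in 0:2) {
    k <- k + 1L
    cols[, k] <- as.vector(pad[(1:P) + dy, (1:P) + dx, ch])
  }
  cols
}

## Stack im2col matrices for a list of patches (n*P^2 x 27).
stackIm2col <- function(patches, P) {
  do.call(rbind, lapply(patches, im2col3, P = P))
}

initSegWeights <- function(config) {
  F <- config@convFilters; D <- config@perPathwayEmbedDim
  P2 <- config@patchPx^2
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)),
                                nr, nc)
  withSeed(subSeed(config@seed, 31L), list(
    WcF = he(27L, F), bcF = rep(0, F),
    WcC = he(27L, F), bcC = rep(0, F),
    WeF = he(F, D), beF = rep(0, D),
    WeC = he(F, D), beC = rep(0, D),
    Wd = he(2L * D, P2), bd = rep(0, P2),
    Ws = he(F, 1L)))
}

#' Build a dual-pathway segmentation model
#'
#' Instantiates the network with seeded He-initialized weights. The model
#' maps a (focus, context) patch pair to a per-pixel tumor probability map
#' at focus resolution; [segEmbed()] exposes the concatenated pooled
#' embedding (always `2 * perPathwayEmbedDim` long).
#'
#' @param config a [SegModelConfig-class].
#' @return An untrained [SegModel-class].
#' @examples
#' m <- buildSegModel(segModelConfig("tiny_cnn"))
#' embeddingDim(m)
#' @export
buildSegModel <- function(config = segModelConfig()) {
  validObject(config)
  new("SegModel", config = config, weights = initSegWeights(config),
      trained = FALSE, classWeights = c(1, 1))
}

## Full forward pass on stacked im2col inputs.
## n patches; returns activations needed for backprop.
segForward <- function(W, Xf, Xc, n, P2) {
  Cf <- Xf %*% W$WcF; Cf <- sweep(Cf, 2, W$bcF, "+"); Cf[Cf < 0] <- 0
  Cc <- Xc %*% W$WcC; Cc <- sweep(Cc, 2, W$bcC, "+"); Cc[Cc < 0] <- 0
  grp <- rep(seq_len(n), each = P2)
  Gf <- rowsum(Cf, grp, reorder = FALSE) / P2
  Gc <- rowsum(Cc, grp, reorder = FALSE) / P2
  Ef <- Gf %*% W$WeF; Ef <- sweep(Ef, 2, W$beF, "+"); Ef[Ef < 0] <- 0
  Ec <- Gc %*% W$WeC; Ec <- sweep(Ec, 2, W$beC, "+"); Ec[Ec < 0] <- 0
  E <- cbind(Ef, Ec)
  Z <- E %*% W$Wd; Z <- sweep(Z, 2, W$bd, "+")
  Z <- Z + t(matrix(Cf %*% W$Ws, nrow = P2, ncol = n))
  p <- 1 / (1 + exp(-Z))
  list(Cf = Cf, Cc = Cc, Gf = Gf, Gc = Gc, Ef = Ef, Ec = Ec, E = E,
       Z = Z, p = p)
}

## Weighted binary cross-entropy and its gradient wrt logits.
segLoss <- function(p, Y, w0, w1) {
  eps <- 1e-9
  Wm <- ifelse(Y > 0.5, w1, w0)
  loss <- -mean(Wm * (Y * log(p + eps) + (1 - Y) * log(1 - p + eps)))
  dZ <- Wm * (p - Y) / length(Y)
  list(loss = loss, dZ = dZ)
}

segBackward <- function(W, fw, Xf, Xc, dZ, n, P2, freezeEncoders = FALSE) {
  g <- list()
  g$Wd <- crossprod(fw$E, dZ); g$bd <- colSums(dZ)
  dSvec <- as.vector(t(dZ))
  g$Ws <- crossprod(fw$Cf, dSvec)
  dE <- dZ %*% t(W$Wd)
  D <- ncol(fw$Ef)
  dCfSkip <- outer(dSvec, drop(W$Ws))  # (nP2) x F
  if (freezeEncoders) {
    ## conv activations still receive skip gradient only through Ws, which
    ## is a decoder weight; encoder weights stay fixed.
    zero <- function(x) x * 0
    g$WcF <- zero(W$WcF); g$bcF <- zero(W$bcF)
    g$WcC <- zero(W$WcC); g$bcC <- zero(W$bcC)
    g$WeF <- zero(W$WeF); g$beF <- zero(W$beF)
    g$WeC <- zero(W$WeC); g$beC <- zero(W$beC)
    return(g)
  }
  dEf <- dE[, seq_len(D), drop = FALSE] * (fw$Ef > 0)
  dEc <- dE[, D + seq_len(D), drop = FALSE] * (fw$Ec > 0)
  g$WeF <- crossprod(fw$Gf, dEf); g$beF <- colSums(dEf)
  g$WeC <- crossprod(fw$Gc, dEc); g$beC <- colSums(dEc)
  dGf <- dEf %*% t(W$WeF); dGc <- dEc %*% t(W$WeC)
  idx <- rep(seq_len(n), each = P2)
  dCf <- (dGf[idx, , drop = FALSE] / P2 + dCfSkip) * (fw$Cf > 0)
  dCc <- (dGc[idx, , drop = FALSE] / P2) * (fw$Cc > 0)
  g$WcF <- crossprod(Xf, dCf); g$bcF <- colSums(dCf)
  g$WcC <- crossprod(Xc, dCc); g$bcC <- colSums(dCc)
  g
}

adamInit <- function(W) {
  list(m = lapply(W, function(x) x * 0), v = lapply(W, function(x) x * 0),
       t = 0L)
}

adamStep <- function(W, g, st, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(g)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g[[nm]]^2
    mh <- st$m[[nm]] / (1 - beta1^st$t)
    vh <- st$v[[nm]] / (1 - beta2^st$t)
    W[[nm]] <- W[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(W = W, st = st)
}

## Assemble stacked design matrices for a list of patch pairs.
segDesign <- function(pairs, P) {
  n <- length(pairs$focus)
  list(Xf = stackIm2col(pairs$focus, P), Xc = stackIm2col(pairs$context, P),
       Y = if (length(pairs$mask))
         do.call(rbind, lapply(pairs$mask, function(m) as.vector(m))) else
           NULL,
       n = n)
}

## Pull pairs out of one or more PatchPairSet objects into flat lists.
flattenPairs <- function(sets) {
  if (is(sets, "PatchPairSet")) sets <- list(sets)
  list(focus = do.call(c, lapply(sets, function(s) s@focus)),
       context = do.call(c, lapply(sets, function(s) s@context)),
       mask = do.call(c, lapply(sets, function(s) s@maskPatch)))
}

#' Apply a random augmentation to a patch pair
#'
#' The same geometric transform (horizontal/vertical flips and a rotation
#' by a multiple of 90 degrees) is applied to the focus patch, context
#' patch and mask; photometric jitter (brightness shift, contrast scaling)
#' is applied to the images only, so the mask stays strictly binary.
#' Free-angle rotation is available behind `rot90Only = FALSE` with
#' nearest-neighbour mask interpolation.
#'
#' @param pair list with elements `focus`, `context` (RGB arrays) and
#'   `mask` (binary matrix).
#' @param seed integer seed controlling the draw.
#' @param rot90Only restrict rotation to multiples of 90 degrees (default).
#' @return The transformed pair (same structure).
#' @export
augmentPair <- function(pair, seed = 1L, rot90Only = TRUE) {
  withSeed(subSeed(seed, 41L), {
    hf <- stats::runif(1) < 0.5
    vf <- stats::runif(1) < 0.5
    k <- sample(0:3, 1)
    br <- stats::runif(1, -0.1, 0.1)
    ctr <- stats::runif(1, 0.8, 1.2)
    angle <- if (rot90Only) 90 * k else stats::runif(1, 0, 360)
    geo <- function(m, binary = FALSE) {
      if (length(dim(m)) == 3L) {
        for (ch in 1:3) m[, , ch] <- geo(m[, , ch])
        return(m)
      }
      if (hf) m <- m[, rev(seq_len(ncol(m)))]
      if (vf) m <- m[rev(seq_len(nrow(m))), ]
      if (rot90Only) {
        for (i in seq_len(k)) m <- t(m[rev(seq_len(nrow(m))), ])
      } else {
        m <- EBImage::imageData(EBImage::rotate(
          EBImage::Image(m), angle, output.dim = dim(m)))
        if (binary) m <- round(m)
      }
      m
    }
    out <- pair
    out$focus <- pmin(pmax(geo(pair$focus) * ctr + br, 0), 1)
    out$context <- pmin(pmax(geo(pair$context) * ctr + br, 0), 1)
    out$mask <- geo(pair$mask, binary = TRUE)
    out
  })
}

## Class weights from training pixel counts, normalized to mean 1.
segClassWeights <- function(Y, mode) {
  if (mode == "fixed") return(c(1, 1))
  n1 <- sum(Y); n0 <- length(Y) - n1
  if (n1 == 0 || n0 == 0)
    stop("degenerate class weights: training fold has a single class ",
         "(tumor pixels: ", n1, ")", call. = FALSE)
  c(length(Y) / (2 * n0), length(Y) / (2 * n1))
}

## Core training loop over prepared design matrices.
segFit <- function(model, train, val, config) {
  P2 <- config@patchPx^2
  cw <- segClassWeights(train$Y, config@classWeightMode)
  W <- model@weights
  st <- adamInit(W)
  history <- data.frame(epoch = integer(), stage = character(),
                        train_loss = numeric(), val_loss = numeric())
  best <- list(loss = Inf, W = W, wait = 0L)
  epochGlobal <- 0L
  stages <- list(c("transfer", config@transferEpochs),
                 c("finetune", config@finetuneEpochs))
  for (stage in stages) {
    nm <- stage[1]; nEp <- as.integer(stage[2])
    freeze <- nm == "transfer"
    for (ep in seq_len(nEp)) {
      epochGlobal <- epochGlobal + 1L
      lr <- config@learningRate * config@lrDecay^(epochGlobal - 1L)
      ord <- withSeed(subSeed(config@seed, 100L + epochGlobal),
                      sample.int(train$n))
      batches <- split(ord, ceiling(seq_along(ord) / config@batchSize))
      epLoss <- 0
      for (b in batches) {
        rows <- as.vector(outer(seq_len(P2), (b - 1L) * P2, "+"))
        Xf <- train$Xf[rows, , drop = FALSE]
        Xc <- train$Xc[rows, , drop = FALSE]
        Y <- train$Y[b, , drop = FALSE]
        fw <- segForward(W, Xf, Xc, length(b), P2)
        ls <- segLoss(fw$p, Y, cw[1], cw[2])
        g <- segBackward(W, fw, Xf, Xc, ls$dZ, length(b), P2,
                         freezeEncoders = freeze)
        upd <- adamStep(W, g, st, lr)
        W <- upd$W; st <- upd$st
        epLoss <- epLoss + ls$loss * length(b)
      }
      epLoss <- epLoss / train$n
      vLoss <- NA_real_
      if (!is.null(val) && val$n > 0) {
        fwv <- segForward(W, val$Xf, val$Xc, val$n, P2)
        vLoss <- segLoss(fwv$p, val$Y, cw[1], cw[2])$loss
        if (vLoss < best$loss - 1e-6) {
          best$loss <- vLoss; best$W <- W; best$wait <- 0L
        } else {
          best$wait <- best$wait + 1L
        }
      }
      history <- rbind(history, data.frame(epoch = epochGlobal, stage = nm,
                                           train_loss = epLoss,
                                           val_loss = vLoss))
      if (!is.null(val) && best$wait >= config@earlyStoppingPatience) break
    }
    if (!is.null(val) && best$wait >= config@earlyStoppingPatience) break
  }
  if (!is.null(val) && is.finite(best$loss)) W <- best$W
  model@weights <- W
  model@trained <- TRUE
  model@classWeights <- cw
  list(model = model, history = history)
}

#' Train the segmentation network with slide-level cross-validation
#'
#' Slides are partitioned into `config@folds` folds (seeded shuffle); every
#' patch of a slide belongs to exactly one fold, so no slide contributes to
#' both training and validation of the same fold. Per fold the network is
#' trained with pixel-wise cross-entropy weighted by the inverse tumor /
#' non-tumor pixel frequency of the training fold, in two stages (encoder
#' weights frozen during the transfer epochs, all weights during
#' fine-tuning), with early stopping on validation loss.
#'
#' @param pairsBySlide named list of [PatchPairSet-class], one per slide.
#' @param config a [SegModelConfig-class].
#' @param augmentTimes augmented copies added per training pair (0 = none).
#' @return A list of [TrainedFold-class], length `config@folds`.
#' @export
trainSegCV <- function(pairsBySlide, config = segModelConfig(),
                       augmentTimes = 0L) {
  validObject(config)
  ids <- names(pairsBySlide)
  stopIfNot(length(ids) >= config@folds,
            "need at least as many slides as folds")
  ## shuffle slides, then deal round-robin into folds
  foldOf <- withSeed(subSeed(config@seed, 51L), {
    ord <- sample(ids)
    stats::setNames(rep_len(seq_len(config@folds), length(ord)), ord)
  })
  out <- vector("list", config@folds)
  for (f in seq_len(config@folds)) {
    valIds <- ids[foldOf[ids] == f]
    trainIds <- setdiff(ids, valIds)
    trPairs <- flattenPairs(pairsBySlide[trainIds])
    if (augmentTimes > 0) {
      extra <- list(focus = list(), context = list(), mask = list())
      idx <- 0L
      for (a in seq_len(augmentTimes)) for (i in seq_along(trPairs$focus)) {
        idx <- idx + 1L
        pr <- augmentPair(list(focus = trPairs$focus[[i]],
                               context = trPairs$context[[i]],
                               mask = trPairs$mask[[i]]),
                          seed = subSeed(config@seed, 1000L * a + i))
        extra$focus[[idx]] <- pr$focus
        extra$context[[idx]] <- pr$context
        extra$mask[[idx]] <- pr$mask
      }
      trPairs <- list(focus = c(trPairs$focus, extra$focus),
                      context = c(trPairs$context, extra$context),
                      mask = c(trPairs$mask, extra$mask))
    }
    vlPairs <- flattenPairs(pairsBySlide[valIds])
    train <- segDesign(trPairs, config@patchPx)
    val <- if (length(vlPairs$focus)) segDesign(vlPairs, config@patchPx) else
      NULL
    fit <- segFit(buildSegModel(config), train, val, config)
    out[[f]] <- new("TrainedFold", foldIndex = f, model = fit$model,
                    trainSlides = trainIds, valSlides = valIds,
                    history = fit$history)
  }
  out
}

#' Concatenation-layer embeddings for a set of patch pairs
#'
#' The feature-extraction hook: returns the concatenated pooled embedding
#' (length `2 * perPathwayEmbedDim`) for each pair.
#'
#' @param model a built [SegModel-class].
#' @param pairs a [PatchPairSet-class] or flat list with `focus`/`context`.
#' @return Matrix, one row per pair.
#' @export
segEmbed <- function(model, pairs) {
  if (is(pairs, "PatchPairSet")) pairs <- flattenPairs(pairs)
  P <- model@config@patchPx
  if (!length(pairs$focus))
    return(matrix(0, 0, embeddingDim(model)))
  d <- segDesign(pairs, P)
  fw <- segForward(model@weights, d$Xf, d$Xc, d$n, P^2)
  fw$E
}

#' Predict a per-pixel tumor probability map for a whole slide
#'
#' The slide is tiled with the training grid (including the Otsu background
#' filter), each kept pair is run through the network, and the per-patch
#' probability maps are stitched back to the slide frame (overlapping
#' pixels averaged). Pixels never visited by a kept tile are no-data (NA).
#' The binary mask calls a pixel tumor when its probability is greater
#' than or equal to `config@probThreshold` (canonical 0.5).
#'
#' @param model a trained [SegModel-class].
#' @param slide a [SyntheticSlide-class] or RGB array.
#' @param grid optional [PatchGridConfig-class]; defaults to a
#'   non-overlapping grid at the model's patch size.
#' @return A [SlideProbabilityMap-class].
#' @export
predictSlide <- function(model, slide, grid = NULL) {
  if (!isTrained(model))
    stop("model has not been trained", call. = FALSE)
  P <- model@config@patchPx
  if (is.null(grid)) grid <- patchGridConfig(patchPx = P)
  pairs <- extractPatchPairs(slide, grid)
  h <- pairs@slideDim[1]; w <- pairs@slideDim[2]
  acc <- matrix(0, h, w); cnt <- matrix(0L, h, w)
  if (nPairs(pairs) > 0) {
    d <- segDesign(flattenPairs(pairs), P)
    fw <- segForward(model@weights, d$Xf, d$Xc, d$n, P^2)
    man <- pairs@manifest[pairs@manifest$kept, , drop = FALSE]
    for (r in seq_len(nrow(man))) {
      y0 <- man$y0[r]; x0 <- man$x0[r]
      pm <- matrix(fw$p[man$pair[r], ], P, P)
      acc[(y0 + 1):(y0 + P), (x0 + 1):(x0 + P)] <-
        acc[(y0 + 1):(y0 + P), (x0 + 1):(x0 + P)] + pm
      cnt[(y0 + 1):(y0 + P), (x0 + 1):(x0 + P)] <-
        cnt[(y0 + 1):(y0 + P), (x0 + 1):(x0 + P)] + 1L
    }
  }
  probs <- ifelse(cnt > 0, acc / pmax(cnt, 1L), NA_real_)
  new("SlideProbabilityMap", probs = matrix(probs, h, w),
      threshold = model@config@probThreshold)
}

#' Stitch externally supplied per-patch probability maps to the slide frame
#'
#' Utility for round-trip checks: writes per-patch probability matrices
#' back at their manifest positions (overlaps averaged), NA elsewhere.
#'
#' @param pairs a [PatchPairSet-class].
#' @param patchProbs list of `patchPx x patchPx` probability matrices, one
#'   per kept pair.
#' @param threshold threshold stored on the returned map.
#' @return A [SlideProbabilityMap-class].
#' @export
stitchProbabilities <- function(pairs, patchProbs, threshold = 0.5) {
  stopIfNot(length(patchProbs) == nPairs(pairs),
            "need one probability patch per kept pair")
  h <- pairs@slideDim[1]; w <- pairs@slideDim[2]
  P <- pairs@config@patchPx
  acc <- matrix(0, h, w); cnt <- matrix(0L, h, w)
  man <- pairs@manifest[pairs@manifest$kept, , drop = FALSE]
  for (r in seq_len(nrow(man))) {
    y0 <- man$y0[r]; x0 <- man$x0[r]
    acc[(y0 + 1):(y0 + P), (x0 + 1):(x0 + P)] <-
      acc[(y0 + 1):(y0 + P), (x0 + 1):(x0 + P)] + patchProbs[[man$pair[r]]]
    cnt[(y0 + 1):(y0 + P), (x0 + 1):(x0 + P)] <-
      cnt[(y0 + 1):(y0 + P), (x0 + 1):(x0 + P)] + 1L
  }
  probs <- ifelse(cnt > 0, acc / pmax(cnt, 1L), NA_real_)
  new("SlideProbabilityMap", probs = matrix(probs, h, w),
      threshold = threshold)
}
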