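## Internal helpers: seed handling, argument checks, small numeric utilities.

## Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

## Derive a per-component substream seed from a master seed so each stage can
## be regenerated independently. Kept below 2^31 - 1 (R integers are 32-bit).
subSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(stream)) %%
               2147483629)
}

stopIfNot <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

isCount <- function(x, min = 1L) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x == round(x) && x >= min
}

isFraction <- function(x, lo = 0, hi = 1) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= lo && x <= hi
}

## Quantize a numeric array in [0, 1] to 8-bit levels (256 grey levels).
quantize8 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  round(x * 255) / 255
}

## Luminance of an RGB array (H x W x 3) as the channel mean, in [0, 1].
luminance <- function(img) {
  stopIfNot(length(dim(img)) == 3L && dim(img)[3] == 3L,
            "expected an RGB array with 3 channels")
  (img[, , 1] + img[, , 2] + img[, , 3]) / 3
}
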