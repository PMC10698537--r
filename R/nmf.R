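## Non-negative matrix factorization with NNDSVD initialization and HALS
## (hierarchical alternating least squares) coordinate-descent updates under
## the Frobenius loss. Transform of unseen rows solves non-negative least
## squares against the frozen component matrix with the same updates.

## NNDSVD initialization (positive sections of the leading singular vectors).
nndsvdInit <- function(X, rank, seed = 1L) {
  n <- nrow(X); m <- ncol(X)
  sv <- svd(X, nu = min(rank, min(n, m)), nv = min(rank, min(n, m)))
  W <- matrix(0, n, rank); H <- matrix(0, rank, m)
  r0 <- min(rank, length(sv$d))
  W[, 1] <- sqrt(sv$d[1]) * abs(sv$u[, 1])
  H[1, ] <- sqrt(sv$d[1]) * abs(sv$v[, 1])
  if (r0 >= 2) for (j in 2:r0) {
    x <- sv$u[, j]; y <- sv$v[, j]
    xp <- pmax(x, 0); xn <- pmax(-x, 0)
    yp <- pmax(y, 0); yn <- pmax(-y, 0)
    npx <- sqrt(sum(xp^2)); nnx <- sqrt(sum(xn^2))
    npy <- sqrt(sum(yp^2)); nny <- sqrt(sum(yn^2))
    if (npx * npy >= nnx * nny) {
      u <- if (npx > 0) xp / npx else xp
      v <- if (npy > 0) yp / npy else yp
      sig <- npx * npy
    } else {
      u <- if (nnx > 0) xn / nnx else xn
      v <- if (nny > 0) yn / nny else yn
      sig <- nnx * nny
    }
    W[, j] <- sqrt(sv$d[j] * sig) * u
    H[j, ] <- sqrt(sv$d[j] * sig) * v
  }
  if (rank > r0) {
    fill <- withSeed(subSeed(seed, 61L),
                     mean(X) * matrix(stats::runif((rank - r0) * (n + m)),
                                      nrow = rank - r0))
    W[, (r0 + 1):rank] <- t(fill[, seq_len(n), drop = FALSE])
    H[(r0 + 1):rank, ] <- fill[, n + seq_len(m), drop = FALSE]
  }
  list(W = W, H = H)
}

halsUpdateW <- function(X, W, H, eps = 1e-12) {
  HHt <- tcrossprod(H)
  XHt <- tcrossprod(X, H)
  for (j in seq_len(nrow(H))) {
    denom <- max(HHt[j, j], eps)
    W[, j] <- pmax(0, W[, j] + (XHt[, j] - W %*% HHt[, j]) / denom)
  }
  W
}

halsUpdateH <- function(X, W, H, eps = 1e-12) {
  WtW <- crossprod(W)
  WtX <- crossprod(W, X)
  for (j in seq_len(nrow(H))) {
    denom <- max(WtW[j, j], eps)
    H[j, ] <- pmax(0, H[j, ] + (WtX[j, ] - WtW[j, ] %*% H) / denom)
  }
  H
}

#' Non-negative matrix factorization (Frobenius loss)
#'
#' Factorizes a non-negative matrix `X` (rows = slides) into `W %*% H`
#' with `rank` components, using NNDSVD initialization and HALS coordinate
#' descent. Deterministic for a given seed.
#'
#' @param X non-negative numeric matrix.
#' @param rank number of components (<= min(dim(X))).
#' @param maxIter maximum alternating sweeps.
#' @param tol relative change in reconstruction error for convergence.
#' @param seed seed used only to fill components beyond the available
#'   singular vectors.
#' @return List with `W` (rows x rank), `H` (rank x cols) and `loss`
#'   (final Frobenius reconstruction error).
#' @export
nmfFit <- function(X, rank, maxIter = 200L, tol = 1e-7, seed = 1L) {
  X <- as.matrix(X)
  stopIfNot(all(X >= 0), "NMF requires a non-negative input matrix")
  stopIfNot(isCount(rank) && rank <= min(dim(X)),
            "rank must be a positive integer <= min(dim(X))")
  init <- nndsvdInit(X, rank, seed)
  W <- init$W; H <- init$H
  prev <- Inf
  for (it in seq_len(maxIter)) {
    W <- halsUpdateW(X, W, H)
    H <- halsUpdateH(X, W, H)
    err <- sqrt(sum((X - W %*% H)^2))
    if (is.finite(prev) && abs(prev - err) <= tol * max(prev, 1e-12)) break
    prev <- err
  }
  list(W = W, H = H, loss = sqrt(sum((X - W %*% H)^2)))
}

#' Project new non-negative rows onto frozen NMF components
#'
#' Solves `min_{W >= 0} ||X - W H||_F` for the given component matrix `H`
#' by HALS updates on `W` only; the components are never modified.
#'
#' @param X non-negative matrix with the same column space as the training
#'   data.
#' @param H frozen component matrix from [nmfFit()].
#' @param maxIter maximum update sweeps.
#' @return Matrix `W` (rows x rank).
#' @export
nmfTransform <- function(X, H, maxIter = 200L) {
  X <- as.matrix(X)
  stopIfNot(all(X >= 0), "NMF transform requires non-negative input")
  stopIfNot(ncol(X) == ncol(H), "column mismatch with component matrix")
  W <- matrix(1e-3, nrow(X), nrow(H))
  prev <- Inf
  for (it in seq_len(maxIter)) {
    W <- halsUpdateW(X, W, H)
    err <- sqrt(sum((X - W %*% H)^2))
    if (is.finite(prev) && abs(prev - err) <= 1e-9 * max(prev, 1e-12)) break
    prev <- err
  }
  W
}
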