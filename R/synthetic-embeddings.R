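#' Generate synthetic patch-embedding matrices with latent cluster structure
#'
#' Stands in for the per-patch feature vectors extracted after the
#' concatenation layer of a trained segmentation model. Embeddings are
#' drawn from a mixture of `nLatentClusters` isotropic Gaussians (unit
#' within-cluster standard deviation) whose centers are separated by
#' `clusterSeparation` within-cluster standard deviations. Each slide has
#' its own Dirichlet-distributed mixture weights, so slide-level
#' bag-of-visual-words histograms differ between slides; the latent labels
#' are returned so downstream clustering can be checked against ground
#' truth.
#'
#' @param nSlides number of slides.
#' @param patchesPerSlide patches (= embedding rows) per slide.
#' @param dim embedding dimensionality (>= 1).
#' @param nLatentClusters number of mixture components (>= 1).
#' @param clusterSeparation pairwise center distance in units of the
#'   within-cluster standard deviation.
#' @param seed integer RNG seed; the same seed yields identical matrices.
#' @return A list with `embeddings` (list of `patchesPerSlide x dim`
#'   matrices), `labels` (list of integer latent labels), `centers`
#'   (`nLatentClusters x dim` matrix) and `weights` (`nSlides x
#'   nLatentClusters` slide mixture weights).
#' @export
generatePatchEmbeddings <- function(nSlides, patchesPerSlide, dim,
                                    nLatentClusters, clusterSeparation = 4,
                                    seed = 1L) {
  stopIfNot(isCount(nSlides) && isCount(patchesPerSlide) && isCount(dim) &&
              isCount(nLatentClusters),
            "counts must be positive integers")
  stopIfNot(clusterSeparation >= 0, "clusterSeparation must be >= 0")
  withSeed(subSeed(seed, 11L), {
    k <- nLatentClusters
    ## centers at pairwise distance clusterSeparation (x 1 within-cluster sd)
    if (k <= dim) {
      centers <- diag(1, k, dim) * clusterSeparation / sqrt(2)
    } else {
      centers <- matrix(stats::rnorm(k * dim), k, dim)
      centers <- centers / sqrt(rowSums(centers^2)) *
        clusterSeparation / sqrt(2)
    }
    weights <- matrix(stats::rgamma(nSlides * k, shape = 1), nSlides, k)
    weights <- weights / rowSums(weights)
    labels <- vector("list", nSlides)
    embeddings <- vector("list", nSlides)
    for (s in seq_len(nSlides)) {
      lab <- sample.int(k, patchesPerSlide, replace = TRUE,
                        prob = weights[s, ])
      emb <- centers[lab, , drop = FALSE] +
        matrix(stats::rnorm(patchesPerSlide * dim), patchesPerSlide, dim)
      labels[[s]] <- lab
      embeddings[[s]] <- emb
    }
    names(embeddings) <- names(labels) <- sprintf("slide%03d", seq_len(nSlides))
    list(embeddings = embeddings, labels = labels, centers = centers,
         weights = weights)
  })
}
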