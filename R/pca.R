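#' Fit a per-block PCA compression model
#'
#' The linear baseline: the top-`k` principal directions of the centered
#' training block.  Centering uses training means only; held-out samples
#' are centered with the same means at reconstruction time.
#'
#' @param train_dosages numeric training submatrix (samples x SNPs).
#' @param k latent dimension, `k <= min(n_train - 1, n_snps)`.
#' @param block_id label carried into error messages and reports.
#' @return a list of class `pca_block_model` with `basis` (SNPs x k,
#'   orthonormal), `center`, `k`, `block_id`.
#' @export
fit_pca <- function(train_dosages, k, block_id = "block") {
  X <- as.matrix(train_dosages)
  storage.mode(X) <- "double"
  k <- as.integer(k)
  if (k < 1L || k > ncol(X) || k > nrow(X) - 1L) {
    abort(sprintf(
      "k = %d out of range for a %d x %d block (need 1 <= k <= min(n-1, p))",
      k, nrow(X), ncol(X)))
  }
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  basis <- pc$rotation[, seq_len(k), drop = FALSE]
  structure(list(basis = basis, center = pc$center, k = k,
                 block_id = block_id),
            class = "pca_block_model")
}

#' Reconstruct dosages from a PCA model
#'
#' Projects (training-mean-centered) samples onto the stored basis and
#' back, re-adds the center, and clips to `[0, 2]` so PCA reconstructions
#' share the autoencoder's prediction domain before rounding (set
#' `clip = FALSE` for the raw linear reconstruction).
#'
#' @param m a [fit_pca()] model.
#' @param dosages matrix with the block's SNP columns.
#' @param clip clip reconstructions into `[0, 2]` (default `TRUE`).
#' @return a real matrix of the same shape as `dosages`.
#' @export
pca_reconstruct <- function(m, dosages, clip = TRUE) {
  stopifnot(inherits(m, "pca_block_model"))
  X <- as.matrix(dosages)
  storage.mode(X) <- "double"
  if (ncol(X) != nrow(m$basis)) {
    abort(sprintf("block '%s': input has %d columns, model expects %d",
                  m$block_id, ncol(X), nrow(m$basis)))
  }
  Xc <- sweep(X, 2L, m$center, "-")
  scores <- Xc %*% m$basis
  rec <- sweep(scores %*% t(m$basis), 2L, m$center, "+")
  if (clip) rec <- pmin(pmax(rec, 0), 2)
  rec
}

#' Project samples onto a PCA model's latent space
#'
#' @inheritParams pca_reconstruct
#' @return an `n_samples x k` score matrix.
#' @export
pca_encode <- function(m, dosages) {
  stopifnot(inherits(m, "pca_block_model"))
  X <- as.matrix(dosages)
  storage.mode(X) <- "double"
  sweep(X, 2L, m$center, "-") %*% m$basis
}
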