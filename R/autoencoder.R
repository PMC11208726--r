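#' Autoencoder architecture specification
#'
#' An autoencoder is fully determined by four numbers: the block width
#' (`input_dim`), the encoder/decoder depth (`hl` hidden layers on each
#' side), the bottleneck width (`bn`), and the `shape` of the width taper.
#' The taper exponent `p` is 0 for `rectangular` (all non-bottleneck layers
#' as wide as the input) and 0.5 for `elliptic`.  The network has
#' `2*hl + 3` layers in total.
#'
#' @param input_dim number of SNPs in the block (>= 1).
#' @param hl hidden layers per side (>= 1).
#' @param bn bottleneck width (1 <= bn <= input_dim).
#' @param shape `"elliptic"` or `"rectangular"`.
#' @return a list of class `architecture_spec`.
#' @export
architecture_spec <- function(input_dim, hl = 4L, bn = 3L,
                              shape = c("elliptic", "rectangular")) {
  shape <- match.arg(shape)
  input_dim <- as.integer(input_dim); hl <- as.integer(hl); bn <- as.integer(bn)
  if (input_dim < 1L) abort("input_dim must be >= 1")
  if (hl < 1L) abort("hl must be >= 1")
  if (bn < 1L) abort("bn must be >= 1")
  if (bn > input_dim) abort("bn must not exceed input_dim")
  structure(list(input_dim = input_dim, hl = hl, bn = bn, shape = shape,
                 p = if (shape == "elliptic") 0.5 else 0),
            class = "architecture_spec")
}

#' Layer width profile of an autoencoder
#'
#' Widths for layers `l = -(hl+1), ..., 0, ..., hl+1`:
#' `n(l) = bn + (input_dim - bn) * (|l| / (hl + 1))^p`, rounded to the
#' nearest integer (halves away from zero).  The boundary layers are the
#' input dimension exactly and the bottleneck (`l = 0`) is `bn` exactly.
#' The profile is symmetric and, for the elliptic shape, non-increasing
#' from the input to the bottleneck.
#'
#' @param spec an [architecture_spec()].
#' @return an integer vector of length `2*hl + 3`.
#' @export
#' @examples
#' layer_widths(architecture_spec(10, hl = 4, bn = 3, shape = "elliptic"))
layer_widths <- function(spec) {
  stopifnot(inherits(spec, "architecture_spec"))
  ls <- seq.int(-(spec$hl + 1L), spec$hl + 1L)
  w <- vapply(ls, function(l) {
    al <- abs(l)
    if (al == 0L) return(as.numeric(spec$bn))
    if (al == spec$hl + 1L) return(as.numeric(spec$input_dim))
    round_half_away(spec$bn +
                      (spec$input_dim - spec$bn) * (al / (spec$hl + 1))^spec$p)
  }, numeric(1))
  as.integer(w)
}

#' Output activation mapping reals into the dosage range
#'
#' `r(x) = tanh(x) + 1`: strictly increasing, symmetric about
#' `r(0) = 1`, with open range `(0, 2)` matching the recoded dosage values.
#'
#' @param x numeric vector.
#' @return numeric vector in `(0, 2)`.
#' @export
output_activation <- function(x) tanh(x) + 1

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)

#' Training recipe for per-block autoencoders
#'
#' Fixed standardized recipe: 50 epochs, batch size 32, Adam with learning
#' rate 1e-4, mean-squared-error loss on raw dosage inputs, leaky-ReLU
#' hidden activations and He-uniform weight initialization.  All fields can
#' be overridden (e.g. fewer epochs for quick experiments).
#'
#' @param epochs training passes over the data.
#' @param batch_size minibatch size.
#' @param learning_rate Adam step size.
#' @param leaky_slope negative-part slope of the hidden activation.
#' @param beta1,beta2,epsilon Adam moment parameters.
#' @param seed integer seed controlling initialization and shuffling.
#' @return a list of class `train_recipe`.
#' @export
train_recipe <- function(epochs = 50L, batch_size = 32L,
                         learning_rate = 1e-4, leaky_slope = 0.01,
                         beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                         seed = 1L) {
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, leaky_slope = leaky_slope,
                 beta1 = beta1, beta2 = beta2, epsilon = epsilon,
                 seed = as.integer(seed)),
            class = "train_recipe")
}

#' Build an untrained per-block autoencoder
#'
#' Dense layers with the [layer_widths()] profile, leaky-ReLU on every
#' layer except the output, which uses [output_activation()].  Weights are
#' He-uniform samples (`U(-sqrt(6/fan_in), sqrt(6/fan_in))`) drawn from
#' `recipe$seed`; biases start at zero.  The same seed yields identical
#' initial weights.
#'
#' @param spec an [architecture_spec()].
#' @param recipe a [train_recipe()].
#' @param seed optional override of `recipe$seed` for initialization.
#' @return a list of class `autoencoder` with elements `spec`, `widths`,
#'   `W` (weight matrices), `b` (bias vectors).
#' @export
build_autoencoder <- function(spec, recipe = train_recipe(), seed = NULL) {
  widths <- layer_widths(spec)
  nlayers <- length(widths) - 1L
  seed <- seed %||% recipe$seed
  W <- vector("list", nlayers)
  b <- vector("list", nlayers)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  for (k in seq_len(nlayers)) {
    fan_in <- widths[k]
    lim <- sqrt(6 / fan_in)
    W[[k]] <- matrix(runif(fan_in * widths[k + 1L], -lim, lim),
                     nrow = fan_in)
    b[[k]] <- rep(0, widths[k + 1L])
  }
  structure(list(spec = spec, widths = widths, W = W, b = b),
            class = "autoencoder")
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(value) {
  if (is.null(value)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", value, envir = globalenv())
  }
  invisible(value)
}

# Forward pass; returns the activation list (A[[1]] = input).
ae_forward <- function(net, X, slope) {
  L <- length(net$W)
  A <- vector("list", L + 1L)
  A[[1L]] <- X
  for (k in seq_len(L)) {
    Z <- A[[k]] %*% net$W[[k]]
    Z <- sweep(Z, 2L, net$b[[k]], "+")
    A[[k + 1L]] <- if (k < L) leaky_relu(Z, slope) else output_activation(Z)
  }
  A
}

#' Train an autoencoder on one haplotype block
#'
#' Minibatch Adam on the mean-squared reconstruction error of raw dosage
#' values, for exactly `recipe$epochs` passes with `recipe$batch_size`
#' samples per batch.  Samples are reshuffled every epoch with a stream
#' derived from `(recipe$seed, block_id)`, so results are reproducible and
#' independent of the order in which blocks are trained.
#'
#' @param net an [build_autoencoder()] network (or an [architecture_spec()],
#'   in which case the network is built first).
#' @param dosages numeric matrix (samples x SNPs) with entries in
#'   `{0, 1, 2}`; the block submatrix.
#' @param recipe a [train_recipe()].
#' @param val_frac fraction of rows held out for validation metrics
#'   (ignored when `val_idx` is given).
#' @param val_idx explicit validation row indices.
#' @param block_id label used in messages and seed derivation.
#' @return an object of class `trained_block_model`: the trained network
#'   plus `train_mse`, `val_mse`, `train_acc`, `val_acc` and the per-epoch
#'   training-loss `history`.
#' @export
train_block <- function(net, dosages, recipe = train_recipe(),
                        val_frac = 0.2, val_idx = NULL, block_id = "block") {
  if (inherits(net, "architecture_spec")) {
    net <- build_autoencoder(net, recipe)
  }
  stopifnot(inherits(net, "autoencoder"))
  X <- as.matrix(dosages)
  storage.mode(X) <- "double"
  if (ncol(X) != net$spec$input_dim) {
    abort(sprintf("block '%s': input has %d SNPs but spec expects %d",
                  block_id, ncol(X), net$spec$input_dim))
  }
  if (ncol(X) == 1L) {
    warn(sprintf("block '%s' has a single SNP; pass-through is preferable",
                 block_id))
  }

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(derive_seed(recipe$seed, block_id))

  n <- nrow(X)
  if (is.null(val_idx) && val_frac > 0) {
    val_idx <- sample.int(n, size = max(1L, round(val_frac * n)))
  }
  train_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- X[train_idx, , drop = FALSE]
  Xval <- if (length(val_idx)) X[val_idx, , drop = FALSE] else NULL

  fit <- ae_fit(net, Xtr, recipe)
  net <- fit$net

  train_out <- reconstruct(net, Xtr, recipe)
  m_train <- snp_accuracy(train_out, Xtr)
  res <- list(
    net = net, spec = net$spec, recipe = recipe, block_id = block_id,
    history = fit$history,
    train_mse = mean((train_out - Xtr)^2),
    train_acc = m_train$overall,
    val_mse = NA_real_, val_acc = NA_real_
  )
  if (!is.null(Xval)) {
    val_out <- reconstruct(net, Xval, recipe)
    res$val_mse <- mean((val_out - Xval)^2)
    res$val_acc <- snp_accuracy(val_out, Xval)$overall
  }
  structure(res, class = "trained_block_model")
}

# The optimizer core: minibatch Adam over epochs; returns list(net, history).
ae_fit <- function(net, Xtr, recipe) {
  L <- length(net$W)
  slope <- recipe$leaky_slope
  mW <- lapply(net$W, function(w) w * 0); vW <- mW
  mb <- lapply(net$b, function(x) x * 0); vb <- mb
  t_step <- 0L
  n <- nrow(Xtr)
  history <- numeric(recipe$epochs)
  lr <- recipe$learning_rate
  b1 <- recipe$beta1; b2 <- recipe$beta2; eps <- recipe$epsilon

  for (epoch in seq_len(recipe$epochs)) {
    ord <- sample.int(n)
    starts <- seq.int(1L, n, by = recipe$batch_size)
    epoch_loss <- 0
    for (s in starts) {
      rows <- ord[s:min(s + recipe$batch_size - 1L, n)]
      B <- Xtr[rows, , drop = FALSE]
      nb <- nrow(B)

      A <- ae_forward(net, B, slope)
      Y <- A[[L + 1L]]
      err <- Y - B
      epoch_loss <- epoch_loss + sum(err^2)

      # output layer: d/dZ of tanh(Z)+1 is 1 - (Y-1)^2
      dZ <- (2 * err / (nb * ncol(B))) * (1 - (Y - 1)^2)
      for (k in L:1L) {
        gW <- crossprod(A[[k]], dZ)
        gb <- colSums(dZ)
        if (k > 1L) {
          dA <- tcrossprod(dZ, net$W[[k]])
          dZ <- dA * ifelse(A[[k]] > 0, 1, slope)
        }
        t_step_k <- t_step + 1L
        mW[[k]] <- b1 * mW[[k]] + (1 - b1) * gW
        vW[[k]] <- b2 * vW[[k]] + (1 - b2) * gW^2
        mb[[k]] <- b1 * mb[[k]] + (1 - b1) * gb
        vb[[k]] <- b2 * vb[[k]] + (1 - b2) * gb^2
        mhatW <- mW[[k]] / (1 - b1^t_step_k)
        vhatW <- vW[[k]] / (1 - b2^t_step_k)
        mhatb <- mb[[k]] / (1 - b1^t_step_k)
        vhatb <- vb[[k]] / (1 - b2^t_step_k)
        net$W[[k]] <- net$W[[k]] - lr * mhatW / (sqrt(vhatW) + eps)
        net$b[[k]] <- net$b[[k]] - lr * mhatb / (sqrt(vhatb) + eps)
      }
      t_step <- t_step + 1L
    }
    history[epoch] <- epoch_loss / (n * ncol(Xtr))
  }
  list(net = net, history = history)
}

#' Encode samples to the bottleneck representation
#'
#' Deterministic forward pass up to (and including) the bottleneck layer.
#'
#' @param m a [train_block()] result (or a raw `autoencoder`).
#' @param dosages matrix whose column count equals the spec's `input_dim`.
#' @param recipe recipe supplying the hidden activation slope.
#' @return an `n_samples x bn` embedding matrix.
#' @export
encode <- function(m, dosages, recipe = NULL) {
  net <- if (inherits(m, "trained_block_model")) m$net else m
  recipe <- recipe %||% (if (inherits(m, "trained_block_model")) m$recipe
                         else train_recipe())
  X <- as.matrix(dosages)
  if (ncol(X) != net$spec$input_dim) {
    abort(sprintf("encode: input has %d columns, spec expects %d (block '%s')",
                  ncol(X), net$spec$input_dim,
                  if (inherits(m, "trained_block_model")) m$block_id else "?"))
  }
  A <- ae_forward(net, X, recipe$leaky_slope)
  A[[net$spec$hl + 2L]]  # activation of the bottleneck layer
}

#' Reconstruct dosages through the full autoencoder
#'
#' @inheritParams encode
#' @return an `n_samples x input_dim` real matrix with entries in `(0, 2)`.
#' @export
reconstruct <- function(m, dosages, recipe = NULL) {
  net <- if (inherits(m, "trained_block_model")) m$net else m
  recipe <- recipe %||% (if (inherits(m, "trained_block_model")) m$recipe
                         else train_recipe())
  X <- as.matrix(dosages)
  if (ncol(X) != net$spec$input_dim) {
    abort(sprintf("reconstruct: input has %d columns, spec expects %d",
                  ncol(X), net$spec$input_dim))
  }
  A <- ae_forward(net, X, recipe$leaky_slope)
  A[[length(A)]]
}

#' SNP reconstruction accuracy
#'
#' Rounds predictions to the nearest integer dosage (halves upward, clamped
#' to `{0, 1, 2}`) and reports the fraction of entries matching the truth,
#' together with the accuracy restricted to each true dosage value.
#'
#' @param predicted real-valued reconstruction matrix.
#' @param truth integer dosage matrix of the same shape.
#' @return a list with `overall`, `by_dosage` (named fractions for truth
#'   0/1/2, `NA` when a dosage value is absent) and `n_by_dosage`.
#' @export
snp_accuracy <- function(predicted, truth) {
  predicted <- as.matrix(predicted); truth <- as.matrix(truth)
  if (!identical(dim(predicted), dim(truth))) {
    abort("predicted and truth must have the same shape")
  }
  rounded <- pmin(pmax(floor(predicted + 0.5), 0), 2)
  correct <- rounded == truth
  by_dosage <- vapply(0:2, function(d) {
    sel <- truth == d
    if (!any(sel)) NA_real_ else mean(correct[sel])
  }, numeric(1))
  names(by_dosage) <- as.character(0:2)
  n_by_dosage <- vapply(0:2, function(d) sum(truth == d), numeric(1))
  names(n_by_dosage) <- as.character(0:2)
  list(overall = mean(correct), by_dosage = by_dosage,
       n_by_dosage = n_by_dosage)
}

#' Compression ratio of a bottleneck
#'
#' The compressed-to-original size ratio `bn / input_dim`; chromosome-wide,
#' the same formula applies to summed dimensions.
#'
#' @param bn bottleneck width(s).
#' @param input_dim block width(s), must be positive.
#' @return `bn / input_dim`.
#' @export
#' @examples
#' compression_ratio(3, 30)
compression_ratio <- function(bn, input_dim) {
  if (any(input_dim <= 0)) abort("input_dim must be positive")
  if (any(bn < 1) || any(bn > input_dim)) {
    abort("bn must satisfy 1 <= bn <= input_dim")
  }
  bn / input_dim
}

#' @export
print.trained_block_model <- function(x, ...) {
  cat(sprintf(
    "<trained_block_model> %s: %s hl=%d bn=%d input_dim=%d\n",
    x$block_id, x$spec$shape, x$spec$hl, x$spec$bn, x$spec$input_dim
  ))
  cat(sprintf("  train MSE %.4g, acc %.4f | val MSE %.4g, acc %.4f\n",
              x$train_mse, x$train_acc, x$val_mse, x$val_acc))
  invisible(x)
}
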