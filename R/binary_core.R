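# Binarized layers, straight-through gradients, batch normalization, and the
# full-precision (tanh) control network.
#
# A BNN stores, for every synapse, a real-valued hidden weight W^h and the
# binary weight W^b = sign(W^h) actually used in the forward and backward
# passes. Only the sign is visible to inference; the magnitude of W^h is free
# to grow without bound and is what the metaplastic rule consolidates.

#' Binarize hidden weights
#'
#' Elementwise sign with the tie convention `sign(0) = +1`, so every entry of
#' the result is exactly +1 or -1.
#'
#' @param hidden numeric vector, matrix or array of hidden weights.
#' @return object of the same shape with entries in \{-1, +1\}.
#' @examples
#' binarize(c(-2.3, 0.1))  # -1 +1
#' binarize(0)             # +1
#' @export
binarize <- function(hidden) {
  if (!all(is.finite(hidden)))
    stop("binarize(): hidden weights contain non-finite values")
  b <- sign(hidden)
  b[b == 0] <- 1
  b
}

#' Specify a fully connected network
#'
#' @param sizes integer vector of layer widths including input and output,
#'   e.g. `c(784, 4096, 4096, 10)`.
#' @param kind `"binary"` for a binarized network (binary weights, sign
#'   activation) or `"real"` for the full-precision control network (real
#'   weights, tanh activation). The two differ only in those two respects.
#' @param use_bn apply batch normalization to every layer's pre-activations
#'   (including the output layer).
#' @param dropout dropout probability applied to hidden activations during
#'   training (0 disables).
#' @return a `bnn_spec` object.
#' @export
mlp_spec <- function(sizes, kind = c("binary", "real"), use_bn = TRUE,
                     dropout = 0) {
  kind <- match.arg(kind)
  if (length(sizes) < 2L || any(sizes < 1L))
    stop("`sizes` must list at least input and output widths, all >= 1")
  layers <- lapply(seq_len(length(sizes) - 1L), function(l)
    list(type = "dense", d_in = sizes[l], d_out = sizes[l + 1L],
         dropout = if (l < length(sizes) - 1L) dropout else 0))
  structure(list(layers = layers, sizes = as.integer(sizes), kind = kind,
                 activation = if (kind == "binary") "sign" else "tanh",
                 use_bn = isTRUE(use_bn)),
            class = "bnn_spec")
}

#' Specify the binary VGG-7 convolutional architecture
#'
#' Six 3x3 convolution layers of 128-128-256-256-512-512 filters (2x2 max
#' pooling after each pair), followed by two fully connected layers of 2048
#' units with dropout 0.5 and a linear classifier head. The architecture is
#' constructible (weights allocated, counted, serialized); the convolutional
#' forward pass is not implemented in this package.
#'
#' @param input_shape `c(height, width, channels)` of the input images.
#' @param n_classes number of output classes.
#' @return a `bnn_spec` object with convolutional layers.
#' @export
vgg7_spec <- function(input_shape = c(32, 32, 3), n_classes = 10) {
  filters <- c(128, 128, 256, 256, 512, 512)
  in_ch <- c(input_shape[3], filters[-length(filters)])
  conv <- lapply(seq_along(filters), function(i)
    list(type = "conv", k = 3L, c_in = in_ch[i], c_out = filters[i],
         pool_after = i %% 2L == 0L, dropout = 0))
  # three 2x2 poolings halve each spatial dimension three times
  flat <- prod(floor(input_shape[1:2] / 8)) * filters[length(filters)]
  dense_sizes <- c(flat, 2048L, 2048L, n_classes)
  dense <- lapply(1:3, function(l)
    list(type = "dense", d_in = dense_sizes[l], d_out = dense_sizes[l + 1L],
         dropout = if (l <= 2) 0.5 else 0))
  structure(list(layers = c(conv, dense), sizes = NULL, kind = "binary",
                 activation = "sign", use_bn = TRUE,
                 input_shape = input_shape),
            class = "bnn_spec")
}

layer_fan_in <- function(ly) {
  if (ly$type == "dense") ly$d_in else ly$k * ly$k * ly$c_in
}

layer_n_units <- function(ly) {
  if (ly$type == "dense") ly$d_out else ly$c_out
}

new_bn_layer <- function(n) {
  list(gamma = rep(1, n), beta = rep(0, n),
       run_mean = rep(0, n), run_var = rep(1, n))
}

#' Build a network from a specification
#'
#' Hidden weights are initialized uniform on
#' `(-1/sqrt(fan_in), +1/sqrt(fan_in))`; batch-norm scale is 1 and shift 0.
#' Initialization is reproducible from `seed` and does not disturb the
#' caller's RNG state.
#'
#' @param spec a `bnn_spec`.
#' @param seed integer seed for the weight draw.
#' @return a `bnn` model object holding per-layer hidden weights `W_h`, the
#'   binary weights `W_b = binarize(W_h)`, and batch-norm slot 1.
#' @export
build_network <- function(spec, seed) {
  if (!inherits(spec, "bnn_spec")) stop("`spec` must be a bnn_spec")
  layers <- with_seed(seed, lapply(spec$layers, function(ly) {
    fan <- layer_fan_in(ly)
    bound <- 1 / sqrt(fan)
    if (ly$type == "dense") {
      W_h <- matrix(stats::runif(ly$d_in * ly$d_out, -bound, bound),
                    ly$d_in, ly$d_out)
    } else {
      W_h <- array(stats::runif(ly$k * ly$k * ly$c_in * ly$c_out,
                                -bound, bound),
                   dim = c(ly$k, ly$k, ly$c_in, ly$c_out))
    }
    list(W_h = W_h, W_b = binarize(W_h))
  }))
  bn1 <- lapply(spec$layers, function(ly) new_bn_layer(layer_n_units(ly)))
  structure(list(spec = spec, layers = layers,
                 bn = if (spec$use_bn) list(bn1) else list(),
                 bn_eps = 1e-5, bn_momentum = 0.1, seed = seed),
            class = "bnn")
}

#' @export
print.bnn <- function(x, ...) {
  kinds <- vapply(x$spec$layers, `[[`, "", "type")
  cat(sprintf("<bnn> %s network, %d layers (%s), %s params, %d BN slot(s)\n",
              x$spec$kind, length(x$layers), paste(kinds, collapse = ","),
              format(count_params(x), big.mark = ","), length(x$bn)))
  invisible(x)
}

#' Count synaptic weights in a network
#' @param net a `bnn` model.
#' @return total number of weight parameters (batch-norm excluded).
#' @export
count_params <- function(net) {
  sum(vapply(net$layers, function(l) length(l$W_h), 0L))
}

# make sure batch-norm slot `slot` exists (task-specific BN creates one slot
# per task on demand, freshly initialized)
ensure_bn_slot <- function(net, slot) {
  if (!net$spec$use_bn) return(net)
  while (length(net$bn) < slot) {
    net$bn[[length(net$bn) + 1L]] <-
      lapply(net$spec$layers, function(ly) new_bn_layer(layer_n_units(ly)))
  }
  net
}

#' Forward pass
#'
#' Runs inference with the binary weights (or the real weights for the
#' control network). Each layer's pre-activations are batch-normalized (batch
#' statistics in training mode, running statistics otherwise) and passed
#' through the sign (binary net) or tanh (control net) activation; the final
#' layer emits real-valued class scores.
#'
#' @param net a `bnn` model.
#' @param x input batch, `n x d` matrix already scaled to `[-1, 1]`.
#' @param bn_slot which batch-norm slot to use (task-specific BN).
#' @param training use batch statistics and apply dropout; requires batch
#'   size >= 2 when batch norm is on.
#' @return list with `scores` (`n x n_classes`) and `cache` of intermediates
#'   for [bnn_backward()].
#' @export
bnn_forward <- function(net, x, bn_slot = 1L, training = FALSE) {
  spec <- net$spec
  if (any(vapply(spec$layers, `[[`, "", "type") == "conv"))
    stop("convolutional forward pass is not implemented; VGG-7 specs are constructible only")
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != spec$layers[[1]]$d_in)
    stop(sprintf("input has %d features, network expects %d",
                 ncol(x), spec$layers[[1]]$d_in))
  if (training && spec$use_bn && nrow(x) < 2L)
    stop("batch size 1 in training mode: batch variance undefined")
  if (spec$use_bn && bn_slot > length(net$bn))
    stop(sprintf("batch-norm slot %d not initialized (have %d)",
                 bn_slot, length(net$bn)))
  L <- length(net$layers)
  cache <- vector("list", L)
  A <- x
  for (l in seq_len(L)) {
    ly <- net$layers[[l]]
    W <- if (spec$kind == "binary") ly$W_b else ly$W_h
    Z <- A %*% W
    if (spec$use_bn) {
      bn <- net$bn[[bn_slot]][[l]]
      n <- nrow(Z)
      if (training) {
        mu <- colMeans(Z)
        zc <- Z - rep(mu, each = n)
        va <- colMeans(zc^2)
        invstd <- 1 / sqrt(va + net$bn_eps)
        xhat <- zc * rep(invstd, each = n)
      } else {
        mu <- bn$run_mean
        va <- NULL
        invstd <- 1 / sqrt(bn$run_var + net$bn_eps)
        xhat <- (Z - rep(bn$run_mean, each = n)) * rep(invstd, each = n)
      }
      S <- xhat * rep(bn$gamma, each = n) + rep(bn$beta, each = n)
    } else {
      S <- Z; xhat <- NULL; invstd <- NULL; mu <- NULL; va <- NULL
    }
    mask <- NULL
    if (l < L) {
      Aout <- if (spec$activation == "sign") binarize(S) else tanh(S)
      p <- spec$layers[[l]]$dropout %||% 0
      if (training && p > 0) {
        mask <- matrix(stats::runif(length(Aout)) >= p, nrow(Aout)) / (1 - p)
        Aout <- Aout * mask
      }
    } else {
      Aout <- S
    }
    cache[[l]] <- list(A = A, S = S, xhat = xhat, invstd = invstd,
                       batch_mu = mu, batch_var = va, mask = mask)
    A <- Aout
  }
  list(scores = A, cache = cache)
}

#' Backward pass
#'
#' Backpropagates a gradient on the class scores through the network.
#' Gradients with respect to weights are computed with the binary weight
#' values; the sign activation uses the straight-through estimator (identity
#' inside `|pre-activation| <= 1`, zero outside), the control network the
#' exact tanh derivative.
#'
#' @param net a `bnn` model.
#' @param cache intermediates from a training-mode [bnn_forward()] call.
#' @param dscores gradient of the loss w.r.t. the scores (`n x n_classes`).
#' @param bn_slot batch-norm slot used in the forward pass.
#' @return list with `dW` (per-layer gradients w.r.t. the weights used in the
#'   forward pass) and `dgamma`, `dbeta` (batch-norm parameter gradients).
#' @export
bnn_backward <- function(net, cache, dscores, bn_slot = 1L) {
  if (is.null(cache) || !length(cache)) stop("missing forward cache")
  spec <- net$spec
  L <- length(net$layers)
  dW <- vector("list", L); dgamma <- vector("list", L); dbeta <- vector("list", L)
  dA <- dscores
  for (l in rev(seq_len(L))) {
    cc <- cache[[l]]
    if (l < L) {
      if (!is.null(cc$mask)) dA <- dA * cc$mask
      dS <- if (spec$activation == "sign") dA * (abs(cc$S) <= 1)
            else dA * (1 - tanh(cc$S)^2)
    } else {
      dS <- dA
    }
    if (spec$use_bn) {
      bn <- net$bn[[bn_slot]][[l]]
      dgamma[[l]] <- colSums(dS * cc$xhat)
      dbeta[[l]] <- colSums(dS)
      n <- nrow(dS)
      dxhat <- dS * rep(bn$gamma, each = n)
      t1 <- colSums(dxhat)
      t2 <- colSums(dxhat * cc$xhat)
      dZ <- dxhat * n
      dZ <- dZ - rep(t1, each = n)
      dZ <- dZ - cc$xhat * rep(t2, each = n)
      dZ <- dZ * rep(cc$invstd / n, each = n)
    } else {
      dgamma[[l]] <- NULL; dbeta[[l]] <- NULL
      dZ <- dS
    }
    dW[[l]] <- crossprod(cc$A, dZ)
    if (l > 1L) {
      ly <- net$layers[[l]]
      W <- if (spec$kind == "binary") ly$W_b else ly$W_h
      dA <- tcrossprod(dZ, W)
    }
  }
  list(dW = dW, dgamma = dgamma, dbeta = dbeta)
}

# update running batch-norm statistics from a training-mode forward cache
update_bn_running <- function(net, cache, bn_slot) {
  if (!net$spec$use_bn) return(net)
  mom <- net$bn_momentum
  for (l in seq_along(net$layers)) {
    cc <- cache[[l]]
    bn <- net$bn[[bn_slot]][[l]]
    bn$run_mean <- (1 - mom) * bn$run_mean + mom * cc$batch_mu
    bn$run_var <- (1 - mom) * bn$run_var + mom * cc$batch_var
    net$bn[[bn_slot]][[l]] <- bn
  }
  net
}

#' Softmax cross-entropy loss and score gradient
#'
#' @param scores `n x K` real class scores.
#' @param y integer class labels in `1..K`.
#' @return list with `loss` (mean negative log-likelihood over the batch) and
#'   `dscores` (its gradient, `(softmax - onehot)/n`).
#' @export
softmax_cross_entropy <- function(scores, y) {
  n <- nrow(scores); K <- ncol(scores)
  if (length(y) != n) stop("labels and scores disagree on batch size")
  if (any(y < 1L | y > K)) stop("labels out of range")
  z <- scores - apply(scores, 1L, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  idx <- cbind(seq_len(n), y)
  loss <- -mean(log(pmax(p[idx], 1e-300)))
  d <- p
  d[idx] <- d[idx] - 1
  list(loss = loss, dscores = d / n, prob = p)
}

#' Predict class labels
#' @param net a `bnn` model.
#' @param x input batch.
#' @param bn_slot batch-norm slot to evaluate with.
#' @return integer labels in `1..K`.
#' @export
predict_labels <- function(net, x, bn_slot = 1L) {
  s <- bnn_forward(net, x, bn_slot = bn_slot, training = FALSE)$scores
  max.col(s, ties.method = "first")
}

#' Classification accuracy in percent
#' @inheritParams predict_labels
#' @param y true labels.
#' @return accuracy in `[0, 100]`.
#' @export
accuracy <- function(net, x, y, bn_slot = 1L) {
  100 * mean(predict_labels(net, x, bn_slot) == y)
}

#' Save a model checkpoint
#'
#' Serializes hidden weights, batch-norm slots, optimizer state and the spec
#' to an uncompressed RDS archive; `save -> load -> save` is byte-identical.
#'
#' @param net a `bnn` model.
#' @param path file path.
#' @param opt optional optimizer state to include.
#' @export
save_checkpoint <- function(net, path, opt = NULL) {
  saveRDS(list(format = "metabnn-checkpoint-1", net = net, opt = opt),
          path, compress = FALSE)
  invisible(path)
}

#' Load a model checkpoint
#' @param path file written by [save_checkpoint()].
#' @return list with `net` and `opt`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "metabnn-checkpoint-1"))
    stop("not a metabnn checkpoint")
  ck[c("net", "opt")]
}
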