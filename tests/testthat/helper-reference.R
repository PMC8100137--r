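# Independent reference implementation of plain Adam training of a
# binarized network (no batch norm), written directly from the declared
# conventions: hidden weights W, binary weights sign(W) with sign(0) = +1,
# sign activation on hidden layers with straight-through gradient inside
# |pre-activation| <= 1, softmax cross-entropy, and textbook Adam with bias
# correction. It shares no code with the package optimizer and serves as
# the oracle for the m = 0 reduction.

ref_sign <- function(w) ifelse(w >= 0, 1, -1)

ref_forward <- function(W_hidden, x) {
  L <- length(W_hidden)
  acts <- vector("list", L + 1L)
  pre <- vector("list", L)
  acts[[1]] <- x
  for (l in seq_len(L)) {
    pre[[l]] <- acts[[l]] %*% ref_sign(W_hidden[[l]])
    acts[[l + 1L]] <- if (l < L) ref_sign(pre[[l]]) else pre[[l]]
  }
  list(acts = acts, pre = pre, scores = acts[[L + 1L]])
}

ref_loss_grad <- function(scores, y) {
  n <- nrow(scores)
  z <- scores - apply(scores, 1L, max)
  p <- exp(z) / rowSums(exp(z))
  hot <- matrix(0, n, ncol(scores))
  hot[cbind(seq_len(n), y)] <- 1
  (p - hot) / n
}

ref_backward <- function(W_hidden, fw, dscores) {
  L <- length(W_hidden)
  dW <- vector("list", L)
  delta <- dscores
  for (l in rev(seq_len(L))) {
    if (l < L) delta <- delta * (abs(fw$pre[[l]]) <= 1)
    dW[[l]] <- t(fw$acts[[l]]) %*% delta
    if (l > 1L) delta <- delta %*% t(ref_sign(W_hidden[[l]]))
  }
  dW
}

# full-batch plain Adam-BNN training; returns the hidden weights after
# `steps` updates
ref_adam_bnn <- function(W_init, x, y, steps, lr = 1e-3, beta1 = 0.9,
                         beta2 = 0.999, eps = 1e-8) {
  W <- W_init
  mom1 <- lapply(W, function(w) w * 0)
  mom2 <- lapply(W, function(w) w * 0)
  for (t in seq_len(steps)) {
    fw <- ref_forward(W, x)
    dW <- ref_backward(W, fw, ref_loss_grad(fw$scores, y))
    for (l in seq_along(W)) {
      mom1[[l]] <- beta1 * mom1[[l]] + (1 - beta1) * dW[[l]]
      mom2[[l]] <- beta2 * mom2[[l]] + (1 - beta2) * dW[[l]]^2
      upd <- (mom1[[l]] / (1 - beta1^t)) /
        (sqrt(mom2[[l]] / (1 - beta2^t)) + eps)
      W[[l]] <- W[[l]] - lr * upd
    }
  }
  W
}
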