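# Consolidation baselines run on the same BNN: elastic weight consolidation
# (EWC) with a Fisher-diagonal importance computed on the binary weights, the
# random-importance control (same importances, shuffled), and a path-integral
# (synaptic-intelligence-style) importance.

#' Empirical Fisher-diagonal importance map
#'
#' Estimates per-synapse importance as the mean, over sampled training
#' batches, of the squared gradient of the batch negative log-likelihood with
#' respect to the binary weight (gradient via the straight-through backward
#' pass). Anchors are the current binary weights. Both the importances and
#' the anchors depend only on the binary weight values, never on hidden
#' magnitudes.
#'
#' @param net a trained `bnn` model.
#' @param x,y training data of the just-finished task.
#' @param n_batches number of sampled batches (default 100).
#' @param batch_size examples per sampled batch.
#' @param bn_slot batch-norm slot of the task.
#' @param seed optional seed for the batch sampling.
#' @return an `importance_map` with per-layer `F` (>= 0) and `anchor` (+-1).
#' @export
fisher_diag <- function(net, x, y, n_batches = 100L, batch_size = 32L,
                        bn_slot = 1L, seed = NULL) {
  if (is.null(x) || nrow(x) == 0L) stop("empty data iterator")
  draw <- function() {
    F_acc <- lapply(net$layers, function(l) l$W_h * 0)
    for (b in seq_len(n_batches)) {
      idx <- sample.int(nrow(x), min(batch_size, nrow(x)))
      fw <- bnn_forward(net, x[idx, , drop = FALSE], bn_slot = bn_slot,
                        training = TRUE)
      ce <- softmax_cross_entropy(fw$scores, y[idx])
      gr <- bnn_backward(net, fw$cache, ce$dscores, bn_slot = bn_slot)
      for (l in seq_along(F_acc))
        F_acc[[l]] <- F_acc[[l]] + gr$dW[[l]]^2
    }
    lapply(F_acc, function(f) f / n_batches)
  }
  F_hat <- if (is.null(seed)) draw() else with_seed(seed, draw())
  structure(list(F = F_hat,
                 anchor = lapply(net$layers, `[[`, "W_b"),
                 n_batches = n_batches),
            class = "importance_map")
}

#' EWC quadratic penalty
#'
#' `(lambda/2) * sum_tasks sum_i F_i (W^b_i - W^b*_i)^2`, accumulated over
#' one (importance, anchor) pair per completed task. On binary weights each
#' term is 0 (unflipped) or `2 * lambda * F_i` (flipped, since
#' `(-1-1)^2 = 4`).
#'
#' @param net a `bnn` model.
#' @param maps list of [fisher_diag()] importance maps (one per past task).
#' @param lambda regularization strength (default 5e3).
#' @return scalar penalty; 0 with a warning when `maps` is empty.
#' @export
ewc_penalty <- function(net, maps, lambda = 5e3) {
  if (length(maps) == 0L) {
    warning("no importance maps: EWC penalty is 0")
    return(0)
  }
  tot <- 0
  for (mp in maps) {
    for (l in seq_along(net$layers)) {
      d <- net$layers[[l]]$W_b - mp$anchor[[l]]
      tot <- tot + sum(mp$F[[l]] * d^2)
    }
  }
  lambda / 2 * tot
}

#' Gradient of the EWC penalty with respect to the hidden weights
#'
#' `lambda * F_i * (W^b_i - W^b*_i)` per map, passed to the hidden weights
#' through an identity straight-through estimator on the binarization. Add
#' the result to the task gradients `dW` before the optimizer step.
#'
#' @inheritParams ewc_penalty
#' @return list of per-layer gradient arrays.
#' @export
ewc_gradient <- function(net, maps, lambda = 5e3) {
  g <- lapply(net$layers, function(l) l$W_h * 0)
  for (mp in maps) {
    for (l in seq_along(g)) {
      g[[l]] <- g[[l]] +
        lambda * mp$F[[l]] * (net$layers[[l]]$W_b - mp$anchor[[l]])
    }
  }
  g
}

#' Shuffle an importance map (random-consolidation control)
#'
#' Permutes the importance factors uniformly at random across all synapses
#' of the network; the multiset of importances and the anchors are preserved
#' exactly. Same seed, same permutation.
#'
#' @param map an `importance_map`.
#' @param seed permutation seed.
#' @return the shuffled `importance_map`.
#' @export
shuffle_importance <- function(map, seed) {
  sizes <- vapply(map$F, length, 0L)
  pool <- unlist(lapply(map$F, as.numeric), use.names = FALSE)
  pool <- with_seed(seed, sample(pool))
  ends <- cumsum(sizes)
  map$F <- lapply(seq_along(map$F), function(l) {
    out <- pool[(ends[l] - sizes[l] + 1L):ends[l]]
    shp <- dim(map$F[[l]])
    if (!is.null(shp)) dim(out) <- shp
    out
  })
  map
}

#' Path-integral (synaptic-intelligence-style) importance tracker
#'
#' Accumulates, per synapse, the running sum of `-gradient * parameter
#' change` along the training trajectory; [pi_finalize()] normalizes by the
#' squared total displacement plus a damping term. Natural for the
#' full-precision control network; on a BNN the binary-weight displacement is
#' in \{0, +-2\} so the importance concentrates on flipped synapses (the
#' negative-result adaptation).
#'
#' @param net model whose tracked weights initialize the reference point.
#' @param use `"hidden"` to track hidden weights (full-precision path) or
#'   `"binary"` to track binary weights (BNN adaptation).
#' @return a `pi_tracker`.
#' @export
pi_init <- function(net, use = c("hidden", "binary")) {
  use <- match.arg(use)
  w <- weights_of(net, use)
  structure(list(use = use, omega = lapply(w, function(x) x * 0),
                 w_prev = w, w_start = w),
            class = "pi_tracker")
}

weights_of <- function(net, use) {
  lapply(net$layers, function(l) if (use == "hidden") l$W_h else l$W_b)
}

#' Accumulate one step of the path integral
#' @param tr a [pi_init()] tracker.
#' @param grads per-layer loss gradients at the step (the `dW` list).
#' @param net the model after the step.
#' @return the updated tracker.
#' @export
pi_update <- function(tr, grads, net) {
  w_new <- weights_of(net, tr$use)
  for (l in seq_along(tr$omega)) {
    tr$omega[[l]] <- tr$omega[[l]] - grads[[l]] * (w_new[[l]] - tr$w_prev[[l]])
  }
  tr$w_prev <- w_new
  tr
}

#' Finalize a path-integral importance map
#' @param tr tracker after the task's training steps.
#' @param net the model at task end (provides anchors).
#' @param damping positive constant guarding the denominator against zero
#'   displacement.
#' @return an `importance_map` with `F = omega / (displacement^2 + damping)`.
#' @export
pi_finalize <- function(tr, net, damping = 0.1) {
  if (damping <= 0) stop("`damping` must be positive")
  w_end <- weights_of(net, tr$use)
  F_hat <- lapply(seq_along(tr$omega), function(l) {
    disp <- w_end[[l]] - tr$w_start[[l]]
    tr$omega[[l]] / (disp^2 + damping)
  })
  structure(list(F = F_hat, anchor = lapply(net$layers, `[[`, "W_b"),
                 n_batches = NA_integer_),
            class = "importance_map")
}
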