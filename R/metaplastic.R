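# The metaplastic optimizer: Adam-based updates in which any update pushing a
# hidden weight back toward zero (i.e. opposing the current binary sign) is
# attenuated by f_meta(m, W^h). Updates away from zero, and all batch-norm
# updates, are applied unattenuated. With m = 0 the rule reduces exactly to
# plain Adam training of a BNN.

#' Metaplastic attenuation function
#'
#' `f_meta(m, w) = 1 - tanh^2(m * w)`. Equal to 1 for `m = 0` or `w = 0`,
#' even in `w`, strictly positive, decaying exponentially to 0 as `|w|` grows;
#' `m` sets how fast binary weights consolidate.
#'
#' @param m nonnegative consolidation strength (scalar).
#' @param w hidden weight value(s).
#' @return attenuation factor(s) in `(0, 1]`, same shape as `w`.
#' @examples
#' f_meta(0, 3)    # 1
#' f_meta(1.35, 0) # 1
#' f_meta(1, 2)    # ~0.0707
#' @export
f_meta <- function(m, w) {
  if (length(m) != 1L || !is.finite(m) || m < 0)
    stop("`m` must be a single nonnegative number")
  # sech^2(m w), evaluated as 4 e^{-2|mw|} / (1 + e^{-2|mw|})^2: identical to
  # 1 - tanh^2 but stays strictly positive up to |m w| ~ 372 instead of
  # underflowing to 0 near |m w| ~ 19
  e <- exp(-2 * abs(m * w))
  4 * e / (1 + e)^2
}

#' Hard-zero metaplastic attenuation
#'
#' Equals [f_meta()] for `|w|` below `threshold` and is exactly 0 at or above
#' it: consolidated weights beyond the threshold can never be flipped by the
#' attenuated branch. As `threshold -> Inf` the smooth variant is recovered.
#'
#' @inheritParams f_meta
#' @param threshold positive cutoff on `|w|`.
#' @return attenuation factor(s) in `[0, 1]`.
#' @export
f_meta_hard_zero <- function(m, w, threshold) {
  if (missing(threshold) || is.null(threshold) || !is.finite(threshold) ||
      threshold <= 0)
    stop("hard-zero variant requires a finite positive `threshold`")
  out <- f_meta(m, w)
  out[abs(w) >= threshold] <- 0
  out
}

#' Default hard-zero threshold
#'
#' The hidden-weight magnitude at which the smooth attenuation drops below
#' `floor` (default 1e-3), so the hard-zero variant only differs from the
#' smooth one in its saturated tail.
#'
#' @param m consolidation strength (> 0).
#' @param floor attenuation level defining the cutoff.
#' @export
hard_zero_threshold <- function(m, floor = 1e-3) {
  if (m <= 0) stop("threshold defined for m > 0")
  atanh(sqrt(1 - floor)) / m
}

#' Learning-rate decay schedule across tasks
#'
#' The baseline control schedule: the initial learning rate is divided by ten
#' for each new task.
#'
#' @param task_index 0-based task index.
#' @param base_lr learning rate for the first task.
#' @return `base_lr * 10^(-task_index)`.
#' @export
lr_decay_schedule <- function(task_index, base_lr) {
  if (any(task_index < 0)) stop("task_index must be >= 0")
  base_lr * 10^(-task_index)
}

#' Optimizer configuration
#'
#' @param m metaplasticity parameter (>= 0; 0 recovers plain Adam-BNN
#'   training).
#' @param variant `"smooth"` (default) or `"hard_zero"`.
#' @param threshold hard-zero cutoff; defaults to [hard_zero_threshold()] of
#'   the configured `m` when the hard-zero variant is selected.
#' @param lr base learning rate.
#' @param beta1,beta2 Adam moment decay rates.
#' @param eps Adam epsilon.
#' @param lr_decay_per_task divide the learning rate by 10 for each new task
#'   (the LR-decay control baseline).
#' @param synapse `"scalar"` for the ordinary hidden weight, `"chain"` for
#'   the multi-timescale chain synapse (see [chain_synapse()]).
#' @param chain_n,chain_gain chain depth and flow-modulation gain when
#'   `synapse = "chain"`.
#' @return a `meta_config` list.
#' @export
meta_config <- function(m = 0, variant = c("smooth", "hard_zero"),
                        threshold = NULL, lr = 1e-3,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                        lr_decay_per_task = FALSE,
                        synapse = c("scalar", "chain"),
                        chain_n = 4L, chain_gain = 1) {
  variant <- match.arg(variant)
  synapse <- match.arg(synapse)
  if (m < 0) stop("`m` must be nonnegative")
  if (variant == "hard_zero" && is.null(threshold)) {
    if (m <= 0) stop("hard-zero variant needs m > 0 or an explicit threshold")
    threshold <- hard_zero_threshold(m)
  }
  structure(list(m = m, variant = variant, threshold = threshold, lr = lr,
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 lr_decay_per_task = isTRUE(lr_decay_per_task),
                 synapse = synapse, chain_n = as.integer(chain_n),
                 chain_gain = chain_gain),
            class = "meta_config")
}

#' Initialize Adam optimizer state
#'
#' First/second moment accumulators for every weight tensor (`U_W`) and, per
#' batch-norm slot, for the scale/shift parameters (`U_theta`), plus the step
#' counter.
#'
#' @param net a `bnn` model.
#' @param cfg a [meta_config()].
#' @return an `adam_state` object.
#' @export
adam_init <- function(net, cfg = meta_config()) {
  W <- lapply(net$layers, function(l)
    list(m = l$W_h * 0, v = l$W_h * 0))
  chain <- NULL
  if (cfg$synapse == "chain") {
    chain <- lapply(net$layers, function(l) {
      syn <- chain_synapse(n = cfg$chain_n, gain = cfg$chain_gain,
                           shape_like = l$W_h)
      syn$u[[1]] <- l$W_h
      syn
    })
  }
  structure(list(t = 0L, W = W, bn = list(), chain = chain,
                 flips_last = 0L), class = "adam_state")
}

ensure_bn_opt <- function(opt, net, slot) {
  while (length(opt$bn) < slot) {
    s <- length(opt$bn) + 1L
    opt$bn[[s]] <- lapply(net$spec$layers, function(ly) {
      n <- layer_n_units(ly)
      list(mg = rep(0, n), vg = rep(0, n), mb = rep(0, n), vb = rep(0, n))
    })
  }
  opt
}

adam_direction <- function(st, g, cfg, t) {
  st$m <- cfg$beta1 * st$m + (1 - cfg$beta1) * g
  st$v <- cfg$beta2 * st$v + (1 - cfg$beta2) * g^2
  mhat <- st$m / (1 - cfg$beta1^t)
  vhat <- st$v / (1 - cfg$beta2^t)
  list(st = st, U = mhat / (sqrt(vhat) + cfg$eps))
}

#' One metaplastic optimizer step
#'
#' Computes the Adam composite update `U_W` from the weight gradients, then
#' applies, elementwise: if `U_W * W^b > 0` (the update would shrink `|W^h|`,
#' opposing the current binary sign) the hidden weight moves by
#' `-lr * U_W * f_meta(m, W^h)`; otherwise by the unattenuated `-lr * U_W`.
#' Batch-norm parameters are updated unattenuated, and the binary weights are
#' refreshed from the new hidden signs. Ties `U_W * W^b = 0` take the
#' unattenuated branch.
#'
#' @param net a `bnn` model.
#' @param opt optimizer state from [adam_init()].
#' @param grads gradients from [bnn_backward()] (computed with binary
#'   weights), optionally with an EWC term already added to `dW`.
#' @param cfg a [meta_config()].
#' @param lr learning rate for this step (defaults to `cfg$lr`; pass the
#'   decayed rate when using the LR-decay schedule).
#' @param bn_slot batch-norm slot whose parameters receive the `U_theta`
#'   update.
#' @return list with updated `net` and `opt`; `opt$flips_last` counts binary
#'   weights that changed sign in this step.
#' @export
metaplastic_step <- function(net, opt, grads, cfg, lr = cfg$lr, bn_slot = 1L) {
  opt$t <- opt$t + 1L
  t <- opt$t
  flips <- 0L
  for (l in seq_along(net$layers)) {
    g <- grads$dW[[l]]
    Wh <- net$layers[[l]]$W_h
    if (!identical(dim(g) %||% length(g), dim(Wh) %||% length(Wh)))
      stop(sprintf("gradient/weight shape mismatch in layer %d", l))
    ad <- adam_direction(opt$W[[l]], g, cfg, t)
    opt$W[[l]] <- ad$st
    U <- ad$U
    Wb <- net$layers[[l]]$W_b
    Wh_new <- Wh - lr * U
    if (cfg$m > 0) {
      # attenuate only where the update opposes the current binary sign
      oppose <- which((U * Wb) > 0)
      if (length(oppose)) {
        wo <- Wh[oppose]
        att <- if (cfg$variant == "smooth") f_meta(cfg$m, wo)
               else f_meta_hard_zero(cfg$m, wo, cfg$threshold)
        Wh_new[oppose] <- wo - lr * U[oppose] * att
      }
    }
    if (cfg$synapse == "chain") {
      syn <- opt$chain[[l]]
      syn <- chain_step(syn, du1 = Wh_new - syn$u[[1]])
      opt$chain[[l]] <- syn
      Wh_new <- syn$u[[1]]
    }
    Wb_new <- binarize(Wh_new)
    flips <- flips + sum(Wb_new != Wb)
    net$layers[[l]]$W_h <- Wh_new
    net$layers[[l]]$W_b <- Wb_new
  }
  if (net$spec$use_bn && !is.null(grads$dgamma[[1]])) {
    opt <- ensure_bn_opt(opt, net, bn_slot)
    for (l in seq_along(net$layers)) {
      st <- opt$bn[[bn_slot]][[l]]
      bn <- net$bn[[bn_slot]][[l]]
      st$mg <- cfg$beta1 * st$mg + (1 - cfg$beta1) * grads$dgamma[[l]]
      st$vg <- cfg$beta2 * st$vg + (1 - cfg$beta2) * grads$dgamma[[l]]^2
      st$mb <- cfg$beta1 * st$mb + (1 - cfg$beta1) * grads$dbeta[[l]]
      st$vb <- cfg$beta2 * st$vb + (1 - cfg$beta2) * grads$dbeta[[l]]^2
      Ug <- (st$mg / (1 - cfg$beta1^t)) / (sqrt(st$vg / (1 - cfg$beta2^t)) + cfg$eps)
      Ub <- (st$mb / (1 - cfg$beta1^t)) / (sqrt(st$vb / (1 - cfg$beta2^t)) + cfg$eps)
      bn$gamma <- bn$gamma - lr * Ug
      bn$beta <- bn$beta - lr * Ub
      opt$bn[[bn_slot]][[l]] <- st
      net$bn[[bn_slot]][[l]] <- bn
    }
  }
  opt$flips_last <- flips
  list(net = net, opt = opt)
}
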