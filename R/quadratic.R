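# The quadratic binary task (QBT): the analytically tractable counterpart of
# BNN training. The loss is the quadratic L(W^b) = 1/2 (W^b - W*)' H (W^b - W*)
# over binary read-outs W^b = sign(W^h), with SPD curvature H and real optimum
# W*; hidden weights follow W^h_{t+1} = W^h_t - eta * H (sign(W^h_t) - W*).
# When a component of W* exceeds 1 in magnitude the corresponding hidden
# weight diverges linearly, and the loss increase from flipping its binary
# sign grows with the hidden weight — the formal justification for reading
# |W^h| as a consolidation importance.

#' Define a quadratic binary task
#'
#' @param H SPD curvature matrix (`d x d`), or a positive vector interpreted
#'   as a diagonal curvature.
#' @param w_star real optimum vector `W*`.
#' @param eta step size.
#' @param w0 initial hidden weights (default all zero; the `sign(0) = +1`
#'   convention applies).
#' @return a `qbt` object.
#' @export
qbt_task <- function(H, w_star, eta = 0.1, w0 = NULL) {
  if (is.matrix(H)) {
    d <- nrow(H)
    if (ncol(H) != d) stop("H must be square")
    if (max(abs(H - t(H))) > 1e-8 * max(1, max(abs(H))))
      stop("H must be symmetric")
    ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("H must be positive definite")
    diag_H <- FALSE
  } else {
    if (any(H <= 0)) stop("diagonal curvature must be positive")
    d <- length(H)
    ev <- sort(H, decreasing = TRUE)
    diag_H <- TRUE
  }
  if (length(w_star) != d) stop("dimension mismatch between H and w_star")
  if (is.null(w0)) w0 <- rep(0, d)
  if (length(w0) != d) stop("dimension mismatch between H and w0")
  structure(list(H = H, w_star = w_star, eta = eta, w_h = w0,
                 diag = diag_H, eigenvalues = ev, d = d, t = 0L),
            class = "qbt")
}

qbt_grad <- function(task, b) {
  # gradient of the loss at the binary read-out: H (b - W*)
  if (task$diag) task$H * (b - task$w_star) else drop(task$H %*% (b - task$w_star))
}

#' QBT loss at a binary configuration
#'
#' `L = 1/2 (W^b - W*)' H (W^b - W*)`.
#'
#' @param wb vector in \{-1, +1\}^d.
#' @param task a [qbt_task()].
#' @return scalar loss.
#' @export
qbt_loss <- function(wb, task) {
  if (length(wb) != task$d) stop("dimension mismatch")
  r <- wb - task$w_star
  if (task$diag) 0.5 * sum(task$H * r^2) else 0.5 * sum(r * (task$H %*% r))
}

#' One QBT optimization step
#'
#' Applies `W^h <- W^h - eta * H (sign(W^h) - W*)` and refreshes the binary
#' read-out.
#'
#' @param task a [qbt_task()].
#' @return the advanced task.
#' @export
qbt_step <- function(task) {
  b <- binarize(task$w_h)
  task$w_h <- task$w_h - task$eta * qbt_grad(task, b)
  task$t <- task$t + 1L
  task
}

#' Run a QBT trajectory and summarize divergence
#'
#' Iterates the update scheme for `T` steps, recording the hidden weights
#' every `record_every` steps, then estimates each coordinate's asymptotic
#' slope (hidden-weight units per step) by a least-squares fit over the last
#' half of the recorded trajectory. A coordinate is flagged diverging when
#' `|slope|` exceeds `tol` (default `1e-3 * eta * max eigenvalue`). In the
#' diagonal case diverging slopes approach
#' `eta * lambda_i * (|W*_i| - 1) * sign(W*_i)`.
#'
#' @param task a [qbt_task()].
#' @param T number of steps (>= 2).
#' @param record_every recording stride.
#' @param tol divergence tolerance on `|slope|`.
#' @return list with the final `task`, the recorded `trajectory`
#'   (steps x d), `steps`, and a `divergence` data.frame (slope, diverging).
#' @export
run_trajectory <- function(task, T, record_every = max(1L, T %/% 200L),
                           tol = 1e-3 * task$eta * max(task$eigenvalues)) {
  if (T < 2L) stop("T too small to fit slopes")
  rec_steps <- seq(record_every, T, by = record_every)
  traj <- matrix(NA_real_, length(rec_steps), task$d)
  r <- 1L
  for (t in seq_len(T)) {
    task <- qbt_step(task)
    if (r <= length(rec_steps) && t == rec_steps[r]) {
      traj[r, ] <- task$w_h
      r <- r + 1L
    }
  }
  half <- rec_steps >= rec_steps[length(rec_steps)] / 2
  tt <- rec_steps[half]
  slopes <- vapply(seq_len(task$d), function(i) {
    y <- traj[half, i]
    sum((tt - mean(tt)) * (y - mean(y))) / sum((tt - mean(tt))^2)
  }, 0)
  list(task = task, trajectory = traj, steps = rec_steps,
       divergence = data.frame(coord = seq_len(task$d), slope = slopes,
                               diverging = abs(slopes) > tol))
}

#' Loss change from flipping one binary read-out sign
#'
#' Exact loss difference when the i-th component of `sign(W^h)` is flipped
#' with everything else fixed:
#' `Delta_i L = -2 s_i [H (W^b - W*)]_i + 2 H_ii`. For diagonal curvature
#' this reduces to `2 lambda_i s_i W*_i`.
#'
#' @param task a [qbt_task()] (at any point of its trajectory).
#' @param i coordinate index, or a vector of indices (each flipped alone).
#' @return scalar or vector of exact loss variations.
#' @export
flip_loss_delta <- function(task, i = seq_len(task$d)) {
  if (any(i < 1L | i > task$d)) stop("index out of range")
  b <- binarize(task$w_h)
  g <- qbt_grad(task, b)
  hii <- if (task$diag) task$H else diag(task$H)
  (-2 * b * g + 2 * hii)[i]
}

#' Random SPD curvature via the subgroup algorithm
#'
#' Draws eigenvalues from the requested distribution (resampling any
#' non-positive draws), builds a Haar-random rotation `R` by the subgroup
#' algorithm — a random 2-D rotation lifted one dimension at a time by the
#' Householder-style reflection `(I - 2 x x')` with
#' `x = (e1 - v)/||e1 - v||`, `v` uniform on the sphere — and returns
#' `H = R' D R`, symmetric positive definite with spectrum exactly `D`.
#'
#' @param d dimension (>= 2).
#' @param eigenvalues list describing the eigenvalue distribution:
#'   `list(dist = "uniform", min =, max =)` or
#'   `list(dist = "normal", mean =, sd =)`.
#' @param seed RNG seed.
#' @return list with `H`, the rotation `R`, and the sorted drawn spectrum
#'   `values`.
#' @export
random_spd <- function(d, eigenvalues = list(dist = "uniform", min = 0.5, max = 2),
                       seed = 1L) {
  if (d < 2L) stop("d must be >= 2")
  with_seed(seed, {
    draw <- function(n) {
      if (eigenvalues$dist == "uniform") {
        if (eigenvalues$min <= 0) stop("uniform eigenvalue min must be > 0")
        stats::runif(n, eigenvalues$min, eigenvalues$max)
      } else if (eigenvalues$dist == "normal") {
        stats::rnorm(n, eigenvalues$mean, eigenvalues$sd)
      } else stop("unknown eigenvalue distribution")
    }
    lam <- draw(d)
    while (any(lam <= 0)) lam[lam <= 0] <- draw(sum(lam <= 0))
    R <- random_rotation(d)
    H <- t(R) %*% (lam * R)   # R' D R with D = diag(lam)
    H <- (H + t(H)) / 2       # kill roundoff asymmetry
    list(H = H, R = R, values = sort(lam))
  })
}

# Haar-random rotation by the subgroup algorithm (2-D seed rotation, then
# iterative dimension lifting with reflections mapping e1 to a uniform
# sphere point). Uses the ambient RNG.
random_rotation <- function(d) {
  th <- stats::runif(1, 0, 2 * pi)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  n <- 2L
  while (n < d) {
    v <- stats::rnorm(n + 1L)
    v <- v / sqrt(sum(v^2))
    e1 <- c(1, rep(0, n))
    x <- e1 - v
    nx <- sqrt(sum(x^2))
    Rhat <- diag(n + 1L)
    Rhat[2:(n + 1L), 2:(n + 1L)] <- R
    if (nx < 1e-12) {
      R <- Rhat  # v == e1: the reflection degenerates to the identity lift
    } else {
      x <- x / nx
      R <- (diag(n + 1L) - 2 * tcrossprod(x)) %*% Rhat
    }
    n <- n + 1L
  }
  R
}

#' Binned flip-loss analysis on a QBT
#'
#' Bins the coordinates by normalized hidden-weight magnitude
#' `|W^h| / max |W^h|`, and reports, per bin, the mean and standard deviation
#' of the exact loss increase from flipping one binary sign at a time. The
#' monotone growth of the bin means with the normalized hidden weight is the
#' theory-level signature that large hidden weights mark important binary
#' weights.
#'
#' @param task a [qbt_task()] advanced to the state of interest (e.g. via
#'   [run_trajectory()]).
#' @param bins number of equal-width bins over `[0, 1]`.
#' @return data.frame with bin, bin center, n, mean and sd of the loss
#'   increase; empty bins are reported with `n = 0` and `NA` statistics.
#' @export
binned_flip_analysis <- function(task, bins = 10L) {
  wa <- abs(task$w_h)
  norm <- wa / max(wa)
  deltas <- flip_loss_delta(task)
  edges <- seq(0, 1, length.out = bins + 1L)
  idx <- pmin(findInterval(norm, edges, rightmost.closed = TRUE), bins)
  out <- data.frame(bin = seq_len(bins),
                    center = (edges[-1] + edges[-(bins + 1L)]) / 2,
                    n = 0L, mean = NA_real_, sd = NA_real_)
  for (b in seq_len(bins)) {
    sel <- deltas[idx == b]
    out$n[b] <- length(sel)
    if (length(sel)) {
      out$mean[b] <- mean(sel)
      out$sd[b] <- if (length(sel) > 1L) stats::sd(sel) else 0
    }
  }
  out
}

#' Binned flip-loss analysis on a trained BNN
#'
#' The network analog of [binned_flip_analysis()]: per layer, hidden weights
#' are binned by `|W^h|` normalized to the layer maximum; within each bin a
#' fixed number of binary weights is sign-switched simultaneously, the loss
#' increase on the given data is measured, normalized per switched weight,
#' and averaged over several random realizations of the switched set.
#'
#' @param net a trained `bnn` model.
#' @param x,y evaluation data.
#' @param layer layer index to analyze.
#' @param bins number of bins over normalized `|W^h|`.
#' @param flips_per_bin number of weights switched per realization (capped
#'   at the bin occupancy).
#' @param realizations random realizations averaged per bin (default 100).
#' @param bn_slot batch-norm slot for evaluation.
#' @param seed RNG seed for the realization draws.
#' @return data.frame as in [binned_flip_analysis()] (mean/sd of the loss
#'   increase per switched weight).
#' @export
bnn_flip_analysis <- function(net, x, y, layer = 1L, bins = 10L,
                              flips_per_bin = 100L, realizations = 100L,
                              bn_slot = 1L, seed = 1L) {
  Wh <- net$layers[[layer]]$W_h
  norm <- abs(Wh) / max(abs(Wh))
  edges <- seq(0, 1, length.out = bins + 1L)
  idx <- pmin(findInterval(norm, edges, rightmost.closed = TRUE), bins)
  base_loss <- softmax_cross_entropy(
    bnn_forward(net, x, bn_slot = bn_slot)$scores, y)$loss
  out <- data.frame(bin = seq_len(bins),
                    center = (edges[-1] + edges[-(bins + 1L)]) / 2,
                    n = 0L, mean = NA_real_, sd = NA_real_)
  with_seed(seed, for (b in seq_len(bins)) {
    members <- which(idx == b)
    out$n[b] <- length(members)
    if (!length(members) || flips_per_bin == 0L) {
      if (length(members) && flips_per_bin == 0L) { out$mean[b] <- 0; out$sd[b] <- 0 }
      next
    }
    k <- min(flips_per_bin, length(members))
    dl <- vapply(seq_len(realizations), function(r) {
      pick <- if (length(members) == 1L) members else sample(members, k)
      net$layers[[layer]]$W_b[pick] <- -net$layers[[layer]]$W_b[pick]
      loss <- softmax_cross_entropy(
        bnn_forward(net, x, bn_slot = bn_slot)$scores, y)$loss
      net$layers[[layer]]$W_b[pick] <- -net$layers[[layer]]$W_b[pick]
      (loss - base_loss) / k
    }, 0)
    out$mean[b] <- mean(dl)
    out$sd[b] <- stats::sd(dl)
  })
  out
}

#' Verify the QBT theory numerically
#'
#' Runs the two analytic checks on a diagonal task — fitted hidden-weight
#' slopes against `eta * lambda_i (|W*_i| - 1) sign(W*_i)`, and the measured
#' flip loss against the asymptotic law `2 lambda_i + 2 |slope_i| / eta` and
#' the closed form `2 lambda_i |W*_i|` — plus the binned-monotonicity check
#' on a non-diagonal task from [random_spd()].
#'
#' @param d_diag,d_full dimensions of the diagonal and full tasks.
#' @param T_diag,T_full step counts.
#' @param eta step size.
#' @param seed RNG seed for the random draws.
#' @return list of summary statistics (maximum relative errors in percent,
#'   Spearman correlation of the bin means, occupied-bin count).
#' @export
qbt_verify <- function(d_diag = 20L, d_full = 500L, T_diag = 10000L,
                       T_full = 2000L, eta = 0.1, seed = 1L) {
  dg <- with_seed(seed, {
    lam <- stats::runif(d_diag, 0.5, 2)
    ws <- stats::runif(d_diag, 1.2, 3) * sample(c(-1, 1), d_diag, TRUE)
    list(lam = lam, ws = ws)
  })
  tr <- run_trajectory(qbt_task(dg$lam, dg$ws, eta = eta), T = T_diag)
  slope_pred <- eta * dg$lam * (abs(dg$ws) - 1) * sign(dg$ws)
  slope_err <- abs(tr$divergence$slope - slope_pred) / abs(slope_pred)
  measured <- flip_loss_delta(tr$task)
  thm_pred <- 2 * dg$lam + 2 * abs(tr$divergence$slope) / eta
  closed <- 2 * dg$lam * abs(dg$ws)
  div <- tr$divergence$diverging
  spd <- random_spd(d_full, list(dist = "uniform", min = 0.5, max = 2),
                    seed = seed + 1L)
  ws_full <- with_seed(seed + 2L, stats::runif(d_full, -2, 2))
  trf <- run_trajectory(qbt_task(spd$H, ws_full, eta = eta), T = T_full)
  bf <- binned_flip_analysis(trf$task, bins = 10L)
  occ <- !is.na(bf$mean)
  list(
    slope_max_rel_err_pct = 100 * max(slope_err),
    theorem1_max_rel_err_pct = 100 * max(abs(measured[div] - thm_pred[div]) /
                                           thm_pred[div]),
    closed_form_max_rel_err_pct = 100 * max(abs(measured[div] - closed[div]) /
                                              closed[div]),
    n_diverging = sum(div),
    bin_spearman = stats::cor(bf$bin[occ], bf$mean[occ], method = "spearman"),
    n_occupied_bins = sum(occ)
  )
}
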