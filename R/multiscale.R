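# Multi-timescale chain synapse: each synapse carries a chain of hidden
# variables u_1..u_N coupled by a discrete diffusion with geometrically
# decaying conductances. u_1 plays the role of the hidden weight (binary
# read-out = sign(u_1)); deeper levels integrate on slower timescales, so old
# consolidation slowly leaks away and the network forgets its earliest tasks
# first instead of saturating. This is a reconstruction of the described
# mechanism class, selectable via `meta_config(synapse = "chain")`.

#' Create a chain synapse state
#'
#' @param n chain depth `N >= 1`; `N = 1` degenerates to the plain hidden
#'   weight (no diffusion).
#' @param gain flow-modulation gain multiplying all inter-level conductances
#'   (neutral value 1).
#' @param shape_like array/matrix giving the per-level tensor shape; levels
#'   start at 0.
#' @param couplings optional positive, strictly decreasing conductances
#'   `g[k]` between levels k and k+1; default `2^(-2k)`.
#' @param dt diffusion time step.
#' @return a `chain_synapse` object with levels `u[[1]]..u[[n]]`.
#' @export
chain_synapse <- function(n = 4L, gain = 1, shape_like = 0,
                          couplings = NULL, dt = 1) {
  n <- as.integer(n)
  if (n < 1L) stop("chain depth must be >= 1")
  if (is.null(couplings)) couplings <- 2^(-2 * seq_len(max(n - 1L, 0L)))
  if (n > 1L) {
    if (length(couplings) != n - 1L)
      stop("need one coupling per adjacent level pair")
    if (any(couplings <= 0) || any(diff(couplings) >= 0))
      stop("couplings must be positive and strictly decreasing with depth")
  }
  zero <- shape_like * 0
  structure(list(u = rep(list(zero), n), g = couplings, gain = gain, dt = dt),
            class = "chain_synapse")
}

#' One chain-synapse step
#'
#' Applies the external training update `du1` to the top level, then relaxes
#' every level by one step of discrete diffusion: interior levels receive
#' `dt * [g[k-1](u[k-1]-u[k]) + g[k](u[k+1]-u[k])]`, boundary levels the
#' one-sided term. The gain multiplies all inter-level flows; with `g -> 0`
#' (or `N = 1`) `u_1` evolves exactly as a plain hidden weight.
#'
#' @param syn a [chain_synapse()].
#' @param du1 external update added to `u_1` (same shape as the levels).
#' @param dt override of the stored time step.
#' @return the updated synapse.
#' @export
chain_step <- function(syn, du1, dt = syn$dt) {
  if (!all(vapply(syn$u, function(u) all(is.finite(u)), TRUE)))
    stop("chain state contains non-finite values")
  N <- length(syn$u)
  u <- syn$u
  u[[1]] <- u[[1]] + du1
  if (N == 1L) {
    syn$u <- u
    return(syn)
  }
  g <- syn$g * syn$gain
  flow <- vector("list", N)
  for (k in seq_len(N)) {
    f <- 0
    if (k > 1L) f <- f + g[k - 1L] * (u[[k - 1L]] - u[[k]])
    if (k < N) f <- f + g[k] * (u[[k + 1L]] - u[[k]])
    flow[[k]] <- f
  }
  for (k in seq_len(N)) u[[k]] <- u[[k]] + dt * flow[[k]]
  syn$u <- u
  syn
}
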