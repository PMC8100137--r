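# internal helpers

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != round(x))
    stop(sprintf("`%s` must be a single nonnegative integer", name), call. = FALSE)
}

#' Rescale features affinely to [-1, 1]
#'
#' Maps a numeric matrix linearly so that `lo` maps to -1 and `hi` to +1.
#' By default the observed range of `x` is used; pass the training-set range
#' when scaling test data so both live on the same scale.
#'
#' @param x numeric matrix (examples in rows).
#' @param lo,hi scalars defining the source range; defaults to `range(x)`.
#' @return matrix of the same shape with values in `[-1, 1]` (for data within
#'   `[lo, hi]`).
#' @export
scale_to_unit <- function(x, lo = min(x), hi = max(x)) {
  if (hi <= lo) stop("degenerate range: hi must exceed lo")
  2 * (x - lo) / (hi - lo) - 1
}
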