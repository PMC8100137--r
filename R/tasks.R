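# Task construction: the synthetic Gaussian-prototype generator (the
# download-free stand-in for the permuted image benchmarks), permuted-task
# and stream-sharding protocols, the interleaved baseline, and IDX dataset
# readers/writers for the MNIST-family layout.

#' Synthetic classification task specification
#'
#' The base task is Gaussian-prototype classification: one prototype per
#' class drawn from `N(0, proto_scale^2 I)` on a random subset of
#' `active_frac * dim` "active" features, examples drawn as prototype +
#' isotropic Gaussian noise on those features; the remaining features are
#' exactly constant, like the dead border pixels of handwritten-digit
#' images (under batch normalization a constant feature carries vanishing
#' gradient, giving the heavy-tailed importance structure of the image
#' benchmarks). Labels are defined by the generating prototype, and train
#' and test sets are disjoint by construction. Subsequent tasks are fixed
#' coordinate permutations of the base features, mirroring the
#' permuted-pixel continual-learning benchmark: each task's active set
#' lands on a different subset of input weights.
#'
#' @param n_classes number of classes.
#' @param dim feature dimension.
#' @param proto_scale standard deviation of the prototype draw.
#' @param noise_sd within-class noise standard deviation.
#' @param n_train,n_test examples per class in the train/test split.
#' @param active_frac fraction of features carrying class signal.
#' @param seed generator seed.
#' @return a `synthetic_task_spec`.
#' @export
synthetic_task_spec <- function(n_classes = 5L, dim = 64L, proto_scale = 1,
                                noise_sd = 2, n_train = 100L, n_test = 50L,
                                active_frac = 0.5, seed = 1L) {
  if (active_frac <= 0 || active_frac > 1)
    stop("`active_frac` must be in (0, 1]")
  structure(list(n_classes = as.integer(n_classes), dim = as.integer(dim),
                 proto_scale = proto_scale, noise_sd = noise_sd,
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 active_frac = active_frac, seed = as.integer(seed)),
            class = "synthetic_task_spec")
}

sample_split <- function(protos, n_per_class, noise_sd, active) {
  K <- nrow(protos); d <- ncol(protos)
  y <- rep(seq_len(K), each = n_per_class)
  noise <- matrix(0, length(y), d)
  noise[, active] <- stats::rnorm(length(y) * length(active), 0, noise_sd)
  list(x = protos[y, , drop = FALSE] + noise, y = y)
}

#' Generate a sequence of synthetic permuted tasks
#'
#' Task 1 is the base Gaussian-prototype task; tasks 2..n apply one fixed,
#' per-task coordinate permutation to every train and test example. Features
#' are affinely scaled to `[-1, 1]` using the base training range. Each task
#' carries its own batch-norm slot index. Fully reproducible from the spec
#' seed.
#'
#' @param spec a [synthetic_task_spec()].
#' @param n_tasks number of tasks (task 1 unpermuted).
#' @return a `task_sequence`: list of tasks, each with `train$x`, `train$y`,
#'   `test$x`, `test$y`, `perm` (NULL for the base task) and `bn_slot`.
#' @export
generate_synthetic_tasks <- function(spec, n_tasks = 1L) {
  base <- with_seed(spec$seed, {
    n_active <- max(1L, round(spec$active_frac * spec$dim))
    active <- sort(sample.int(spec$dim, n_active))
    protos <- matrix(0, spec$n_classes, spec$dim)
    protos[, active] <- stats::rnorm(spec$n_classes * n_active, 0,
                                     spec$proto_scale)
    tr <- sample_split(protos, spec$n_train, spec$noise_sd, active)
    te <- sample_split(protos, spec$n_test, spec$noise_sd, active)
    list(protos = protos, active = active, train = tr, test = te)
  })
  # nearest-prototype sanity check: warn when noise swamps class structure
  dists <- as.matrix(stats::dist(rbind(base$protos, base$train$x)))
  dists <- dists[-seq_len(spec$n_classes), seq_len(spec$n_classes), drop = FALSE]
  bayes_like <- mean(max.col(-dists) == base$train$y)
  if (bayes_like < 1 / spec$n_classes + 0.1)
    warning("noise_sd is so large the task is near chance level")
  lo <- min(base$train$x); hi <- max(base$train$x)
  base$train$x <- scale_to_unit(base$train$x, lo, hi)
  base$test$x <- scale_to_unit(base$test$x, lo, hi)
  tasks <- vector("list", n_tasks)
  tasks[[1]] <- list(train = base$train, test = base$test, perm = NULL,
                     active = base$active, bn_slot = 1L)
  for (k in seq_len(n_tasks)[-1]) {
    tk <- make_permutation_task(tasks[[1]], seed = spec$seed + k)
    tk$bn_slot <- k
    tk$active <- which(tk$perm %in% base$active)
    tasks[[k]] <- tk
  }
  structure(tasks, class = "task_sequence")
}

#' Derive a permuted task from a base task
#'
#' Draws one feature permutation from `seed` and applies it identically to
#' every train and test example; `seed = NULL` returns the base task
#' unchanged (the identity convention for task 1).
#'
#' @param base_task list with `train$x/y` and `test$x/y` on a flat feature
#'   representation.
#' @param seed permutation seed, or NULL for identity.
#' @return the permuted task with its `perm` recorded.
#' @export
make_permutation_task <- function(base_task, seed = NULL) {
  if (is.null(seed)) {
    base_task$perm <- NULL
    return(base_task)
  }
  d <- ncol(base_task$train$x)
  perm <- with_seed(seed, sample.int(d))
  base_task$train$x <- base_task$train$x[, perm, drop = FALSE]
  base_task$test$x <- base_task$test$x[, perm, drop = FALSE]
  base_task$perm <- perm
  base_task
}

#' Split a dataset into disjoint stream shards
#'
#' Draws `n_shards` disjoint index sets of `shard_size` examples each for
#' sequential stream learning. With `labels` supplied the split is
#' stratified: each class is dealt across shards so every shard contains all
#' classes (as in the progressive-learning protocol).
#'
#' @param dataset_size total number of examples.
#' @param n_shards,shard_size shard count and size;
#'   `n_shards * shard_size <= dataset_size`.
#' @param seed shuffling seed.
#' @param labels optional class labels enabling stratified sharding.
#' @return list of `n_shards` integer index vectors (0 duplicates, disjoint).
#' @export
make_stream_shards <- function(dataset_size, n_shards, shard_size, seed = 1L,
                               labels = NULL) {
  if (n_shards * shard_size > dataset_size)
    stop("oversubscribed: n_shards * shard_size exceeds dataset_size")
  with_seed(seed, {
    if (is.null(labels)) {
      pool <- sample.int(dataset_size, n_shards * shard_size)
      split(pool, rep(seq_len(n_shards), each = shard_size))
    } else {
      if (length(labels) != dataset_size)
        stop("labels length must equal dataset_size")
      shards <- rep(list(integer(0)), n_shards)
      # deal each class round-robin across shards, then trim per shard
      order_all <- unlist(lapply(split(seq_len(dataset_size), labels),
                                 sample), use.names = FALSE)
      assign_to <- rep_len(seq_len(n_shards), length(order_all))
      for (s in seq_len(n_shards)) {
        cand <- order_all[assign_to == s]
        shards[[s]] <- sample(cand)[seq_len(min(shard_size, length(cand)))]
      }
      shards
    }
  })
}

#' Pool tasks into one interleaved training set
#'
#' Concatenates all tasks' (already transformed) training examples and
#' shuffles them; evaluation remains per-task. One task reduces to plain
#' training.
#'
#' @param tasks a `task_sequence` (or list of tasks).
#' @param seed shuffle seed.
#' @return list with pooled `x`, `y`.
#' @export
interleaved_mixture <- function(tasks, seed = 1L) {
  if (!length(tasks)) stop("need at least one task")
  x <- do.call(rbind, lapply(tasks, function(t) t$train$x))
  y <- unlist(lapply(tasks, function(t) t$train$y), use.names = FALSE)
  ord <- with_seed(seed, sample.int(length(y)))
  list(x = x[ord, , drop = FALSE], y = y[ord])
}

#' Read an IDX (MNIST-layout) file
#'
#' Big-endian IDX container of unsigned bytes; gzip-compressed files are
#' accepted transparently. Images are returned as an `n x features` matrix
#' of raw byte values (no scaling), 1-D files as an integer vector.
#'
#' @param path file path (`.gz` allowed).
#' @return integer vector (1-D files) or matrix with one example per row;
#'   attribute `idx_dims` carries the header dimensions.
#' @export
read_idx <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4L)
  if (length(magic) < 4L || magic[1] != as.raw(0) || magic[2] != as.raw(0))
    stop("bad IDX magic number")
  type <- as.integer(magic[3])
  if (type != 0x08L) stop("only unsigned-byte IDX payloads are supported")
  ndim <- as.integer(magic[4])
  if (ndim < 1L || ndim > 4L) stop("bad IDX magic number")
  dims <- readBin(con, "integer", ndim, size = 4L, endian = "big")
  if (length(dims) < ndim || any(dims < 0)) stop("truncated IDX header")
  n <- prod(dims)
  data <- readBin(con, "integer", n, size = 1L, signed = FALSE)
  if (length(data) < n) stop("truncated IDX payload")
  out <- if (ndim == 1L) as.integer(data)
         else matrix(data, nrow = dims[1], ncol = prod(dims[-1]), byrow = TRUE)
  attr(out, "idx_dims") <- dims
  out
}

#' Write an IDX (MNIST-layout) file
#'
#' @param x integer vector (labels) or matrix with one example per row;
#'   values must fit in an unsigned byte.
#' @param path output path; a `.gz` suffix gzip-compresses.
#' @param dims header dimensions; defaults to `length(x)` for vectors and
#'   `c(nrow(x), ncol(x))` for matrices.
#' @export
write_idx <- function(x, path, dims = NULL) {
  vals <- as.integer(if (is.matrix(x)) t(x) else x)
  if (any(vals < 0L | vals > 255L)) stop("values must be in 0..255")
  if (is.null(dims)) dims <- if (is.matrix(x)) c(nrow(x), ncol(x)) else length(x)
  if (prod(dims) != length(vals)) stop("dims inconsistent with data length")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0L, 0L, 0x08L, length(dims))), con)
  writeBin(as.integer(dims), con, size = 4L, endian = "big")
  writeBin(as.raw(vals), con)
  invisible(path)
}

#' Load an IDX image/label pair as a dataset
#'
#' @param images_path,labels_path IDX files for images and labels.
#' @return list with `x` (examples x features, raw byte values) and `y`
#'   (integer labels); errors when the two files disagree on the example
#'   count.
#' @export
load_idx_dataset <- function(images_path, labels_path) {
  x <- read_idx(images_path)
  y <- read_idx(labels_path)
  if (!is.matrix(x)) stop("images file must be at least 2-D")
  if (length(y) != nrow(x))
    stop("label file length must equal image count")
  list(x = x, y = as.integer(y))
}
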