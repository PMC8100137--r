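# Orchestration: continual / stream / interleaved training loops, evaluation,
# hidden-weight histograms, multi-run summaries, and config-driven runs.

# one task's (or shard's) training epochs; returns updated net/opt, the
# cumulative flip count, and an optional path-integral tracker
train_epochs <- function(net, opt, x, y, cfg, epochs, batch_size, bn_slot, lr,
                         ewc_maps = NULL, lambda_ewc = 5e3, pi_track = NULL,
                         on_epoch = NULL) {
  n <- nrow(x)
  flips <- 0L
  for (e in seq_len(epochs)) {
    ord <- sample.int(n)
    for (s in seq(1L, n, by = batch_size)) {
      idx <- ord[s:min(s + batch_size - 1L, n)]
      if (length(idx) < 2L && net$spec$use_bn) next
      fw <- bnn_forward(net, x[idx, , drop = FALSE], bn_slot = bn_slot,
                        training = TRUE)
      ce <- softmax_cross_entropy(fw$scores, y[idx])
      gr <- bnn_backward(net, fw$cache, ce$dscores, bn_slot = bn_slot)
      if (length(ewc_maps)) {
        eg <- ewc_gradient(net, ewc_maps, lambda_ewc)
        for (l in seq_along(gr$dW)) gr$dW[[l]] <- gr$dW[[l]] + eg[[l]]
      }
      net <- update_bn_running(net, fw$cache, bn_slot)
      st <- metaplastic_step(net, opt, gr, cfg, lr = lr, bn_slot = bn_slot)
      net <- st$net; opt <- st$opt
      flips <- flips + opt$flips_last
      if (!is.null(pi_track)) pi_track <- pi_update(pi_track, gr$dW, net)
    }
    if (!is.null(on_epoch)) on_epoch(e, net)
  }
  list(net = net, opt = opt, flips = flips, pi_track = pi_track)
}

#' Train a network on a sequence of tasks
#'
#' Tasks are trained strictly in order; once a task's training window has
#' closed its data is never accessed again (only its test set is used for
#' evaluation). With task-specific batch norm each task trains and is
#' evaluated with its own slot. After every epoch, all tasks seen so far are
#' evaluated on their test sets.
#'
#' @param net a `bnn` model (freshly built).
#' @param tasks a `task_sequence` from [generate_synthetic_tasks()] (or any
#'   list of tasks with `train`, `test`, `bn_slot`).
#' @param cfg a [meta_config()]; `cfg$m` is active for
#'   `baseline = "metaplasticity"` and forced to 0 for the control
#'   baselines.
#' @param epochs_per_task training epochs per task.
#' @param batch_size minibatch size.
#' @param baseline consolidation method: `"metaplasticity"`, `"ewc"`,
#'   `"random_ewc"`, `"lr_decay"`, `"si"`, or `"none"`.
#' @param lambda_ewc EWC regularization strength (default 5e3).
#' @param fisher_batches,fisher_batch_size Fisher-estimate sampling for the
#'   EWC baselines.
#' @param seed RNG seed covering batching, Fisher sampling and shuffling.
#' @param task_specific_bn give each task its own batch-norm slot.
#' @param eval_every evaluate all seen tasks every `eval_every` epochs (the
#'   last epoch of each task is always evaluated, so the post-task and final
#'   accuracies are recorded at any cadence). Default 1: once per epoch.
#' @return a `continual_metrics` list: `history` (task, epoch, eval_task,
#'   accuracy in percent), `final` accuracies after the last task,
#'   `flips_per_task`, and the trained `net`/`opt`.
#' @export
train_continual <- function(net, tasks, cfg, epochs_per_task = 20L,
                            batch_size = 32L,
                            baseline = c("metaplasticity", "ewc", "random_ewc",
                                         "lr_decay", "si", "none"),
                            lambda_ewc = 5e3, fisher_batches = 100L,
                            fisher_batch_size = 32L, seed = 1L,
                            task_specific_bn = TRUE, eval_every = 1L) {
  baseline <- match.arg(baseline)
  run_cfg <- cfg
  if (baseline != "metaplasticity") run_cfg$m <- 0
  with_seed(seed, {
    history <- list()
    flips_per_task <- integer(length(tasks))
    opt <- adam_init(net, run_cfg)
    maps <- list()
    for (k in seq_along(tasks)) {
      slot <- if (task_specific_bn) tasks[[k]]$bn_slot %||% k else 1L
      net <- ensure_bn_slot(net, slot)
      lr_k <- if (baseline == "lr_decay" || run_cfg$lr_decay_per_task)
        lr_decay_schedule(k - 1L, run_cfg$lr) else run_cfg$lr
      pi_track <- if (baseline == "si") pi_init(net, use = "binary") else NULL
      rec <- function(epoch, cur_net) {
        if (epoch %% eval_every != 0L && epoch != epochs_per_task) return()
        acc <- evaluate_all(cur_net, tasks, up_to = k,
                            task_specific_bn = task_specific_bn)
        history[[length(history) + 1L]] <<-
          data.frame(task = k, epoch = epoch, eval_task = seq_len(k),
                     accuracy = acc)
      }
      out <- train_epochs(net, opt, tasks[[k]]$train$x, tasks[[k]]$train$y,
                          run_cfg, epochs_per_task, batch_size, slot, lr_k,
                          ewc_maps = if (baseline %in% c("ewc", "random_ewc", "si"))
                            maps else NULL,
                          lambda_ewc = lambda_ewc, pi_track = pi_track,
                          on_epoch = rec)
      net <- out$net; opt <- out$opt
      flips_per_task[k] <- out$flips
      if (baseline %in% c("ewc", "random_ewc")) {
        mp <- fisher_diag(net, tasks[[k]]$train$x, tasks[[k]]$train$y,
                          n_batches = fisher_batches,
                          batch_size = fisher_batch_size, bn_slot = slot)
        if (baseline == "random_ewc")
          mp <- shuffle_importance(mp, seed = seed + 1000L + k)
        maps[[length(maps) + 1L]] <- mp
      } else if (baseline == "si") {
        maps[[length(maps) + 1L]] <- pi_finalize(out$pi_track, net)
      }
    }
    history <- do.call(rbind, history)
    structure(list(history = history,
                   final = evaluate_all(net, tasks, length(tasks),
                                        task_specific_bn = task_specific_bn),
                   flips_per_task = flips_per_task,
                   baseline = baseline, net = net, opt = opt),
              class = "continual_metrics")
  })
}

#' @export
print.continual_metrics <- function(x, ...) {
  cat(sprintf("<continual_metrics> %s, %d task(s)\n", x$baseline,
              length(x$final)))
  cat("final accuracy (%):",
      paste(formatC(x$final, format = "f", digits = 1), collapse = "  "), "\n")
  invisible(x)
}

#' Evaluate test accuracy on every task learned so far
#'
#' Each task is evaluated on its own (already transformed) test set with its
#' own batch-norm slot restored.
#'
#' @param net a `bnn` model.
#' @param tasks a `task_sequence`.
#' @param up_to evaluate tasks `1..up_to`.
#' @param task_specific_bn use each task's own slot (otherwise slot 1).
#' @return numeric vector of accuracies in percent, length `up_to`.
#' @export
evaluate_all <- function(net, tasks, up_to = length(tasks),
                         task_specific_bn = TRUE) {
  vapply(seq_len(up_to), function(j) {
    slot <- if (task_specific_bn) tasks[[j]]$bn_slot %||% j else 1L
    accuracy(net, tasks[[j]]$test$x, tasks[[j]]$test$y, bn_slot = slot)
  }, 0)
}

#' Mean accuracy over tasks learned so far
#'
#' Collapses a `continual_metrics` history into the running mean over the
#' tasks already trained, per epoch of training.
#'
#' @param metrics a `continual_metrics` object or its `history` data.frame.
#' @return data.frame with `task`, `epoch`, `mean_accuracy`.
#' @export
mean_accuracy_so_far <- function(metrics) {
  h <- if (inherits(metrics, "continual_metrics")) metrics$history else metrics
  agg <- stats::aggregate(accuracy ~ task + epoch, data = h, FUN = mean)
  names(agg)[3] <- "mean_accuracy"
  agg[order(agg$task, agg$epoch), ]
}

#' Histogram of hidden weights per layer
#'
#' Counts over the signed hidden weights and over their magnitudes; overlaying
#' histograms across checkpoints shows how consolidated weights separate from
#' the near-zero pool as tasks are learned.
#'
#' @param net a `bnn` model.
#' @param bins number of bins.
#' @return list per layer with `signed` and `abs` components, each a list of
#'   `breaks`, `counts`, `mids`; total counts equal the parameter count.
#' @export
hidden_weight_histogram <- function(net, bins = 50L) {
  lapply(net$layers, function(l) {
    w <- as.numeric(l$W_h)
    rng <- range(w)
    if (diff(rng) == 0) rng <- rng + c(-1e-8, 1e-8)
    hs <- graphics::hist(w, breaks = seq(rng[1], rng[2], length.out = bins + 1L),
                         plot = FALSE)
    ha <- graphics::hist(abs(w), breaks = seq(0, max(abs(w)) + 1e-12,
                                              length.out = bins + 1L),
                         plot = FALSE)
    list(signed = hs[c("breaks", "counts", "mids")],
         abs = ha[c("breaks", "counts", "mids")])
  })
}

#' Stream learning: one task from sequential data shards
#'
#' Trains on disjoint shards strictly in order, never revisiting past shards,
#' with batch-norm settings common to all shards (there are no task
#' boundaries). The test set is evaluated after each shard.
#'
#' @param net a `bnn` model.
#' @param x,y full training data; shards index into it.
#' @param shards list of disjoint index vectors from [make_stream_shards()].
#' @param x_test,y_test held-out evaluation data.
#' @param cfg a [meta_config()].
#' @param epochs_per_shard epochs spent on each shard.
#' @param batch_size minibatch size.
#' @param seed RNG seed.
#' @return list with `history` (shard, accuracy), trained `net`, `opt`.
#' @export
train_stream <- function(net, x, y, shards, x_test, y_test, cfg,
                         epochs_per_shard = 20L, batch_size = 32L, seed = 1L) {
  with_seed(seed, {
    opt <- adam_init(net, cfg)
    acc <- numeric(length(shards))
    for (s in seq_along(shards)) {
      idx <- shards[[s]]
      out <- train_epochs(net, opt, x[idx, , drop = FALSE], y[idx], cfg,
                          epochs_per_shard, batch_size, bn_slot = 1L,
                          lr = cfg$lr)
      net <- out$net; opt <- out$opt
      acc[s] <- accuracy(net, x_test, y_test, bn_slot = 1L)
    }
    list(history = data.frame(shard = seq_along(shards), accuracy = acc),
         net = net, opt = opt)
  })
}

#' Interleaved (non-sequential) training baseline
#'
#' Pools every task's training data into one shuffled mixture and trains on
#' it, evaluating each task per epoch. This is the upper-bound control
#' against which sequential protocols are compared.
#'
#' @inheritParams train_continual
#' @param epochs total training epochs on the mixture.
#' @return list with `history` (epoch, eval_task, accuracy), `final`, `net`,
#'   `opt`.
#' @export
train_interleaved <- function(net, tasks, cfg, epochs = 20L, batch_size = 32L,
                              seed = 1L) {
  mix <- interleaved_mixture(tasks, seed = seed)
  with_seed(seed, {
    opt <- adam_init(net, cfg)
    history <- list()
    rec <- function(epoch, cur_net) {
      acc <- evaluate_all(cur_net, tasks, task_specific_bn = FALSE)
      history[[length(history) + 1L]] <<-
        data.frame(epoch = epoch, eval_task = seq_along(tasks), accuracy = acc)
    }
    out <- train_epochs(net, opt, mix$x, mix$y, cfg, epochs, batch_size,
                        bn_slot = 1L, lr = cfg$lr, on_epoch = rec)
    list(history = do.call(rbind, history),
         final = evaluate_all(out$net, tasks, task_specific_bn = FALSE),
         net = out$net, opt = out$opt)
  })
}

#' Mean and standard deviation of final accuracies over repeated runs
#'
#' @param finals list of per-run final-accuracy vectors (same length).
#' @return data.frame with `task`, `mean`, `sd` (percent).
#' @export
summarize_runs <- function(finals) {
  m <- do.call(rbind, finals)
  data.frame(task = seq_len(ncol(m)),
             mean = colMeans(m),
             sd = apply(m, 2L, stats::sd))
}
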