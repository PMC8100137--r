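# Config-driven experiment runs: YAML in, metrics (CSV + JSON) and a
# checkpoint out; every run reproducible from its config + seed.

require_keys <- function(x, keys, where) {
  missing <- setdiff(keys, names(x))
  if (length(missing))
    stop(sprintf("config error in `%s`: missing required key(s): %s",
                 where, paste(missing, collapse = ", ")), call. = FALSE)
}

config_to_objects <- function(cfg) {
  require_keys(cfg, c("experiment", "seed"), "top level")
  if (!cfg$experiment %in% c("continual", "stream", "interleaved", "qbt_verify"))
    stop(sprintf("config error: unknown experiment `%s`", cfg$experiment),
         call. = FALSE)
  out <- list(experiment = cfg$experiment, seed = cfg$seed)
  if (cfg$experiment != "qbt_verify") {
    require_keys(cfg, c("network", "tasks", "optimizer", "training"), "top level")
    require_keys(cfg$network, "sizes", "network")
    require_keys(cfg$tasks, c("n_classes", "dim"), "tasks")
    require_keys(cfg$training, c("epochs", "batch_size"), "training")
    op <- cfg$optimizer
    out$net_spec <- mlp_spec(unlist(cfg$network$sizes),
                             kind = cfg$network$kind %||% "binary",
                             use_bn = cfg$network$use_bn %||% TRUE,
                             dropout = cfg$network$dropout %||% 0)
    out$opt_cfg <- meta_config(m = op$m %||% 0,
                               variant = op$variant %||% "smooth",
                               threshold = op$threshold,
                               lr = op$lr %||% 1e-3,
                               lr_decay_per_task = op$lr_decay_per_task %||% FALSE,
                               synapse = op$synapse %||% "scalar",
                               chain_n = op$chain_n %||% 4L,
                               chain_gain = op$chain_gain %||% 1)
    out$task_spec <- synthetic_task_spec(
      n_classes = cfg$tasks$n_classes, dim = cfg$tasks$dim,
      proto_scale = cfg$tasks$proto_scale %||% 1,
      noise_sd = cfg$tasks$noise_sd %||% 2,
      n_train = cfg$tasks$n_train %||% 100L,
      n_test = cfg$tasks$n_test %||% 50L,
      seed = cfg$seed)
    out$baseline <- (cfg$baseline %||% list())$method %||% "metaplasticity"
    out$lambda_ewc <- (cfg$baseline %||% list())$lambda_ewc %||% 5e3
    out$training <- cfg$training
    out$tasks_cfg <- cfg$tasks
  }
  out
}

#' Run an experiment described by a config file
#'
#' Reads a YAML configuration, validates its schema, runs the requested
#' experiment (`continual`, `stream`, `interleaved`, or `qbt_verify`) and
#' writes metrics as CSV and JSON plus a model checkpoint under the output
#' directory. A dry run validates the config without training.
#'
#' @param path YAML config file (or an already-parsed list).
#' @param out_dir output directory (default from the config's `output: dir`,
#'   falling back to `"results"`).
#' @param dry_run validate and return the parsed objects without running.
#' @return invisibly, the experiment's result object (or the parsed config
#'   for dry runs).
#' @export
run_config <- function(path, out_dir = NULL, dry_run = NULL) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  obj <- config_to_objects(cfg)
  dry <- dry_run %||% cfg$dry_run %||% FALSE
  if (isTRUE(dry)) return(invisible(obj))
  out_dir <- out_dir %||% (cfg$output %||% list())$dir %||% "results"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- switch(obj$experiment,
    qbt_verify = qbt_verify(seed = obj$seed),
    continual = {
      seq_ <- generate_synthetic_tasks(obj$task_spec,
                                       n_tasks = obj$tasks_cfg$n_tasks %||% 1L)
      net <- build_network(obj$net_spec, seed = obj$seed)
      train_continual(net, seq_, obj$opt_cfg,
                      epochs_per_task = obj$training$epochs,
                      batch_size = obj$training$batch_size,
                      baseline = obj$baseline, lambda_ewc = obj$lambda_ewc,
                      seed = obj$seed)
    },
    interleaved = {
      seq_ <- generate_synthetic_tasks(obj$task_spec,
                                       n_tasks = obj$tasks_cfg$n_tasks %||% 1L)
      net <- build_network(obj$net_spec, seed = obj$seed)
      train_interleaved(net, seq_, obj$opt_cfg,
                        epochs = obj$training$epochs,
                        batch_size = obj$training$batch_size, seed = obj$seed)
    },
    stream = {
      seq_ <- generate_synthetic_tasks(obj$task_spec, n_tasks = 1L)
      base <- seq_[[1]]
      n_shards <- obj$tasks_cfg$n_shards %||% 20L
      shard_size <- obj$tasks_cfg$shard_size %||%
        (nrow(base$train$x) %/% n_shards)
      shards <- make_stream_shards(nrow(base$train$x), n_shards, shard_size,
                                   seed = obj$seed, labels = base$train$y)
      net <- build_network(obj$net_spec, seed = obj$seed)
      train_stream(net, base$train$x, base$train$y, shards,
                   base$test$x, base$test$y, obj$opt_cfg,
                   epochs_per_shard = obj$training$epochs,
                   batch_size = obj$training$batch_size, seed = obj$seed)
    })
  if (obj$experiment == "qbt_verify") {
    jsonlite::write_json(res, file.path(out_dir, "qbt_report.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(res$history, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(seed = obj$seed, experiment = obj$experiment,
                              history = res$history,
                              final = res$final %||% NULL),
                         file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    save_checkpoint(res$net, file.path(out_dir, "checkpoint.rds"), res$opt)
  }
  invisible(res)
}
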