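# Orchestration: continual training bookkeeping, evaluation, histograms,
# multi-run summaries, and config-driven runs.

tiny_tasks <- function(n_tasks = 2, seed = 13) {
  spec <- synthetic_task_spec(n_classes = 3, dim = 10, noise_sd = 1,
                              n_train = 12, n_test = 8, active_frac = 1,
                              seed = seed)
  generate_synthetic_tasks(spec, n_tasks = n_tasks)
}

test_that("an untrained wide-output network scores at chance level on every task", {
  spec <- synthetic_task_spec(n_classes = 10, dim = 16, noise_sd = 1.5,
                              n_train = 10, n_test = 100, seed = 21)
  tasks <- generate_synthetic_tasks(spec, n_tasks = 2)
  net <- build_network(mlp_spec(c(16, 12, 10)), seed = 3)
  # an untrained net only has the shared slot-1 batch-norm state
  acc <- evaluate_all(net, tasks, task_specific_bn = FALSE)
  expect_length(acc, 2L)
  # 1000 test examples at 10 classes: binomial fluctuation around 10%
  expect_true(all(acc > 2 & acc < 25))
})

test_that("metrics bookkeeping records epochs x tasks-seen rows and final accuracies", {
  tasks <- tiny_tasks()
  net <- build_network(mlp_spec(c(10, 6, 3)), seed = 1)
  res <- train_continual(net, tasks, meta_config(m = 0, lr = 0.01),
                         epochs_per_task = 3, batch_size = 6, seed = 1)
  # task 1: 3 epochs x 1 task; task 2: 3 epochs x 2 tasks
  expect_identical(nrow(res$history), 3L * 1L + 3L * 2L)
  expect_length(res$final, 2L)
  expect_true(all(res$final >= 0 & res$final <= 100))
  expect_length(res$flips_per_task, 2L)
  expect_s3_class(res, "continual_metrics")
})

test_that("a sparser evaluation cadence still records the last epoch of every task", {
  tasks <- tiny_tasks()
  net <- build_network(mlp_spec(c(10, 6, 3)), seed = 1)
  res <- train_continual(net, tasks, meta_config(m = 0, lr = 0.01),
                         epochs_per_task = 5, batch_size = 6, seed = 1,
                         eval_every = 5)
  expect_identical(sort(unique(res$history$epoch)), 5L)
  full <- train_continual(build_network(mlp_spec(c(10, 6, 3)), seed = 1),
                          tasks, meta_config(m = 0, lr = 0.01),
                          epochs_per_task = 5, batch_size = 6, seed = 1)
  expect_identical(res$final, full$final)
})

test_that("continual training is deterministic given the seed", {
  tasks <- tiny_tasks()
  run <- function() {
    net <- build_network(mlp_spec(c(10, 6, 3)), seed = 2)
    train_continual(net, tasks, meta_config(m = 1, lr = 0.02),
                    epochs_per_task = 2, batch_size = 6, seed = 7)
  }
  a <- run(); b <- run()
  expect_identical(a$history, b$history)
  expect_identical(a$final, b$final)
})

test_that("control baselines force plain training regardless of the configured m", {
  tasks <- tiny_tasks()
  run <- function(m, baseline) {
    net <- build_network(mlp_spec(c(10, 6, 3)), seed = 4)
    train_continual(net, tasks, meta_config(m = m, lr = 0.02),
                    epochs_per_task = 2, batch_size = 6, seed = 4,
                    baseline = baseline)$final
  }
  expect_identical(run(1.35, "lr_decay"), run(0, "lr_decay"))
  expect_identical(run(0, "metaplasticity"), run(0, "none"))
})

test_that("task accuracy under its own normalization slot is untouched by later slots' statistics", {
  tasks <- tiny_tasks()
  net <- build_network(mlp_spec(c(10, 6, 3)), seed = 5)
  res <- train_continual(net, tasks[1], meta_config(m = 0, lr = 0.02),
                         epochs_per_task = 3, batch_size = 6, seed = 5)
  before <- accuracy(res$net, tasks[[1]]$test$x, tasks[[1]]$test$y, bn_slot = 1)
  # pollute slot 2's running statistics without touching any weights
  net2 <- metabnn:::ensure_bn_slot(res$net, 2L)
  fw <- bnn_forward(net2, tasks[[2]]$train$x, bn_slot = 2L, training = TRUE)
  net2 <- metabnn:::update_bn_running(net2, fw$cache, 2L)
  after <- accuracy(net2, tasks[[1]]$test$x, tasks[[1]]$test$y, bn_slot = 1)
  expect_identical(after, before)
})

test_that("hidden-weight histograms conserve mass and start concentrated near zero", {
  net <- build_network(mlp_spec(c(10, 6, 3)), seed = 6)
  hs <- hidden_weight_histogram(net, bins = 20)
  for (l in seq_along(hs)) {
    expect_identical(sum(hs[[l]]$signed$counts),
                     length(net$layers[[l]]$W_h))
    expect_identical(sum(hs[[l]]$abs$counts), length(net$layers[[l]]$W_h))
  }
  # a fresh network has every hidden weight inside the fan-in bound
  expect_lt(max(abs(hs[[1]]$signed$breaks)), 1 / sqrt(10) + 1e-9)
})

test_that("the running mean over learned tasks aggregates the history correctly", {
  h <- data.frame(task = c(1, 1, 2, 2, 2, 2),
                  epoch = c(1, 1, 1, 1, 2, 2),
                  eval_task = c(1, 1, 1, 2, 1, 2),
                  accuracy = c(90, 90, 80, 60, 82, 64))
  m <- mean_accuracy_so_far(h[-2, ])
  expect_equal(m$mean_accuracy[m$task == 2 & m$epoch == 1], 70)
  expect_equal(m$mean_accuracy[m$task == 2 & m$epoch == 2], 73)
})

test_that("multi-run summaries report the per-task mean and one standard deviation", {
  s <- summarize_runs(list(c(90, 80), c(94, 84), c(92, 82)))
  expect_equal(s$mean, c(92, 82))
  expect_equal(s$sd, c(2, 2))
  expect_identical(s$task, 1:2)
})

test_that("config-driven runs validate their schema, honor dry runs, and reproduce exactly", {
  cfg <- list(experiment = "continual", seed = 11,
              network = list(sizes = c(10, 6, 3)),
              tasks = list(n_classes = 3, dim = 10, noise_sd = 1,
                           n_train = 12, n_test = 8, n_tasks = 2),
              optimizer = list(m = 1, lr = 0.02),
              training = list(epochs = 2, batch_size = 6))
  dry <- run_config(cfg, dry_run = TRUE)
  expect_identical(dry$experiment, "continual")
  expect_s3_class(dry$opt_cfg, "meta_config")
  bad <- cfg; bad$training$epochs <- NULL
  expect_error(run_config(bad, dry_run = TRUE), "epochs")
  expect_error(run_config(list(experiment = "nope", seed = 1), dry_run = TRUE),
               "unknown experiment")
  d1 <- file.path(tempdir(), "run1"); d2 <- file.path(tempdir(), "run2")
  run_config(cfg, out_dir = d1)
  run_config(cfg, out_dir = d2)
  expect_true(file.exists(file.path(d1, "metrics.csv")))
  expect_true(file.exists(file.path(d1, "metrics.json")))
  expect_true(file.exists(file.path(d1, "checkpoint.rds")))
  expect_identical(readLines(file.path(d1, "metrics.csv")),
                   readLines(file.path(d2, "metrics.csv")))
  ck <- load_checkpoint(file.path(d1, "checkpoint.rds"))
  expect_s3_class(ck$net, "bnn")
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a YAML config file on disk drives the same validated pipeline", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("experiment: qbt_verify", "seed: 3"), yml)
  out <- file.path(tempdir(), "qv")
  dry <- run_config(yml, dry_run = TRUE)
  expect_identical(dry$seed, 3L)
  unlink(yml); unlink(out, recursive = TRUE)
})
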