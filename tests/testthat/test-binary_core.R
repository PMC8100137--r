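# Core binarized-network mechanics: sign conventions, initialization,
# forward/backward correctness (validated against finite differences and an
# independent reference), loss, and checkpointing.

test_that("binarize maps to {-1,+1} with sign(0) = +1 and rejects non-finite input", {
  expect_identical(binarize(c(-2.3, 0.1, 0)), c(-1, 1, 1))
  expect_true(all(binarize(matrix(rnorm(100), 10)) %in% c(-1, 1)))
  m <- matrix(c(0, -0.5, 2, 0), 2)
  expect_identical(binarize(m), matrix(c(1, -1, 1, 1), 2))
  expect_error(binarize(c(1, NA)), "non-finite")
  expect_error(binarize(c(1, Inf)), "non-finite")
})

test_that("network construction is seeded, bounded by fan-in, and leaves the caller's RNG alone", {
  spec <- mlp_spec(c(20, 10, 3))
  a <- build_network(spec, seed = 7)
  b <- build_network(spec, seed = 7)
  expect_identical(lapply(a$layers, `[[`, "W_h"), lapply(b$layers, `[[`, "W_h"))
  expect_lt(max(abs(a$layers[[1]]$W_h)), 1 / sqrt(20))
  expect_lt(max(abs(a$layers[[2]]$W_h)), 1 / sqrt(10))
  expect_identical(a$layers[[1]]$W_b, binarize(a$layers[[1]]$W_h))
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(build_network(spec, seed = 1)); after <- runif(3)
  expect_identical(before, after)
  expect_error(mlp_spec(c(5)), "at least")
  expect_error(build_network(list(), seed = 1), "bnn_spec")
})

test_that("forward pass validates batch shape, batch size, and batch-norm slots", {
  net <- build_network(mlp_spec(c(8, 6, 3)), seed = 1)
  x <- matrix(runif(5 * 8, -1, 1), 5, 8)
  out <- bnn_forward(net, x, training = TRUE)
  expect_identical(dim(out$scores), c(5L, 3L))
  expect_error(bnn_forward(net, x[, 1:7]), "features")
  expect_error(bnn_forward(net, x[1, , drop = FALSE], training = TRUE),
               "batch size 1")
  expect_error(bnn_forward(net, x, bn_slot = 3L), "slot")
  # evaluation mode accepts single examples (running statistics)
  expect_silent(bnn_forward(net, x[1, , drop = FALSE], training = FALSE))
})

test_that("full-precision control network gradients match finite differences through batch norm", {
  net <- build_network(mlp_spec(c(6, 5, 3), kind = "real"), seed = 3)
  set.seed(11)
  x <- matrix(runif(8 * 6, -1, 1), 8, 6)
  y <- sample(1:3, 8, TRUE)
  loss_at <- function(net) {
    fw <- bnn_forward(net, x, training = TRUE)
    softmax_cross_entropy(fw$scores, y)$loss
  }
  fw <- bnn_forward(net, x, training = TRUE)
  gr <- bnn_backward(net, fw$cache, softmax_cross_entropy(fw$scores, y)$dscores)
  h <- 1e-6
  for (l in 1:2) {
    for (idx in c(1L, 5L, length(net$layers[[l]]$W_h))) {
      np <- net; np$layers[[l]]$W_h[idx] <- np$layers[[l]]$W_h[idx] + h
      nm <- net; nm$layers[[l]]$W_h[idx] <- nm$layers[[l]]$W_h[idx] - h
      num <- (loss_at(np) - loss_at(nm)) / (2 * h)
      expect_equal(gr$dW[[l]][idx], num, tolerance = 1e-4)
    }
  }
  # batch-norm parameter gradients too
  gp <- net; gp$bn[[1]][[1]]$gamma[2] <- gp$bn[[1]][[1]]$gamma[2] + h
  gm <- net; gm$bn[[1]][[1]]$gamma[2] <- gm$bn[[1]][[1]]$gamma[2] - h
  expect_equal(gr$dgamma[[1]][2], (loss_at(gp) - loss_at(gm)) / (2 * h),
               tolerance = 1e-4)
  bp <- net; bp$bn[[1]][[2]]$beta[1] <- bp$bn[[1]][[2]]$beta[1] + h
  bm <- net; bm$bn[[1]][[2]]$beta[1] <- bm$bn[[1]][[2]]$beta[1] - h
  expect_equal(gr$dbeta[[2]][1], (loss_at(bp) - loss_at(bm)) / (2 * h),
               tolerance = 1e-4)
})

test_that("binary network backward agrees with the independent straight-through reference", {
  net <- build_network(mlp_spec(c(10, 8, 3), use_bn = FALSE), seed = 5)
  set.seed(21)
  x <- matrix(runif(12 * 10, -1, 1), 12, 10)
  y <- sample(1:3, 12, TRUE)
  fw <- bnn_forward(net, x, training = TRUE)
  ce <- softmax_cross_entropy(fw$scores, y)
  gr <- bnn_backward(net, fw$cache, ce$dscores)
  W <- lapply(net$layers, `[[`, "W_h")
  rfw <- ref_forward(W, x)
  expect_equal(rfw$scores, fw$scores, tolerance = 1e-12)
  rdW <- ref_backward(W, rfw, ref_loss_grad(rfw$scores, y))
  for (l in 1:2) expect_equal(gr$dW[[l]], rdW[[l]], tolerance = 1e-12)
})

test_that("softmax cross-entropy has correct value, gradient, and input validation", {
  set.seed(4)
  s <- matrix(rnorm(6 * 4), 6, 4)
  y <- sample(1:4, 6, TRUE)
  ce <- softmax_cross_entropy(s, y)
  expect_equal(softmax_cross_entropy(matrix(0, 3, 5), c(1L, 3L, 5L))$loss,
               log(5))
  h <- 1e-6
  for (idx in c(1L, 9L, 24L)) {
    sp <- s; sp[idx] <- sp[idx] + h
    sm <- s; sm[idx] <- sm[idx] - h
    num <- (softmax_cross_entropy(sp, y)$loss -
              softmax_cross_entropy(sm, y)$loss) / (2 * h)
    expect_equal(ce$dscores[idx], num, tolerance = 1e-5)
  }
  expect_equal(rowSums(ce$prob), rep(1, 6))
  expect_error(softmax_cross_entropy(s, y[-1]), "batch size")
  expect_error(softmax_cross_entropy(s, rep(9L, 6)), "range")
})

test_that("running batch-norm statistics follow the declared momentum update", {
  net <- build_network(mlp_spec(c(4, 3)), seed = 2)
  x <- matrix(runif(10 * 4, -1, 1), 10, 4)
  fw <- bnn_forward(net, x, training = TRUE)
  net2 <- metabnn:::update_bn_running(net, fw$cache, 1L)
  mu <- fw$cache[[1]]$batch_mu
  va <- fw$cache[[1]]$batch_var
  expect_equal(net2$bn[[1]][[1]]$run_mean, 0.9 * rep(0, 3) + 0.1 * mu)
  expect_equal(net2$bn[[1]][[1]]$run_var, 0.9 * rep(1, 3) + 0.1 * va)
})

test_that("checkpoints round-trip byte-identically and reject foreign files", {
  net <- build_network(mlp_spec(c(6, 4, 2)), seed = 9)
  opt <- adam_init(net, meta_config(m = 1))
  p1 <- tempfile(fileext = ".rds"); p2 <- tempfile(fileext = ".rds")
  save_checkpoint(net, p1, opt)
  ck <- load_checkpoint(p1)
  expect_identical(ck$net, net)
  expect_identical(ck$opt, opt)
  save_checkpoint(ck$net, p2, ck$opt)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  bad <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(load_checkpoint(bad), "checkpoint")
  unlink(c(p1, p2, bad))
})

test_that("the convolutional architecture is constructible but refuses to run inference", {
  spec <- vgg7_spec(c(32, 32, 3), n_classes = 10)
  net <- build_network(spec, seed = 1)
  # six conv layers + three dense layers
  expect_length(net$layers, 9L)
  expect_identical(dim(net$layers[[1]]$W_h), c(3L, 3L, 3L, 128L))
  # flattened 4x4x512 feeds the first 2048-unit dense layer
  expect_identical(dim(net$layers[[7]]$W_h), c(8192L, 2048L))
  expect_gt(count_params(net), 2e7)
  expect_error(bnn_forward(net, matrix(0, 2, 10)), "constructible only")
})

test_that("parameter counting and prediction work on a separable task", {
  net <- build_network(mlp_spec(c(5, 4, 2)), seed = 1)
  expect_identical(count_params(net), 5L * 4L + 4L * 2L)
  expect_true(all(predict_labels(net, matrix(0.3, 7, 5)) %in% 1:2))
  expect_true(accuracy(net, matrix(0.3, 7, 5), rep(1L, 7)) %in%
                c(0, 100 * (1:7) / 7))
})
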