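test_that("untrained classifiers have seeded, deterministic initial weights", {
  cfg <- train_config(seed = 13)
  m1 <- build_classifier(cfg)
  m2 <- build_classifier(cfg)
  expect_identical(m1$net, m2$net)
  m3 <- build_classifier(train_config(seed = 14))
  expect_false(identical(m1$net, m3$net))
})

test_that("forward passes emit valid softmax probabilities, order preserved", {
  m <- build_classifier(train_config(seed = 13))
  x <- simulate_labeled_set(2, scene_config(beadline = TRUE), seed = 3,
                            preprocess_cfg = preprocess_config())
  p <- predict(m, x$x)          # batch of shape (n, 55, 55)
  expect_equal(nrow(p), 6L)
  expect_equal(rowSums(p[, c("p0", "p1", "p2")]), rep(1, 6), tolerance = 1e-6)
  expect_equal(p$label, max.col(as.matrix(p[, c("p0", "p1", "p2")]),
                                ties.method = "first") - 1L)
  expect_equal(p$confidence, 100 * apply(p[, c("p0", "p1", "p2")], 1, max))
  # inference determinism
  expect_identical(predict(m, x$x), p)
  # order preservation: single-image predictions match the batch rows
  p1 <- predict(m, x$x[3, , ])
  expect_equal(unlist(p1), unlist(p[3, ]), tolerance = 1e-12)
  # wrong spatial size: contract error, no silent resize
  expect_error(predict(m, matrix(0, 54, 54)), "no silent resize")
})

test_that("the depth-50 variant shares the I/O contract", {
  cfg <- train_config(seed = 5, arch_depth = "50")
  m <- build_classifier(cfg)
  x <- array(runif(2 * 55 * 55, 0, 65535), c(2, 55, 55))
  p <- predict(m, x)
  expect_equal(nrow(p), 2L)
  expect_equal(rowSums(p[, c("p0", "p1", "p2")]), rep(1, 2), tolerance = 1e-6)
  m2 <- build_classifier(cfg)
  expect_identical(m$net[[1]]$W, m2$net[[1]]$W)
  expect_error(train_config(arch_depth = "50", input_side = 16),
               "input_side >= 32")
})

test_that("backpropagated gradients match finite differences", {
  cfg <- train_config(seed = 21, input_side = 16)
  m <- build_classifier(cfg)
  set.seed(2)
  X <- array(runif(16 * 16 * 3), c(16, 16, 3))
  y <- c(0L, 1L, 2L)
  g <- dropclass:::cpp_net_grad(m$net, X, y, 1L)
  eps <- 1e-6
  fd <- function(mutate, get_grad) {
    net2 <- m$net
    net2 <- mutate(net2, eps)
    lp <- dropclass:::cpp_net_loss(net2, X, y, 1L)
    net2 <- mutate(net2, -2 * eps)
    lm <- dropclass:::cpp_net_loss(net2, X, y, 1L)
    c(num = (lp - lm) / (2 * eps), ana = get_grad(g))
  }
  checks <- list(
    fd(function(n, e) { n[[1]]$W[4] <- n[[1]]$W[4] + e; n },
       function(g) g$grads[[1]]$dW[4]),
    fd(function(n, e) { n[[3]]$convs[[1]]$W[11] <- n[[3]]$convs[[1]]$W[11] + e; n },
       function(g) g$grads[[3]]$convs[[1]]$dW[11]),
    fd(function(n, e) { n[[5]]$proj$W[7] <- n[[5]]$proj$W[7] + e; n },
       function(g) g$grads[[5]]$proj$dW[7]),
    fd(function(n, e) { n[[5]]$convs[[2]]$b[2] <- n[[5]]$convs[[2]]$b[2] + e; n },
       function(g) g$grads[[5]]$convs[[2]]$db[2]),
    fd(function(n, e) { n[[8]]$W[5] <- n[[8]]$W[5] + e; n },
       function(g) g$grads[[8]]$dW[5]))
  for (ck in checks)
    expect_equal(ck[["num"]], ck[["ana"]], tolerance = 1e-5)
})

test_that("training descends, validates its inputs and is reproducible", {
  set.seed(1)
  d <- simulate_labeled_set(40, scene_config(beadline = TRUE), seed = 17,
                            preprocess_cfg = preprocess_config())
  cfg <- train_config(epochs = 2, batch_size = 20, seed = 33)
  # loss on the training split after epoch 1 is below the initialization loss
  init <- build_classifier(cfg)
  p0 <- predict(init, d$x)
  init_loss <- mean(-log(pmax(as.matrix(p0[, c("p0", "p1", "p2")])[
    cbind(seq_along(d$y), d$y + 1L)], 1e-12)))
  m <- train_classifier(d$x, d$y, cfg)
  expect_lt(m$history$train_loss[1], init_loss)
  expect_equal(nrow(m$history), 2L)
  expect_true(m$trained)
  # run-to-run reproducibility on one machine
  m2 <- train_classifier(d$x, d$y, cfg)
  expect_identical(m$net, m2$net)
  expect_identical(m$history, m2$history)
  # contract errors and imbalance warnings
  expect_error(train_classifier(d$x, rep(0L, length(d$y)), cfg), "class")
  expect_warning(train_classifier(d$x[1:90, , ], rep(c(0L, 1L, 2L),
                                                     c(40, 40, 10)),
                                  cfg), "imbalanced")
})

test_that("saved classifiers reload with identical predictions", {
  d <- withr::local_tempdir()
  x <- simulate_labeled_set(15, scene_config(beadline = TRUE), seed = 19,
                            preprocess_cfg = preprocess_config())
  m <- train_classifier(x$x, x$y, train_config(epochs = 1, batch_size = 16,
                                               seed = 3))
  save_classifier(m, d)
  expect_true(file.exists(file.path(d, "config.json")))
  m2 <- load_classifier(d)
  expect_equal(predict(m2, x$x), predict(m, x$x))
})

test_that("class structure is recovered when the generative signal is strong", {
  # beadline-free droplets at default noise: the trained small model
  # separates the three classes almost perfectly
  scene <- scene_config(beadline = FALSE)
  tr <- simulate_labeled_set(800, scene, seed = 5,
                             preprocess_cfg = preprocess_config())
  ev <- simulate_labeled_set(150, scene, seed = 55,
                             preprocess_cfg = preprocess_config())
  m <- train_classifier(tr$x, tr$y, train_config(seed = 8))
  s <- score_predictions(predict(m, ev$x)$label, ev$y)
  expect_gte(s$overall_accuracy, 95)
})
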