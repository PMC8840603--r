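test_that("feature fusion concatenates channels and conserves every value", {
  set.seed(1)
  xa <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  xb <- array(rnorm(4 * 4 * 5), c(4, 4, 5))
  xc <- array(rnorm(4 * 4 * 7), c(4, 4, 7))
  y <- fuse_features(xa, xb, xc)
  expect_equal(dim(y), c(4L, 4L, 15L))
  expect_equal(sort(as.vector(y)), sort(c(xa, xb, xc)))
  expect_equal(y[, , 1:3], xa)
  expect_equal(y[, , 4:8], xb)
  expect_equal(y[, , 9:15], xc)
  # a zero-channel branch contributes nothing
  y2 <- fuse_features(xa, array(0, c(4, 4, 0)), xc)
  expect_equal(dim(y2)[3], 10L)
  expect_equal(y2[, , 1:3], xa)
  # equal-width branches triple the channel count
  y3 <- fuse_features(xa, xa, xa)
  expect_equal(dim(y3)[3], 9L)
  expect_error(fuse_features(xa, array(0, c(5, 4, 2)), xc), "spatial")
})

test_that("pixel recombination matches the hand-enumerated 2x2x4 layout", {
  x <- array(0, c(2, 2, 4))
  # channel c holds value 10*c + position
  for (ch in 1:4) x[, , ch] <- matrix(10 * ch + c(1, 3, 2, 4), 2, 2, byrow = TRUE)
  y <- pixel_shuffle(x)
  expect_equal(dim(y), c(4L, 4L, 1L))
  # input channel 1 -> even-grid (dy=0, dx=0); 2 -> dx=1; 3 -> dy=1; 4 -> both
  expected <- matrix(c(11, 21, 13, 23,
                       31, 41, 33, 43,
                       12, 22, 14, 24,
                       32, 42, 34, 44), 4, 4, byrow = TRUE)
  expect_equal(y[, , 1], expected)
  # inverse gather undoes the rearrangement
  expect_equal(fpmkit:::pixel_shuffle_bwd(y), x)
})

test_that("each upsampling stage doubles the spatial size; stages compose", {
  x <- array(rnorm(24 * 24 * 8), c(24, 24, 8))
  y <- upsample_stage(x)
  expect_equal(dim(y), c(48L, 48L, 2L))
  # element count conserved by the recombination itself
  expect_equal(prod(dim(y)), prod(dim(x)))
  # chaining k stages scales by 2^k
  z <- array(rnorm(4 * 4 * 16), c(4, 4, 16))
  z2 <- upsample_stage(upsample_stage(z))
  expect_equal(dim(z2)[1:2], c(16L, 16L))
  expect_error(upsample_stage(array(0, c(4, 4, 3))), "divisible")
})

test_that("the assembled model maps S x S x 2 to S x S x 2 deterministically", {
  model <- fpm_network(channels = 8, growth = 4, seed = 1)
  expect_lt(n_parameters(model), 1e6)
  for (S in c(16L, 48L, 96L)) {
    x <- array(rnorm(S * S * 2), c(S, S, 2))
    out <- predict(model, x, raw = TRUE)
    expect_equal(dim(out), c(S, S, 2L))
    expect_true(all(is.finite(out)))
    expect_identical(out, predict(model, x, raw = TRUE))
  }
  # identical seeds build identical models
  expect_identical(fpm_network(seed = 7)$params, fpm_network(seed = 7)$params)
  expect_error(predict(model, array(0, c(8, 8, 3))), "dual-channel")
})

test_that("named backbones require the missing deep-learning backend", {
  expect_error(fpm_network("resnet50"), "backend")
  expect_error(fpm_network("densenet121"), "backend")
})

test_that("analytic gradients agree with central differences", {
  set.seed(2)
  model <- fpm_network(channels = 4, growth = 2, seed = 3)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  y <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  fwd <- fpmkit:::net_forward(model, x)
  g <- fpmkit:::net_backward(model, fwd$cache,
                             2 * (fwd$out - y) / length(y))
  eps <- 1e-6
  loss_at <- function(m) mean((fpmkit:::net_forward(m, x,
                                                    keep_cache = FALSE)$out - y)^2)
  for (layer in c("stem", "a2", "b_se", "c2", "head1", "head2", "out")) {
    for (gn in names(g[[layer]])) {
      pn <- sub("^d", "", gn)
      len <- length(model$params[[layer]][[pn]])
      for (i in unique(c(1L, len))) {
        m2 <- model
        m2$params[[layer]][[pn]][i] <- m2$params[[layer]][[pn]][i] + eps
        lp <- loss_at(m2)
        m2$params[[layer]][[pn]][i] <- m2$params[[layer]][[pn]][i] - 2 * eps
        lm <- loss_at(m2)
        num <- (lp - lm) / (2 * eps)
        expect_equal(g[[layer]][[gn]][i], num, tolerance = 1e-4,
                     info = paste(layer, pn, i))
      }
    }
  }
})

test_that("toy training reduces the loss and is seed-deterministic", {
  data <- toy_dataset(32, seed = 4)
  model <- fpm_network(channels = 8, growth = 4, seed = 5)
  cfg <- train_config(learning_rate = 1e-3, batch_size = 4, epochs = 20,
                      seed = 6)
  fit1 <- fpm_train(model, data, cfg)
  expect_equal(nrow(fit1$history), 20)
  expect_lt(tail(fit1$history$train_loss, 1), fit1$history$train_loss[1])
  fit2 <- fpm_train(model, data, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$model$params, fit2$model$params)
})

test_that("the model can overfit a single example to near-zero error", {
  ex <- toy_dataset(1, seed = 7)[[1]]
  model <- fpm_network(channels = 8, growth = 4, seed = 8)
  fit <- fpm_train(model, list(ex),
                   train_config(learning_rate = 2e-3, batch_size = 1,
                                epochs = 200, seed = 9))
  pred <- predict(fit$model, ex$input, raw = TRUE)
  expect_lt(mean((pred - ex$truth)^2), 1e-3)
  # and the trained model beats the untrained one on its own example
  before <- predict(model, ex$input, raw = TRUE)
  expect_lt(mean((pred - ex$truth)^2), mean((before - ex$truth)^2))
})

test_that("validation losses are tracked alongside training", {
  data <- toy_dataset(8, seed = 10)
  fit <- fpm_train(fpm_network(seed = 11), data[1:6],
                   train_config(learning_rate = 1e-3, epochs = 3, seed = 12),
                   validation = data[7:8])
  expect_true(all(c("train_loss", "val_loss") %in% names(fit$history)))
  expect_true(all(is.finite(fit$history$val_loss)))
})
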