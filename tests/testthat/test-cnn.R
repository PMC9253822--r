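test_that("channel attention gates follow the closed forms", {
  C <- 3L; L <- 5L
  set.seed(1)
  F_in <- matrix(rnorm(C * L), C, L)
  # saturated MLP: gates -> 1, so F_c -> F
  block <- list(W1 = matrix(0, C, 2), b1 = c(0, 0),
                W2 = matrix(0, 2, C), b2 = rep(50, C))
  out <- cam_forward(F_in, block)
  expect_equal(out$F_c, F_in, tolerance = 1e-12)
  # single channel, identity MLP, constant activation v: gate = sigmoid(2v)
  v <- 0.37
  blk1 <- list(W1 = matrix(1, 1, 1), b1 = 0,
               W2 = matrix(1, 1, 1), b2 = 0)
  out1 <- cam_forward(matrix(v, 1, 4), blk1)
  expect_equal(unname(out1$weights), 1 / (1 + exp(-2 * v)))
  expect_equal(out1$F_c, matrix(v, 1, 4) / (1 + exp(-2 * v)))
  # all-zero input gives F_c = 0 with gates strictly inside (0, 1)
  set.seed(2)
  blk2 <- list(W1 = matrix(rnorm(6), 3), b1 = rnorm(2),
               W2 = matrix(rnorm(6), 2), b2 = rnorm(3))
  out0 <- cam_forward(matrix(0, 3, 4), blk2)
  expect_true(all(out0$F_c == 0))
  expect_true(all(out0$weights > 0 & out0$weights < 1))
})

test_that("layer shapes follow the published architecture", {
  cfg <- network_config(n_f = 9, n_class = 4, seed = 1)
  expect_equal(cfg$conv_filters, 512L)
  expect_equal(cfg$dense_widths, c(2048L, 1024L))
  expect_equal(cfg$dropout, 0.4)
  expect_equal(cfg$epochs, 150L)
  expect_equal(cfg$batch_size, 20L)
  expect_equal(cfg$learning_rate, 0.01)
  params <- cnn_init(cfg)
  expect_equal(dim(params$Wc), c(3L, 512L))
  expect_equal(nrow(params$Wd1), 9L * 512L)   # flattened width 4,608
  expect_equal(dim(params$Wd3), c(1024L, 4L))
  probs <- network_forward(matrix(rnorm(3 * 9), 3, 9), cfg, params)
  expect_equal(dim(probs), c(3L, 4L))
  expect_lt(max(abs(rowSums(probs) - 1)), 1e-6)
  expect_error(network_forward(matrix(0, 2, 5), cfg), "n_f")
})

test_that("disabling attention equals forcing unit gates", {
  cfg_on <- network_config(n_f = 6, n_class = 3, attention = TRUE,
                           conv_filters = 8, dense_widths = c(16, 8),
                           dropout = 0, bottleneck_ratio = 2, seed = 5)
  cfg_off <- cfg_on; cfg_off$attention <- FALSE
  params <- cnn_init(cfg_on)   # shared non-attention weights, same seed
  set.seed(9)
  X <- matrix(rnorm(4 * 6), 4, 6)
  on1 <- residuemap:::cnn_forward(params, X, cfg_on, force_gate = 1)
  off <- residuemap:::cnn_forward(params, X, cfg_off)
  expect_equal(on1$logits, off$logits, tolerance = 1e-12)
  # real gates are strictly inside (0, 1)
  on <- residuemap:::cnn_forward(params, X, cfg_on)
  expect_true(all(on$s > 0 & on$s < 1))
})

test_that("backpropagation matches finite differences", {
  cfg <- network_config(n_f = 5, n_class = 3, attention = TRUE,
                        conv_filters = 4, dense_widths = c(8, 6),
                        dropout = 0, bottleneck_ratio = 2, seed = 3)
  p <- cnn_init(cfg)
  set.seed(4)
  X <- matrix(rnorm(4 * 5), 4, 5)
  y <- c(1, 2, 3, 1)
  Y <- diag(3)[y, ]
  loss_of <- function(pp) {
    pr <- residuemap:::cnn_forward(pp, X, cfg)$probs
    -mean(log(pr[cbind(1:4, y)]))
  }
  g <- residuemap:::cnn_backward(p, residuemap:::cnn_forward(p, X, cfg),
                                 Y, cfg)
  for (nm in names(g)) {
    for (k in sample(length(p[[nm]]), min(3, length(p[[nm]])))) {
      eps <- 1e-6
      p2 <- p; p2[[nm]][k] <- p2[[nm]][k] + eps
      num <- (loss_of(p2) - loss_of(p)) / eps
      expect_equal(g[[nm]][k], num, tolerance = 1e-3)
    }
  }
})

test_that("training reduces the loss and is seed-deterministic", {
  set.seed(8)
  n <- 200
  lab <- sample(1:3, n, replace = TRUE)
  X <- matrix(rnorm(n * 4), n, 4) + 3 * diag(4)[c(lab, lab)[1:n], 1:4] * 0 +
    3 * cbind(lab == 1, lab == 2, lab == 3, 0)
  cfg <- network_config(n_f = 4, n_class = 3, conv_filters = 8,
                        dense_widths = c(16, 8), epochs = 10,
                        dropout = 0.1, seed = 2)
  fit <- cnn_train(X, lab, cfg)
  expect_lt(mean(tail(fit$loss, 2)), mean(head(fit$loss, 2)))
  fit2 <- cnn_train(X, lab, cfg)
  expect_identical(fit$params, fit2$params)
})
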