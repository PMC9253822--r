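#' Network configuration for the 1D convolutional classifier
#'
#' The default architecture takes the `n_f` features of a pixel as a
#' length-`n_f`, single-channel sequence and applies: Conv1D (512
#' filters, kernel 3, same padding) + ReLU, optionally the channel
#' attention module, flatten (width `n_f * 512`), dropout 0.4, dense 2048
#' (ReLU), dense 1024 (ReLU), dense `n_class` (linear), softmax. Training
#' uses cross-entropy loss and Adam at the initial learning rate 0.01 for
#' 150 epochs with batch size 20.
#'
#' `fast = TRUE` switches to a reduced profile (64 filters, dense
#' 256/128, 30 epochs) used for quick experiments and the test suite.
#'
#' @param n_f input feature count.
#' @param n_class output class count (>= 2).
#' @param attention enable the channel attention module (`cnn_ca`).
#' @param conv_filters,kernel_size convolution width and kernel.
#' @param dense_widths widths of the two hidden dense layers.
#' @param dropout dropout fraction after flatten.
#' @param epochs,batch_size,learning_rate optimizer settings.
#' @param bottleneck_ratio channel/bottleneck ratio of the shared
#'   attention perceptron.
#' @param fast use the reduced profile.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @export
network_config <- function(n_f, n_class, attention = TRUE,
                           conv_filters = 512L, kernel_size = 3L,
                           dense_widths = c(2048L, 1024L), dropout = 0.4,
                           epochs = 150L, batch_size = 20L,
                           learning_rate = 0.01, bottleneck_ratio = 8L,
                           fast = FALSE, seed = 1L) {
  if (fast) {
    if (missing(conv_filters)) conv_filters <- 64L
    if (missing(dense_widths)) dense_widths <- c(256L, 128L)
    if (missing(epochs)) epochs <- 30L
  }
  stopifnot(n_f >= 1, n_class >= 2, dropout >= 0, dropout < 1,
            kernel_size %% 2 == 1)
  structure(list(n_f = as.integer(n_f), n_class = as.integer(n_class),
                 attention = attention,
                 conv_filters = as.integer(conv_filters),
                 kernel_size = as.integer(kernel_size),
                 dense_widths = as.integer(dense_widths),
                 dropout = dropout, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 bottleneck_ratio = as.integer(bottleneck_ratio),
                 seed = as.integer(seed)),
            class = "network_config")
}

sigmoid <- function(x) 1 / (1 + exp(-x))
relu <- function(x) pmax(x, 0)

he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

#' Initialize network parameters
#'
#' @param config a [network_config()].
#' @return named list of weight matrices and bias vectors.
#' @export
cnn_init <- function(config) {
  with_seed(config$seed, {
    L <- config$n_f; C <- config$conv_filters; K <- config$kernel_size
    Cb <- max(1L, C %/% config$bottleneck_ratio)
    H1 <- config$dense_widths[1]; H2 <- config$dense_widths[2]
    p <- list(
      Wc = he_init(K, C, K), bc = numeric(C),
      Wd1 = he_init(L * C, H1, L * C), bd1 = numeric(H1),
      Wd2 = he_init(H1, H2, H1), bd2 = numeric(H2),
      Wd3 = matrix(stats::rnorm(H2 * config$n_class, 0, sqrt(1 / H2)),
                   H2, config$n_class),
      bd3 = numeric(config$n_class))
    if (config$attention) {
      p$Wa1 <- he_init(C, Cb, C); p$ba1 <- numeric(Cb)
      p$Wa2 <- matrix(stats::rnorm(Cb * C, 0, sqrt(1 / Cb)), Cb, C)
      p$ba2 <- numeric(C)
    }
    p
  })
}

#' Channel attention forward pass
#'
#' Computes per-channel gates `M(F) = sigmoid(MLP(avgpool(F)) +
#' MLP(maxpool(F)))` with a shared two-layer perceptron (pooling over the
#' length axis) and returns `F_c = M(F) * F` broadcast along the length
#' axis. Gates are strictly inside (0, 1) for finite inputs.
#'
#' @param F_in channels x length numeric matrix (one sample).
#' @param block list with `W1` (C x Cb), `b1`, `W2` (Cb x C), `b2`.
#' @return list with `F_c` (same shape as `F_in`) and `weights` (length-C
#'   gate vector).
#' @export
cam_forward <- function(F_in, block) {
  stopifnot(is.matrix(F_in), nrow(F_in) == nrow(block$W1),
            ncol(block$W1) == nrow(block$W2),
            ncol(block$W2) == nrow(F_in))
  mlp <- function(v) {
    drop(relu(v %*% block$W1 + block$b1) %*% block$W2 + block$b2)
  }
  a <- mlp(matrix(rowMeans(F_in), 1))
  m <- mlp(matrix(apply(F_in, 1, max), 1))
  s <- sigmoid(a + m)
  list(F_c = F_in * s, weights = s)
}

# Forward pass for a batch. X: B x n_f standardized features. Returns the
# cache needed for backprop when train = TRUE (dropout active).
cnn_forward <- function(params, X, config, train = FALSE,
                        force_gate = NULL) {
  B <- nrow(X); L <- config$n_f; C <- config$conv_filters
  K <- config$kernel_size; hp <- (K - 1L) %/% 2L
  Xp <- cbind(matrix(0, B, hp), X, matrix(0, B, hp))
  Z0 <- array(0, c(B, L, C))
  for (l in seq_len(L)) {
    Z0[, l, ] <- Xp[, l:(l + K - 1L), drop = FALSE] %*% params$Wc +
      rep(params$bc, each = B)
  }
  Fa <- array(relu(Z0), c(B, L, C))
  cache <- list(Xp = Xp, Z0 = Z0, Fa = Fa)
  if (config$attention) {
    Fp <- aperm(Fa, c(2, 1, 3))            # L x B x C
    Ap <- matrix(colMeans(Fp), B, C)       # average pool over length
    Mp <- matrix(Fa[, 1, ], B, C)
    arg <- matrix(1L, B, C)
    if (L > 1) for (l in 2:L) {
      cur <- matrix(Fa[, l, ], B, C)
      upd <- cur > Mp
      Mp[upd] <- cur[upd]; arg[upd] <- l
    }
    ha <- relu(Ap %*% params$Wa1 + rep(params$ba1, each = B))
    hm <- relu(Mp %*% params$Wa1 + rep(params$ba1, each = B))
    z <- ha %*% params$Wa2 + hm %*% params$Wa2 + rep(params$ba2, each = B)
    s <- if (is.null(force_gate)) sigmoid(z) else
      matrix(force_gate, B, C)
    Fc <- Fa * aperm(array(s, c(B, C, L)), c(1, 3, 2))
    cache <- c(cache, list(Ap = Ap, Mp = Mp, arg = arg, ha = ha, hm = hm,
                           s = s))
  } else {
    Fc <- Fa
  }
  Xf <- matrix(Fc, B, L * C)
  if (train && config$dropout > 0) {
    keep <- matrix(stats::rbinom(B * L * C, 1L, 1 - config$dropout),
                   B, L * C) / (1 - config$dropout)
    Xf <- Xf * keep
    cache$keep <- keep
  }
  d1 <- relu(Xf %*% params$Wd1 + rep(params$bd1, each = B))
  d2 <- relu(d1 %*% params$Wd2 + rep(params$bd2, each = B))
  logits <- d2 %*% params$Wd3 + rep(params$bd3, each = B)
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  c(cache, list(Xf = Xf, d1 = d1, d2 = d2, logits = logits, probs = probs))
}

#' Network forward pass to class probabilities
#'
#' Convenience wrapper running one (seeded-initialization) forward pass;
#' mainly useful for inspecting layer shapes and softmax output.
#'
#' @param X batch matrix, `n_f` columns.
#' @param config a [network_config()].
#' @param params optional parameter list (default: fresh [cnn_init()]).
#' @return matrix of class probabilities, rows summing to 1.
#' @export
network_forward <- function(X, config, params = NULL) {
  X <- as.matrix(X)
  if (ncol(X) != config$n_f) stop("input length must equal n_f")
  if (is.null(params)) params <- cnn_init(config)
  cnn_forward(params, X, config, train = FALSE)$probs
}

cnn_backward <- function(params, cache, Y, config) {
  B <- nrow(Y); L <- config$n_f; C <- config$conv_filters
  K <- config$kernel_size
  g <- list()
  dlogits <- (cache$probs - Y) / B
  g$Wd3 <- t(cache$d2) %*% dlogits; g$bd3 <- colSums(dlogits)
  dd2 <- (dlogits %*% t(params$Wd3)) * (cache$d2 > 0)
  g$Wd2 <- t(cache$d1) %*% dd2; g$bd2 <- colSums(dd2)
  dd1 <- (dd2 %*% t(params$Wd2)) * (cache$d1 > 0)
  g$Wd1 <- t(cache$Xf) %*% dd1; g$bd1 <- colSums(dd1)
  dXf <- dd1 %*% t(params$Wd1)
  if (!is.null(cache$keep)) dXf <- dXf * cache$keep
  dFc <- array(dXf, c(B, L, C))
  if (config$attention) {
    s <- cache$s
    sArr <- aperm(array(s, c(B, C, L)), c(1, 3, 2))
    dF <- dFc * sArr
    tmp <- dFc * cache$Fa
    ds <- matrix(colSums(aperm(tmp, c(2, 1, 3))), B, C)
    dz <- ds * s * (1 - s)
    dha <- (dz %*% t(params$Wa2)) * (cache$ha > 0)
    dhm <- (dz %*% t(params$Wa2)) * (cache$hm > 0)
    g$Wa2 <- t(cache$ha) %*% dz + t(cache$hm) %*% dz
    g$ba2 <- colSums(dz)
    g$Wa1 <- t(cache$Ap) %*% dha + t(cache$Mp) %*% dhm
    g$ba1 <- colSums(dha) + colSums(dhm)
    dAp <- dha %*% t(params$Wa1)
    dMp <- dhm %*% t(params$Wa1)
    for (l in seq_len(L)) {
      dF[, l, ] <- dF[, l, ] + dAp / L + dMp * (cache$arg == l)
    }
  } else {
    dF <- dFc
  }
  dZ0 <- dF * (cache$Z0 > 0)
  g$Wc <- matrix(0, K, C); g$bc <- numeric(C)
  for (l in seq_len(L)) {
    dZl <- matrix(dZ0[, l, ], B, C)
    g$Wc <- g$Wc + t(cache$Xp[, l:(l + K - 1L), drop = FALSE]) %*% dZl
    g$bc <- g$bc + colSums(dZl)
  }
  g
}

#' Train the 1D convolutional network
#'
#' Mini-batch Adam on cross-entropy loss. All randomness (initialization,
#' epoch shuffling, dropout) is governed by the config seed.
#'
#' @param X standardized feature matrix (rows = samples).
#' @param y integer class index per sample (1-based, `1..n_class`).
#' @param config a [network_config()].
#' @return list with `params`, `config` and the per-epoch mean `loss`.
#' @export
cnn_train <- function(X, y, config) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == config$n_f, all(y >= 1), all(y <= config$n_class))
  params <- cnn_init(config)
  m <- lapply(params, function(p) p * 0)
  v <- lapply(params, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; t <- 0
  Y <- matrix(0, nrow(X), config$n_class)
  Y[cbind(seq_len(nrow(X)), y)] <- 1
  losses <- numeric(config$epochs)
  with_seed(config$seed + 1L, {
    for (ep in seq_len(config$epochs)) {
      ord <- sample(nrow(X))
      batch_loss <- c()
      for (start in seq(1, nrow(X), by = config$batch_size)) {
        take <- ord[start:min(start + config$batch_size - 1L, nrow(X))]
        cache <- cnn_forward(params, X[take, , drop = FALSE], config,
                             train = TRUE)
        batch_loss <- c(batch_loss,
                        -mean(log(pmax(cache$probs[cbind(
                          seq_along(take), y[take])], 1e-12))))
        grads <- cnn_backward(params, cache, Y[take, , drop = FALSE],
                              config)
        t <- t + 1
        for (nm in names(grads)) {
          m[[nm]] <- b1 * m[[nm]] + (1 - b1) * grads[[nm]]
          v[[nm]] <- b2 * v[[nm]] + (1 - b2) * grads[[nm]]^2
          mhat <- m[[nm]] / (1 - b1^t)
          vhat <- v[[nm]] / (1 - b2^t)
          params[[nm]] <- params[[nm]] -
            config$learning_rate * mhat / (sqrt(vhat) + eps)
        }
      }
      losses[ep] <- mean(batch_loss)
    }
  })
  list(params = params, config = config, loss = losses)
}
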