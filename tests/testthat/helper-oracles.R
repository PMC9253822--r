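# Independent oracles used across the suite. These deliberately avoid the
# package's internal code paths: filters are hard-coded from the published
# Daubechies-3 taps and applied by explicit periodized convolution.

oracle_db3_lo <- c(0.3326705529509569, 0.8068915093133388,
                   0.4598775021193313, -0.1350110200103908,
                   -0.0854412738822415, 0.0352262918821007)
oracle_db3_hi <- (-1)^(0:5) * rev(oracle_db3_lo)

# periodized convolve + downsample-by-2 of a length-n signal
oracle_conv_ds <- function(x, h) {
  n <- length(x)
  vapply(seq_len(n / 2), function(k) {
    s <- 0
    for (t in seq_along(h)) {
      s <- s + h[t] * x[((2 * (k - 1) + t - 1) %% n) + 1]
    }
    s
  }, numeric(1))
}

# analysis operator as a matrix, built column-by-column from the
# convolution above (basis-vector probing)
oracle_step_matrix <- function(h, n) {
  cols <- vapply(seq_len(n), function(j) {
    e <- numeric(n); e[j] <- 1
    oracle_conv_ds(e, h)
  }, numeric(n / 2))
  matrix(cols, nrow = n / 2, ncol = n)
}

# full M-level pyramid of a w x w window; returns the four final-level
# scalars c(A, H, V, D); H carries the high-pass along the row axis
oracle_window_coeffs <- function(win) {
  w <- nrow(win)
  M <- as.integer(log2(w))
  A <- win
  for (m in seq_len(M)) {
    s <- nrow(A)
    L <- oracle_step_matrix(oracle_db3_lo, s)
    H <- oracle_step_matrix(oracle_db3_hi, s)
    lo_r <- A %*% t(L)
    hi_r <- A %*% t(H)
    fin <- list(A = L %*% lo_r, H = H %*% lo_r,
                V = L %*% hi_r, D = H %*% hi_r)
    A <- fin$A
  }
  c(fin$A, fin$H, fin$V, fin$D)
}

# naive per-pixel sliding-window feature image (reflect padding, pixel
# anchored at window position w/2, 0-based)
oracle_feature_image <- function(img, w, rule = "maxabs") {
  r <- nrow(img); cc <- ncol(img); p <- w / 2
  ri <- c(rev(seq_len(p)), seq_len(r), r + 1 - seq_len(p))
  ci <- c(rev(seq_len(p)), seq_len(cc), cc + 1 - seq_len(p))
  xp <- img[ri, ci]
  out <- matrix(0, r, cc)
  for (i in seq_len(r)) {
    for (j in seq_len(cc)) {
      cf <- oracle_window_coeffs(xp[i:(i + w - 1), j:(j + w - 1)])
      out[i, j] <- if (rule == "approx") cf[1] else cf[which.max(abs(cf))]
    }
  }
  out
}

# flood-fill connected components of `value` pixels in an integer matrix;
# returns sorted component sizes
oracle_flood_sizes <- function(labels, value, connectivity = 4L) {
  r <- nrow(labels); cc <- ncol(labels)
  seen <- matrix(FALSE, r, cc)
  offs <- if (connectivity == 4L) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    expand_off <- expand.grid(dr = -1:1, dc = -1:1)
    expand_off <- expand_off[!(expand_off$dr == 0 & expand_off$dc == 0), ]
    split(as.matrix(expand_off), seq_len(nrow(expand_off)))
  }
  sizes <- integer()
  for (sr in seq_len(r)) for (sc in seq_len(cc)) {
    if (seen[sr, sc] || labels[sr, sc] != value) next
    queue <- list(c(sr, sc)); seen[sr, sc] <- TRUE; size <- 0L
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]; size <- size + 1L
      for (d in offs) {
        nr <- cur[1] + d[1]; nc <- cur[2] + d[2]
        if (nr >= 1 && nr <= r && nc >= 1 && nc <= cc &&
            !seen[nr, nc] && labels[nr, nc] == value) {
          seen[nr, nc] <- TRUE
          queue[[length(queue) + 1L]] <- c(nr, nc)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sort(sizes)
}

# shared small synthetic scene + feature stack, built once per test run
fixture_env <- new.env()
fixture_scene <- function() {
  if (is.null(fixture_env$scene)) {
    sc <- generate_scene(scene_spec(size = c(128, 128), seed = 11))
    stack <- build_feature_stack(sc$image)
    samples <- generate_sample_set(sc$truth, 300, seed = 11)
    fixture_env$scene <- list(scene = sc, stack = stack,
                              samples = samples,
                              tab = features_at(stack, samples))
  }
  fixture_env$scene
}
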