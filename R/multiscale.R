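#' Multi-scale wavelet feature image
#'
#' For every pixel, the neighbourhood window of side `window_size`
#' (anchored so that the pixel sits at window position `2^(M-1)`,
#' i.e. just below-right of the geometric centre of the even window) is
#' decomposed `M = log2(window_size)` levels with the periodized wavelet
#' filter bank and fused to one value, compressing the spatial context of
#' the window into the pixel. Image edges are handled by reflect-padding
#' the input before windowing.
#'
#' The implementation exploits linearity: the four final-level window
#' coefficients are separable linear functionals of the window, so the
#' whole feature image reduces to four separable sliding correlations
#' followed by the per-pixel fusion rule. It is numerically identical to
#' running the explicit per-window pyramid at every pixel.
#'
#' @param component r x c numeric matrix (typically the rescaled first
#'   principal component).
#' @param window_size window side, one of 2, 4, 8, 16, 32, 64.
#' @param wavelet wavelet name, default `"db3"`.
#' @param rule fusion rule, `"maxabs"` (default) or `"approx"`.
#' @param normalize `"none"` returns raw coefficients (a constant input
#'   `v` yields `v * 2^M`); `"gain"` divides by the `2^M` constant gain
#'   so feature values stay on the DN scale of the input, which is what
#'   the block-variance heterogeneity diagnostic uses.
#' @return r x c numeric feature image.
#' @export
extract_feature_image <- function(component, window_size, wavelet = "db3",
                                  rule = c("maxabs", "approx"),
                                  normalize = c("none", "gain")) {
  rule <- match.arg(rule)
  normalize <- match.arg(normalize)
  stopifnot(is.matrix(component))
  w <- as.integer(window_size)
  if (w < 2 || bitwAnd(w, w - 1L) != 0) {
    stop("window_size must be a power of two >= 2")
  }
  r <- nrow(component); cc <- ncol(component)
  p <- w %/% 2L
  if (p >= r || p >= cc) {
    stop("window larger than the padded image supports")
  }
  fun <- wavelet_functionals(w, wavelet)
  Xp <- pad_reflect(component, p)
  rowpass <- function(u) {
    Y <- matrix(0, r, cc + 2L * p)
    for (t in seq_len(w)) Y <- Y + u[t] * Xp[t:(t + r - 1L), , drop = FALSE]
    Y
  }
  colpass <- function(Y, v) {
    Fm <- matrix(0, r, cc)
    for (t in seq_len(w)) Fm <- Fm + v[t] * Y[, t:(t + cc - 1L), drop = FALSE]
    Fm
  }
  Ya <- rowpass(fun$alpha)
  A <- colpass(Ya, fun$alpha)
  if (rule == "approx") {
    feat <- A
  } else {
    Yb <- rowpass(fun$beta)
    V <- colpass(Ya, fun$beta)    # hi along columns
    H <- colpass(Yb, fun$alpha)   # hi along rows
    D <- colpass(Yb, fun$beta)
    feat <- A; fabs <- abs(A)
    for (cand in list(H, V, D)) {
      m <- abs(cand) > fabs
      feat[m] <- cand[m]
      fabs[m] <- abs(cand[m])
    }
  }
  if (normalize == "gain") feat <- feat / w else feat
}

ms_layer_names <- function(windows) paste0("B_ms", windows)

#' Names of the optimal image dataset layers
#'
#' The nine-feature stack (four spectral bands plus the 4-64 pixel
#' multi-scale layers) selected by the importance-guided subset search.
#' @export
oid_features <- function() {
  c("B_blue", "B_green", "B_red", "B_nir",
    "B_ms4", "B_ms8", "B_ms16", "B_ms32", "B_ms64")
}

#' Names of the spectral-only baseline layers
#' @export
dt1_features <- function() c("B_blue", "B_green", "B_red", "B_nir")

#' Build the per-pixel feature stack
#'
#' Assembles the named feature layers on the image grid: the spectral
#' bands (`B_<band>`), the rescaled first principal component (`PC1`),
#' and the multi-scale wavelet layers (`B_ms2` ... `B_ms64`) computed
#' from PC1. Multi-scale layers are standardized to zero mean and unit
#' variance before classifier use; spectral layers and PC1 are kept on
#' their DN scale (per-model standardization happens inside
#' [train_classifier()] where a method needs it).
#'
#' @param image an `msi_image`.
#' @param windows multi-scale window sizes, default `c(2,4,8,16,32,64)`.
#' @param wavelet wavelet name.
#' @param rule coefficient fusion rule.
#' @param layers optional character vector restricting which layers to
#'   build (e.g. [dt1_features()]).
#' @param standardize_ms standardize multi-scale layers (default TRUE).
#' @return a `feature_stack`: named list of r x c `layers`, per-layer
#'   `provenance`, and the valid-pixel `mask`.
#' @export
build_feature_stack <- function(image, windows = c(2, 4, 8, 16, 32, 64),
                                wavelet = "db3",
                                rule = c("maxabs", "approx"),
                                layers = NULL, standardize_ms = TRUE) {
  rule <- match.arg(rule)
  stopifnot(inherits(image, "msi_image"))
  spectral <- paste0("B_", image$band_names)
  all_names <- c(spectral, "PC1", ms_layer_names(windows))
  if (is.null(layers)) layers <- all_names
  if (!all(layers %in% all_names)) {
    stop("unknown layer(s): ",
         paste(setdiff(layers, all_names), collapse = ", "))
  }
  out <- list(); prov <- list()
  for (b in seq_along(spectral)) {
    if (spectral[b] %in% layers) {
      out[[spectral[b]]] <- get_band(image, b)
      prov[[spectral[b]]] <- list(kind = "spectral", band = image$band_names[b])
    }
  }
  ms_wanted <- intersect(ms_layer_names(windows), layers)
  need_pc1 <- "PC1" %in% layers || length(ms_wanted) > 0
  if (need_pc1) {
    pc1 <- pc1_image(image)
    if ("PC1" %in% layers) {
      out$PC1 <- pc1
      prov$PC1 <- list(kind = "pca", component = 1, rescaled = "0-255")
    }
    for (w in windows) {
      nm <- paste0("B_ms", w)
      if (!(nm %in% ms_wanted)) next
      f <- extract_feature_image(pc1, w, wavelet, rule)
      p <- list(kind = "multiscale", window = w, wavelet = wavelet,
                fusion = rule, standardized = standardize_ms)
      if (standardize_ms) {
        mu <- mean(f); sd <- stats::sd(as.vector(f))
        if (sd == 0) sd <- 1
        f <- (f - mu) / sd
        p$center <- mu; p$scale <- sd
      }
      out[[nm]] <- f
      prov[[nm]] <- p
    }
  }
  out <- out[intersect(all_names, names(out))]
  structure(list(layers = out, provenance = prov, mask = valid_mask(image)),
            class = "feature_stack")
}

#' @export
print.feature_stack <- function(x, ...) {
  dm <- dim(x$layers[[1]])
  cat(sprintf("<feature_stack> %d layer(s) on %d x %d grid: %s\n",
              length(x$layers), dm[1], dm[2],
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Per-sample feature table from a stack
#'
#' @param stack a `feature_stack`.
#' @param samples a `sample_set` on the same grid.
#' @param features layer names to extract (default all).
#' @return data.frame of feature values, rows aligned with `samples`.
#' @export
features_at <- function(stack, samples, features = NULL) {
  if (is.null(features)) features <- names(stack$layers)
  r <- nrow(stack$layers[[1]])
  idx <- sample_pixel_index(samples, r)
  out <- lapply(features, function(nm) {
    lay <- stack$layers[[nm]]
    if (is.null(lay)) stop("stack has no layer ", nm)
    lay[idx]
  })
  names(out) <- features
  as.data.frame(out, optional = TRUE)
}

# Full-grid feature matrix (r*c rows, column-major pixel order).
stack_matrix <- function(stack, features) {
  do.call(cbind, lapply(features, function(nm) {
    lay <- stack$layers[[nm]]
    if (is.null(lay)) stop("stack has no layer ", nm)
    as.vector(lay)
  }))
}

#' Block-variance heterogeneity diagnostic
#'
#' Splits a layer into disjoint `block_size` x `block_size` blocks
#' (trailing partial blocks dropped) and reports the population variance
#' of each block plus the overall population variance of the full layer.
#' Falling block variances with growing multi-scale window size indicate
#' that the features attenuate intra-object heterogeneity.
#'
#' @param layer numeric matrix.
#' @param block_size block side in pixels (>= 2).
#' @param mask optional logical matrix; FALSE pixels are excluded.
#' @return list with `blocks` (matrix of per-block variances) and
#'   `overall`.
#' @export
block_variance <- function(layer, block_size, mask = NULL) {
  stopifnot(is.matrix(layer))
  if (block_size < 2) stop("block_size must be >= 2")
  if (block_size > min(dim(layer))) stop("block_size exceeds layer extent")
  nb_r <- nrow(layer) %/% block_size
  nb_c <- ncol(layer) %/% block_size
  pvar <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 1) return(NA_real_)
    mean((v - mean(v))^2)
  }
  if (!is.null(mask)) layer[!mask] <- NA_real_
  blocks <- matrix(NA_real_, nb_r, nb_c)
  for (i in seq_len(nb_r)) {
    for (j in seq_len(nb_c)) {
      ri <- (i - 1L) * block_size + seq_len(block_size)
      ci <- (j - 1L) * block_size + seq_len(block_size)
      blocks[i, j] <- pvar(layer[ri, ci])
    }
  }
  list(blocks = blocks, overall = pvar(layer))
}
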