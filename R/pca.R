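#' Principal component analysis of a multispectral image
#'
#' Eigendecomposition of the d x d band covariance matrix computed over
#' all valid pixels (bands mean-centered, not standardized). The rotation
#' holds eigenvector rows so that component images are `X = A (Z - mean)`.
#' Eigenvector signs are fixed so the largest-magnitude entry of each row
#' is positive, making results reproducible across linear algebra
#' backends.
#'
#' @param image an `msi_image` with at least 2 bands.
#' @return a `pca_model` with fields `rotation` (d' x d), `eigenvalues`
#'   (DN^2, non-increasing), `band_means`, `contribution` (fractions
#'   summing to 1) and `band_names`.
#' @export
fit_pca <- function(image) {
  stopifnot(inherits(image, "msi_image"))
  d <- dim(image$pixels)[3]
  if (d < 2L) stop("PCA requires at least 2 bands")
  mask <- valid_mask(image)
  n <- sum(mask)
  if (n < d) stop("fewer valid pixels than bands")
  Z <- matrix(0, n, d)
  for (b in seq_len(d)) {
    v <- image$pixels[, , b]
    Z[, b] <- v[mask]
  }
  mu <- colMeans(Z)
  S <- stats::cov(Z)
  e <- eigen(S, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  rot <- t(e$vectors)
  for (i in seq_len(d)) {
    j <- which.max(abs(rot[i, ]))
    if (rot[i, j] < 0) rot[i, ] <- -rot[i, ]
  }
  tot <- sum(vals)
  if (tot == 0) stop("degenerate image: all bands constant")
  structure(list(rotation = rot, eigenvalues = vals, band_means = mu,
                 contribution = vals / tot, band_names = image$band_names),
            class = "pca_model")
}

#' @export
print.pca_model <- function(x, ...) {
  cat("<pca_model>", length(x$eigenvalues), "components\n")
  cat("  contribution:",
      paste(sprintf("%.2f%%", 100 * x$contribution), collapse = ", "), "\n")
  invisible(x)
}

#' Variance contribution rates
#'
#' Each eigenvalue divided by the sum of all eigenvalues: the fraction of
#' total band variance carried by each component.
#'
#' @param model a fitted `pca_model`.
#' @export
variance_contributions <- function(model) {
  stopifnot(inherits(model, "pca_model"))
  if (sum(model$eigenvalues) == 0) stop("degenerate model: zero variance")
  model$eigenvalues / sum(model$eigenvalues)
}

#' Project an image onto its principal components
#'
#' @param image the `msi_image` the model was fitted on (or one with the
#'   same bands).
#' @param model a `pca_model`.
#' @param k number of leading components to return.
#' @return list of `k` component images, each a list with `pixels`
#'   (r x c matrix of the mean-centered projection) and `component_index`.
#' @export
pca_transform <- function(image, model, k = 1L) {
  stopifnot(inherits(image, "msi_image"), inherits(model, "pca_model"))
  d <- dim(image$pixels)[3]
  if (d != ncol(model$rotation)) stop("band count mismatch")
  if (k < 1L || k > nrow(model$rotation)) stop("k out of range 1..d'")
  r <- dim(image$pixels)[1]; c <- dim(image$pixels)[2]
  out <- vector("list", k)
  for (i in seq_len(k)) {
    comp <- matrix(0, r, c)
    for (b in seq_len(d)) {
      comp <- comp + model$rotation[i, b] *
        (image$pixels[, , b] - model$band_means[b])
    }
    out[[i]] <- structure(list(pixels = comp, component_index = i),
                          class = "component_image")
  }
  out
}

#' Reconstruct bands from component images
#'
#' Inverse projection `Z = A' X + mean`; with all d components this is a
#' lossless reconstruction (rotation is orthonormal).
#'
#' @param components list of component images from [pca_transform()].
#' @param model the `pca_model` used for the forward transform.
#' @export
pca_inverse <- function(components, model) {
  stopifnot(inherits(model, "pca_model"))
  k <- length(components)
  dm <- dim(components[[1]]$pixels)
  d <- ncol(model$rotation)
  px <- array(0, c(dm[1], dm[2], d))
  for (b in seq_len(d)) {
    acc <- matrix(model$band_means[b], dm[1], dm[2])
    for (i in seq_len(k)) {
      acc <- acc + model$rotation[i, b] * components[[i]]$pixels
    }
    px[, , b] <- acc
  }
  multispectral_image(px, band_names = model$band_names)
}

#' First principal component rescaled to 0-255
#'
#' Convenience wrapper used before wavelet processing so that window
#' features are comparable across scenes. A constant component maps to 0.
#'
#' @param image an `msi_image`.
#' @param model optional pre-fitted `pca_model`.
#' @export
pc1_image <- function(image, model = NULL) {
  if (is.null(model)) model <- fit_pca(image)
  pc1 <- pca_transform(image, model, k = 1L)[[1]]$pixels
  rng <- range(pc1)
  if (rng[2] == rng[1]) return(matrix(0, nrow(pc1), ncol(pc1)))
  (pc1 - rng[1]) / (rng[2] - rng[1]) * 255
}
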