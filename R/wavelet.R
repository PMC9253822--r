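#' Wavelet filter taps
#'
#' Orthonormal analysis filters for the supported bases. `db3` (Daubechies,
#' 3 vanishing moments, 6 taps) is the default basis throughout the
#' package; `haar` is provided for didactic tests. The high-pass filter is
#' the quadrature mirror of the scaling filter,
#' `g[t] = (-1)^t h[L-1-t]`.
#'
#' @param name wavelet name, `"db3"` or `"haar"`.
#' @return list with numeric vectors `lo` and `hi`.
#' @export
wavelet_filters <- function(name = "db3") {
  lo <- switch(name,
    db3 = c(0.3326705529509569, 0.8068915093133388, 0.4598775021193313,
            -0.1350110200103908, -0.0854412738822415, 0.0352262918821007),
    haar = c(1, 1) / sqrt(2),
    stop("unknown wavelet: ", name))
  L <- length(lo)
  hi <- (-1)^(0:(L - 1)) * rev(lo)
  list(lo = lo, hi = hi, name = name)
}

# One periodized analysis step as a (w/2) x w matrix: row k (0-based)
# correlates the filter with the signal starting at sample 2k, indices
# wrapped modulo w. For w shorter than the filter the taps fold onto the
# same samples, which keeps the transform orthonormal at every even w
# (down to the Haar-like w = 2 case).
analysis_matrix <- function(filter, w) {
  stopifnot(w %% 2 == 0, w >= 2)
  M <- matrix(0, w / 2, w)
  for (k in 0:(w / 2 - 1)) {
    for (t in seq_along(filter)) {
      j <- (2 * k + t - 1) %% w
      M[k + 1, j + 1] <- M[k + 1, j + 1] + filter[t]
    }
  }
  M
}

#' Multi-level separable wavelet decomposition of a square window
#'
#' Implements the classic filter-bank pyramid: at each level the current
#' approximation is filtered along rows then columns with the periodized
#' low/high-pass pair and downsampled by two, yielding the approximation
#' `A` and the horizontal/vertical/diagonal detail sub-images `H`, `V`,
#' `D`. With a `2^M` window decomposed `M` levels the final sub-images
#' are single coefficients.
#'
#' @param window a `w x w` numeric matrix with `w` a power of two.
#' @param levels number of decomposition levels `M >= 1` (at most
#'   `log2(w)`).
#' @param wavelet wavelet name (see [wavelet_filters()]).
#' @return a `wavelet_pyramid`: list of per-level lists `A`, `H`, `V`,
#'   `D`, plus `wavelet` and `boundary` (always `"periodized"`).
#' @export
decompose_window <- function(window, levels, wavelet = "db3") {
  stopifnot(is.matrix(window), nrow(window) == ncol(window))
  w <- nrow(window)
  if (w < 2 || bitwAnd(w, w - 1L) != 0) {
    stop("window side must be a power of two >= 2")
  }
  if (levels < 1 || 2^levels > w) stop("levels out of range for window")
  f <- wavelet_filters(wavelet)
  out <- vector("list", levels)
  A <- window
  for (m in seq_len(levels)) {
    s <- nrow(A)
    L <- analysis_matrix(f$lo, s)
    H <- analysis_matrix(f$hi, s)
    # row pass: filter along each row (across columns), then column pass
    lo_r <- A %*% t(L); hi_r <- A %*% t(H)
    out[[m]] <- list(A = L %*% lo_r, H = H %*% lo_r,
                     V = L %*% hi_r, D = H %*% hi_r)
    A <- out[[m]]$A
  }
  structure(list(levels = out, wavelet = wavelet,
                 boundary = "periodized"),
            class = "wavelet_pyramid")
}

#' Fuse final-level wavelet coefficients to one value
#'
#' After a full decomposition (final sub-images 1 x 1), reduces the four
#' coefficients to a single feature value. `maxabs` keeps the coefficient
#' of largest absolute value (returned with its sign, ties resolved in
#' A, H, V, D order), discarding the lower-energy coefficients; `approx`
#' keeps the approximation coefficient.
#'
#' @param pyramid a `wavelet_pyramid` whose final level is 1 x 1.
#' @param rule `"maxabs"` or `"approx"`.
#' @export
fuse_coefficients <- function(pyramid, rule = c("maxabs", "approx")) {
  rule <- match.arg(rule)
  fin <- pyramid$levels[[length(pyramid$levels)]]
  if (length(fin$A) != 1L) {
    stop("final level must be 1 x 1; decompose the full window depth")
  }
  cf <- c(fin$A, fin$H, fin$V, fin$D)
  if (rule == "approx") cf[1] else cf[which.max(abs(cf))]
}

# 1-D linear functionals of the full M-level cascade on a length-w
# signal (w = 2^M): alpha . x is the final approximation coefficient,
# beta . x the final-level detail coefficient. Because the separable 2-D
# transform is a tensor product, the four final window coefficients are
# A = a' X a, H = b' X a (row functional b), V = a' X b, D = b' X b,
# which is what lets extract_feature_image run as separable filtering
# instead of an explicit per-window pyramid.
wavelet_functionals <- function(w, wavelet = "db3") {
  f <- wavelet_filters(wavelet)
  M <- as.integer(log2(w))
  stopifnot(2^M == w)
  P <- diag(w)
  s <- w
  while (s > 2) {
    P <- analysis_matrix(f$lo, s) %*% P
    s <- s / 2
  }
  list(alpha = as.vector(analysis_matrix(f$lo, 2) %*% P),
       beta  = as.vector(analysis_matrix(f$hi, 2) %*% P))
}
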