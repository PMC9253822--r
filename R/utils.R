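#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All stochastic operations in the package route through this so that a
# single seed argument makes a whole run reproducible without clobbering
# the user's random stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

#' Stratified train/validation assignment
#'
#' Returns a character vector of "train"/"validation" tags aligned with
#' `labels`; per-class train counts are `round(n_k * ratio)`, i.e. within
#' one record of the exact proportion. Deterministic under the seed.
#'
#' @param labels class id per record.
#' @param ratio train fraction (default 7:3).
#' @param seed RNG seed.
#' @export
stratified_split <- function(labels, ratio = 0.7, seed = 1L) {
  stopifnot(ratio > 0, ratio < 1)
  split <- character(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      n_train <- round(length(idx) * ratio)
      take <- if (length(idx) == 1L) idx[seq_len(n_train)] else
        sample(idx, n_train)
      split[idx] <- "validation"
      split[take] <- "train"
    }
  })
  split
}

clip01 <- function(x, lo = 0, hi = 255) pmin(pmax(x, lo), hi)

# Reflect-pad a matrix by `top/bottom/left/right` pixels (edge pixel not
# duplicated, i.e. "reflect" in the scipy sense of mode="mirror" is NOT
# used; this is symmetric half-sample reflection: a b c -> b a | a b c | c b).
pad_reflect <- function(x, top, bottom = top, left = top, right = left) {
  r <- nrow(x); c <- ncol(x)
  if (top >= r || bottom >= r || left >= c || right >= c) {
    stop("padding must be smaller than the grid extent")
  }
  ri <- c(rev(seq_len(top)), seq_len(r), r + 1 - seq_len(bottom))
  ci <- c(rev(seq_len(left)), seq_len(c), c + 1 - seq_len(right))
  x[ri, ci, drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
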