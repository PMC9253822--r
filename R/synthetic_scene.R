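#' Synthetic scene specification
#'
#' Describes a labeled multispectral test scene emulating the image
#' structure of harvested corn fields at ~1 m resolution: striped
#' bright/dark residue rows (Type 1), homogeneous bright full residue
#' cover (Type 2), dark stubble fields (Type 3), and heterogeneous
#' wide-range "other" surfaces. Per-class gray models follow the digital
#' number ranges observed for the three cover types (Type 1 and other:
#' 0-250, Type 2: 130-255, Type 3: 25-175).
#'
#' Bands are generated as one shared latent texture plus small
#' band-specific offsets and independent Gaussian noise, which produces
#' the strong cross-band correlation that makes the first principal
#' component dominate the band covariance.
#'
#' @param size integer `(r, c)` scene extent in pixels.
#' @param n_bands number of spectral bands (4 = blue/green/red/nir).
#' @param layout data.frame with columns `class`, `row0`, `col0`,
#'   `height`, `width` (0-based patch origins); patches must tile the
#'   grid without overlap. Default: one quadrant per class 1-4.
#' @param class_models named list (by class id) of `list(range = c(low,
#'   high), texture = ...)` with texture one of `"striped"`,
#'   `"homogeneous_bright"`, `"homogeneous_dark"`, `"speckled"`.
#' @param stripe_period stripe width in pixels for striped patches.
#' @param noise_sd per-band additive Gaussian noise, in DN.
#' @param band_offsets numeric per-band DN offsets added to the latent.
#' @param seed RNG seed.
#' @export
scene_spec <- function(size = c(512L, 512L), n_bands = 4L,
                       layout = NULL, class_models = NULL,
                       stripe_period = 3L, noise_sd = 8,
                       band_offsets = NULL, seed = 1L) {
  stopifnot(length(size) == 2L, all(size >= 1), n_bands >= 1,
            stripe_period >= 1)
  if (is.null(layout)) {
    r2 <- size[1] %/% 2; c2 <- size[2] %/% 2
    layout <- data.frame(
      class  = 1:4,
      row0   = c(0L, 0L, r2, r2),
      col0   = c(0L, c2, 0L, c2),
      height = c(r2, r2, size[1] - r2, size[1] - r2),
      width  = c(c2, size[2] - c2, c2, size[2] - c2))
  }
  if (is.null(class_models)) {
    class_models <- list(
      `1` = list(range = c(0, 250),   texture = "striped"),
      `2` = list(range = c(130, 255), texture = "homogeneous_bright"),
      `3` = list(range = c(25, 175),  texture = "homogeneous_dark"),
      `4` = list(range = c(0, 250),   texture = "speckled"))
  }
  if (is.null(band_offsets)) {
    band_offsets <- if (n_bands == 4L) c(-12, -4, 4, 14) else
      seq(-10, 10, length.out = n_bands)
  }
  stopifnot(length(band_offsets) == n_bands)
  for (m in class_models) {
    stopifnot(length(m$range) == 2L, m$range[1] < m$range[2],
              m$range[1] >= 0, m$range[2] <= 255)
  }
  # patches must tile the grid without overlap
  occ <- matrix(0L, size[1], size[2])
  for (k in seq_len(nrow(layout))) {
    p <- layout[k, ]
    if (p$row0 < 0 || p$col0 < 0 ||
        p$row0 + p$height > size[1] || p$col0 + p$width > size[2]) {
      stop("patch ", k, " extends outside the scene")
    }
    ri <- p$row0 + seq_len(p$height); ci <- p$col0 + seq_len(p$width)
    occ[ri, ci] <- occ[ri, ci] + 1L
  }
  if (any(occ > 1L)) stop("patches overlap")
  if (any(occ == 0L)) stop("patches must tile the whole grid")
  structure(list(size = as.integer(size), n_bands = as.integer(n_bands),
                 layout = layout, class_models = class_models,
                 stripe_period = as.integer(stripe_period),
                 noise_sd = noise_sd, band_offsets = band_offsets,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Spectral-confusion benchmark scene
#'
#' A [scene_spec()] engineered so that classes overlap spectrally but
#' differ in texture, emulating the confusion that makes per-pixel
#' spectral classification of residue cover hard: the bright rows of the
#' striped class match the homogeneous bright class, its dark rows match
#' the dark stubble class, and the speckled "other" class spans the full
#' gray range. Texture-aware multi-scale features are required to
#' separate the classes on such a scene.
#'
#' @param size scene extent.
#' @param seed RNG seed.
#' @param ... further arguments passed to [scene_spec()].
#' @export
overlap_scene_spec <- function(size = c(256L, 256L), seed = 1L, ...) {
  scene_spec(size = size, seed = seed,
             class_models = list(
               `1` = list(range = c(0, 250),   texture = "striped"),
               `2` = list(range = c(235, 255), texture = "homogeneous_bright"),
               `3` = list(range = c(0, 25),    texture = "homogeneous_dark"),
               `4` = list(range = c(0, 250),   texture = "speckled")),
             ...)
}

# Latent (noise-free) texture for one patch; values stay inside
# model$range before band offsets and noise are added.
patch_latent <- function(model, h, w, stripe_period) {
  lo <- model$range[1]; hi <- model$range[2]; span <- hi - lo
  switch(model$texture,
    striped = {
      stripe <- ((seq_len(h) - 1L) %/% stripe_period) %% 2L
      matrix(ifelse(stripe == 0L, hi, lo), h, w)
    },
    homogeneous_bright = ,
    homogeneous_dark = {
      base <- stats::runif(1, lo + 0.3 * span, hi - 0.15 * span)
      matrix(base, h, w)
    },
    speckled = matrix(stats::runif(h * w, lo, hi), h, w),
    stop("unknown texture kind: ", model$texture)
  )
}

#' Generate a labeled synthetic scene
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (an `msi_image`, values clipped to 0-255)
#'   and `truth` (a `class_map` holding the exact layout).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  r <- spec$size[1]; c <- spec$size[2]
  latent <- matrix(0, r, c)
  labels <- matrix(0L, r, c)
  with_seed(spec$seed, {
    for (k in seq_len(nrow(spec$layout))) {
      p <- spec$layout[k, ]
      ri <- p$row0 + seq_len(p$height); ci <- p$col0 + seq_len(p$width)
      model <- spec$class_models[[as.character(p$class)]]
      if (is.null(model)) stop("no gray model for class ", p$class)
      latent[ri, ci] <- patch_latent(model, p$height, p$width,
                                     spec$stripe_period)
      labels[ri, ci] <- p$class
    }
    px <- array(0, c(r, c, spec$n_bands))
    for (b in seq_len(spec$n_bands)) {
      noise <- if (spec$noise_sd > 0) {
        matrix(stats::rnorm(r * c, 0, spec$noise_sd), r, c)
      } else 0
      px[, , b] <- clip01(latent + spec$band_offsets[b] + noise)
    }
  })
  image <- multispectral_image(px, geotransform = c(0, 1, 0, 0, 0, -1))
  truth <- class_map(labels, class_names = default_class_names(),
                     provenance = list(generator = "synthetic_scene",
                                       seed = spec$seed))
  list(image = image, truth = truth)
}

#' Draw a labeled pixel sample set from a class map
#'
#' Uniform random pixels without replacement per class, with a seeded
#' stratified train/validation split.
#'
#' @param truth a `class_map` (typically the generated scene layout).
#' @param n_per_class samples per class.
#' @param seed RNG seed.
#' @param ratio train fraction (default 7:3).
#' @param classes class ids to sample; default all non-zero classes present.
#' @export
generate_sample_set <- function(truth, n_per_class, seed = 1L,
                                ratio = 0.7, classes = NULL) {
  stopifnot(inherits(truth, "class_map"), n_per_class >= 0)
  if (is.null(classes)) {
    classes <- sort(setdiff(unique(as.vector(truth$labels)), 0L))
  }
  r <- nrow(truth$labels)
  if (n_per_class == 0L || length(classes) == 0L) {
    rec <- data.frame(row = integer(), col = integer(), label = integer(),
                      split = character())
    return(sample_set(rec, truth$class_names))
  }
  recs <- with_seed(seed, {
    lapply(classes, function(cl) {
      avail <- which(truth$labels == cl)
      if (length(avail) < n_per_class) {
        stop(sprintf("class %d has only %d pixels (< %d requested)",
                     cl, length(avail), n_per_class))
      }
      idx <- sample(avail, n_per_class)
      data.frame(row = (idx - 1L) %% r, col = (idx - 1L) %/% r,
                 label = cl)
    })
  })
  rec <- do.call(rbind, recs)
  rec$split <- stratified_split(rec$label, ratio = ratio, seed = seed)
  sample_set(rec, truth$class_names)
}
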