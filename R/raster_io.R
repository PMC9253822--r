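#' Multispectral image container
#'
#' In-memory representation of a co-registered multi-band raster. Pixel
#' values are digital numbers (DN, unitless). All downstream modules
#' consume this type; file access happens only in [read_multispectral()]
#' and [write_raster()].
#'
#' @param pixels an `r x c` matrix (single band) or `r x c x d` array.
#' @param band_names character vector of unique band names; defaults to
#'   `band_1 ... band_d`, or `blue, green, red, nir` for 4-band imagery.
#' @param geotransform optional numeric 6-vector (origin x, pixel width,
#'   row rotation, origin y, column rotation, pixel height).
#' @param nodata optional numeric sentinel marking invalid pixels.
#' @return an object of class `msi_image` with fields `pixels`,
#'   `band_names`, `geotransform`, `nodata`.
#' @export
multispectral_image <- function(pixels, band_names = NULL,
                                geotransform = NULL, nodata = NULL) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  d <- dim(pixels)[3]
  if (any(dim(pixels) < 1L)) stop("image must have r >= 1, c >= 1, d >= 1")
  if (is.null(band_names)) {
    band_names <- if (d == 4L) c("blue", "green", "red", "nir")
                  else paste0("band_", seq_len(d))
  }
  if (length(band_names) != d) stop("band_names length must equal band count")
  if (anyDuplicated(band_names)) stop("band_names must be unique")
  if (!is.null(geotransform) && length(geotransform) != 6L) {
    stop("geotransform must be a numeric 6-vector")
  }
  structure(list(pixels = pixels, band_names = band_names,
                 geotransform = geotransform, nodata = nodata),
            class = "msi_image")
}

#' @export
print.msi_image <- function(x, ...) {
  dm <- dim(x$pixels)
  cat(sprintf("<msi_image> %d x %d pixels, %d band(s): %s\n",
              dm[1], dm[2], dm[3], paste(x$band_names, collapse = ", ")))
  if (!is.null(x$nodata)) cat("  nodata:", x$nodata, "\n")
  invisible(x)
}

#' @export
dim.msi_image <- function(x) dim(x$pixels)

#' Extract one band as a matrix
#' @param image an `msi_image`.
#' @param band band name or index.
#' @export
get_band <- function(image, band) {
  stopifnot(inherits(image, "msi_image"))
  if (is.character(band)) band <- match(band, image$band_names)
  if (is.na(band) || band < 1 || band > dim(image$pixels)[3]) {
    stop("unknown band")
  }
  image$pixels[, , band]
}

#' Logical mask of valid (non-nodata, finite) pixels
#' @param image an `msi_image`.
#' @export
valid_mask <- function(image) {
  px <- image$pixels
  ok <- apply(is.finite(px), c(1, 2), all)
  if (!is.null(image$nodata)) {
    ok <- ok & !apply(px == image$nodata, c(1, 2), any)
  }
  ok
}

#' Categorical class map
#'
#' Single-band categorical raster of predicted (or reference) residue
#' cover types. Label 0 is reserved for nodata / unclassified pixels;
#' classes 1-4 default to the three residue cover types plus "other".
#'
#' @param labels integer matrix of class ids.
#' @param class_names named character vector mapping id to name.
#' @param provenance free-form list recording how the map was produced.
#' @export
class_map <- function(labels, class_names = NULL, provenance = list()) {
  stopifnot(is.matrix(labels))
  if (any(dim(labels) < 1L)) stop("class map must have positive extent")
  labels <- matrix(as.integer(round(labels)), nrow(labels), ncol(labels))
  if (any(labels < 0L, na.rm = TRUE)) stop("class labels must be >= 0")
  if (is.null(class_names)) {
    ids <- sort(setdiff(unique(as.vector(labels)), 0L))
    class_names <- stats::setNames(paste0("class_", ids), ids)
  }
  structure(list(labels = labels, class_names = class_names,
                 provenance = provenance),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  cat(sprintf("<class_map> %d x %d, classes: %s\n",
              nrow(x$labels), ncol(x$labels),
              paste(sprintf("%s=%s", names(x$class_names), x$class_names),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.class_map <- function(x) dim(x$labels)

#' @export
plot.class_map <- function(x, ...) {
  k <- max(x$labels, 1L)
  cols <- c("grey20", grDevices::hcl.colors(k, "Set 2"))
  graphics::image(t(x$labels[nrow(x$labels):1, , drop = FALSE]),
                  col = cols, breaks = seq(-0.5, k + 0.5, by = 1),
                  axes = FALSE, asp = ncol(x$labels) / nrow(x$labels), ...)
  invisible(x)
}

default_class_names <- function() {
  stats::setNames(c("type1_striped", "type2_bright", "type3_dark", "other"),
                  1:4)
}

#' Labeled pixel sample table
#'
#' @param records data.frame with integer columns `row`, `col` (0-based,
#'   row-major, origin at the top-left pixel) and `label`, plus optionally
#'   a `split` column of "train"/"validation" tags.
#' @param class_names named character vector mapping class id to name.
#' @export
sample_set <- function(records, class_names = NULL) {
  stopifnot(is.data.frame(records))
  need <- c("row", "col", "label")
  if (!all(need %in% names(records))) {
    stop("records must have columns row, col, label")
  }
  if (is.null(class_names)) {
    ids <- sort(unique(records$label))
    class_names <- stats::setNames(paste0("class_", ids), ids)
  }
  if (nrow(records) && !all(records$label %in% as.integer(names(class_names)))) {
    stop("every label must be a known class id")
  }
  structure(records, class = c("sample_set", "data.frame"),
            class_names = class_names)
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> %d records, %d classes", nrow(x),
              length(attr(x, "class_names"))))
  if ("split" %in% names(x) && nrow(x)) {
    tb <- table(x$split)
    cat(" (", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), ")",
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Linear pixel indices of a sample set
#'
#' Converts the 0-based (row, col) sample coordinates to 1-based linear
#' indices into an `r`-row matrix (column-major, as R stores matrices).
#' @param samples a `sample_set` (or data.frame with `row`, `col`).
#' @param r number of grid rows.
#' @export
sample_pixel_index <- function(samples, r) {
  samples$row + 1L + samples$col * r
}

sidecar_path <- function(path) paste0(path, ".aux.json")

#' Read a multi-band raster from disk
#'
#' Reads a (multi-page) TIFF written by [write_raster()], restoring band
#' names, geotransform, nodata sentinel and the original value scale from
#' the JSON sidecar. Plain TIFFs produced elsewhere are read as raw
#' stored values with no metadata.
#'
#' @param path path to a readable TIFF with at least one band.
#' @return an [multispectral_image()].
#' @export
read_multispectral <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- if (file.exists(sidecar_path(path))) {
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  } else list()
  # with our sidecar the pages are normalized fractions of the recorded
  # scale; foreign TIFFs are read as raw stored values
  pages <- tiff::readTIFF(path, all = TRUE, as.is = is.null(meta$storage))
  if (!is.list(pages)) pages <- list(pages)
  # a single page holding an r x c x d array is also accepted
  if (length(pages) == 1L && length(dim(pages[[1]])) == 3L) {
    a <- pages[[1]]
    pages <- lapply(seq_len(dim(a)[3]), function(i) a[, , i])
  }
  if (length(pages) == 0L) stop("no raster bands found in ", path)
  px <- array(0, c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) {
    v <- pages[[i]]
    if (!is.null(meta$storage)) {
      v <- v * meta$scale[i] + meta$offset[i]
      if (isTRUE(meta$integer_valued[i])) v <- round(v)
    }
    px[, , i] <- v
  }
  multispectral_image(
    px,
    band_names = meta$band_names %||% NULL,
    geotransform = if (length(meta$geotransform)) {
      as.numeric(meta$geotransform)
    } else NULL,
    nodata = if (is.null(meta$nodata)) NULL else as.numeric(meta$nodata)
  )
}

#' Read a categorical class map from disk
#' @param path path written by [write_raster()] for a `class_map`.
#' @export
read_class_map <- function(path) {
  img <- read_multispectral(path)
  meta <- if (file.exists(sidecar_path(path))) {
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  } else list()
  cn <- meta$class_names
  class_map(img$pixels[, , 1],
            class_names = if (length(cn)) {
              stats::setNames(unlist(cn), names(cn))
            } else NULL)
}

#' Write a raster to disk
#'
#' Images are written as multi-page TIFF (one page per band): integer
#' grids within 0..65535 as lossless 16-bit pages, other grids as 32-bit
#' scaled values. Band names, geotransform, nodata, class names and the
#' value scaling are recorded in a JSON sidecar next to the file.
#'
#' @param x an `msi_image` or `class_map`.
#' @param path destination file path.
#' @export
write_raster <- function(x, path) UseMethod("write_raster")

#' @export
write_raster.msi_image <- function(x, path) {
  d <- dim(x$pixels)[3]
  pages <- vector("list", d)
  off <- sc <- numeric(d); intv <- logical(d)
  int16 <- TRUE
  for (i in seq_len(d)) {
    v <- x$pixels[, , i]
    intv[i] <- all(is.finite(v)) && all(v == round(v))
    if (!(intv[i] && min(v) >= 0 && max(v) <= 65535)) int16 <- FALSE
  }
  for (i in seq_len(d)) {
    v <- x$pixels[, , i]
    if (int16) {
      off[i] <- 0; sc[i] <- 65535
      pages[[i]] <- v / 65535
    } else {
      off[i] <- min(v); sc[i] <- max(v) - min(v)
      if (sc[i] == 0) sc[i] <- 1
      pages[[i]] <- (v - off[i]) / sc[i]
    }
  }
  ok <- try(tiff::writeTIFF(pages, path,
                            bits.per.sample = if (int16) 16L else 32L,
                            compression = "none"), silent = TRUE)
  if (inherits(ok, "try-error")) stop("cannot write raster: ", path)
  meta <- list(kind = "msi_image",
               storage = if (int16) "uint16" else "float32",
               offset = off, scale = sc, integer_valued = intv,
               band_names = x$band_names,
               geotransform = x$geotransform, nodata = x$nodata)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @export
write_raster.class_map <- function(x, path) {
  img <- multispectral_image(x$labels, band_names = "class")
  write_raster(img, path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  meta$kind <- "class_map"
  meta$class_names <- as.list(x$class_names)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a labeled sample table from CSV
#'
#' The CSV must have a header `row,col,label` and optionally `split`;
#' coordinates are 0-based (row, col) from the top-left pixel. When the
#' split column is absent a seeded stratified 7:3 train/validation split
#' is generated (per-class proportions within one record of the ratio).
#'
#' @param path CSV file path.
#' @param grid_shape integer `(r, c)`; records outside the grid are an error.
#' @param class_names optional fixed id-to-name mapping; labels outside it
#'   are a validation error.
#' @param ratio train fraction for the generated split.
#' @param seed RNG seed for the generated split.
#' @export
read_samples <- function(path, grid_shape, class_names = NULL,
                         ratio = 0.7, seed = 1L) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         strip.white = TRUE)
  need <- c("row", "col", "label")
  if (!all(need %in% names(raw))) {
    stop("sample CSV must have header row,col,label[,split]")
  }
  if (nrow(raw) == 0L) {
    rec <- data.frame(row = integer(), col = integer(), label = integer(),
                      split = character())
    return(sample_set(rec, class_names %||% default_class_names()))
  }
  num <- function(field) {
    v <- suppressWarnings(as.numeric(raw[[field]]))
    bad <- which(!is.finite(v) | v != round(v))
    if (length(bad)) {
      stop(sprintf("malformed '%s' value at line %d of %s",
                   field, bad[1] + 1L, path))
    }
    as.integer(v)
  }
  rec <- data.frame(row = num("row"), col = num("col"), label = num("label"))
  out <- which(rec$row < 0 | rec$row >= grid_shape[1] |
               rec$col < 0 | rec$col >= grid_shape[2])
  if (length(out)) {
    stop(sprintf("sample outside the %d x %d grid at line %d",
                 grid_shape[1], grid_shape[2], out[1] + 1L))
  }
  if (!is.null(class_names) &&
      !all(rec$label %in% as.integer(names(class_names)))) {
    bad <- which(!(rec$label %in% as.integer(names(class_names))))[1]
    stop(sprintf("unknown class label at line %d", bad + 1L))
  }
  if ("split" %in% names(raw)) {
    sp <- raw$split
    if (!all(sp %in% c("train", "validation"))) {
      stop("split column values must be 'train' or 'validation'")
    }
    rec$split <- sp
  } else {
    rec$split <- stratified_split(rec$label, ratio = ratio, seed = seed)
  }
  sample_set(rec, class_names)
}

#' Write a sample table to CSV
#' @param samples a `sample_set`.
#' @param path destination CSV path.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(as.data.frame(samples), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
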