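# Connected-component labeling of an arbitrary integer grid: pixels are
# in the same component iff they share a value and are 4- (or 8-)
# adjacent. Components are numbered in raster-scan (row-major) order of
# their first pixel. Returns an integer matrix of component ids
# (0 outside `foreground` when given).
label_grid <- function(labels, connectivity = 4L, foreground = NULL) {
  r <- nrow(labels); cc <- ncol(labels)
  idx <- seq_len(r * cc)
  mask <- if (is.null(foreground)) rep(TRUE, r * cc) else
    as.vector(labels %in% foreground)
  edge_pairs <- function(a, b) {
    keep <- mask[a] & mask[b] & (labels[a] == labels[b])
    cbind(a[keep], b[keep])
  }
  row_i <- (idx - 1L) %% r + 1L
  col_i <- (idx - 1L) %/% r + 1L
  down <- idx[row_i < r]
  right <- idx[col_i < cc]
  edges <- rbind(edge_pairs(down, down + 1L),
                 edge_pairs(right, right + r))
  if (connectivity == 8L) {
    dr <- idx[row_i < r & col_i < cc]           # down-right
    ur <- idx[row_i > 1L & col_i < cc]          # up-right
    edges <- rbind(edges, edge_pairs(dr, dr + r + 1L),
                   edge_pairs(ur, ur + r - 1L))
  } else if (connectivity != 4L) stop("connectivity must be 4 or 8")
  gr <- igraph::make_graph(edges = as.vector(t(edges)), n = r * cc,
                           directed = FALSE)
  comp <- igraph::components(gr)$membership
  out <- integer(r * cc)
  vid <- idx[mask]
  if (length(vid)) {
    cid <- comp[vid]
    n <- max(cid)
    scan_key <- (vid - 1L) %% r * cc + (vid - 1L) %/% r  # row-major rank
    first <- tapply(scan_key, factor(cid, levels = seq_len(n)), min)
    present <- which(!is.na(first))
    renum <- integer(n)
    renum[present] <- rank(first[present], ties.method = "first")
    out[vid] <- renum[cid]
  }
  matrix(as.integer(out), r, cc)
}

#' Label connected components of one class
#'
#' Maximal 4- (or 8-) connected same-class regions, numbered in
#' raster-scan order of each component's first pixel.
#'
#' @param map a `class_map`.
#' @param class_id the class to label (absent class gives an empty
#'   labeling).
#' @param connectivity 4 (default) or 8.
#' @return a `component_labeling`: list with `component_id` (integer
#'   matrix, 0 outside the class), `sizes` (pixel count per component),
#'   `bbox` (per-component `rmin, rmax, cmin, cmax`, 0-based), `class_id`
#'   and `n`.
#' @export
label_components <- function(map, class_id, connectivity = 4L) {
  stopifnot(inherits(map, "class_map"))
  comp <- label_grid(map$labels, connectivity, foreground = class_id)
  n <- max(comp)
  sizes <- if (n) tabulate(comp[comp > 0L], nbins = n) else integer()
  bbox <- NULL
  if (n) {
    r <- nrow(comp)
    idx <- which(comp > 0L)
    ri <- (idx - 1L) %% r; ci <- (idx - 1L) %/% r
    cid <- comp[idx]
    bbox <- data.frame(
      component = seq_len(n),
      rmin = tapply(ri, cid, min), rmax = tapply(ri, cid, max),
      cmin = tapply(ci, cid, min), cmax = tapply(ci, cid, max))
  }
  structure(list(component_id = comp, sizes = sizes, bbox = bbox,
                 class_id = class_id, n = n,
                 connectivity = connectivity),
            class = "component_labeling")
}

#' Connected-domain calibration of a classification map
#'
#' Removes salt-and-pepper noise class by class: for each class in
#' `order`, every connected component of that class smaller than
#' `threshold` pixels is deleted and its pixels are reassigned to the
#' majority class among the component's 4-adjacent neighbouring pixels
#' (ties broken by the larger adjacent component, then the lower class
#' id). Later classes in the order see earlier reassignments. The
#' default follows the residue-mapping protocol: threshold 60 pixels,
#' denoising Type 2 first, then Type 3, then Type 1; the "other" class
#' is left untouched. Label 0 (nodata) is never created nor consumed.
#'
#' @param map a `class_map`.
#' @param order class ids processed in sequence.
#' @param threshold minimum component size in pixels (single value or
#'   one per entry of `order`).
#' @param connectivity 4 (default) or 8.
#' @param until_stable repeat the full pass until no pixel changes.
#' @param max_iter safety cap for `until_stable`.
#' @return the calibrated `class_map` (provenance records the settings).
#' @export
calibrate_map <- function(map, order = c(2L, 3L, 1L), threshold = 60L,
                          connectivity = 4L, until_stable = FALSE,
                          max_iter = 25L) {
  stopifnot(inherits(map, "class_map"), length(order) >= 1,
            all(threshold >= 1))
  thresholds <- rep_len(threshold, length(order))
  labels <- map$labels
  r <- nrow(labels); cc <- ncol(labels)
  pass <- function(labels) {
    for (k in seq_along(order)) {
      cl <- order[k]
      if (!any(labels == cl)) {
        warning("class ", cl, " absent from map; skipped")
        next
      }
      # census of the whole map at pass entry for this class: component
      # ids for every class (used for the tie-break by component size)
      all_comp <- label_grid(labels, connectivity)
      all_sizes <- tabulate(all_comp, nbins = max(all_comp))
      snapshot <- labels
      comp <- label_grid(snapshot, connectivity, foreground = cl)
      n <- max(comp)
      if (n == 0L) next
      sizes <- tabulate(comp[comp > 0L], nbins = n)
      for (ci in which(sizes < thresholds[k])) {
        pix <- which(comp == ci)
        ri <- (pix - 1L) %% r + 1L; cj <- (pix - 1L) %/% r + 1L
        nbr <- c(pix[ri > 1L] - 1L, pix[ri < r] + 1L,
                 pix[cj > 1L] - r, pix[cj < cc] + r)
        nbr <- setdiff(unique(nbr), pix)
        vals <- snapshot[nbr]
        keep <- vals != 0L
        nbr <- nbr[keep]; vals <- vals[keep]
        if (!length(vals)) next  # isolated in nodata: leave unchanged
        tab <- table(vals)
        best <- as.integer(names(tab)[tab == max(tab)])
        if (length(best) > 1L) {
          adjsize <- vapply(best, function(b) {
            max(all_sizes[unique(all_comp[nbr[vals == b]])])
          }, numeric(1))
          best <- best[adjsize == max(adjsize)]
          best <- min(best)
        }
        labels[pix] <- best
      }
    }
    labels
  }
  iter <- 0L
  repeat {
    new_labels <- pass(labels)
    iter <- iter + 1L
    if (!until_stable || identical(new_labels, labels) ||
        iter >= max_iter) {
      labels <- new_labels
      break
    }
    labels <- new_labels
  }
  class_map(labels, class_names = map$class_names,
            provenance = c(map$provenance,
                           list(calibration = list(
                             order = order, threshold = thresholds,
                             connectivity = connectivity,
                             until_stable = until_stable, passes = iter))))
}
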