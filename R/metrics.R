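#' Confusion matrix
#'
#' Counts with rows = reference class, columns = predicted class.
#'
#' @param reference reference class ids.
#' @param predicted predicted class ids (same length).
#' @param class_ids optional fixed class set (default: union observed).
#' @return k x k integer matrix with dimnames `reference`/`predicted`.
#' @export
confusion_matrix <- function(reference, predicted, class_ids = NULL) {
  if (length(reference) != length(predicted)) {
    stop("reference and predicted must have equal length")
  }
  if (is.null(class_ids)) {
    class_ids <- sort(unique(c(reference, predicted)))
  }
  f <- function(v) factor(v, levels = class_ids)
  cm <- table(reference = f(reference), predicted = f(predicted))
  matrix(as.integer(cm), length(class_ids), length(class_ids),
         dimnames = list(reference = as.character(class_ids),
                         predicted = as.character(class_ids)))
}

#' Overall accuracy
#'
#' The proportion of correctly predicted samples: matrix trace over the
#' grand total.
#'
#' @param cm confusion matrix from [confusion_matrix()].
#' @export
overall_accuracy <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  sum(diag(cm)) / total
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `(OA - P_k) / (1 - P_k)` with the random
#' agreement probability `P_k = sum_i row_i * col_i / total^2`.
#'
#' @param cm confusion matrix from [confusion_matrix()].
#' @export
kappa_coefficient <- function(cm) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  pe <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (pe >= 1) stop("kappa undefined: random agreement probability is 1")
  (overall_accuracy(cm) - pe) / (1 - pe)
}

#' Elapsed wall-clock seconds
#'
#' @param start,end timestamps (`POSIXct` or numeric seconds), `end >=
#'   start`.
#' @export
time_cost <- function(start, end) {
  tc <- as.numeric(difftime(end, start, units = "secs"))
  if (is.na(tc)) tc <- as.numeric(end) - as.numeric(start)
  if (tc < 0) stop("end timestamp precedes start")
  tc
}

#' Full accuracy report
#'
#' @param cm confusion matrix.
#' @param tc optional classification time in seconds.
#' @return a `metrics_report`: list with `oa`, `kappa`, `pe`, `tc`,
#'   per-class `producer_accuracy` (recall) and `user_accuracy`
#'   (precision), and the confusion matrix.
#' @export
metrics_report <- function(cm, tc = NA_real_) {
  oa <- overall_accuracy(cm)
  pe <- sum(rowSums(cm) * colSums(cm)) / sum(cm)^2
  structure(list(
    oa = oa, kappa = kappa_coefficient(cm), pe = pe, tc = tc,
    producer_accuracy = diag(cm) / pmax(rowSums(cm), 1),
    user_accuracy = diag(cm) / pmax(colSums(cm), 1),
    confusion = cm), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> OA %.4f, kappa %.4f (P_k %.4f)",
              x$oa, x$kappa, x$pe))
  if (is.finite(x$tc)) cat(sprintf(", TC %.2fs", x$tc))
  cat("\n")
  invisible(x)
}

#' Write a metrics report to JSON
#' @param report a `metrics_report`.
#' @param path destination path.
#' @export
write_metrics <- function(report, path) {
  out <- list(oa = report$oa, kappa = report$kappa, pe = report$pe,
              tc = report$tc,
              producer_accuracy = as.list(report$producer_accuracy),
              user_accuracy = as.list(report$user_accuracy),
              confusion = unclass(report$confusion))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Evaluate a class map against reference samples
#'
#' @param map a `class_map`.
#' @param samples a `sample_set`; only records with the given split tag
#'   are used.
#' @param split which split to score (default `"validation"`).
#' @param tc optional classification time to carry into the report.
#' @export
evaluate_map <- function(map, samples, split = "validation",
                         tc = NA_real_) {
  stopifnot(inherits(map, "class_map"))
  rec <- as.data.frame(samples)
  if ("split" %in% names(rec) && !is.null(split)) {
    rec <- rec[rec$split == split, , drop = FALSE]
  }
  if (nrow(rec) == 0L) stop("no samples to evaluate")
  pred <- map$labels[sample_pixel_index(rec, nrow(map$labels))]
  metrics_report(confusion_matrix(rec$label, pred), tc = tc)
}
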