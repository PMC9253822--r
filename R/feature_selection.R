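#' Gini importance of features
#'
#' Mean normalized impurity-decrease (Gini) importance over repeated
#' random-forest fits with distinct seeds. Repeating the fit averages out
#' the forest's sampling randomness; ten repeats are the default.
#'
#' @param features per-sample feature table (data.frame or matrix).
#' @param labels class id per sample (>= 2 classes required).
#' @param n_repeats number of forest fits to average.
#' @param seed base RNG seed (fit `i` uses `seed + i - 1`).
#' @param num_trees trees per forest.
#' @return an `importance_table` data.frame with columns `feature` and
#'   `importance` (fractions summing to 1), sorted decreasing, with
#'   attributes `n_repeats` and `seed`.
#' @export
gini_importance <- function(features, labels, n_repeats = 10L, seed = 1L,
                            num_trees = 500L) {
  features <- as.data.frame(features)
  if (length(unique(labels)) < 2L) {
    stop("Gini importance needs at least 2 classes")
  }
  if (ncol(features) < 1L) stop("need at least one feature")
  stopifnot(n_repeats >= 1L)
  dat <- cbind(features, .label = factor(labels))
  acc <- numeric(ncol(features))
  for (i in seq_len(n_repeats)) {
    fit <- ranger::ranger(
      dependent.variable.name = ".label", data = dat,
      num.trees = num_trees, importance = "impurity",
      seed = seed + i - 1L, num.threads = 1L)
    imp <- fit$variable.importance[names(features)]
    acc <- acc + imp / sum(imp)
  }
  imp <- acc / n_repeats
  out <- data.frame(feature = names(features), importance = imp,
                    row.names = NULL)
  out <- out[order(-out$importance, out$feature), ]
  rownames(out) <- NULL
  structure(out, class = c("importance_table", "data.frame"),
            n_repeats = n_repeats, seed = seed)
}

#' @export
print.importance_table <- function(x, ...) {
  cat(sprintf("<importance_table> %d feature(s), mean of %d fit(s)\n",
              nrow(x), attr(x, "n_repeats")))
  print.data.frame(transform(x, importance = sprintf("%.2f%%",
                                                     100 * importance)))
  invisible(x)
}

#' Importance-guided feature subset search
#'
#' Evaluates nested feature subsets grown in importance-ranking order,
#' plus any explicitly supplied extra subsets (e.g. the spectral-only
#' baseline). Each trial trains the evaluation classifier on the train
#' split and scores Cohen's kappa and overall accuracy on the validation
#' split; the subset with the highest kappa wins, ties broken by smaller
#' subset then lexicographic order.
#'
#' @param features per-sample feature table covering all candidates.
#' @param labels class ids aligned with `features`.
#' @param split "train"/"validation" tag per sample.
#' @param order character vector: features in decreasing importance
#'   (e.g. `importance_table$feature`).
#' @param extra_trials list of explicit character-vector subsets to
#'   evaluate in addition to the nested ones.
#' @param method evaluation classifier passed to [train_classifier()]
#'   (default `"rf"`).
#' @param config hyperparameter overrides for the evaluation classifier;
#'   the default uses a lighter 300-tree forest since the search refits
#'   once per candidate subset.
#' @param seed RNG seed.
#' @return list with `trials` (data.frame: subset, n_features, kappa,
#'   oa) and `selected` (character vector).
#' @export
subset_search <- function(features, labels, split, order,
                          extra_trials = list(), method = "rf",
                          config = list(num_trees = 300L), seed = 1L) {
  features <- as.data.frame(features)
  if (!all(order %in% names(features))) {
    stop("ranking must only name available features")
  }
  candidates <- lapply(seq_along(order), function(k) order[seq_len(k)])
  candidates <- c(candidates, extra_trials)
  if (length(candidates) == 0L) stop("no candidate subsets")
  tr <- split == "train"
  trials <- data.frame(subset = character(), n_features = integer(),
                       kappa = numeric(), oa = numeric())
  for (sub in candidates) {
    if (length(sub) == 0L) stop("candidate subsets must be non-empty")
    model <- train_classifier(method, features[tr, sub, drop = FALSE],
                              labels[tr], config = config, seed = seed)
    pred <- predict_classifier(model, features[!tr, sub, drop = FALSE])
    cm <- confusion_matrix(labels[!tr], pred)
    trials <- rbind(trials, data.frame(
      subset = paste(sub, collapse = "+"),
      n_features = length(sub),
      kappa = kappa_coefficient(cm), oa = overall_accuracy(cm)))
  }
  key <- order(-trials$kappa, trials$n_features, trials$subset)
  best <- candidates[[key[1]]]
  list(trials = trials, selected = best, method = method)
}
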