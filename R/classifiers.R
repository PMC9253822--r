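#' Default hyperparameters
#'
#' The tuned settings used for the residue-cover classification task:
#' random forests of 1,411 trees (depth 281, sqrt features) on the fused
#' nine-feature stack and 1,091 trees (depth 381, "auto" = sqrt features)
#' on the spectral-only stack; an RBF support vector machine with cost
#' 510.0 and "scale" gamma; networks trained 150 epochs with batch size
#' 20, initial learning rate 0.01 and dropout 0.4; and connected-domain
#' calibration with a 60-pixel threshold applied to Type 2, then Type 3,
#' then Type 1.
#'
#' @return nested list of defaults by component.
#' @export
default_hyperparameters <- function() {
  list(
    rf_oid = list(num_trees = 1411L, max_depth = 281L,
                  max_features = "sqrt"),
    rf_dt1 = list(num_trees = 1091L, max_depth = 381L,
                  max_features = "auto"),
    svm = list(cost = 510.0, gamma = "scale", kernel = "radial",
               multiclass = "one-vs-rest"),
    cnn = list(epochs = 150L, batch_size = 20L, learning_rate = 0.01,
               dropout = 0.4, conv_filters = 512L,
               dense_widths = c(2048L, 1024L)),
    calibration = list(threshold = 60L, order = c(2L, 3L, 1L))
  )
}

mtry_from <- function(max_features, p) {
  if (is.numeric(max_features)) return(as.integer(max_features))
  switch(max_features,
         sqrt = , auto = max(1L, floor(sqrt(p))),
         stop("unknown max_features: ", max_features))
}

# sklearn-style "scale" gamma: 1 / (p * Var(X)) with the variance taken
# over all entries of the training matrix.
gamma_scale <- function(X) {
  v <- stats::var(as.vector(as.matrix(X)))
  if (!is.finite(v) || v == 0) v <- 1
  1 / (ncol(X) * v)
}

#' Train a residue-cover classifier
#'
#' Uniform interface over the five supported methods. `nb`, `rf` and
#' `svm` delegate to established solvers (e1071, ranger); `cnn` and
#' `cnn_ca` are the package's own one-dimensional convolutional network,
#' without / with the channel attention module. Features are standardized
#' internally (training-split statistics) for `svm`, `cnn` and `cnn_ca`;
#' `nb` and `rf` see raw values.
#'
#' @param method one of `"nb"`, `"rf"`, `"svm"`, `"cnn"`, `"cnn_ca"`.
#' @param features per-sample feature table (finite-valued).
#' @param labels class ids aligned with `features`.
#' @param config named list of hyperparameter overrides; defaults come
#'   from [default_hyperparameters()] (`rf` uses the fused-stack preset,
#'   switch with `config = list(preset = "dt1")`).
#' @param seed RNG seed for all stochastic fits.
#' @return a `trained_model` with the fitted state, feature names,
#'   scaling parameters, class ids and training time in seconds.
#' @export
train_classifier <- function(method, features, labels, config = list(),
                             seed = 1L) {
  features <- as.data.frame(features)
  if (nrow(features) == 0L) stop("train split is empty")
  if (!all(vapply(features, function(v) all(is.finite(v)), logical(1)))) {
    stop("features must be finite-valued (no NA/NaN/Inf)")
  }
  stopifnot(length(labels) == nrow(features))
  class_ids <- sort(unique(as.integer(labels)))
  y <- factor(as.integer(labels), levels = class_ids)
  defaults <- default_hyperparameters()
  t0 <- Sys.time()
  scaling <- NULL
  fit <- switch(method,
    nb = e1071::naiveBayes(features, y),
    rf = {
      preset <- config$preset %||% "oid"
      def <- if (identical(preset, "dt1")) defaults$rf_dt1 else defaults$rf_oid
      cfg <- utils::modifyList(def, config[setdiff(names(config), "preset")])
      ranger::ranger(
        x = features, y = y,
        num.trees = cfg$num_trees,
        mtry = mtry_from(cfg$max_features, ncol(features)),
        max.depth = cfg$max_depth,
        seed = seed, num.threads = 1L)
    },
    svm = {
      cfg <- utils::modifyList(defaults$svm, config)
      scaling <- list(center = vapply(features, mean, numeric(1)),
                      scale = vapply(features, stats::sd, numeric(1)))
      scaling$scale[scaling$scale == 0] <- 1
      Xs <- scale(as.matrix(features), scaling$center, scaling$scale)
      gam <- if (identical(cfg$gamma, "scale")) gamma_scale(Xs) else cfg$gamma
      # one-vs-rest: one binary machine per class, winner by decision value
      machines <- lapply(class_ids, function(cl) {
        yy <- factor(ifelse(as.integer(as.character(y)) == cl, "pos", "neg"),
                     levels = c("pos", "neg"))
        with_seed(seed, e1071::svm(Xs, yy, type = "C-classification",
                                   kernel = cfg$kernel, cost = cfg$cost,
                                   gamma = gam, scale = FALSE))
      })
      list(machines = machines, gamma = gam, cfg = cfg)
    },
    cnn = ,
    cnn_ca = {
      args <- config
      args$n_f <- ncol(features)
      args$n_class <- length(class_ids)
      args$attention <- config$attention %||%
        identical(method, "cnn_ca")
      args$seed <- config$seed %||% seed
      cfg <- do.call(network_config, args)
      scaling <- list(center = vapply(features, mean, numeric(1)),
                      scale = vapply(features, stats::sd, numeric(1)))
      scaling$scale[scaling$scale == 0] <- 1
      Xs <- scale(as.matrix(features), scaling$center, scaling$scale)
      cnn_train(Xs, match(as.integer(as.character(y)), class_ids), cfg)
    },
    stop("unknown method: ", method)
  )
  structure(list(method = method, fit = fit,
                 feature_names = names(features), scaling = scaling,
                 class_ids = class_ids, seed = seed,
                 train_time = time_cost(t0, Sys.time())),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> %s on %d feature(s), classes %s (%.2fs)\n",
              x$method, length(x$feature_names),
              paste(x$class_ids, collapse = ","), x$train_time))
  invisible(x)
}

#' Predict class ids for a feature table
#'
#' @param model a `trained_model`.
#' @param features data.frame containing (at least) the model's features.
#' @return integer vector of predicted class ids.
#' @export
predict_classifier <- function(model, features) {
  stopifnot(inherits(model, "trained_model"))
  # ensure the solvers' S3 predict methods are registered, e.g. for
  # models deserialized in a fresh session
  requireNamespace("ranger", quietly = TRUE)
  requireNamespace("e1071", quietly = TRUE)
  features <- as.data.frame(features)
  if (!all(model$feature_names %in% names(features))) {
    stop("missing feature(s): ",
         paste(setdiff(model$feature_names, names(features)), collapse = ", "))
  }
  X <- features[, model$feature_names, drop = FALSE]
  switch(model$method,
    nb = as.integer(as.character(
      stats::predict(model$fit, X, type = "class"))),
    rf = as.integer(as.character(
      stats::predict(model$fit, data = X, num.threads = 1L)$predictions)),
    svm = {
      Xs <- scale(as.matrix(X), model$scaling$center, model$scaling$scale)
      dec <- vapply(model$fit$machines, function(m) {
        dv <- attr(stats::predict(m, Xs, decision.values = TRUE),
                   "decision.values")
        # orient so larger means "pos" regardless of level ordering
        if (grepl("^pos/", colnames(dv)[1])) dv[, 1] else -dv[, 1]
      }, numeric(nrow(Xs)))
      dec <- matrix(dec, nrow = nrow(Xs))
      model$class_ids[max.col(dec, ties.method = "first")]
    },
    cnn = ,
    cnn_ca = {
      Xs <- scale(as.matrix(X), model$scaling$center, model$scaling$scale)
      probs <- cnn_forward(model$fit$params, Xs, model$fit$config,
                           train = FALSE)$probs
      model$class_ids[max.col(probs, ties.method = "first")]
    },
    stop("unknown method: ", model$method)
  )
}

#' Classify every pixel of a feature stack
#'
#' @param model a `trained_model` whose features are all present in the
#'   stack.
#' @param stack a `feature_stack`.
#' @param class_names optional id-to-name mapping for the output map.
#' @param batch_size pixels per prediction batch.
#' @return list with `map` (a `class_map`; nodata pixels are labeled 0)
#'   and `tc` (wall-clock prediction seconds).
#' @export
predict_map <- function(model, stack, class_names = NULL,
                        batch_size = 65536L) {
  stopifnot(inherits(model, "trained_model"),
            inherits(stack, "feature_stack"))
  t0 <- Sys.time()
  dm <- dim(stack$layers[[1]])
  X <- stack_matrix(stack, model$feature_names)
  colnames(X) <- model$feature_names
  valid <- as.vector(stack$mask) & apply(is.finite(X), 1, all)
  labels <- integer(nrow(X))
  idx <- which(valid)
  for (start in seq(1L, length.out = ceiling(length(idx) / batch_size),
                    by = batch_size)) {
    take <- idx[start:min(start + batch_size - 1L, length(idx))]
    labels[take] <- predict_classifier(
      model, as.data.frame(X[take, , drop = FALSE]))
  }
  map <- class_map(matrix(labels, dm[1], dm[2]),
                   class_names = class_names %||% default_class_names(),
                   provenance = list(model = model$method,
                                     features = model$feature_names,
                                     seed = model$seed))
  list(map = map, tc = time_cost(t0, Sys.time()))
}
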