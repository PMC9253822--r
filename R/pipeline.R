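#' Pipeline configuration
#'
#' Builds (or validates) the configuration for [run_pipeline()]. The
#' configuration can also be read from a YAML or JSON file. Every field
#' has a default so `pipeline_config(out_dir = tempdir())` runs a full
#' synthetic-scene experiment.
#'
#' @param out_dir output directory (created if needed).
#' @param seed master seed for scene generation, sampling and model fits.
#' @param scene either a [scene_spec()] or a list of arguments for one;
#'   set `input$image`/`input$samples` instead to use files on disk.
#' @param input optional list with `image` (TIFF path) and `samples`
#'   (CSV path) replacing the synthetic scene.
#' @param n_per_class samples drawn per class on synthetic scenes.
#' @param windows multi-scale window sizes.
#' @param wavelet,fusion wavelet basis and coefficient fusion rule.
#' @param method classifier (`nb`, `rf`, `svm`, `cnn`, `cnn_ca`).
#' @param model_config hyperparameter overrides for the classifier.
#' @param features feature subset to train on; `"auto"` runs the
#'   importance-guided subset search, otherwise a character vector such
#'   as [oid_features()].
#' @param importance_repeats repeats for the Gini importance table.
#' @param calibration list with `order`, `threshold`, `until_stable`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, scene = list(),
                            input = NULL, n_per_class = 500L,
                            windows = c(2, 4, 8, 16, 32, 64),
                            wavelet = "db3", fusion = "maxabs",
                            method = "svm", model_config = list(),
                            features = oid_features(),
                            importance_repeats = 10L,
                            calibration = list()) {
  cal_def <- default_hyperparameters()$calibration
  calibration <- utils::modifyList(
    list(order = cal_def$order, threshold = cal_def$threshold,
         until_stable = FALSE), calibration)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 scene = scene, input = input,
                 n_per_class = as.integer(n_per_class),
                 windows = windows, wavelet = wavelet, fusion = fusion,
                 method = method, model_config = model_config,
                 features = features,
                 importance_repeats = as.integer(importance_repeats),
                 calibration = calibration),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#' @param path configuration file.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(pipeline_config, cfg)
}

#' Run the full classification workflow
#'
#' Scene (generated or loaded) -> feature stack -> Gini importance ->
#' feature subset -> classifier training -> per-pixel map -> connected
#' domain calibration -> accuracy report. All artifacts are written
#' under `config$out_dir` along with a run manifest (seed, stage
#' timings, artifact checksums).
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return list with `metrics` (a `metrics_report` on the validation
#'   split of the calibrated map), `raw_metrics`, `map`, `calibrated`,
#'   `selected_features`, `importance` and `paths`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[residuemap] ", ...)
  paths <- list()
  timing <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    v <- force(expr)
    timing[[name]] <<- time_cost(t0, Sys.time())
    say(sprintf("%s (%.2fs)", name, timing[[name]]))
    v
  }

  scene <- stage("scene", {
    if (!is.null(config$input)) {
      img <- read_multispectral(config$input$image)
      smp <- read_samples(config$input$samples, dim(img$pixels)[1:2],
                          seed = config$seed)
      list(image = img, truth = NULL, samples = smp)
    } else {
      spec <- if (inherits(config$scene, "scene_spec")) config$scene else
        do.call(scene_spec, utils::modifyList(list(seed = config$seed),
                                              config$scene))
      sc <- generate_scene(spec)
      sc$samples <- generate_sample_set(sc$truth, config$n_per_class,
                                        seed = config$seed)
      sc
    }
  })
  paths$image <- file.path(config$out_dir, "scene.tif")
  write_raster(scene$image, paths$image)
  if (!is.null(scene$truth)) {
    paths$truth <- file.path(config$out_dir, "truth.tif")
    write_raster(scene$truth, paths$truth)
  }
  paths$samples <- file.path(config$out_dir, "samples.csv")
  write_samples(scene$samples, paths$samples)

  stack <- stage("features", build_feature_stack(
    scene$image, windows = config$windows, wavelet = config$wavelet,
    rule = config$fusion))
  paths$stack <- file.path(config$out_dir, "features.tif")
  write_raster(multispectral_image(
    array(unlist(stack$layers), c(dim(stack$layers[[1]]),
                                  length(stack$layers))),
    band_names = names(stack$layers)), paths$stack)

  tab <- features_at(stack, scene$samples)
  labels <- scene$samples$label
  split <- scene$samples$split

  imp <- stage("importance", gini_importance(
    tab, labels, n_repeats = config$importance_repeats,
    seed = config$seed))
  paths$importance <- file.path(config$out_dir, "importance.json")
  jsonlite::write_json(imp, paths$importance, auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")

  selected <- config$features
  trials <- NULL
  if (identical(config$features, "auto")) {
    sel <- stage("subset_search", subset_search(
      tab, labels, split, order = imp$feature, seed = config$seed,
      extra_trials = list(dt1_features())))
    selected <- sel$selected
    trials <- sel$trials
    paths$trials <- file.path(config$out_dir, "subset_trials.json")
    jsonlite::write_json(sel$trials, paths$trials, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
  }

  tr <- split == "train"
  model <- stage("train", train_classifier(
    config$method, tab[tr, selected, drop = FALSE], labels[tr],
    config = config$model_config, seed = config$seed))

  pm <- stage("classify", predict_map(model, stack))
  paths$raw_map <- file.path(config$out_dir, "map_raw.tif")
  write_raster(pm$map, paths$raw_map)

  calibrated <- stage("calibrate", calibrate_map(
    pm$map, order = config$calibration$order,
    threshold = config$calibration$threshold,
    until_stable = isTRUE(config$calibration$until_stable)))
  paths$calibrated_map <- file.path(config$out_dir, "map_calibrated.tif")
  write_raster(calibrated, paths$calibrated_map)

  raw_metrics <- evaluate_map(pm$map, scene$samples, tc = pm$tc)
  metrics <- evaluate_map(calibrated, scene$samples, tc = pm$tc)
  paths$metrics <- file.path(config$out_dir, "metrics.json")
  write_metrics(metrics, paths$metrics)

  manifest <- list(
    seed = config$seed, method = config$method,
    features = selected, windows = config$windows,
    wavelet = config$wavelet, fusion = config$fusion,
    calibration = config$calibration[c("order", "threshold")],
    timings = timing,
    artifacts = lapply(paths, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("residuemap")))
  paths$manifest <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA)

  list(metrics = metrics, raw_metrics = raw_metrics, map = pm$map,
       calibrated = calibrated, selected_features = selected,
       importance = imp, trials = trials, model = model, paths = paths)
}

#' Compare classification methods on spectral-only and fused stacks
#'
#' Trains each method on the spectral-only baseline (DT1) and the fused
#' feature subset (OID) of one scene and scores kappa, overall accuracy
#' and classification time on the validation split, yielding a
#' method-by-dataset comparison table.
#'
#' @param tab per-sample feature table containing both subsets.
#' @param labels,split class ids and train/validation tags.
#' @param methods methods to compare.
#' @param oid,dt1 the two feature subsets.
#' @param configs optional per-method config overrides (named list).
#' @param seed RNG seed.
#' @return data.frame with columns method, dataset, kappa, oa, tc.
#' @export
compare_methods <- function(tab, labels, split,
                            methods = c("nb", "rf", "svm"),
                            oid = oid_features(), dt1 = dt1_features(),
                            configs = list(), seed = 1L) {
  out <- data.frame()
  tr <- split == "train"
  for (m in methods) {
    for (ds in c("dt1", "oid")) {
      feats <- if (ds == "oid") oid else dt1
      cfg <- configs[[m]] %||% list()
      if (m == "rf") cfg$preset <- ds
      model <- train_classifier(m, tab[tr, feats, drop = FALSE],
                                labels[tr], config = cfg, seed = seed)
      t0 <- Sys.time()
      pred <- predict_classifier(model, tab[!tr, feats, drop = FALSE])
      tc <- time_cost(t0, Sys.time())
      cm <- confusion_matrix(labels[!tr], pred)
      out <- rbind(out, data.frame(
        method = m, dataset = toupper(ds),
        kappa = kappa_coefficient(cm), oa = overall_accuracy(cm),
        tc = tc))
    }
  }
  out
}
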