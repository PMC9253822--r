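tiny_cnn_cfg <- list(fast = TRUE, epochs = 15, conv_filters = 8,
                     dense_widths = c(32, 16))

test_that("every method solves a linearly separable two-class problem", {
  set.seed(30)
  n <- 120
  lab <- rep(1:2, each = n / 2)
  tab <- data.frame(x = rnorm(n, ifelse(lab == 1, -4, 4)),
                    y = rnorm(n))
  val <- data.frame(x = rnorm(60, ifelse(rep(1:2, each = 30) == 1, -4, 4)),
                    y = rnorm(60))
  for (m in c("nb", "rf", "svm", "cnn", "cnn_ca")) {
    cfg <- if (m %in% c("cnn", "cnn_ca")) tiny_cnn_cfg else list()
    model <- train_classifier(m, tab, lab, config = cfg, seed = 1)
    pred <- predict_classifier(model, val)
    expect_equal(overall_accuracy(
      confusion_matrix(rep(1:2, each = 30), pred)), 1.0)
  }
})

test_that("the printed default hyperparameters are wired in", {
  def <- default_hyperparameters()
  expect_equal(def$rf_oid,
               list(num_trees = 1411L, max_depth = 281L,
                    max_features = "sqrt"))
  expect_equal(def$rf_dt1,
               list(num_trees = 1091L, max_depth = 381L,
                    max_features = "auto"))
  expect_equal(def$svm$cost, 510.0)
  expect_equal(def$svm$kernel, "radial")
  expect_equal(def$svm$gamma, "scale")
  fx <- fixture_scene()
  tr <- fx$samples$split == "train"
  model <- train_classifier("rf", fx$tab[tr, dt1_features()],
                            fx$samples$label[tr], seed = 1)
  expect_equal(model$fit$num.trees, 1411L)   # fused-stack preset default
  model2 <- train_classifier("rf", fx$tab[tr, dt1_features()],
                             fx$samples$label[tr],
                             config = list(preset = "dt1"), seed = 1)
  expect_equal(model2$fit$num.trees, 1091L)
  expect_equal(model2$fit$mtry, 2L)          # floor(sqrt(4))
})

test_that("svm beats naive Bayes on the four-class textured scene", {
  fx <- fixture_scene()
  tr <- fx$samples$split == "train"
  lab <- fx$samples$label
  kap <- function(m) {
    model <- train_classifier(m, fx$tab[tr, oid_features()], lab[tr],
                              seed = 2)
    pred <- predict_classifier(model, fx$tab[!tr, oid_features()])
    kappa_coefficient(confusion_matrix(lab[!tr], pred))
  }
  expect_gt(kap("svm"), kap("nb"))
})

test_that("seeded fits are deterministic", {
  fx <- fixture_scene()
  tr <- fx$samples$split == "train"
  tab <- fx$tab[, oid_features()]
  lab <- fx$samples$label
  for (m in c("rf", "svm")) {
    p1 <- predict_classifier(
      train_classifier(m, tab[tr, ], lab[tr], seed = 7), tab[!tr, ])
    p2 <- predict_classifier(
      train_classifier(m, tab[tr, ], lab[tr], seed = 7), tab[!tr, ])
    expect_identical(p1, p2)
  }
  sub <- seq(1, sum(tr), by = 8)   # keep all classes represented
  m1 <- train_classifier("cnn_ca", tab[tr, ][sub, ], lab[tr][sub],
                         config = tiny_cnn_cfg, seed = 7)
  m2 <- train_classifier("cnn_ca", tab[tr, ][sub, ], lab[tr][sub],
                         config = tiny_cnn_cfg, seed = 7)
  expect_identical(m1$fit$params, m2$fit$params)
})

test_that("invalid feature tables are rejected", {
  tab <- data.frame(x = c(1, NaN), y = c(0, 1))
  expect_error(train_classifier("rf", tab, c(1, 2)), "finite")
  expect_error(train_classifier("mystery", data.frame(x = 1:4),
                                c(1, 1, 2, 2)), "unknown method")
  expect_error(train_classifier("rf", data.frame(x = numeric()),
                                integer()), "empty")
})

test_that("predict_map labels the grid and zeroes nodata pixels", {
  fx <- fixture_scene()
  tr <- fx$samples$split == "train"
  model <- train_classifier("rf", fx$tab[tr, oid_features()],
                            fx$samples$label[tr], seed = 3)
  pm <- predict_map(model, fx$stack)
  expect_s3_class(pm$map, "class_map")
  expect_equal(dim(pm$map$labels), dim(fx$stack$layers[[1]]))
  expect_gte(pm$tc, 0)
  # a forest grown to purity memorizes its own training pixels
  idx <- sample_pixel_index(fx$samples[tr, ], 128)
  expect_gt(mean(pm$map$labels[idx] == fx$samples$label[tr]), 0.99)
  # nodata pixels come out as label 0
  stack0 <- fx$stack
  stack0$mask[1:10, 1:10] <- FALSE
  pm0 <- predict_map(model, stack0)
  expect_true(all(pm0$map$labels[1:10, 1:10] == 0L))
  stack_missing <- fx$stack
  stack_missing$layers$B_nir <- NULL
  expect_error(predict_map(model, stack_missing), "B_nir")
})
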