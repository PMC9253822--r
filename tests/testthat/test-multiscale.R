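test_that("feature extraction matches the naive per-pixel oracle", {
  set.seed(31)
  img <- matrix(runif(16 * 16, 0, 255), 16, 16)
  for (w in c(2, 4, 8)) {
    for (rule in c("maxabs", "approx")) {
      expect_lt(max(abs(extract_feature_image(img, w, rule = rule) -
                          oracle_feature_image(img, w, rule))), 1e-9)
    }
  }
})

test_that("constant images give the c * 2^M constant feature image", {
  img <- matrix(42, 40, 40)
  for (w in c(2, 4, 8, 16, 32)) {
    f <- extract_feature_image(img, w)
    expect_equal(max(abs(f - 42 * w)), 0, tolerance = 1e-9)
    g <- extract_feature_image(img, w, normalize = "gain")
    expect_equal(max(abs(g - 42)), 0, tolerance = 1e-9)
  }
})

test_that("translating the input translates interior feature pixels", {
  set.seed(12)
  img <- matrix(runif(30 * 30, 0, 255), 30, 30)
  shifted <- img[c(2:30, 30), ]   # shift up one row
  for (w in c(2, 4)) {
    f0 <- extract_feature_image(img, w)
    f1 <- extract_feature_image(shifted, w)
    inner_r <- (w + 2):(30 - w - 2)
    inner_c <- (w + 2):(30 - w - 2)
    expect_lt(max(abs(f1[inner_r - 1, inner_c] - f0[inner_r, inner_c])),
              1e-9)
  }
})

test_that("windows larger than the padded image are rejected", {
  expect_error(extract_feature_image(matrix(0, 10, 10), 32), "larger")
  expect_error(extract_feature_image(matrix(0, 10, 10), 3), "power of two")
})

test_that("the feature stack holds the 11 named layers on one grid", {
  fx <- fixture_scene()
  stack <- fx$stack
  expect_named(stack$layers,
               c("B_blue", "B_green", "B_red", "B_nir", "PC1",
                 "B_ms2", "B_ms4", "B_ms8", "B_ms16", "B_ms32", "B_ms64"))
  expect_length(stack$layers, 11L)
  for (lay in stack$layers) expect_equal(dim(lay), c(128, 128))
  # multi-scale layers standardized for classifier use
  expect_equal(mean(stack$layers$B_ms8), 0, tolerance = 1e-10)
  expect_equal(stats::sd(as.vector(stack$layers$B_ms8)), 1,
               tolerance = 1e-10)
  expect_true(stack$provenance$B_ms8$standardized)
})

test_that("a DT1-restricted stack has only the spectral layers", {
  sc <- generate_scene(scene_spec(size = c(32, 32), seed = 1))
  stack <- build_feature_stack(sc$image, layers = dt1_features())
  expect_named(stack$layers, dt1_features())
  expect_error(build_feature_stack(sc$image, layers = "B_ms128"),
               "unknown layer")
})

test_that("features_at returns values from the addressed pixels", {
  fx <- fixture_scene()
  ss <- fx$samples[1:5, ]
  tab <- features_at(fx$stack, ss, c("B_blue", "PC1"))
  for (k in 1:5) {
    expect_equal(tab$B_blue[k],
                 fx$stack$layers$B_blue[ss$row[k] + 1, ss$col[k] + 1])
  }
})

test_that("block variance matches a two-pass oracle and drops partials", {
  expect_equal(block_variance(matrix(7, 8, 8), 4)$blocks,
               matrix(0, 2, 2))
  set.seed(4)
  lay <- matrix(rnorm(13 * 13), 13, 13)
  bv <- block_variance(lay, 4)
  expect_equal(dim(bv$blocks), c(3, 3))
  blk <- lay[5:8, 9:12]
  expect_equal(bv$blocks[2, 3], sum((blk - mean(blk))^2) / 16,
               tolerance = 1e-12)
  expect_equal(bv$overall, sum((lay - mean(lay))^2) / 169,
               tolerance = 1e-12)
  expect_error(block_variance(lay, 1), ">= 2")
  expect_error(block_variance(lay, 20), "exceeds")
})

test_that("a 25-block census arises from a 5x-block-size layer", {
  bv <- block_variance(matrix(rnorm(45 * 45), 45, 45), 9)
  expect_equal(length(bv$blocks), 25L)
})
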