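test_that("connectivity is honored for diagonal neighbours", {
  m <- matrix(0L, 5, 5); m[2, 2] <- 1L; m[3, 3] <- 1L
  cm <- class_map(m, class_names = c(`1` = "a"))
  expect_equal(label_components(cm, 1, 4)$n, 2L)
  expect_equal(label_components(cm, 1, 8)$n, 1L)
  expect_equal(label_components(cm, 9, 4)$n, 0L)  # absent class
})

test_that("a single-class map is one component covering the grid", {
  cm <- class_map(matrix(2L, 7, 9))
  lab <- label_components(cm, 2)
  expect_equal(lab$n, 1L)
  expect_equal(lab$sizes, 63L)
  expect_equal(unname(unlist(lab$bbox[1, c("rmin", "rmax", "cmin", "cmax")])),
               c(0, 6, 0, 8))
})

test_that("component census matches the flood-fill oracle", {
  set.seed(17)
  for (rep in 1:10) {
    m <- matrix(sample(1:2, 900, TRUE), 30, 30)
    cm <- class_map(m)
    for (conn in c(4L, 8L)) {
      for (cl in 1:2) {
        lab <- label_components(cm, cl, conn)
        expect_equal(sort(lab$sizes), oracle_flood_sizes(m, cl, conn))
        expect_equal(sum(lab$sizes), sum(m == cl))
      }
    }
  }
})

test_that("components are numbered in raster-scan order of first pixel", {
  m <- matrix(0L, 4, 6)
  m[4, 1] <- 1L          # later in raster order
  m[1, 5] <- 1L          # first row, so first component
  lab <- label_components(class_map(m), 1)
  expect_equal(lab$component_id[1, 5], 1L)
  expect_equal(lab$component_id[4, 1], 2L)
})

test_that("small components are absorbed by their surroundings", {
  g <- matrix(2L, 10, 10); g[5, 5:7] <- 1L
  out <- calibrate_map(class_map(g), order = c(2L, 1L), threshold = 4)
  expect_true(all(out$labels == 2L))
  # components at or above threshold are untouched
  g2 <- matrix(2L, 10, 10); g2[3:6, 3:6] <- 1L
  out2 <- calibrate_map(class_map(g2), order = c(2L, 1L), threshold = 4)
  expect_identical(out2$labels, g2)
})

test_that("calibration is idempotent, conservative and keeps nodata", {
  set.seed(23)
  m <- matrix(sample(1:4, 1600, TRUE), 40, 40)
  m[1:3, ] <- 0L                       # nodata strip
  cm <- class_map(m, class_names = default_class_names())
  c1 <- calibrate_map(cm, threshold = 8)
  c2 <- calibrate_map(c1, threshold = 8)
  expect_identical(c1$labels, c2$labels)
  expect_equal(length(c1$labels), 1600L)
  expect_identical(c1$labels == 0L, m == 0L)   # label 0 never touched
  expect_equal(c1$provenance$calibration$order, c(2L, 3L, 1L))
})

test_that("the convergence loop removes every sub-threshold component", {
  set.seed(29)
  m <- matrix(sample(1:4, 2500, TRUE), 50, 50)
  out <- calibrate_map(class_map(m), order = c(2L, 3L, 1L),
                       threshold = 10, until_stable = TRUE)
  for (cl in c(2L, 3L, 1L)) {
    sizes <- label_components(out, cl)$sizes
    if (length(sizes)) expect_gte(min(sizes), 10L)
  }
})

test_that("later classes see earlier reassignments", {
  # a small class-2 blob sits inside class 3; after the class-2 pass the
  # enlarged class-3 region must be processed as one component
  g <- matrix(1L, 12, 12)
  g[4:9, 4:9] <- 3L
  g[6, 6] <- 2L
  out <- calibrate_map(class_map(g), order = c(2L, 3L), threshold = 2)
  expect_true(all(out$labels[4:9, 4:9] == 3L))
  expect_equal(sum(out$labels == 2L), 0L)
})

test_that("absent ordered classes are skipped with a warning", {
  g <- matrix(1L, 6, 6)
  expect_warning(calibrate_map(class_map(g), order = c(2L, 1L),
                               threshold = 2), "absent")
})
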