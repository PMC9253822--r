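test_that("raster write/read round-trips images and metadata", {
  sc <- generate_scene(scene_spec(size = c(24, 24), seed = 2))
  f <- withr::local_tempfile(fileext = ".tif")
  write_raster(sc$image, f)
  back <- read_multispectral(f)
  expect_equal(dim(back$pixels), dim(sc$image$pixels))
  expect_lt(max(abs(back$pixels - sc$image$pixels)), 1e-5)
  expect_identical(back$band_names, sc$image$band_names)
  expect_identical(back$geotransform, sc$image$geotransform)

  # integer-valued grids come back bit-identical
  xi <- multispectral_image(array(sample(0:255, 24 * 24 * 3, TRUE),
                                  c(24, 24, 3)),
                            nodata = 0)
  f2 <- withr::local_tempfile(fileext = ".tif")
  write_raster(xi, f2)
  back2 <- read_multispectral(f2)
  expect_identical(back2$pixels + 0, xi$pixels + 0)
  expect_identical(back2$nodata, 0)

  # single-band file accepted
  one <- multispectral_image(matrix(1:12, 3, 4))
  f3 <- withr::local_tempfile(fileext = ".tif")
  write_raster(one, f3)
  expect_equal(dim(read_multispectral(f3)$pixels)[3], 1L)
})

test_that("class maps round-trip with their class names", {
  sc <- generate_scene(scene_spec(size = c(20, 20), seed = 3))
  f <- withr::local_tempfile(fileext = ".tif")
  write_raster(sc$truth, f)
  back <- read_class_map(f)
  expect_identical(back$labels, sc$truth$labels)
  expect_identical(back$class_names, sc$truth$class_names)
})

test_that("degenerate grids are rejected at construction", {
  expect_error(multispectral_image(array(0, c(0, 5, 1))), "r >= 1")
  expect_error(class_map(matrix(integer(), 0, 0)), "positive extent")
  expect_error(multispectral_image(array(0, c(2, 2, 2)),
                                   band_names = c("a", "a")), "unique")
})

test_that("sample CSV reading reproduces the survey-scale class counts", {
  counts <- c(758, 746, 779, 819)   # Type 1..3 and other
  set.seed(5)
  idx <- sample(200 * 200, sum(counts))
  rec <- data.frame(row = (idx - 1) %% 200, col = (idx - 1) %/% 200,
                    label = rep(1:4, counts))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(rec, f, row.names = FALSE, quote = FALSE)
  ss <- read_samples(f, c(200, 200), seed = 9)
  expect_equal(nrow(ss), 3102L)
  expect_equal(as.vector(table(ss$label)), counts)
  # generated stratified split is 7:3 within one record per class
  for (cl in 1:4) {
    n_tr <- sum(ss$label == cl & ss$split == "train")
    expect_lte(abs(n_tr - 0.7 * counts[cl]), 1)
  }
  # deterministic under the seed
  ss2 <- read_samples(f, c(200, 200), seed = 9)
  expect_identical(ss$split, ss2$split)
})

test_that("sample CSV validation pinpoints bad records", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("row,col,label", "1,2,1", "3,x,2"), f)
  expect_error(read_samples(f, c(10, 10)), "line 3")
  writeLines(c("row,col,label", "1,2,1", "12,0,2"), f)
  expect_error(read_samples(f, c(10, 10)), "outside")
  writeLines(c("row,col,label", "1,2,9"), f)
  expect_error(read_samples(f, c(10, 10),
                            class_names = c(`1` = "a", `2` = "b")),
               "unknown class label")
  writeLines("row,col,label", f)
  expect_equal(nrow(read_samples(f, c(10, 10))), 0L)
})

test_that("a 1,000-record table splits 700/300 per stratum", {
  rec <- data.frame(row = rep(0:49, 20), col = rep(0:19, each = 50),
                    label = rep(1:2, each = 500))
  f <- withr::local_tempfile(fileext = ".csv")
  write.csv(rec, f, row.names = FALSE, quote = FALSE)
  ss <- read_samples(f, c(50, 20), seed = 4)
  tb <- table(ss$label, ss$split)
  expect_true(all(abs(tb[, "train"] - 350) <= 1))
  expect_true(all(abs(tb[, "validation"] - 150) <= 1))
})
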