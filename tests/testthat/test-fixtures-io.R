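test_that("fixture generation is bitwise deterministic given the seed", {
  a <- generate_dataset(3, size = 64, seed = 7)
  b <- generate_dataset(3, size = 64, seed = 7)
  expect_identical(a, b)
  c <- generate_dataset(3, size = 64, seed = 8)
  expect_false(identical(a, c))
})

test_that("masks are binary, non-empty, and within the area bounds", {
  ar <- c(0.05, 0.20)
  samples <- generate_dataset(12, size = 64, area_range = ar, seed = 9)
  for (s in samples) {
    expect_equal(dim(s$image), c(64, 64, 3))
    expect_equal(dim(s$mask), c(64, 64))
    expect_true(all(s$mask %in% c(0L, 1L)))
    frac <- mean(s$mask)
    expect_gte(frac, ar[1] * 0.9)
    expect_lte(frac, ar[2] * 1.1)
    expect_gt(sum(s$mask), 0)
    expect_true(all(s$image >= 0 & s$image <= 1))
  }
})

test_that("foreground and background intensities separate by a margin", {
  samples <- generate_dataset(8, size = 64, margin = 0.25, seed = 10)
  for (s in samples) {
    fg <- mean(s$image[array(s$mask == 1, dim(s$image))])
    bg <- mean(s$image[array(s$mask == 0, dim(s$image))])
    expect_gt(abs(fg - bg), 0.1)
  }
})

test_that("invalid sizes are rejected", {
  expect_error(generate_dataset(1, size = 60), "multiple of 32")
  expect_error(generate_dataset(0, size = 64), "n must be")
})

test_that("ratio splits floor val/test and give the remainder to train", {
  samples <- generate_dataset(10, size = 64, seed = 11)
  sp <- split_dataset(samples, ratios = c(0.6, 0.2, 0.2), seed = 1)
  expect_equal(lengths(sp[c("train", "val", "test")]),
               c(train = 6L, val = 2L, test = 2L))
})

test_that("count splits are exact and the split is a partition", {
  samples <- generate_dataset(10, size = 64, seed = 12)
  sp <- split_dataset(samples, counts = c(7, 1, 2), seed = 2)
  expect_equal(lengths(sp[c("train", "val", "test")]),
               c(train = 7L, val = 1L, test = 2L))
  ids <- function(set) vapply(set, function(s) s$meta$index, numeric(1))
  all_ids <- c(ids(sp$train), ids(sp$val), ids(sp$test))
  expect_setequal(all_ids, 1:10)
  expect_equal(anyDuplicated(all_ids), 0L)
  expect_error(split_dataset(samples, counts = c(5, 1, 2)), "summing")
  expect_error(split_dataset(samples, ratios = c(0.5, 0.2, 0.2)), "summing")
})

test_that("datasets round-trip through the PNG directory layout", {
  samples <- generate_dataset(3, size = 64, seed = 13)
  dir <- tempfile("fixtures")
  write_dataset(samples, dir)
  back <- load_dataset(file.path(dir, "images"), file.path(dir, "masks"))
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_identical(back[[i]]$mask, samples[[i]]$mask)
    # 8-bit PNG quantisation: images agree to 1/255
    expect_lt(max(abs(back[[i]]$image - samples[[i]]$image)), 1 / 255)
  }
})

test_that("resizing on load keeps masks exactly binary", {
  samples <- generate_dataset(2, size = 96, seed = 14)
  dir <- tempfile("fixtures")
  write_dataset(samples, dir)
  back <- load_dataset(file.path(dir, "images"), file.path(dir, "masks"),
                       target_size = 64)
  for (s in back) {
    expect_equal(dim(s$image), c(64, 64, 3))
    expect_equal(dim(s$mask), c(64, 64))
    expect_true(all(s$mask %in% c(0L, 1L)))
  }
})

test_that("unmatched files raise an error naming the offenders", {
  samples <- generate_dataset(2, size = 64, seed = 15)
  dir <- tempfile("fixtures")
  write_dataset(samples, dir)
  file.remove(file.path(dir, "masks", "sample_0002.png"))
  expect_error(load_dataset(file.path(dir, "images"), file.path(dir, "masks")),
               "sample_0002")
})
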