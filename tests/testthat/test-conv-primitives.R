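test_that("squeeze-excitation preserves shape and gates in (0, 1)", {
  set.seed(3)
  x <- rand_map(2, 4, 4, 8, seed = 3)
  m <- se_module(8, reduction = 4)
  y <- squeeze_excitation(x, m)
  expect_equal(dim(y), dim(x))
  # gates strictly inside (0, 1): |y| < |x| wherever x != 0
  expect_true(all(abs(y) < abs(x) | x == 0))
  # nonnegative input: output sup-norm cannot exceed the input's
  xp <- abs(x)
  expect_lte(max(abs(squeeze_excitation(xp, m))), max(abs(xp)))
  expect_error(se_module(8, reduction = 0), "positive")
})

test_that("zero-weight SE gates every channel at exactly one half", {
  x <- rand_map(1, 3, 5, 4, seed = 4)
  m <- zero_params(se_module(4), c("fc1", "fc2"))
  expect_equal(squeeze_excitation(x, m), 0.5 * x, tolerance = 1e-12)
})

test_that("SE matches the closed form on a hand-computable 2-channel input", {
  # 1x1 spatial: pooled value is the input itself
  m <- se_module(2, reduction = 1)
  m$fc1$w$W <- matrix(c(0.5, -0.2, 0.1, 0.3), 2, 2)
  m$fc1$w$b <- c(0.05, -0.05)
  m$fc2$w$W <- matrix(c(-0.4, 0.6, 0.2, -0.1), 2, 2)
  m$fc2$w$b <- c(0.1, 0.2)
  x <- array(c(1.2, -0.7), c(1, 1, 1, 2))
  pooled <- c(1.2, -0.7)
  h <- pmax(as.vector(pooled %*% m$fc1$w$W) + m$fc1$w$b, 0)
  gate <- 1 / (1 + exp(-(as.vector(h %*% m$fc2$w$W) + m$fc2$w$b)))
  expect_equal(as.vector(squeeze_excitation(x, m)), pooled * gate,
               tolerance = 1e-12)
})

test_that("fused-MBConv is the exact identity under a zero final projection", {
  x <- rand_map(2, 5, 5, 6, seed = 5)
  m <- zero_params(fused_mbconv_module(6), c("^proj"))
  expect_identical(fused_mbconv(x, m), x)
})

test_that("fused-MBConv preserves shape and matches the nested-loop oracle", {
  set.seed(6)
  for (shp in list(c(1, 2, 2, 1), c(1, 3, 4, 2))) {
    x <- array(rnorm(prod(shp)), shp)
    m <- fused_mbconv_module(shp[4], se_reduction = 2)
    y <- fused_mbconv(x, m)
    expect_equal(dim(y), shp)
    expect_equal(y, oracle_fused_mbconv(x, m), tolerance = 1e-10)
  }
})

test_that("downsample halves space and doubles channels on even inputs", {
  set.seed(7)
  for (shp in list(c(1, 2, 2, 1), c(2, 6, 4, 3), c(1, 56, 56, 2))) {
    x <- array(rnorm(prod(shp)), shp)
    y <- downsample(x)
    expect_equal(dim(y), c(shp[1], shp[2] / 2, shp[3] / 2, 2 * shp[4]))
  }
  expect_error(downsample(rand_map(1, 3, 3, 4)), "even spatial")
})

test_that("downsample is deterministic given fixed weights", {
  x <- rand_map(1, 4, 4, 2, seed = 8)
  m <- downsample_module(2)
  expect_identical(gctransunet:::downsample_fwd(m, x)$y,
                   gctransunet:::downsample_fwd(m, x)$y)
})

test_that("stem reduces by the patch size into the embedding width", {
  cfg <- get_config("gcvit-t")
  set.seed(9)
  m <- stem_module(cfg$patch_size, cfg$base_dim)
  x <- array(runif(1 * 8 * 8 * 3), c(1, 8, 8, 3))
  m2 <- stem_module(4L, 2L)
  expect_equal(dim(stem(x, cfg, m = m2)), c(1, 2, 2, 2))
  expect_error(stem(array(0, c(1, 9, 9, 3)), cfg, m = m),
               "not divisible by patch size")
  # embedding conv parameter count follows the closed form k^2 * 3 * C + C
  k <- dim(m$embed$w$W)[1]
  expect_equal(length(m$embed$w$W) + length(m$embed$w$b),
               k^2 * 3 * 64 + 64)
})

test_that("stem output at 224 matches the stage-1 geometry of the tiny net", {
  cfg <- get_config("gcvit-t")
  set.seed(10)
  m <- stem_module(cfg$patch_size, cfg$base_dim)
  x <- array(runif(1 * 224 * 224 * 3), c(1, 224, 224, 3))
  expect_equal(dim(stem(x, cfg, m = m)), c(1, 56, 56, 64))
})
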