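test_that("decoder rebuilds full resolution through the halving schedule", {
  set.seed(38)
  cfg <- get_config("toy")
  dec <- gctransunet:::decoder_module(cfg)
  # channel schedule: base 64 -> 32 -> 16 -> 8 -> 8 -> num_classes
  expect_equal(dim(dec$step1$conv$w$W)[4], 32)
  expect_equal(dim(dec$step2$conv$w$W)[4], 16)
  expect_equal(dim(dec$step3$conv$w$W)[4], 8)
  expect_equal(dim(dec$step4$conv$w$W)[4], 8)
  expect_equal(dim(dec$head$w$W), c(8L, 1L))
  bottleneck <- rand_map(1, 4, 4, 64, seed = 38)
  skips <- list(rand_map(1, 32, 32, 8, seed = 39),
                rand_map(1, 16, 16, 16, seed = 40),
                rand_map(1, 8, 8, 32, seed = 41))
  logits <- decode(bottleneck, skips, cfg, m = dec)
  expect_equal(dim(logits), c(1, 64, 64, 1))
  bad <- skips
  bad[[3]] <- rand_map(1, 4, 4, 32, seed = 42)
  expect_error(decode(bottleneck, bad, cfg, m = dec), "skip feature size")
})

test_that("bilinear upsampling reproduces constants exactly", {
  x <- array(3.25, c(1, 5, 5, 2))
  y <- gctransunet:::bilinear_fwd(x, 10L, 10L)$y
  expect_equal(max(abs(y - 3.25)), 0)
})

test_that("the assembled network maps images to same-sized logits", {
  net <- gc_transunet("toy", seed = 43)
  img <- array(runif(2 * 64 * 64 * 3), c(2, 64, 64, 3))
  logits <- gc_transunet_forward(img, net)
  expect_equal(dim(logits), c(2, 64, 64, 1))
  # evaluation-mode forward passes are bitwise reproducible
  expect_identical(gc_transunet_forward(img, net), logits)
  # single-image input is accepted
  one <- predict(net, img[1, , , ], type = "prob")
  expect_equal(dim(one), c(64, 64, 1))
  expect_true(all(one >= 0 & one <= 1))
})

test_that("gradients reach every parameter group end to end", {
  net <- gc_transunet("toy", seed = 44)
  img <- array(runif(1 * 64 * 64 * 3), c(1, 64, 64, 3))
  fw <- gctransunet:::model_fwd(net, img, train = TRUE)
  dy <- array(1, dim(fw$y))
  bw <- gctransunet:::model_bwd(net, fw$cache, dy)
  flat <- gctransunet:::nn_collect(net)
  expect_setequal(names(bw$gw), names(flat))
  groups <- c("encoder/stem", "encoder/s1", "encoder/s2", "encoder/s3",
              "encoder/s4", "expand", "conv_more", "cnn/stem", "cnn/block1",
              "cnn/block2", "cnn/block3", "decoder/step1", "decoder/step4",
              "decoder/head")
  for (g in groups) {
    keys <- grep(paste0("^", g), names(bw$gw), value = TRUE)
    total <- sum(vapply(bw$gw[keys], function(a) sum(abs(a)), numeric(1)))
    expect_gt(total, 0)
  }
})

test_that("checkpoints restore weights, config and predictions exactly", {
  net <- gc_transunet("toy", seed = 45)
  img <- array(runif(1 * 64 * 64 * 3), c(1, 64, 64, 3))
  before <- predict(net, img)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(net, path, seed = 45L)
  back <- load_checkpoint(path)
  expect_equal(back$cfg$variant_name, "toy")
  expect_equal(predict(back, img), before, tolerance = 1e-12)
  expect_error(load_checkpoint(tempfile_with <- {
    p <- tempfile(fileext = ".rds"); saveRDS(list(a = 1), p); p
  }), "not a gctransunet checkpoint")
})

test_that("ablation toggles build, run, and move parameters as implied", {
  img <- array(runif(1 * 64 * 64 * 3), c(1, 64, 64, 3))
  base <- gc_transunet("toy", seed = 46)
  p0 <- gctransunet:::nn_num_params(base)
  variant <- function(tog) {
    cfg <- get_config("toy")
    cfg$toggles[[tog]] <- FALSE
    gc_transunet(cfg, seed = 46)
  }
  # removing GTG feature extraction, the Fused-MBConv downsampler stage, or
  # the learned patch expand strictly reduces the count
  for (tog in c("use_gtg_feature_extraction", "use_fused_mbconv_downsample",
                "use_patch_expand")) {
    net <- variant(tog)
    expect_lt(gctransunet:::nn_num_params(net), p0)
    expect_equal(dim(gc_transunet_forward(img, net)), c(1, 64, 64, 1))
  }
  # substituting one attention kind for the other swaps identically shaped
  # projections: the count is unchanged
  for (tog in c("use_local_attention", "use_global_attention")) {
    net <- variant(tog)
    expect_equal(gctransunet:::nn_num_params(net), p0)
    expect_equal(dim(gc_transunet_forward(img, net)), c(1, 64, 64, 1))
  }
})
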