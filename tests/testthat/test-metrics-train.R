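test_that("dice loss matches its closed forms", {
  t <- array(c(1, 1, 0, 0), c(1, 2, 2))
  # perfect overlap: loss bounded by the smoothing term
  expect_lt(dice_loss(t, t, smooth = 1e-6), 1e-6)
  expect_equal(dice_loss(t, t, smooth = 0), 0)
  # disjoint masks: loss tends to 1 as smooth -> 0
  p <- array(c(0, 0, 1, 1), c(1, 2, 2))
  expect_equal(dice_loss(p, t, smooth = 0), 1)
  # worked 4-pixel example: 1 - 2*1/(2+2) = 0.5
  expect_equal(dice_loss(array(c(1, 1, 0, 0), c(1, 4, 1)),
                         array(c(1, 0, 1, 0), c(1, 4, 1)), smooth = 0), 0.5)
  expect_error(dice_loss(array(0, c(1, 3, 1)), array(0, c(1, 4, 1))),
               "shape mismatch")
})

test_that("dice loss decreases monotonically with growing overlap", {
  set.seed(47)
  t <- array(rbinom(64, 1, 0.3), c(1, 8, 8))
  lambdas <- seq(0, 1, by = 0.1)
  losses <- vapply(lambdas, function(l) {
    p <- l * t + (1 - l) * (1 - t)
    dice_loss(p, t)
  }, numeric(1))
  expect_true(all(diff(losses) < 0))
  expect_true(all(losses >= 0 & losses <= 1))
})

test_that("dice loss gradient matches finite differences", {
  set.seed(48)
  p <- array(runif(2 * 4 * 4), c(2, 4, 4))
  t <- array(rbinom(2 * 4 * 4, 1, 0.4), c(2, 4, 4))
  g <- gctransunet:::dice_loss_grad(p, t)
  for (i in sample(length(p), 5)) {
    eps <- 1e-6
    pp <- p; pp[i] <- pp[i] + eps
    pm <- p; pm[i] <- pm[i] - eps
    expect_equal(g[i], (dice_loss(pp, t) - dice_loss(pm, t)) / (2 * eps),
                 tolerance = 1e-5)
  }
})

test_that("metrics agree with the exhaustive pixel-loop oracle", {
  set.seed(49)
  for (rep in 1:20) {
    pred <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8, 8)
    gt <- matrix(rbinom(64, 1, runif(1, 0.1, 0.9)), 8, 8)
    got <- compute_metrics(pred, gt)
    want <- oracle_metrics(as.vector(pred), as.vector(gt))
    for (nm in names(want)) {
      expect_equal(got[[nm]], want[[nm]], tolerance = 1e-12, label = nm)
    }
  }
})

test_that("metric edge cases behave per the confusion-matrix formulas", {
  m1 <- compute_metrics(matrix(1, 4, 4), matrix(1, 4, 4))
  for (nm in c("midce", "accuracy", "recall", "miou", "fwavacc", "f1")) {
    expect_equal(m1[[nm]], 1.0, label = nm)
  }
  # TP=2, FP=1, FN=1, TN=0
  pred <- c(1, 1, 1, 0)
  gt <- c(1, 1, 0, 1)
  m2 <- compute_metrics(pred, gt)
  expect_equal(m2$recall, 2 / 3)
  expect_equal(m2$midce, 2 / 3)
  expect_equal(m2$f1, 2 / 3)
  expect_equal(m2$miou, (2 / 4 + 0) / 2)   # IoU_fg = 1/2, IoU_bg = 0/2
  expect_equal(m2$fwavacc, 3 / 4 * 1 / 2 + 1 / 4 * 0)
  # all-background prediction on all-background truth
  m3 <- compute_metrics(matrix(0, 3, 3), matrix(0, 3, 3))
  expect_equal(m3$accuracy, 1)
  expect_equal(m3$recall, 1)               # zero-denominator convention
  expect_equal(m3$midce, 1)
  expect_error(compute_metrics(matrix(0.5, 2, 2), matrix(0, 2, 2)),
               "binary")
})

test_that("set-level midce is the mean of per-sample dice", {
  set.seed(50)
  samples <- generate_dataset(3, size = 64, seed = 50)
  net <- gc_transunet("toy", seed = 50)
  got <- evaluate_model(net, samples, batch_size = 2L)
  per <- vapply(samples, function(s) {
    pm <- (predict(net, s$image)[, , 1] >= 0.5) * 1
    compute_metrics(pm, s$mask)$midce
  }, numeric(1))
  expect_equal(got$midce, mean(per), tolerance = 1e-12)
  for (nm in c("accuracy", "recall", "miou", "fwavacc", "f1")) {
    expect_true(got[[nm]] >= 0 && got[[nm]] <= 1)
  }
})

test_that("training is seeded, finite, and logs the six metrics", {
  samples <- generate_dataset(2, size = 64, seed = 51)
  s <- train_settings(epochs = 1L, batch_size = 2L, seed = 51)
  f1 <- fit_gc_transunet(gc_transunet("toy", seed = 51), samples, samples, s)
  f2 <- fit_gc_transunet(gc_transunet("toy", seed = 51), samples, samples, s)
  expect_identical(f1$log$loss[1], f2$log$loss[1])
  expect_true(is.finite(f1$log$loss[1]))
  expect_gte(f1$log$loss[1], 0)
  expect_lte(f1$log$loss[1], 1)
  expect_named(f1$log, c("epoch", "loss", "midce", "accuracy", "recall",
                         "miou", "fwavacc", "f1"))
  expect_error(train_settings(learning_rate = 0), "learning_rate")
  expect_error(train_settings(batch_size = 0), "batch_size")
})

test_that("the training log round-trips through CSV", {
  samples <- generate_dataset(2, size = 64, seed = 52)
  log_path <- tempfile(fileext = ".csv")
  fit <- fit_gc_transunet(gc_transunet("toy", seed = 52), samples, samples,
                          train_settings(epochs = 2L, batch_size = 2L,
                                         seed = 52),
                          log_path = log_path)
  back <- utils::read.csv(log_path)
  expect_equal(nrow(back), 2L)
  expect_equal(back$midce, fit$log$midce, tolerance = 1e-12)
})
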