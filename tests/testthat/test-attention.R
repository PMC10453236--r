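test_that("window partition/reverse round-trips bitwise", {
  set.seed(11)
  for (conf in list(c(1, 6, 6, 3, 3), c(2, 8, 4, 2, 2), c(1, 56, 56, 1, 7))) {
    x <- array(rnorm(prod(conf[1:4])), conf[1:4])
    w <- conf[5]
    t <- window_partition(x, w)
    expect_equal(dim(t), c(conf[1] * (conf[2] / w) * (conf[3] / w), w^2,
                           conf[4]))
    expect_identical(window_reverse(t, w, conf[2], conf[3]), x)
  }
})

test_that("a single window is the identity reshape, and errors are raised", {
  x <- rand_map(1, 3, 3, 2, seed = 12)
  t <- window_partition(x, 3)
  expect_equal(dim(t), c(1, 9, 2))
  # row-major token order: token (r-1)*w + c holds pixel (r, c)
  for (r in 1:3) for (c in 1:3) {
    expect_identical(t[1, (r - 1) * 3 + c, ], x[1, r, c, ])
  }
  expect_identical(window_reverse(t, 3, 3, 3), x)
  expect_error(window_partition(x, 2), "not divisible")
  expect_error(window_reverse(t, 3, 6, 3), "inconsistent")
})

test_that("(56/7)^2 windows of 49 tokens come out of a stage-1 sized map", {
  x <- rand_map(1, 56, 56, 2, seed = 13)
  t <- window_partition(x, 7)
  expect_equal(dim(t)[1], 64)
  expect_equal(dim(t)[2], 49)
})

test_that("scaled attention obeys its closed forms and the loop oracle", {
  set.seed(14)
  # one query, one key: softmax of a scalar is 1, output is v
  q <- matrix(rnorm(3), 1, 3); k <- matrix(rnorm(3), 1, 3)
  v <- matrix(rnorm(3), 1, 3)
  expect_equal(scaled_attention(q, k, v), v, tolerance = 1e-12)
  # identical keys, zero bias: uniform softmax, output is the value mean
  k2 <- matrix(rep(rnorm(3), each = 4), 4, 3)
  v2 <- matrix(rnorm(12), 4, 3)
  expect_equal(as.vector(scaled_attention(q, k2, v2)),
               colMeans(v2), tolerance = 1e-12)
  # brute-force oracle on a 3-token, 2-dim instance
  q3 <- matrix(rnorm(6), 3, 2); k3 <- matrix(rnorm(6), 3, 2)
  v3 <- matrix(rnorm(6), 3, 2); b3 <- matrix(rnorm(9), 3, 3)
  expect_equal(scaled_attention(q3, k3, v3, b3),
               oracle_attention(q3, k3, v3, b3), tolerance = 1e-6)
  expect_error(scaled_attention(q3, matrix(0, 3, 3), v3), "mismatch")
})

test_that("local MSA equals the brute-force oracle head by head", {
  set.seed(15)
  w <- 3; C <- 4; heads <- 2
  m <- attention_module(C, heads, w)
  tok <- array(rnorm(2 * w^2 * C), c(2, w^2, C))
  y <- local_msa(tok, m)
  expect_equal(dim(y), dim(tok))
  ridx <- gctransunet:::relpos_index(w)
  hd <- C / heads
  for (g in 1:2) {
    xg <- matrix(tok[g, , ], w^2, C)
    qf <- sweep(xg %*% m$q$w$W, 2, m$q$w$b, `+`)
    kf <- sweep(xg %*% m$k$w$W, 2, m$k$w$b, `+`)
    vf <- sweep(xg %*% m$v$w$W, 2, m$v$w$b, `+`)
    heads_out <- matrix(0, w^2, C)
    for (h in 1:heads) {
      cols <- ((h - 1) * hd + 1):(h * hd)
      bmat <- matrix(m$bias$w$table[ridx, h], w^2, w^2)
      heads_out[, cols] <- oracle_attention(qf[, cols], kf[, cols],
                                            vf[, cols], bmat)
    }
    expected <- sweep(heads_out %*% m$o$w$W, 2, m$o$w$b, `+`)
    expect_equal(matrix(y[g, , ], w^2, C), expected, tolerance = 1e-6)
  }
})

test_that("single-head local MSA with identity output projection is bare attention", {
  set.seed(16)
  w <- 3; C <- 2
  m <- attention_module(C, 1, w)
  m$o$w$W <- diag(C)
  m$o$w$b <- numeric(C)
  tok <- array(rnorm(w^2 * C), c(1, w^2, C))
  xg <- matrix(tok[1, , ], w^2, C)
  qf <- sweep(xg %*% m$q$w$W, 2, m$q$w$b, `+`)
  kf <- sweep(xg %*% m$k$w$W, 2, m$k$w$b, `+`)
  vf <- sweep(xg %*% m$v$w$W, 2, m$v$w$b, `+`)
  bmat <- matrix(m$bias$w$table[gctransunet:::relpos_index(w), 1], w^2, w^2)
  expect_equal(matrix(local_msa(tok, m)[1, , ], w^2, C),
               oracle_attention(qf, kf, vf, bmat), tolerance = 1e-6)
})

test_that("local attention never leaks across windows", {
  set.seed(17)
  w <- 2; C <- 4
  m <- attention_module(C, 2, w)
  one <- array(rnorm(w^2 * C), c(1, w^2, C))
  two <- array(0, c(2, w^2, C))
  two[1, , ] <- one[1, , ]
  two[2, , ] <- one[1, , ]
  y <- local_msa(two, m)
  expect_equal(y[1, , ], y[2, , ], tolerance = 1e-12)
  # gradient of window 1's output w.r.t. window 2's input is exactly zero
  tok <- array(rnorm(2 * w^2 * C), c(2, w^2, C))
  fw <- gctransunet:::mha_fwd(m, tok, tok)
  dy <- array(0, dim(fw$y))
  dy[1, , ] <- 1
  bw <- gctransunet:::mha_bwd(m, fw$cache, dy)
  dtok <- bw$dq_src + bw$dkv_src
  expect_true(all(dtok[2, , ] == 0))
  expect_gt(max(abs(dtok[1, , ])), 0)
})

test_that("global MSA broadcasts shared queries and matches its oracle", {
  set.seed(18)
  w <- 2; C <- 4; B <- 1
  m <- attention_module(C, 2, w)
  gt <- array(rnorm(B * w^2 * C), c(B, w^2, C))
  win <- array(rnorm(2 * w^2 * C), c(2, w^2, C))
  win[2, , ] <- win[1, , ]                  # identical local content
  y <- global_msa(win, gt, m)
  expect_equal(y[1, , ], y[2, , ], tolerance = 1e-12)
  # loop oracle: softmax(q_g k_local' / sqrt(d) + b) v_local per window
  ridx <- gctransunet:::relpos_index(w)
  hd <- C / 2
  qg <- sweep(matrix(gt[1, , ], w^2, C) %*% m$q$w$W, 2, m$q$w$b, `+`)
  for (g in 1:2) {
    xg <- matrix(win[g, , ], w^2, C)
    kf <- sweep(xg %*% m$k$w$W, 2, m$k$w$b, `+`)
    vf <- sweep(xg %*% m$v$w$W, 2, m$v$w$b, `+`)
    ho <- matrix(0, w^2, C)
    for (h in 1:2) {
      cols <- ((h - 1) * hd + 1):(h * hd)
      bmat <- matrix(m$bias$w$table[ridx, h], w^2, w^2)
      ho[, cols] <- oracle_attention(qg[, cols], kf[, cols], vf[, cols], bmat)
    }
    expected <- sweep(ho %*% m$o$w$W, 2, m$o$w$b, `+`)
    expect_equal(matrix(y[g, , ], w^2, C), expected, tolerance = 1e-6)
  }
  expect_error(global_msa(win, array(0, c(1, 3, C)), m), "w\\^2")
})

test_that("softmax rows of every attention map sum to one", {
  set.seed(19)
  m <- attention_module(4, 2, 2)
  tok <- array(rnorm(4 * 4 * 4), c(4, 4, 4))
  fw <- gctransunet:::mha_fwd(m, tok, tok)
  for (p in fw$cache$P) expect_equal(rowSums(p), rep(1, nrow(p)),
                                     tolerance = 1e-6)
})

test_that("equal displacements share one bias entry (w = 3, exhaustive)", {
  w <- 3
  idx <- gctransunet:::relpos_index(w)
  pos <- cbind(rep(1:w, each = w), rep(1:w, times = w))  # (row, col) of token
  for (a in 1:w^2) for (b in 1:w^2) for (a2 in 1:w^2) for (b2 in 1:w^2) {
    same <- all(pos[a, ] - pos[b, ] == pos[a2, ] - pos[b2, ])
    if (same) expect_identical(idx[a, b], idx[a2, b2])
    else expect_false(idx[a, b] == idx[a2, b2])
  }
  expect_lte(max(idx), (2 * w - 1)^2)
  expect_gte(min(idx), 1)
})

test_that("transformer block is the identity under zero output projections", {
  set.seed(20)
  for (kind in c("local", "global")) {
    m <- gcvit_block_module(4, 2, 2, mlp_ratio = 2, kind = kind)
    m <- zero_params(m, c("attn/o", "mlp/fc2"))
    x <- rand_map(1, 4, 4, 4, seed = 21)
    gt <- array(rnorm(1 * 4 * 4), c(1, 4, 4))
    y <- gcvit_block(x, m, global_tokens = gt)
    expect_equal(y, x, tolerance = 1e-12)
  }
})

test_that("block kinds preserve shape; local ignores global tokens", {
  set.seed(22)
  x <- rand_map(2, 4, 4, 4, seed = 22)
  gt <- array(rnorm(2 * 4 * 4), c(2, 4, 4))
  ml <- gcvit_block_module(4, 2, 2, mlp_ratio = 2, kind = "local")
  mg <- gcvit_block_module(4, 2, 2, mlp_ratio = 2, kind = "global")
  expect_equal(dim(gcvit_block(x, ml)), dim(x))
  expect_equal(dim(gcvit_block(x, mg, gt)), dim(x))
  # perturbing the global tokens cannot change a local block's output
  y1 <- gcvit_block(x, ml, global_tokens = gt)
  y2 <- gcvit_block(x, ml, global_tokens = gt + 100)
  expect_identical(y1, y2)
  expect_error(gcvit_block(x, mg), "requires global tokens")
})
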