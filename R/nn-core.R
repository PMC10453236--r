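# Core tensor primitives: forward + reverse-mode backward passes.
#
# Layout conventions (channel-last, batch-first):
#   feature maps  : numeric array (B, H, W, C)
#   token sets    : numeric array (G, T, C)   G = batch * windows (batch fastest)
# Every *_fwd returns list(y, cache); the matching *_bwd consumes (cache, dy)
# and returns list(dx = ..., <grad arrays named after the parameters>).
# Gradients are exact analytic derivatives (verified by finite differences in
# the test suite); no autodiff framework is involved.

mat2 <- function(x, ncol) {
  dim(x) <- c(length(x) %/% ncol, ncol)
  x
}

zeros_like <- function(x) {
  z <- array(0, dim = if (is.null(dim(x))) length(x) else dim(x))
  z
}

#' @noRd
pad_hw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + 2L * p, d[3] + 2L * p, d[4]))
  out[, (p + 1L):(p + d[2]), (p + 1L):(p + d[3]), ] <- x
  out
}

unpad_hw <- function(x, p, H, W) {
  if (p == 0L) return(x)
  x[, (p + 1L):(p + H), (p + 1L):(p + W), , drop = FALSE]
}

# -- dense 2-D convolution via im2col + GEMM ---------------------------------

conv_out_side <- function(side, k, stride, pad) {
  (side + 2L * pad - k) %/% stride + 1L
}

# index matrix (n_out_positions x k^2) into the padded spatial grid; output
# positions ordered with the row index fastest (column-major, matching R
# array layout), kernel offsets ordered row-fastest to match W flattening
im2col_index <- function(H, W, k, stride, pad) {
  Hp <- H + 2L * pad
  Ho <- conv_out_side(H, k, stride, pad)
  Wo <- conv_out_side(W, k, stride, pad)
  orow <- rep.int(seq.int(0L, by = stride, length.out = Ho), Wo)
  ocol <- rep(seq.int(0L, by = stride, length.out = Wo), each = Ho)
  krow <- rep.int(seq_len(k), k)
  kcol <- rep(seq_len(k), each = k)
  outer(orow, krow, `+`) + Hp * (outer(ocol, kcol, `+`) - 1L)
}

conv2d_fwd <- function(x, W, b = NULL, stride = 1L, pad = 0L, keep = FALSE) {
  d <- dim(x)
  B <- d[1]; H <- d[2]; Wd <- d[3]; Cin <- d[4]
  k <- dim(W)[1]
  stopifnot(dim(W)[3] == Cin)
  Cout <- dim(W)[4]
  Ho <- conv_out_side(H, k, stride, pad)
  Wo <- conv_out_side(Wd, k, stride, pad)
  if (Ho < 1L || Wo < 1L) stop("conv2d: input too small for kernel")
  idx <- im2col_index(H, Wd, k, stride, pad)
  xp <- pad_hw(x, pad)
  Hp <- H + 2L * pad; Wp <- Wd + 2L * pad
  Wmat <- mat2(W, Cout)
  y <- array(0, c(B, Ho, Wo, Cout))
  cols <- if (keep) vector("list", B) else NULL
  for (bi in seq_len(B)) {
    xm <- xp[bi, , , ]
    dim(xm) <- c(Hp * Wp, Cin)
    M <- xm[idx, , drop = FALSE]          # (Np*k^2, Cin), Np fastest
    dim(M) <- c(nrow(idx), k * k * Cin)
    yb <- M %*% Wmat
    if (!is.null(b)) yb <- sweep(yb, 2L, b, `+`)
    y[bi, , , ] <- yb
    if (keep) cols[[bi]] <- M
  }
  cache <- list(cols = cols, idx = idx, dims = d, k = k, stride = stride,
                pad = pad, W = W, has_bias = !is.null(b),
                out = c(Ho, Wo, Cout))
  list(y = y, cache = cache)
}

conv2d_bwd <- function(cache, dy) {
  d <- cache$dims
  B <- d[1]; H <- d[2]; Wd <- d[3]; Cin <- d[4]
  k <- cache$k; pad <- cache$pad
  Ho <- cache$out[1]; Wo <- cache$out[2]; Cout <- cache$out[3]
  Hp <- H + 2L * pad; Wp <- Wd + 2L * pad
  Wmat <- mat2(cache$W, Cout)
  idxv <- as.vector(cache$idx)
  Np <- nrow(cache$idx)
  dW <- matrix(0, k * k * Cin, Cout)
  db <- if (cache$has_bias) numeric(Cout) else NULL
  dx <- array(0, c(B, H, Wd, Cin))
  for (bi in seq_len(B)) {
    dyb <- dy[bi, , , ]
    dim(dyb) <- c(Np, Cout)
    M <- cache$cols[[bi]]
    dW <- dW + crossprod(M, dyb)
    if (cache$has_bias) db <- db + colSums(dyb)
    dM <- dyb %*% t(Wmat)                  # (Np, k^2*Cin)
    dim(dM) <- c(Np * k * k, Cin)
    rs <- rowsum(dM, group = idxv)
    dxp <- matrix(0, Hp * Wp, Cin)
    dxp[as.integer(rownames(rs)), ] <- rs
    dim(dxp) <- c(Hp, Wp, Cin)
    dx[bi, , , ] <- dxp[(pad + 1L):(pad + H), (pad + 1L):(pad + Wd), ]
  }
  dim(dW) <- dim(cache$W)
  list(dx = dx, W = dW, b = db)
}

# -- 3x3 depthwise convolution, stride 1, pad 1 ------------------------------

dwconv3_fwd <- function(x, W, b) {
  d <- dim(x)
  B <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  xp <- pad_hw(x, 1L)
  y <- array(0, c(B, H, Wd, C))
  for (ki in 1:3) for (kj in 1:3) {
    sl <- xp[, ki:(ki + H - 1L), kj:(kj + Wd - 1L), , drop = FALSE]
    y <- y + sweep(sl, 4L, W[ki, kj, ], `*`)
  }
  y <- sweep(y, 4L, b, `+`)
  list(y = y, cache = list(xp = xp, W = W, dims = d))
}

dwconv3_bwd <- function(cache, dy) {
  d <- cache$dims
  B <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  dW <- array(0, c(3L, 3L, C))
  dxp <- zeros_like(cache$xp)
  for (ki in 1:3) for (kj in 1:3) {
    sl <- cache$xp[, ki:(ki + H - 1L), kj:(kj + Wd - 1L), , drop = FALSE]
    pr <- dy * sl
    dim(pr) <- c(B * H * Wd, C)
    dW[ki, kj, ] <- colSums(pr)
    dxp[, ki:(ki + H - 1L), kj:(kj + Wd - 1L), ] <-
      dxp[, ki:(ki + H - 1L), kj:(kj + Wd - 1L), , drop = FALSE] +
      sweep(dy, 4L, cache$W[ki, kj, ], `*`)
  }
  dyf <- dy
  dim(dyf) <- c(B * H * Wd, C)
  list(dx = unpad_hw(dxp, 1L, H, Wd), W = dW, b = colSums(dyf))
}

# -- linear (applies over the last axis, any leading shape) ------------------

linear_fwd <- function(x, W, b = NULL) {
  d <- if (is.null(dim(x))) length(x) else dim(x)
  Cin <- d[length(d)]
  xm <- mat2(x, Cin)
  y <- xm %*% W
  if (!is.null(b)) y <- sweep(y, 2L, b, `+`)
  dim(y) <- c(d[-length(d)], ncol(W))
  list(y = y, cache = list(xm = xm, W = W, d = d, has_bias = !is.null(b)))
}

linear_bwd <- function(cache, dy) {
  Cout <- ncol(cache$W)
  dym <- mat2(dy, Cout)
  dx <- dym %*% t(cache$W)
  dim(dx) <- cache$d
  list(dx = dx,
       W = crossprod(cache$xm, dym),
       b = if (cache$has_bias) colSums(dym) else NULL)
}

# -- normalisations ----------------------------------------------------------

layernorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  d <- if (is.null(dim(x))) length(x) else dim(x)
  C <- d[length(d)]
  xm <- mat2(x, C)
  mu <- rowMeans(xm)
  xc <- xm - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xh <- xc * inv
  y <- sweep(sweep(xh, 2L, gamma, `*`), 2L, beta, `+`)
  dim(y) <- d
  list(y = y, cache = list(xh = xh, inv = inv, gamma = gamma, d = d))
}

layernorm_bwd <- function(cache, dy) {
  d <- cache$d
  C <- d[length(d)]
  dym <- mat2(dy, C)
  xh <- cache$xh
  dxh <- sweep(dym, 2L, cache$gamma, `*`)
  dx <- (dxh - rowMeans(dxh) - xh * rowMeans(dxh * xh)) * cache$inv
  dim(dx) <- d
  list(dx = dx, gamma = colSums(dym * xh), beta = colSums(dym))
}

# group normalisation over (H, W, C_g) per sample and group; gamma/beta per
# channel. groups must divide C.
groupnorm_fwd <- function(x, gamma, beta, groups = 1L, eps = 1e-6) {
  d <- dim(x)
  B <- d[1]; C <- d[4]
  stopifnot(C %% groups == 0L)
  Cg <- C %/% groups
  xh <- zeros_like(x)
  inv <- matrix(0, B, groups)
  for (bi in seq_len(B)) for (g in seq_len(groups)) {
    cs <- ((g - 1L) * Cg + 1L):(g * Cg)
    sl <- x[bi, , , cs]
    mu <- mean(sl)
    v <- mean((sl - mu)^2)
    inv[bi, g] <- 1 / sqrt(v + eps)
    xh[bi, , , cs] <- (sl - mu) * inv[bi, g]
  }
  y <- sweep(sweep(xh, 4L, gamma, `*`), 4L, beta, `+`)
  list(y = y, cache = list(xh = xh, inv = inv, gamma = gamma,
                           groups = groups, d = d))
}

groupnorm_bwd <- function(cache, dy) {
  d <- cache$d
  B <- d[1]; C <- d[4]
  groups <- cache$groups
  Cg <- C %/% groups
  xh <- cache$xh
  dxh <- sweep(dy, 4L, cache$gamma, `*`)
  dx <- zeros_like(dy)
  for (bi in seq_len(B)) for (g in seq_len(groups)) {
    cs <- ((g - 1L) * Cg + 1L):(g * Cg)
    dh <- dxh[bi, , , cs]
    h <- xh[bi, , , cs]
    dx[bi, , , cs] <- (dh - mean(dh) - h * mean(dh * h)) * cache$inv[bi, g]
  }
  pr <- dy * xh
  dim(pr) <- c(B * d[2] * d[3], C)
  dyf <- dy
  dim(dyf) <- c(B * d[2] * d[3], C)
  list(dx = dx, gamma = colSums(pr), beta = colSums(dyf))
}

# batch norm over (B, H, W) per channel; `stats` is an environment holding
# running mean/var (reference semantics: updated in place during training)
batchnorm_fwd <- function(x, gamma, beta, stats, train = FALSE,
                          eps = 1e-5, momentum = 0.1) {
  d <- dim(x)
  C <- d[4]
  xm <- mat2(x, C)
  if (train) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    v <- colMeans(xc * xc)
    stats$mean <- (1 - momentum) * stats$mean + momentum * mu
    stats$var <- (1 - momentum) * stats$var + momentum * v
  } else {
    mu <- stats$mean
    v <- stats$var
    xc <- sweep(xm, 2L, mu)
  }
  inv <- 1 / sqrt(v + eps)
  xh <- sweep(xc, 2L, inv, `*`)
  y <- sweep(sweep(xh, 2L, gamma, `*`), 2L, beta, `+`)
  dim(y) <- d
  list(y = y, cache = list(xh = xh, inv = inv, gamma = gamma, d = d,
                           train = train))
}

batchnorm_bwd <- function(cache, dy) {
  d <- cache$d
  C <- d[length(d)]
  dym <- mat2(dy, C)
  xh <- cache$xh
  dxh <- sweep(dym, 2L, cache$gamma, `*`)
  if (cache$train) {
    dx <- sweep(dxh, 2L, colMeans(dxh)) -
      sweep(xh, 2L, colMeans(dxh * xh), `*`)
    dx <- sweep(dx, 2L, cache$inv, `*`)
  } else {
    dx <- sweep(dxh, 2L, cache$inv, `*`)
  }
  dim(dx) <- d
  list(dx = dx, gamma = colSums(dym * xh), beta = colSums(dym))
}

# -- activations -------------------------------------------------------------

gelu_fwd <- function(x) {
  ph <- stats::pnorm(x)
  list(y = x * ph, cache = list(x = x, ph = ph))
}

gelu_bwd <- function(cache, dy) {
  dy * (cache$ph + cache$x * stats::dnorm(cache$x))
}

relu_fwd <- function(x) {
  m <- x > 0
  list(y = x * m, cache = m)
}

relu_bwd <- function(cache, dy) dy * cache

sigmoid_fwd <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(y = y, cache = y)
}

sigmoid_bwd <- function(cache, dy) dy * cache * (1 - cache)

softmax_rows <- function(m) {
  mx <- apply(m, 1L, max)
  e <- exp(m - mx)
  e / rowSums(e)
}

# -- 2x2 max pooling, stride 2 ----------------------------------------------

maxpool2_fwd <- function(x) {
  d <- dim(x)
  H <- d[2]; W <- d[3]
  stopifnot(H %% 2L == 0L, W %% 2L == 0L)
  oh <- seq(1L, H, 2L); ow <- seq(1L, W, 2L)
  s <- list(x[, oh, ow, , drop = FALSE], x[, oh + 1L, ow, , drop = FALSE],
            x[, oh, ow + 1L, , drop = FALSE], x[, oh + 1L, ow + 1L, , drop = FALSE])
  y <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  taken <- zeros_like(y)
  masks <- vector("list", 4L)
  for (i in 1:4) {
    m <- (s[[i]] == y) & (taken == 0)    # first slice wins ties
    taken <- taken + m
    masks[[i]] <- m
  }
  list(y = y, cache = list(masks = masks, d = d))
}

maxpool2_bwd <- function(cache, dy) {
  d <- cache$d
  H <- d[2]; W <- d[3]
  oh <- seq(1L, H, 2L); ow <- seq(1L, W, 2L)
  dx <- array(0, d)
  dx[, oh, ow, ] <- dy * cache$masks[[1]]
  dx[, oh + 1L, ow, ] <- dy * cache$masks[[2]]
  dx[, oh, ow + 1L, ] <- dy * cache$masks[[3]]
  dx[, oh + 1L, ow + 1L, ] <- dy * cache$masks[[4]]
  dx
}

# -- bilinear resampling (separable; half-pixel centres, clamped edges) ------

# interpolation matrix A (n_out x n_in): y = A %*% x along one axis.
# Exact on constants (rows sum to 1).
interp_matrix <- function(n_in, n_out) {
  A <- matrix(0, n_out, n_in)
  src <- ((seq_len(n_out) - 0.5) * n_in / n_out) - 0.5
  src <- pmin(pmax(src, 0), n_in - 1)
  i0 <- floor(src)
  w1 <- src - i0
  i1 <- pmin(i0 + 1, n_in - 1)
  for (i in seq_len(n_out)) {
    A[i, i0[i] + 1L] <- A[i, i0[i] + 1L] + (1 - w1[i])
    A[i, i1[i] + 1L] <- A[i, i1[i] + 1L] + w1[i]
  }
  A
}

bilinear_apply <- function(x, Ah, Aw) {
  d <- dim(x)
  B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  Ho <- nrow(Ah); Wo <- nrow(Aw)
  y <- array(0, c(B, Ho, Wo, C))
  for (bi in seq_len(B)) {
    xb <- x[bi, , , ]
    dim(xb) <- c(H, W * C)
    z <- Ah %*% xb
    dim(z) <- c(Ho, W, C)
    z <- aperm(z, c(2L, 1L, 3L))
    dim(z) <- c(W, Ho * C)
    z <- Aw %*% z
    dim(z) <- c(Wo, Ho, C)
    y[bi, , , ] <- aperm(z, c(2L, 1L, 3L))
  }
  y
}

bilinear_fwd <- function(x, Ho, Wo) {
  d <- dim(x)
  Ah <- interp_matrix(d[2], Ho)
  Aw <- interp_matrix(d[3], Wo)
  list(y = bilinear_apply(x, Ah, Aw), cache = list(Ah = Ah, Aw = Aw))
}

bilinear_bwd <- function(cache, dy) {
  bilinear_apply(dy, t(cache$Ah), t(cache$Aw))
}

# nearest-neighbour resize (used for masks; no gradient needed)
nearest_resize <- function(x, Ho, Wo) {
  d <- dim(x)
  ri <- pmin(pmax(floor(((seq_len(Ho) - 0.5) * d[1] / Ho)) + 1L, 1L), d[1])
  ci <- pmin(pmax(floor(((seq_len(Wo) - 0.5) * d[2] / Wo)) + 1L, 1L), d[2])
  if (length(d) == 2L) x[ri, ci, drop = FALSE] else x[ri, ci, , drop = FALSE]
}

# -- parameter tree utilities ------------------------------------------------

# A module is a named list; trainable arrays live under an element named "w"
# (itself a named list of numeric arrays). Sub-modules are any other list
# elements. `nn_collect` flattens to a named list of arrays keyed by path.
nn_collect <- function(m, path = character()) {
  out <- list()
  if (!is.list(m)) return(out)
  if (!is.null(m$w)) {
    for (nm in names(m$w)) {
      out[[paste(c(path, nm), collapse = "/")]] <- m$w[[nm]]
    }
  }
  for (nm in names(m)) {
    if (nm %in% c("w", "stats", "cfg", "hyper")) next
    el <- m[[nm]]
    if (is.list(el)) out <- c(out, nn_collect(el, c(path, nm)))
  }
  out
}

nn_num_params <- function(m) sum(vapply(nn_collect(m), length, numeric(1)))

# write a flat named list of arrays (as produced by nn_collect) back into the
# module tree
nn_restore <- function(m, flat) {
  set1 <- function(node, parts, value) {
    if (length(parts) == 1L) {
      stopifnot(!is.null(node$w[[parts]]))
      dim(value) <- dim(node$w[[parts]])
      node$w[[parts]] <- value
      return(node)
    }
    node[[parts[1]]] <- set1(node[[parts[1]]], parts[-1], value)
    node
  }
  for (key in names(flat)) {
    m <- set1(m, strsplit(key, "/", fixed = TRUE)[[1]], flat[[key]])
  }
  m
}

# elementwise map over two parallel flat parameter lists
flat_map2 <- function(a, b, f) {
  stopifnot(identical(names(a), names(b)))
  out <- a
  for (nm in names(a)) out[[nm]] <- f(a[[nm]], b[[nm]])
  out
}

# -- weight initialisation ---------------------------------------------------

# truncated normal (+-2 sd), the ViT convention for projections and convs
init_trunc_normal <- function(dims, sd = 0.02) {
  n <- prod(dims)
  z <- stats::qnorm(stats::runif(n, stats::pnorm(-2), stats::pnorm(2))) * sd
  array(z, dims)
}

init_zeros <- function(dims) array(0, dims)
init_ones <- function(dims) array(1, dims)
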