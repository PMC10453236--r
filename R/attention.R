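# Windowed multi-head self-attention: window partitioning, relative position
# bias, scaled dot-product attention, local MSA (queries from the window's
# own tokens) and global-query MSA (queries from shared global tokens), plus
# the pre-norm transformer block that wraps them.

#' Partition a feature map into non-overlapping windows
#'
#' Tokens are ordered row-major within each window (column index fastest)
#' and windows row-major over the window grid; within the group axis the
#' batch index varies fastest, so group `g` belongs to batch element
#' `((g - 1) %% B) + 1`.
#'
#' @param x feature map array (B, H, W, C), H and W divisible by `w`.
#' @param w window side length.
#' @return token array (B * (H/w) * (W/w), w^2, C).
#' @export
window_partition <- function(x, w) {
  d <- dim(x)
  B <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  if (H %% w != 0L || W %% w != 0L) {
    stop(sprintf("window_partition: %dx%d not divisible by window %d",
                 H, W, w), call. = FALSE)
  }
  nh <- H %/% w; nw <- W %/% w
  dim(x) <- c(B, w, nh, w, nw, C)          # (b, wr, hb, wc, wb, C)
  x <- aperm(x, c(1L, 5L, 3L, 4L, 2L, 6L)) # (b, wb, hb, wc, wr, C)
  dim(x) <- c(B * nw * nh, w * w, C)
  x
}

#' Reassemble windows into a feature map (inverse of [window_partition()])
#'
#' @param t token array (B * (H/w) * (W/w), w^2, C).
#' @param w window side length.
#' @param H,W spatial size of the original map.
#' @return feature map array (B, H, W, C).
#' @export
window_reverse <- function(t, w, H, W) {
  d <- dim(t)
  if (H %% w != 0L || W %% w != 0L || d[2] != w * w) {
    stop("window_reverse: inconsistent window geometry", call. = FALSE)
  }
  nh <- H %/% w; nw <- W %/% w
  if (d[1] %% (nh * nw) != 0L) {
    stop("window_reverse: group count inconsistent with H, W", call. = FALSE)
  }
  B <- d[1] %/% (nh * nw)
  C <- d[3]
  dim(t) <- c(B, nw, nh, w, w, C)          # (b, wb, hb, wc, wr, C)
  t <- aperm(t, c(1L, 5L, 3L, 4L, 2L, 6L)) # (b, wr, hb, wc, wb, C)
  dim(t) <- c(B, H, W, C)
  t
}

# relative position bias index map for a w x w window: entry (q, k) of the
# returned w^2 x w^2 matrix indexes into the (2w-1)^2 displacement table
relpos_index <- function(w) {
  pos_r <- rep(seq_len(w), each = w)   # token = (r-1)*w + c, c fastest
  pos_c <- rep(seq_len(w), times = w)
  dr <- outer(pos_r, pos_r, `-`) + w       # in 1..2w-1
  dc <- outer(pos_c, pos_c, `-`) + w
  (dr - 1L) * (2L * w - 1L) + dc           # in 1..(2w-1)^2
}

#' Multi-head attention module
#'
#' Holds the query/key/value/output projections (each `dim x dim` with
#' bias) and the learned relative position bias table covering all
#' `(2w-1)^2` in-window displacements per head.
#'
#' @param dim token dimension (divisible by `num_heads`).
#' @param num_heads head count.
#' @param w window side length.
#' @return an attention module for [local_msa()] / [global_msa()].
#' @export
attention_module <- function(dim, num_heads, w) {
  if (dim %% num_heads != 0L) {
    stop(sprintf("dim %d not divisible by %d heads", dim, num_heads),
         call. = FALSE)
  }
  list(type = "attention",
       num_heads = as.integer(num_heads),
       head_dim = dim %/% as.integer(num_heads),
       w = as.integer(w),
       q = make_linear(dim, dim),
       k = make_linear(dim, dim),
       v = make_linear(dim, dim),
       o = make_linear(dim, dim),
       bias = list(type = "bias_table",
                   w = list(table = init_trunc_normal(
                     c((2L * w - 1L)^2, num_heads)))))
}

#' Scaled dot-product attention (single head)
#'
#' `softmax(q k' / sqrt(d) + bias) v` with the softmax over the key axis;
#' each softmax row sums to one.
#'
#' @param q,k,v matrices (tokens x head_dim); k and v share token count.
#' @param bias additive logit matrix (q_tokens x k_tokens) or `NULL`.
#' @return matrix (q_tokens x head_dim).
#' @export
scaled_attention <- function(q, k, v, bias = NULL) {
  if (ncol(q) != ncol(k) || nrow(k) != nrow(v)) {
    stop("scaled_attention: dimension mismatch", call. = FALSE)
  }
  logits <- tcrossprod(q, k) / sqrt(ncol(q))
  if (!is.null(bias)) logits <- logits + bias
  softmax_rows(logits) %*% v
}

# core multi-head attention over grouped tokens.
#   q_src: (Gq, Tq, C) queries; kv_src: (G, T, C) keys/values.
#   When Gq < G the queries are shared: window g uses query group
#   ((g - 1) %% Gq) + 1 (batch-fastest group order).
mha_fwd <- function(m, q_src, kv_src) {
  h <- m$num_heads; hd <- m$head_dim
  C <- h * hd
  w <- m$w
  G <- dim(kv_src)[1]; Tk <- dim(kv_src)[2]
  Gq <- dim(q_src)[1]; Tq <- dim(q_src)[2]
  fq <- linear_mod_fwd(m$q, q_src)
  fk <- linear_mod_fwd(m$k, kv_src)
  fv <- linear_mod_fwd(m$v, kv_src)
  qa <- fq$y; dim(qa) <- c(Gq, Tq, hd, h)
  ka <- fk$y; dim(ka) <- c(G, Tk, hd, h)
  va <- fv$y; dim(va) <- c(G, Tk, hd, h)
  ridx <- relpos_index(w)
  scale <- 1 / sqrt(hd)
  out <- array(0, c(G, Tq, hd, h))
  P <- vector("list", G * h)
  for (g in seq_len(G)) {
    gq <- ((g - 1L) %% Gq) + 1L
    for (hh in seq_len(h)) {
      qm <- matrix(qa[gq, , , hh], Tq, hd)
      km <- matrix(ka[g, , , hh], Tk, hd)
      vm <- matrix(va[g, , , hh], Tk, hd)
      bmat <- matrix(m$bias$w$table[ridx, hh], Tq, Tk)
      pm <- softmax_rows(tcrossprod(qm, km) * scale + bmat)
      out[g, , , hh] <- pm %*% vm
      P[[(g - 1L) * h + hh]] <- pm
    }
  }
  dim(out) <- c(G, Tq, C)
  fo <- linear_mod_fwd(m$o, out)
  list(y = fo$y,
       cache = list(fq = fq$cache, fk = fk$cache, fv = fv$cache,
                    fo = fo$cache, qa = qa, ka = ka, va = va, P = P,
                    ridx = ridx, G = G, Gq = Gq, Tq = Tq, Tk = Tk))
}

mha_bwd <- function(m, cache, dy) {
  h <- m$num_heads; hd <- m$head_dim
  G <- cache$G; Gq <- cache$Gq; Tq <- cache$Tq; Tk <- cache$Tk
  scale <- 1 / sqrt(hd)
  ro <- linear_mod_bwd(m$o, cache$fo, dy)
  dout <- ro$dx
  dim(dout) <- c(G, Tq, hd, h)
  dqa <- array(0, c(Gq, Tq, hd, h))
  dka <- array(0, c(G, Tk, hd, h))
  dva <- array(0, c(G, Tk, hd, h))
  dtab <- zeros_like(m$bias$w$table)
  ridxv <- as.vector(cache$ridx)
  for (g in seq_len(G)) {
    gq <- ((g - 1L) %% Gq) + 1L
    for (hh in seq_len(h)) {
      pm <- cache$P[[(g - 1L) * h + hh]]
      dome <- matrix(dout[g, , , hh], Tq, hd)
      vm <- matrix(cache$va[g, , , hh], Tk, hd)
      dP <- tcrossprod(dome, vm)
      dva[g, , , hh] <- dva[g, , , hh] + crossprod(pm, dome)
      dlog <- pm * (dP - rowSums(dP * pm))
      rs <- rowsum(as.vector(dlog), group = ridxv)
      ids <- as.integer(rownames(rs))
      dtab[ids, hh] <- dtab[ids, hh] + rs[, 1L]
      qm <- matrix(cache$qa[gq, , , hh], Tq, hd)
      km <- matrix(cache$ka[g, , , hh], Tk, hd)
      dqa[gq, , , hh] <- dqa[gq, , , hh] + (dlog %*% km) * scale
      dka[g, , , hh] <- dka[g, , , hh] + crossprod(dlog, qm) * scale
    }
  }
  C <- h * hd
  dim(dqa) <- c(Gq, Tq, C)
  dim(dka) <- c(G, Tk, C)
  dim(dva) <- c(G, Tk, C)
  rq <- linear_mod_bwd(m$q, cache$fq, dqa)
  rk <- linear_mod_bwd(m$k, cache$fk, dka)
  rv <- linear_mod_bwd(m$v, cache$fv, dva)
  gw <- c(prefix_gw(rq$gw, "q"), prefix_gw(rk$gw, "k"),
          prefix_gw(rv$gw, "v"), prefix_gw(ro$gw, "o"),
          prefix_gw(list(table = dtab), "bias"))
  list(dq_src = rq$dx, dkv_src = rk$dx + rv$dx, gw = gw)
}

#' Local windowed multi-head self-attention
#'
#' Queries, keys and values are all projected from each window's own
#' tokens; no information crosses window boundaries.
#'
#' @param windows token array (groups, w^2, C) from [window_partition()].
#' @param m an [attention_module()].
#' @return token array of the same shape.
#' @export
local_msa <- function(windows, m) {
  mha_fwd(m, windows, windows)$y
}

#' Global-query multi-head attention
#'
#' Queries are projected from the shared global tokens of each batch
#' element (broadcast to every window of that element); keys and values
#' come from each window's local tokens.
#'
#' @param windows token array (B * num_windows, w^2, C), batch index
#'   fastest along the group axis.
#' @param global_tokens token array (B, w^2, C) from
#'   [generate_global_tokens()].
#' @param m an [attention_module()].
#' @return token array shaped like `windows`.
#' @export
global_msa <- function(windows, global_tokens, m) {
  if (dim(global_tokens)[2] != dim(windows)[2]) {
    stop("global_msa: global token count must equal window capacity w^2",
         call. = FALSE)
  }
  mha_fwd(m, global_tokens, windows)$y
}

# ---------------------------------------------------------------------------
# transformer block: pre-norm residual MSA + MLP (GELU, hidden mlp_ratio*C)

make_mlp <- function(C, mlp_ratio) {
  hidden <- as.integer(round(mlp_ratio * C))
  list(type = "mlp",
       fc1 = make_linear(C, hidden),
       fc2 = make_linear(hidden, C))
}

mlp_fwd <- function(m, x) {
  f1 <- linear_mod_fwd(m$fc1, x)
  g <- gelu_fwd(f1$y)
  f2 <- linear_mod_fwd(m$fc2, g$y)
  list(y = f2$y, cache = list(f1 = f1$cache, g = g$cache, f2 = f2$cache))
}

mlp_bwd <- function(m, cache, dy) {
  r2 <- linear_mod_bwd(m$fc2, cache$f2, dy)
  dg <- gelu_bwd(cache$g, r2$dx)
  r1 <- linear_mod_bwd(m$fc1, cache$f1, dg)
  list(dx = r1$dx, gw = c(prefix_gw(r1$gw, "fc1"), prefix_gw(r2$gw, "fc2")))
}

#' GC-ViT transformer block module
#'
#' Pre-norm residual block: `x + MSA(LN(x))` followed by `+ MLP(LN(.))`.
#' `kind = "local"` attends within windows; `kind = "global"` uses shared
#' global-token queries.
#'
#' @param dim channel width.
#' @param num_heads head count.
#' @param w window side.
#' @param mlp_ratio MLP hidden-width multiplier.
#' @param kind `"local"` or `"global"`.
#' @return a block module usable with [gcvit_block()].
#' @export
gcvit_block_module <- function(dim, num_heads, w, mlp_ratio,
                               kind = c("local", "global")) {
  kind <- match.arg(kind)
  list(type = "gcvit_block", kind = kind, w = as.integer(w),
       norm1 = make_layernorm(dim),
       attn = attention_module(dim, num_heads, w),
       norm2 = make_layernorm(dim),
       mlp = make_mlp(dim, mlp_ratio))
}

block_fwd <- function(m, x, global_tokens = NULL) {
  if (m$kind == "global" && is.null(global_tokens)) {
    stop("global gcvit block requires global tokens", call. = FALSE)
  }
  d <- dim(x)
  H <- d[2]; W <- d[3]
  n1 <- layernorm_mod_fwd(m$norm1, x)
  win <- window_partition(n1$y, m$w)
  at <- if (m$kind == "global") {
    mha_fwd(m$attn, global_tokens, win)
  } else {
    mha_fwd(m$attn, win, win)
  }
  x1 <- x + window_reverse(at$y, m$w, H, W)
  n2 <- layernorm_mod_fwd(m$norm2, x1)
  mp <- mlp_fwd(m$mlp, n2$y)
  list(y = x1 + mp$y,
       cache = list(n1 = n1$cache, at = at$cache, n2 = n2$cache,
                    mp = mp$cache, H = H, W = W))
}

# returns dglobal (gradient w.r.t. global tokens) for global blocks
block_bwd <- function(m, cache, dy) {
  H <- cache$H; W <- cache$W
  rm_ <- mlp_bwd(m$mlp, cache$mp, dy)
  rn2 <- layernorm_mod_bwd(m$norm2, cache$n2, rm_$dx)
  dx1 <- dy + rn2$dx
  dwin <- window_partition(dx1, m$w)
  ra <- mha_bwd(m$attn, cache$at, dwin)
  dglobal <- NULL
  if (m$kind == "global") {
    dn1_tokens <- ra$dkv_src
    dglobal <- ra$dq_src
  } else {
    dn1_tokens <- ra$dkv_src + ra$dq_src
  }
  rn1 <- layernorm_mod_bwd(m$norm1, cache$n1,
                           window_reverse(dn1_tokens, m$w, H, W))
  list(dx = dx1 + rn1$dx, dglobal = dglobal,
       gw = c(prefix_gw(rn1$gw, "norm1"), prefix_gw(ra$gw, "attn"),
              prefix_gw(rn2$gw, "norm2"), prefix_gw(rm_$gw, "mlp")))
}

#' Run one GC-ViT transformer block on a feature map
#'
#' @param x feature map (B, H, W, C), sides divisible by the block's window.
#' @param m a [gcvit_block_module()].
#' @param global_tokens (B, w^2, C) tokens, required when the block kind is
#'   `"global"`.
#' @return feature map with the shape of `x`.
#' @export
gcvit_block <- function(x, m, global_tokens = NULL) {
  block_fwd(m, x, global_tokens)$y
}
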