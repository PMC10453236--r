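# Four-stage GC-ViT encoder, patch expand and ConvMore: image (B, H, W, 3)
# -> (B, H/32, W/32, 8*base_dim) -> expand -> (B, H/16, W/16, decoder width).

#' Encoder stage module
#'
#' One hierarchical stage: a global token generator shared by the stage's
#' global blocks, `depth` transformer blocks alternating local (even
#' positions, counting from 1) and global (odd positions), and a
#' downsampler after stages 1-3. Ablation toggles substitute one attention
#' kind for the other and thin the GTG / downsampler.
#'
#' @param cfg a [gctu_config()].
#' @param stage_index stage number 1-4.
#' @param input_size input image side (defaults to `cfg$input_size`).
#' @return a stage module usable with [run_stage()].
#' @export
stage_module <- function(cfg, stage_index, input_size = cfg$input_size) {
  geo <- stage_geometry(cfg, input_size)
  side <- geo$sides[stage_index]
  C <- geo$dims[stage_index]
  w <- cfg$stage_windows[stage_index]
  depth <- cfg$stage_depths[stage_index]
  heads <- cfg$stage_heads[stage_index]
  tg <- cfg$toggles
  # alternation starts local; toggles substitute the other kind
  kinds <- rep(c("local", "global"), length.out = depth)
  if (!tg$use_global_attention) kinds[kinds == "global"] <- "local"
  if (!tg$use_local_attention) kinds[kinds == "local"] <- "global"
  m <- list(type = "stage", side = side, dim = C, w = w, kinds = kinds,
            gtg = gtg_module(C, side, w,
                             use_features = tg$use_gtg_feature_extraction,
                             se_reduction = cfg$se_reduction),
            blocks = stats::setNames(
              lapply(kinds, function(kk) {
                gcvit_block_module(C, heads, w, cfg$mlp_ratio, kind = kk)
              }),
              paste0("b", seq_len(depth))))
  if (stage_index < 4L) {
    m$down <- downsample_module(C,
                                use_fused = tg$use_fused_mbconv_downsample,
                                se_reduction = cfg$se_reduction)
  }
  m
}

stage_fwd <- function(m, x, keep = FALSE, counter = NULL) {
  needs_global <- any(m$kinds == "global")
  gt <- NULL
  cg <- NULL
  if (needs_global) {
    g <- gtg_fwd(m$gtg, x)
    gt <- g$y
    cg <- g$cache
    if (!is.null(counter)) counter$gtg <- (counter$gtg %||% 0L) + 1L
  }
  cb <- vector("list", length(m$blocks))
  for (i in seq_along(m$blocks)) {
    r <- block_fwd(m$blocks[[i]], x,
                   global_tokens = if (m$kinds[i] == "global") gt else NULL)
    x <- r$y
    cb[[i]] <- r$cache
  }
  cd <- NULL
  if (!is.null(m$down)) {
    r <- downsample_fwd(m$down, x, keep = keep)
    x <- r$y
    cd <- r$cache
  }
  list(y = x, cache = list(gtg = cg, blocks = cb, down = cd,
                           needs_global = needs_global))
}

stage_bwd <- function(m, cache, dy) {
  gw <- list()
  if (!is.null(m$down)) {
    r <- downsample_bwd(m$down, cache$down, dy)
    dy <- r$dx
    gw <- c(gw, prefix_gw(r$gw, "down"))
  }
  dgt <- NULL
  for (i in rev(seq_along(m$blocks))) {
    r <- block_bwd(m$blocks[[i]], cache$blocks[[i]], dy)
    dy <- r$dx
    if (!is.null(r$dglobal)) {
      dgt <- if (is.null(dgt)) r$dglobal else dgt + r$dglobal
    }
    gw <- c(prefix_gw(r$gw, paste0("blocks/b", i)), gw)
  }
  if (cache$needs_global && !is.null(dgt)) {
    r <- gtg_bwd(m$gtg, cache$gtg, dgt)
    dy <- dy + r$dx
    gw <- c(prefix_gw(r$gw, "gtg"), gw)
  }
  list(dx = dy, gw = gw)
}

#' Run one encoder stage
#'
#' @param x stage input feature map.
#' @param stage_index stage number 1-4.
#' @param cfg a [gctu_config()].
#' @param m optional prebuilt [stage_module()].
#' @return the stage output (downsampled except after stage 4).
#' @export
run_stage <- function(x, stage_index, cfg, m = NULL) {
  if (is.null(m)) {
    side_in <- dim(x)[2]
    m <- stage_module(cfg, stage_index,
                      input_size = side_in * cfg$patch_size *
                        2L^(stage_index - 1L))
  }
  stage_fwd(m, x)$y
}

# ---------------------------------------------------------------------------
# encoder = stem + 4 stages + final layer norm

encoder_module <- function(cfg, input_size = cfg$input_size) {
  list(type = "encoder",
       stem = stem_module(cfg$patch_size, cfg$base_dim, cfg$se_reduction),
       s1 = stage_module(cfg, 1L, input_size),
       s2 = stage_module(cfg, 2L, input_size),
       s3 = stage_module(cfg, 3L, input_size),
       s4 = stage_module(cfg, 4L, input_size),
       norm = make_layernorm(cfg$base_dim * 8L))
}

encoder_fwd <- function(m, x, keep = FALSE, counter = NULL) {
  st <- stem_fwd(m$stem, x, keep = keep)
  r1 <- stage_fwd(m$s1, st$y, keep = keep, counter = counter)
  r2 <- stage_fwd(m$s2, r1$y, keep = keep, counter = counter)
  r3 <- stage_fwd(m$s3, r2$y, keep = keep, counter = counter)
  r4 <- stage_fwd(m$s4, r3$y, keep = keep, counter = counter)
  nf <- layernorm_mod_fwd(m$norm, r4$y)
  list(y = nf$y,
       cache = list(stem = st$cache, s1 = r1$cache, s2 = r2$cache,
                    s3 = r3$cache, s4 = r4$cache, norm = nf$cache))
}

encoder_bwd <- function(m, cache, dy) {
  rn <- layernorm_mod_bwd(m$norm, cache$norm, dy)
  gw <- prefix_gw(rn$gw, "norm")
  dy <- rn$dx
  for (nm in c("s4", "s3", "s2", "s1")) {
    r <- stage_bwd(m[[nm]], cache[[nm]], dy)
    dy <- r$dx
    gw <- c(prefix_gw(r$gw, nm), gw)
  }
  rs <- stem_bwd(m$stem, cache$stem, dy)
  list(dx = rs$dx, gw = c(prefix_gw(rs$gw, "stem"), gw))
}

#' Encode an image with the hierarchical GC-ViT encoder
#'
#' @param image array (B, H, W, 3).
#' @param cfg a [gctu_config()].
#' @param m optional prebuilt encoder module.
#' @return feature map (B, H/32, W/32, 8 * base_dim).
#' @export
encode <- function(image, cfg, m = NULL) {
  if (is.null(m)) m <- encoder_module(cfg, input_size = dim(image)[2])
  encoder_fwd(m, image)$y
}

# ---------------------------------------------------------------------------
# patch expand: linear C -> 2C, then redistribute each position's channels
# into a 2x2 spatial block of C/2 channels (side x2, channels /2). The
# ablation variant replaces it with bilinear 2x upsampling + 1x1 conv C->C/2.

#' Patch expand module
#'
#' @param C input channel count (even).
#' @param use_patch_expand when `FALSE`, use the bilinear + 1x1-conv
#'   ablation variant instead of the learned rearrangement.
#' @return a patch-expand module usable with [patch_expand()].
#' @export
patch_expand_module <- function(C, use_patch_expand = TRUE) {
  if (C %% 2L != 0L) stop("patch_expand requires an even channel count",
                          call. = FALSE)
  if (use_patch_expand) {
    list(type = "patch_expand", learned = TRUE, expand = make_linear(C, 2L * C))
  } else {
    list(type = "patch_expand", learned = FALSE, proj = make_linear(C, C %/% 2L))
  }
}

# channel layout of the 2C expanded vector: (C/2 fastest, row offset, col
# offset); out[b, 2h-1+di, 2w-1+dj, c] = z[b, h, w, c + (C/2)(di + 2 dj)]
pixel_shuffle2 <- function(z) {
  d <- dim(z)
  B <- d[1]; H <- d[2]; W <- d[3]; C2 <- d[4] %/% 4L
  dim(z) <- c(B, H, W, C2, 2L, 2L)
  z <- aperm(z, c(1L, 5L, 2L, 6L, 3L, 4L))   # (b, di, h, dj, w, c)
  dim(z) <- c(B, 2L * H, 2L * W, C2)
  z
}

pixel_unshuffle2 <- function(y) {
  d <- dim(y)
  B <- d[1]; H <- d[2] %/% 2L; W <- d[3] %/% 2L; C2 <- d[4]
  dim(y) <- c(B, 2L, H, 2L, W, C2)
  y <- aperm(y, c(1L, 3L, 5L, 6L, 2L, 4L))   # (b, h, w, c, di, dj)
  dim(y) <- c(B, H, W, 4L * C2)
  y
}

patch_expand_fwd <- function(m, x) {
  if (m$learned) {
    f <- linear_mod_fwd(m$expand, x)
    list(y = pixel_shuffle2(f$y), cache = list(f = f$cache))
  } else {
    up <- bilinear_fwd(x, 2L * dim(x)[2], 2L * dim(x)[3])
    f <- linear_mod_fwd(m$proj, up$y)
    list(y = f$y, cache = list(up = up$cache, f = f$cache))
  }
}

patch_expand_bwd <- function(m, cache, dy) {
  if (m$learned) {
    r <- linear_mod_bwd(m$expand, cache$f, pixel_unshuffle2(dy))
    list(dx = r$dx, gw = prefix_gw(r$gw, "expand"))
  } else {
    r <- linear_mod_bwd(m$proj, cache$f, dy)
    list(dx = bilinear_bwd(cache$up, r$dx), gw = prefix_gw(r$gw, "proj"))
  }
}

#' Expand a feature map (double spatial side, halve channels)
#'
#' @param x feature map (B, H, W, C) with even C.
#' @param m optional prebuilt [patch_expand_module()].
#' @param use_patch_expand learned rearrangement (`TRUE`) or bilinear +
#'   1x1-conv variant (`FALSE`); used when `m` is omitted.
#' @return feature map (B, 2H, 2W, C/2).
#' @export
patch_expand <- function(x, m = NULL, use_patch_expand = TRUE) {
  if (is.null(m)) m <- patch_expand_module(dim(x)[4], use_patch_expand)
  patch_expand_fwd(m, x)$y
}

# ---------------------------------------------------------------------------
# ConvMore: 3x3 pad-1 conv to the decoder working width, + BN + ReLU

conv_more_module <- function(cin, cout) {
  list(type = "conv_more",
       conv = make_conv2d(3L, cin, cout, stride = 1L, pad = 1L),
       norm = make_batchnorm(cout))
}

conv_more_fwd <- function(m, x, train = FALSE, keep = FALSE) {
  cv <- conv2d_mod_fwd(m$conv, x, keep = keep)
  bn <- batchnorm_mod_fwd(m$norm, cv$y, train = train)
  rl <- relu_fwd(bn$y)
  list(y = rl$y, cache = list(conv = cv$cache, norm = bn$cache, rl = rl$cache))
}

conv_more_bwd <- function(m, cache, dy) {
  dbn <- relu_bwd(cache$rl, dy)
  rn <- batchnorm_mod_bwd(m$norm, cache$norm, dbn)
  rc <- conv2d_mod_bwd(m$conv, cache$conv, rn$dx)
  list(dx = rc$dx,
       gw = c(prefix_gw(rc$gw, "conv"), prefix_gw(rn$gw, "norm")))
}

#' Widen a feature map to the decoder working width (ConvMore)
#'
#' 3x3 pad-1 convolution + batch norm + ReLU; spatial size unchanged.
#'
#' @param x feature map (B, H, W, C).
#' @param out_channels target channel count.
#' @param m optional prebuilt module.
#' @return feature map (B, H, W, out_channels).
#' @export
conv_more <- function(x, out_channels, m = NULL) {
  if (is.null(m)) m <- conv_more_module(dim(x)[4], out_channels)
  conv_more_fwd(m, x)$y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
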