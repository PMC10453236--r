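# Convolutional feature-extraction branch supplying multi-scale detail
# features (H/2, H/4, H/8) to the decoder through skip connections.
# Layout: 7x7 stride-2 pad-3 stem conv + group norm + ReLU, then three
# residual bottleneck blocks (1x1 -> 3x3 -> 1x1, inner width = out/2,
# group-norm, stride-2 on the 3x3 conv of blocks 2 and 3, projection
# shortcut where shape changes).

bottleneck_module <- function(cin, cout, stride = 1L, gn_groups = 1L) {
  mid <- max(1L, cout %/% 2L)
  m <- list(type = "bottleneck", stride = as.integer(stride),
            proj_needed = (stride != 1L || cin != cout),
            c1 = make_conv2d(1L, cin, mid),
            n1 = make_groupnorm(mid, gn_groups),
            c2 = make_conv2d(3L, mid, mid, stride = stride, pad = 1L),
            n2 = make_groupnorm(mid, gn_groups),
            c3 = make_conv2d(1L, mid, cout))
  if (m$proj_needed) m$proj <- make_conv2d(1L, cin, cout, stride = stride)
  m
}

bottleneck_fwd <- function(m, x, keep = FALSE) {
  f1 <- conv2d_mod_fwd(m$c1, x, keep = keep)
  g1 <- groupnorm_mod_fwd(m$n1, f1$y)
  r1 <- relu_fwd(g1$y)
  f2 <- conv2d_mod_fwd(m$c2, r1$y, keep = keep)
  g2 <- groupnorm_mod_fwd(m$n2, f2$y)
  r2 <- relu_fwd(g2$y)
  f3 <- conv2d_mod_fwd(m$c3, r2$y, keep = keep)
  if (m$proj_needed) {
    fp <- conv2d_mod_fwd(m$proj, x, keep = keep)
    shortcut <- fp$y
    cp <- fp$cache
  } else {
    shortcut <- x
    cp <- NULL
  }
  ro <- relu_fwd(f3$y + shortcut)
  list(y = ro$y,
       cache = list(f1 = f1$cache, g1 = g1$cache, r1 = r1$cache,
                    f2 = f2$cache, g2 = g2$cache, r2 = r2$cache,
                    f3 = f3$cache, proj = cp, ro = ro$cache))
}

bottleneck_bwd <- function(m, cache, dy) {
  ds <- relu_bwd(cache$ro, dy)
  r3 <- conv2d_mod_bwd(m$c3, cache$f3, ds)
  d2 <- relu_bwd(cache$r2, r3$dx)
  rg2 <- groupnorm_mod_bwd(m$n2, cache$g2, d2)
  r2 <- conv2d_mod_bwd(m$c2, cache$f2, rg2$dx)
  d1 <- relu_bwd(cache$r1, r2$dx)
  rg1 <- groupnorm_mod_bwd(m$n1, cache$g1, d1)
  r1 <- conv2d_mod_bwd(m$c1, cache$f1, rg1$dx)
  dx <- r1$dx
  gw <- c(prefix_gw(r1$gw, "c1"), prefix_gw(rg1$gw, "n1"),
          prefix_gw(r2$gw, "c2"), prefix_gw(rg2$gw, "n2"),
          prefix_gw(r3$gw, "c3"))
  if (m$proj_needed) {
    rp <- conv2d_mod_bwd(m$proj, cache$proj, ds)
    dx <- dx + rp$dx
    gw <- c(gw, prefix_gw(rp$gw, "proj"))
  } else {
    dx <- dx + ds
  }
  list(dx = dx, gw = gw)
}

cnn_branch_module <- function(cfg) {
  ch <- cfg$cnn_channels
  g <- cfg$gn_groups
  list(type = "cnn_branch",
       stem = make_conv2d(7L, 3L, ch[1], stride = 2L, pad = 3L),
       stem_norm = make_groupnorm(ch[1], g),
       block1 = bottleneck_module(ch[1], ch[1], stride = 1L, gn_groups = g),
       block2 = bottleneck_module(ch[1], ch[2], stride = 2L, gn_groups = g),
       block3 = bottleneck_module(ch[2], ch[3], stride = 2L, gn_groups = g))
}

cnn_branch_fwd <- function(m, x, keep = FALSE) {
  cv <- conv2d_mod_fwd(m$stem, x, keep = keep)
  gn <- groupnorm_mod_fwd(m$stem_norm, cv$y)
  rl <- relu_fwd(gn$y)
  b1 <- bottleneck_fwd(m$block1, rl$y, keep = keep)
  b2 <- bottleneck_fwd(m$block2, b1$y, keep = keep)
  b3 <- bottleneck_fwd(m$block3, b2$y, keep = keep)
  list(skips = list(b1$y, b2$y, b3$y),     # fine (H/2) to coarse (H/8)
       cache = list(cv = cv$cache, gn = gn$cache, rl = rl$cache,
                    b1 = b1$cache, b2 = b2$cache, b3 = b3$cache))
}

# dskips: list of 3 gradients matching the returned skips
cnn_branch_bwd <- function(m, cache, dskips) {
  r3 <- bottleneck_bwd(m$block3, cache$b3, dskips[[3]])
  r2 <- bottleneck_bwd(m$block2, cache$b2, dskips[[2]] + r3$dx)
  r1 <- bottleneck_bwd(m$block1, cache$b1, dskips[[1]] + r2$dx)
  dg <- relu_bwd(cache$rl, r1$dx)
  rgn <- groupnorm_mod_bwd(m$stem_norm, cache$gn, dg)
  rc <- conv2d_mod_bwd(m$stem, cache$cv, rgn$dx)
  list(dx = rc$dx,
       gw = c(prefix_gw(rc$gw, "stem"), prefix_gw(rgn$gw, "stem_norm"),
              prefix_gw(r1$gw, "block1"), prefix_gw(r2$gw, "block2"),
              prefix_gw(r3$gw, "block3")))
}

#' Extract multi-scale CNN skip features from an image
#'
#' @param image array (B, H, W, 3), side divisible by 8.
#' @param cfg a [gctu_config()].
#' @param m optional prebuilt branch module.
#' @return list of 3 feature maps at sides H/2, H/4, H/8 (fine to coarse)
#'   with channel widths `cfg$cnn_channels`.
#' @export
extract_skip_features <- function(image, cfg, m = NULL) {
  d <- dim(image)
  if (d[2] %% 8L != 0L || d[3] %% 8L != 0L) {
    stop("extract_skip_features: image side must be divisible by 8",
         call. = FALSE)
  }
  if (is.null(m)) m <- cnn_branch_module(cfg)
  cnn_branch_fwd(m, image)$skips
}
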