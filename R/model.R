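# U-Net decoder and full GC-TransUnet assembly, with the user-facing S3
# model class (`gc_transunet`), prediction, and checkpointing.

# one decoder step: bilinear x2 upsample -> [concat skip] -> 3x3 conv +
# batch norm + ReLU
decoder_step_module <- function(cin, skip_ch, cout) {
  list(type = "decoder_step", skip_ch = as.integer(skip_ch),
       conv = make_conv2d(3L, cin + skip_ch, cout, stride = 1L, pad = 1L),
       norm = make_batchnorm(cout))
}

decoder_step_fwd <- function(m, x, skip = NULL, train = FALSE, keep = FALSE) {
  up <- bilinear_fwd(x, 2L * dim(x)[2], 2L * dim(x)[3])
  z <- up$y
  if (m$skip_ch > 0L) {
    if (is.null(skip) || !all(dim(skip)[2:3] == dim(z)[2:3])) {
      stop("decoder: skip feature size does not match upsampled map",
           call. = FALSE)
    }
    d <- dim(z)
    zc <- array(0, c(d[1], d[2], d[3], d[4] + m$skip_ch))
    zc[, , , seq_len(d[4])] <- z
    zc[, , , d[4] + seq_len(m$skip_ch)] <- skip
    z <- zc
  }
  cv <- conv2d_mod_fwd(m$conv, z, keep = keep)
  bn <- batchnorm_mod_fwd(m$norm, cv$y, train = train)
  rl <- relu_fwd(bn$y)
  list(y = rl$y,
       cache = list(up = up$cache, cv = cv$cache, bn = bn$cache,
                    rl = rl$cache, cin = dim(x)[4]))
}

decoder_step_bwd <- function(m, cache, dy) {
  dbn <- relu_bwd(cache$rl, dy)
  rn <- batchnorm_mod_bwd(m$norm, cache$bn, dbn)
  rc <- conv2d_mod_bwd(m$conv, cache$cv, rn$dx)
  dz <- rc$dx
  cin <- cache$cin
  dskip <- NULL
  if (m$skip_ch > 0L) {
    dskip <- dz[, , , cin + seq_len(m$skip_ch), drop = FALSE]
    dz <- dz[, , , seq_len(cin), drop = FALSE]
  }
  dx <- bilinear_bwd(cache$up, dz)
  list(dx = dx, dskip = dskip,
       gw = c(prefix_gw(rc$gw, "conv"), prefix_gw(rn$gw, "norm")))
}

decoder_module <- function(cfg) {
  base <- cfg$decoder_base_channels
  sk <- rev(cfg$cnn_channels)              # coarse (H/8) to fine (H/2)
  widths <- c(base %/% 2L, base %/% 4L, base %/% 8L, base %/% 8L)
  list(type = "decoder",
       step1 = decoder_step_module(base, sk[1], widths[1]),
       step2 = decoder_step_module(widths[1], sk[2], widths[2]),
       step3 = decoder_step_module(widths[2], sk[3], widths[3]),
       step4 = decoder_step_module(widths[3], 0L, widths[4]),
       head = make_linear(widths[4], cfg$num_classes))
}

decoder_fwd <- function(m, x, skips, train = FALSE, keep = FALSE) {
  # skips arrive fine-to-coarse; consume coarse-to-fine
  r1 <- decoder_step_fwd(m$step1, x, skips[[3]], train = train, keep = keep)
  r2 <- decoder_step_fwd(m$step2, r1$y, skips[[2]], train = train, keep = keep)
  r3 <- decoder_step_fwd(m$step3, r2$y, skips[[1]], train = train, keep = keep)
  r4 <- decoder_step_fwd(m$step4, r3$y, NULL, train = train, keep = keep)
  hd <- linear_mod_fwd(m$head, r4$y)
  list(y = hd$y,
       cache = list(r1 = r1$cache, r2 = r2$cache, r3 = r3$cache,
                    r4 = r4$cache, hd = hd$cache))
}

decoder_bwd <- function(m, cache, dy) {
  rh <- linear_mod_bwd(m$head, cache$hd, dy)
  b4 <- decoder_step_bwd(m$step4, cache$r4, rh$dx)
  b3 <- decoder_step_bwd(m$step3, cache$r3, b4$dx)
  b2 <- decoder_step_bwd(m$step2, cache$r2, b3$dx)
  b1 <- decoder_step_bwd(m$step1, cache$r1, b2$dx)
  list(dx = b1$dx,
       dskips = list(b3$dskip, b2$dskip, b1$dskip),  # fine to coarse
       gw = c(prefix_gw(b1$gw, "step1"), prefix_gw(b2$gw, "step2"),
              prefix_gw(b3$gw, "step3"), prefix_gw(b4$gw, "step4"),
              prefix_gw(rh$gw, "head")))
}

#' Decode a bottleneck feature map to full-resolution logits
#'
#' Four decoder steps, each a bilinear 2x upsample, concatenation of the
#' matching CNN skip feature (steps 1-3), and a 3x3 conv + batch norm +
#' ReLU halving the working width; a final 1x1 projection produces the
#' class logits.
#'
#' @param bottleneck feature map (B, H/16, W/16, decoder_base_channels).
#' @param skips list of 3 CNN features at sides H/8, H/4, H/2 passed
#'   fine-to-coarse as returned by [extract_skip_features()].
#' @param cfg a [gctu_config()].
#' @param m optional prebuilt decoder module.
#' @return logits array (B, H, W, num_classes).
#' @export
decode <- function(bottleneck, skips, cfg, m = NULL) {
  if (is.null(m)) m <- decoder_module(cfg)
  decoder_fwd(m, bottleneck, skips)$y
}

# ---------------------------------------------------------------------------
# full model

#' Build a GC-TransUnet model
#'
#' Assembles the complete network: hierarchical GC-ViT encoder, patch
#' expand, ConvMore, CNN skip branch, and U-Net decoder. Weights are
#' initialised from the current RNG stream (call `set.seed()` first for
#' reproducibility).
#'
#' @param config a [gctu_config()] or a variant name accepted by
#'   [get_config()].
#' @param input_size build-time input side; defaults to the configuration's
#'   native size.
#' @param seed optional integer seed applied before weight initialisation.
#' @return an object of class `gc_transunet`.
#' @examples
#' net <- gc_transunet("toy", seed = 1)
#' img <- array(stats::runif(1 * 64 * 64 * 3), c(1, 64, 64, 3))
#' logits <- predict(net, img, type = "logits")
#' dim(logits)   # 1 64 64 1
#' @export
gc_transunet <- function(config = "gcvit-t", input_size = NULL, seed = NULL) {
  cfg <- if (inherits(config, "gctu_config")) config else get_config(config)
  if (!is.null(input_size)) cfg$input_size <- as.integer(input_size)
  rep_ok <- validate_config(cfg)
  if (!rep_ok$ok) {
    stop("invalid configuration: ", paste(rep_ok$violations, collapse = "; "),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  model <- list(type = "gc_transunet", cfg = cfg,
                encoder = encoder_module(cfg),
                expand = patch_expand_module(
                  cfg$base_dim * 8L, cfg$toggles$use_patch_expand),
                conv_more = conv_more_module(
                  cfg$base_dim * 4L, cfg$decoder_base_channels),
                cnn = cnn_branch_module(cfg),
                decoder = decoder_module(cfg))
  class(model) <- c("gc_transunet", "list")
  model
}

model_fwd <- function(model, image, train = FALSE, counter = NULL) {
  keep <- train
  en <- encoder_fwd(model$encoder, image, keep = keep, counter = counter)
  ex <- patch_expand_fwd(model$expand, en$y)
  cm <- conv_more_fwd(model$conv_more, ex$y, train = train, keep = keep)
  cn <- cnn_branch_fwd(model$cnn, image, keep = keep)
  de <- decoder_fwd(model$decoder, cm$y, cn$skips, train = train, keep = keep)
  list(y = de$y,
       cache = list(en = en$cache, ex = ex$cache, cm = cm$cache,
                    cn = cn$cache, de = de$cache))
}

model_bwd <- function(model, cache, dy) {
  rd <- decoder_bwd(model$decoder, cache$de, dy)
  rc <- cnn_branch_bwd(model$cnn, cache$cn, rd$dskips)
  rcm <- conv_more_bwd(model$conv_more, cache$cm, rd$dx)
  rex <- patch_expand_bwd(model$expand, cache$ex, rcm$dx)
  ren <- encoder_bwd(model$encoder, cache$en, rex$dx)
  gw <- c(prefix_gw(ren$gw, "encoder"), prefix_gw(rex$gw, "expand"),
          prefix_gw(rcm$gw, "conv_more"), prefix_gw(rc$gw, "cnn"),
          prefix_gw(rd$gw, "decoder"))
  list(dx = ren$dx + rc$dx, gw = gw)
}

#' Full forward pass of GC-TransUnet
#'
#' `decode(conv_more(patch_expand(encode(image))), extract_skip_features(image))`;
#' deterministic given the model weights.
#'
#' @param image array (B, H, W, 3) or (H, W, 3).
#' @param model a [gc_transunet()] model.
#' @return logits array (B, H, W, num_classes).
#' @export
gc_transunet_forward <- function(image, model) {
  if (length(dim(image)) == 3L) dim(image) <- c(1L, dim(image))
  model_fwd(model, image, train = FALSE)$y
}

#' Predict segmentation masks
#'
#' @param object a [gc_transunet()] model.
#' @param newdata image array (B, H, W, 3) or a single (H, W, 3) image, or
#'   a list of samples as produced by [generate_dataset()].
#' @param type `"prob"` (sigmoid probabilities), `"mask"` (probabilities
#'   thresholded at 0.5), or `"logits"`.
#' @param ... unused.
#' @return array (B, H, W, num_classes), or (H, W, num_classes) for a
#'   single image input.
#' @export
predict.gc_transunet <- function(object, newdata, type = c("prob", "mask", "logits"),
                                 ...) {
  type <- match.arg(type)
  single <- FALSE
  if (is.list(newdata) && !is.null(newdata[[1]]$image)) {
    newdata <- stack_images(newdata)
  } else if (length(dim(newdata)) == 3L) {
    dim(newdata) <- c(1L, dim(newdata))
    single <- TRUE
  }
  logits <- model_fwd(object, newdata, train = FALSE)$y
  out <- switch(type,
                logits = logits,
                prob = sigmoid_fwd(logits)$y,
                mask = (sigmoid_fwd(logits)$y >= 0.5) * 1)
  if (single) dim(out) <- dim(out)[-1L]
  out
}

stack_images <- function(samples) {
  d <- dim(samples[[1]]$image)
  x <- array(0, c(length(samples), d))
  for (i in seq_along(samples)) x[i, , , ] <- samples[[i]]$image
  x
}

stack_masks <- function(samples) {
  d <- dim(samples[[1]]$mask)
  y <- array(0, c(length(samples), d, 1L))
  for (i in seq_along(samples)) y[i, , , 1L] <- samples[[i]]$mask
  y
}

#' @export
print.gc_transunet <- function(x, ...) {
  cat(sprintf("GC-TransUnet (%s @ %d px): %s trainable parameters\n",
              x$cfg$variant_name, x$cfg$input_size,
              format(nn_num_params(x), big.mark = ",")))
  invisible(x)
}

#' @export
summary.gc_transunet <- function(object, ...) {
  rep_ <- count_complexity(object)
  cat(sprintf("GC-TransUnet '%s' at %d x %d input\n",
              object$cfg$variant_name, object$cfg$input_size,
              object$cfg$input_size))
  cat(sprintf("  parameters : %s (%.2f M)\n",
              format(rep_$total_params, big.mark = ","),
              rep_$params_millions))
  cat(sprintf("  forward    : %.2f GFLOPs (multiply-accumulate)\n",
              rep_$flops_giga))
  cat("  per-module breakdown (params / GFLOPs):\n")
  for (nm in names(rep_$breakdown)) {
    b <- rep_$breakdown[[nm]]
    cat(sprintf("    %-10s %12s  %8.3f\n", nm,
                format(b$params, big.mark = ","), b$flops / 1e9))
  }
  invisible(rep_)
}

# ---------------------------------------------------------------------------
# checkpointing: weights + config + seed in one RDS archive

#' Save / load a model checkpoint
#'
#' The checkpoint is a single RDS archive holding the configuration, every
#' trainable array (keyed by its path in the module tree), the batch-norm
#' running statistics, and the seed recorded at save time.
#'
#' @param model a [gc_transunet()] model.
#' @param path file path for the archive.
#' @param seed optional integer stored alongside the weights.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the restored model.
#' @export
save_checkpoint <- function(model, path, seed = NULL) {
  bn <- collect_bn_stats(model)
  saveRDS(list(format = "gctransunet-checkpoint-1",
               config = unclass(model$cfg),
               params = nn_collect(model),
               bn_stats = bn,
               seed = seed),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!identical(ck$format, "gctransunet-checkpoint-1")) {
    stop("not a gctransunet checkpoint: ", path, call. = FALSE)
  }
  cfg <- do.call(gctu_config, ck$config)
  model <- gc_transunet(cfg)
  model <- nn_restore(model, ck$params)
  restore_bn_stats(model, ck$bn_stats)
  class(model) <- c("gc_transunet", "list")
  model
}

# batch-norm running stats live in environments; walk the tree
walk_bn <- function(m, path, f) {
  if (!is.list(m)) return(invisible())
  if (identical(m$type, "batchnorm")) f(m, path)
  for (nm in names(m)) {
    if (nm %in% c("w", "stats", "cfg")) next
    if (is.list(m[[nm]])) walk_bn(m[[nm]], c(path, nm), f)
  }
  invisible()
}

collect_bn_stats <- function(model) {
  out <- list()
  walk_bn(model, character(), function(m, path) {
    key <- paste(path, collapse = "/")
    out[[key]] <<- list(mean = m$stats$mean, var = m$stats$var)
  })
  out
}

restore_bn_stats <- function(model, bn) {
  walk_bn(model, character(), function(m, path) {
    key <- paste(path, collapse = "/")
    if (!is.null(bn[[key]])) {
      m$stats$mean <- bn[[key]]$mean
      m$stats$var <- bn[[key]]$var
    }
  })
  invisible(model)
}
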