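# Model complexity accounting: exact parameter enumeration plus closed-form
# per-layer multiply-accumulate (MAC) counts for one forward pass.
# Convention: FLOPs = MACs; convolutions cost k^2*Cin*Cout*Hout*Wout,
# linear layers in*out per position, attention counts its two matrix
# products (QK' and PV); normalisations, activations, pooling and bilinear
# interpolation are not counted, matching the common profiling tools.

fl_conv2d <- function(m, side_in) {
  d <- dim(m$w$W)
  so <- conv_out_side(side_in, d[1], m$stride, m$pad)
  d[1] * d[2] * d[3] * d[4] * so * so
}

fl_linear <- function(m, n_pos) n_pos * prod(dim(m$w$W))

fl_se <- function(m) fl_linear(m$fc1, 1L) + fl_linear(m$fc2, 1L)

fl_fused <- function(m, side) {
  C <- length(m$dw$w$b)
  9 * C * side^2 + fl_se(m$se) + fl_linear(m$proj, side^2)
}

fl_downsample <- function(m, side) {
  f <- fl_conv2d(m$conv, side)
  if (m$use_fused) f <- f + fl_fused(m$fused, side)
  f
}

fl_gtg <- function(m, side) {
  f <- 0
  for (i in seq_len(m$steps)) {
    if (m$use_features) f <- f + fl_fused(m$blocks[[i]], side)
    side <- side %/% 2L
  }
  f
}

fl_block <- function(m, side) {
  C <- length(m$norm1$w$gamma)
  w <- m$w
  nq <- if (m$kind == "global") w^2 else side^2
  f <- fl_linear(m$attn$q, nq) + fl_linear(m$attn$k, side^2) +
    fl_linear(m$attn$v, side^2) + fl_linear(m$attn$o, side^2)
  f <- f + 2 * side^2 * w^2 * C                  # QK' and PV matmuls
  f + fl_linear(m$mlp$fc1, side^2) + fl_linear(m$mlp$fc2, side^2)
}

fl_stage <- function(m, side) {
  f <- if (any(m$kinds == "global")) fl_gtg(m$gtg, side) else 0
  for (b in m$blocks) f <- f + fl_block(b, side)
  if (!is.null(m$down)) f <- f + fl_downsample(m$down, side)
  f
}

fl_bottleneck <- function(m, side_in) {
  so <- side_in %/% m$stride
  f <- fl_conv2d(m$c1, side_in) + fl_conv2d(m$c2, side_in) +
    fl_conv2d(m$c3, so)
  if (m$proj_needed) f <- f + fl_conv2d(m$proj, side_in)
  f
}

params_of <- function(m) sum(vapply(nn_collect(m), length, numeric(1)))

#' Parameter and FLOP accounting for a model
#'
#' Parameters are enumerated exactly from the weight arrays; FLOPs are
#' accumulated from per-layer closed forms under the multiply-accumulate
#' convention at the stated input size (batch 1).
#'
#' @param model a [gc_transunet()] model.
#' @param input_size square input side; defaults to the model's
#'   configuration.
#' @return a `gctu_complexity` list: `total_params`, `params_millions`,
#'   `flops`, `flops_giga`, `input_size`, and a per-module `breakdown`
#'   (each entry `list(params, flops)`).
#' @export
count_complexity <- function(model, input_size = NULL) {
  cfg <- model$cfg
  if (is.null(input_size)) input_size <- cfg$input_size
  geo <- stage_geometry(cfg, input_size)
  s <- geo$sides

  enc_f <- fl_conv2d(model$encoder$stem$embed, input_size) +
    fl_fused(model$encoder$stem$fused, s[1])
  for (i in 1:4) {
    enc_f <- enc_f + fl_stage(model$encoder[[paste0("s", i)]], s[i])
  }
  ex_f <- if (model$expand$learned) {
    fl_linear(model$expand$expand, s[4]^2)
  } else {
    fl_linear(model$expand$proj, (2L * s[4])^2)
  }
  cm_f <- fl_conv2d(model$conv_more$conv, s[3])
  cnn_f <- fl_conv2d(model$cnn$stem, input_size) +
    fl_bottleneck(model$cnn$block1, input_size %/% 2L) +
    fl_bottleneck(model$cnn$block2, input_size %/% 2L) +
    fl_bottleneck(model$cnn$block3, input_size %/% 4L)
  dec_sides <- input_size %/% c(8L, 4L, 2L, 1L)
  dec_f <- 0
  for (i in 1:4) {
    dec_f <- dec_f + fl_conv2d(model$decoder[[paste0("step", i)]]$conv,
                               dec_sides[i])
  }
  dec_f <- dec_f + fl_linear(model$decoder$head, input_size^2)

  breakdown <- list(
    encoder = list(params = params_of(model$encoder), flops = enc_f),
    patch_expand = list(params = params_of(model$expand), flops = ex_f),
    conv_more = list(params = params_of(model$conv_more), flops = cm_f),
    cnn_branch = list(params = params_of(model$cnn), flops = cnn_f),
    decoder = list(params = params_of(model$decoder), flops = dec_f))
  total_p <- sum(vapply(breakdown, function(b) b$params, numeric(1)))
  total_f <- sum(vapply(breakdown, function(b) b$flops, numeric(1)))
  out <- list(total_params = total_p,
              params_millions = total_p / 1e6,
              flops = total_f,
              flops_giga = total_f / 1e9,
              input_size = as.integer(input_size),
              convention = "multiply-accumulate",
              breakdown = breakdown)
  class(out) <- "gctu_complexity"
  out
}

#' @export
print.gctu_complexity <- function(x, ...) {
  cat(sprintf("%.2f M parameters, %.2f GFLOPs (MAC) at %d px input\n",
              x$params_millions, x$flops_giga, x$input_size))
  invisible(x)
}
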