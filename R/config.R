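# Network configuration registry: named GC-TransUnet variants, validation,
# ablation toggles, and YAML round-tripping.

.variant_registry <- new.env(parent = emptyenv())

default_toggles <- function() {
  list(use_local_attention = TRUE,
       use_global_attention = TRUE,
       use_gtg_feature_extraction = TRUE,
       use_fused_mbconv_downsample = TRUE,
       use_patch_expand = TRUE)
}

#' Construct a GC-TransUnet model configuration
#'
#' A `gctu_config` captures every hyperparameter of one network variant:
#' the transformer encoder geometry (embedding width, per-stage block
#' depths, head counts and window sides, MLP expansion ratio, patch size),
#' the CNN skip branch and decoder widths, and the ablation toggles that
#' switch individual architectural components on or off.
#'
#' @param variant_name label for the configuration.
#' @param base_dim stage-1 embedding width; stage `i` works at
#'   `base_dim * 2^(i-1)` channels.
#' @param stage_depths integer vector of 4 transformer block counts.
#' @param stage_heads integer vector of 4 attention head counts.
#' @param stage_windows integer vector of 4 window side lengths (in patches).
#' @param mlp_ratio hidden-width multiplier of the transformer MLP.
#' @param patch_size stem reduction factor in pixels (stride of the patch
#'   embedding convolution).
#' @param decoder_base_channels decoder working width after ConvMore.
#' @param cnn_channels integer vector of 3 channel widths for the CNN skip
#'   branch features at scales H/2, H/4, H/8.
#' @param num_classes number of output mask channels (1 = sigmoid/binary).
#' @param input_size native square input side in pixels.
#' @param se_reduction squeeze-excitation bottleneck reduction ratio.
#' @param gn_groups group count for group normalisation in the CNN branch.
#' @param toggles named list of ablation switches, see [default_toggles()]
#'   via `gctu_config()$toggles` for the full set.
#' @return an object of class `gctu_config`.
#' @seealso [get_config()], [validate_config()]
#' @export
gctu_config <- function(variant_name = "custom",
                        base_dim = 64L,
                        stage_depths = c(3L, 4L, 19L, 5L),
                        stage_heads = c(2L, 4L, 8L, 16L),
                        stage_windows = c(7L, 7L, 14L, 7L),
                        mlp_ratio = 3,
                        patch_size = 4L,
                        decoder_base_channels = 512L,
                        cnn_channels = c(64L, 128L, 256L),
                        num_classes = 1L,
                        input_size = 224L,
                        se_reduction = 4L,
                        gn_groups = 1L,
                        toggles = default_toggles()) {
  tg <- default_toggles()
  tg[names(toggles)] <- toggles
  cfg <- list(variant_name = variant_name,
              base_dim = as.integer(base_dim),
              stage_depths = as.integer(stage_depths),
              stage_heads = as.integer(stage_heads),
              stage_windows = as.integer(stage_windows),
              mlp_ratio = mlp_ratio,
              patch_size = as.integer(patch_size),
              decoder_base_channels = as.integer(decoder_base_channels),
              cnn_channels = as.integer(cnn_channels),
              num_classes = as.integer(num_classes),
              input_size = as.integer(input_size),
              se_reduction = as.integer(se_reduction),
              gn_groups = as.integer(gn_groups),
              toggles = tg)
  class(cfg) <- "gctu_config"
  cfg
}

builtin_variants <- function() {
  list(
    # tiny: native 224 input
    "gcvit-t" = gctu_config(variant_name = "gcvit-t"),
    # base: wider, larger windows; native 384 input (window sides [12,12,24,12]
    # require 384/4/2^i to be divisible by them)
    "gcvit-b" = gctu_config(variant_name = "gcvit-b",
                            base_dim = 128L,
                            stage_heads = c(4L, 8L, 16L, 32L),
                            stage_windows = c(12L, 12L, 24L, 12L),
                            mlp_ratio = 2,
                            input_size = 384L),
    # desk-scale configuration for tests and smoke training at 64-pixel inputs
    "toy" = gctu_config(variant_name = "toy",
                        base_dim = 8L,
                        stage_depths = c(2L, 2L, 2L, 2L),
                        stage_heads = c(1L, 2L, 4L, 8L),
                        stage_windows = c(4L, 4L, 2L, 2L),
                        mlp_ratio = 2,
                        decoder_base_channels = 64L,
                        cnn_channels = c(8L, 16L, 32L),
                        input_size = 64L)
  )
}

#' Look up a named network configuration
#'
#' Serves the built-in variants (`"gcvit-t"`, `"gcvit-b"`, plus a desk-scale
#' `"toy"`) and any configuration registered with [register_variant()].
#' Lookup is case-insensitive. All ablation toggles default to `TRUE`
#' (the full architecture).
#'
#' @param variant_name variant label.
#' @return a validated [gctu_config()] object.
#' @export
get_config <- function(variant_name) {
  key <- tolower(variant_name)
  reg <- as.list(.variant_registry)
  all <- c(builtin_variants(), reg)
  if (!key %in% names(all)) {
    stop(sprintf("unknown variant '%s'; available: %s", variant_name,
                 paste(sort(unique(names(all))), collapse = ", ")),
         call. = FALSE)
  }
  cfg <- all[[key]]
  rep_ok <- validate_config(cfg)
  if (!rep_ok$ok) {
    stop("registered configuration is invalid: ",
         paste(rep_ok$violations, collapse = "; "), call. = FALSE)
  }
  cfg
}

#' Register a user-defined variant
#'
#' @param name variant label (stored lower-case).
#' @param cfg a [gctu_config()].
#' @return `name`, invisibly.
#' @export
register_variant <- function(name, cfg) {
  stopifnot(inherits(cfg, "gctu_config"))
  assign(tolower(name), cfg, envir = .variant_registry)
  invisible(name)
}

#' Validate a model configuration
#'
#' Checks every structural invariant the architecture relies on and returns
#' a report listing *all* violations rather than stopping at the first:
#' stage vectors have length 4; the input side is divisible by the stem
#' patch size; each stage's feature side is a positive multiple of its
#' window side; the per-stage channel width is divisible by the head count;
#' the global token generator geometry (feature side / window side a power
#' of two) holds; `mlp_ratio > 0` and `patch_size >= 1`.
#'
#' @param cfg a [gctu_config()].
#' @return `list(ok = logical, violations = character vector)`.
#' @export
validate_config <- function(cfg) {
  v <- character()
  add <- function(msg) v <<- c(v, msg)
  if (length(cfg$stage_depths) != 4L) add("stage_depths must have length 4")
  if (length(cfg$stage_heads) != 4L) add("stage_heads must have length 4")
  if (length(cfg$stage_windows) != 4L) add("stage_windows must have length 4")
  if (cfg$mlp_ratio <= 0) add("mlp_ratio must be > 0")
  if (cfg$patch_size < 1L) add("patch_size must be >= 1")
  if (cfg$num_classes < 1L) add("num_classes must be >= 1")
  if (length(cfg$cnn_channels) != 3L) add("cnn_channels must have length 3")
  if (cfg$input_size %% cfg$patch_size != 0L) {
    add(sprintf("input_size %d not divisible by patch_size %d (stem)",
                cfg$input_size, cfg$patch_size))
  } else if (length(cfg$stage_windows) == 4L && length(cfg$stage_heads) == 4L) {
    side0 <- cfg$input_size %/% cfg$patch_size
    for (i in 1:4) {
      side <- side0 %/% (2L^(i - 1L))
      w <- cfg$stage_windows[i]
      dim_i <- cfg$base_dim * 2L^(i - 1L)
      if (side0 %% (2L^(i - 1L)) != 0L || side < 1L) {
        add(sprintf("stage %d feature side is not a positive integer", i))
        next
      }
      if (side %% w != 0L) {
        add(sprintf("stage %d side %d not divisible by window %d", i, side, w))
      } else {
        r <- side %/% w
        if (bitwAnd(r, r - 1L) != 0L) {
          add(sprintf(
            "stage %d side/window ratio %d is not a power of two (GTG)", i, r))
        }
      }
      if (dim_i %% cfg$stage_heads[i] != 0L) {
        add(sprintf("stage %d dim %d not divisible by %d heads",
                    i, dim_i, cfg$stage_heads[i]))
      }
    }
  }
  list(ok = length(v) == 0L, violations = v)
}

#' @export
print.gctu_config <- function(x, ...) {
  cat(sprintf("GC-TransUnet configuration '%s'\n", x$variant_name))
  cat(sprintf("  input %dx%d, patch size %d, base dim %d, mlp ratio %s\n",
              x$input_size, x$input_size, x$patch_size, x$base_dim,
              format(x$mlp_ratio)))
  cat(sprintf("  depths [%s]  heads [%s]  windows [%s]\n",
              paste(x$stage_depths, collapse = ","),
              paste(x$stage_heads, collapse = ","),
              paste(x$stage_windows, collapse = ",")))
  cat(sprintf("  decoder base %d, cnn skips [%s], classes %d\n",
              x$decoder_base_channels,
              paste(x$cnn_channels, collapse = ","), x$num_classes))
  off <- names(Filter(isFALSE, x$toggles))
  if (length(off)) cat("  toggles off:", paste(off, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a configuration as YAML
#'
#' @param cfg a [gctu_config()].
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   the reconstructed [gctu_config()].
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(gctu_config, raw)
}

#' Apply `key=value` overrides to a configuration
#'
#' Used by the command-line interface (`--set depths=2,2,2,2`). Values are
#' parsed as numeric vectors when possible, logical for "true"/"false";
#' keys with a `toggles.` prefix address ablation switches.
#'
#' @param cfg a [gctu_config()].
#' @param overrides character vector of `key=value` strings.
#' @return the modified configuration.
#' @export
apply_overrides <- function(cfg, overrides) {
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("override must be key=value: ", ov)
    key <- kv[1]; val <- kv[2]
    parsed <- if (tolower(val) %in% c("true", "false")) {
      as.logical(toupper(val))
    } else {
      num <- suppressWarnings(as.numeric(strsplit(val, ",", fixed = TRUE)[[1]]))
      if (anyNA(num)) val else num
    }
    if (startsWith(key, "toggles.")) {
      tk <- sub("^toggles\\.", "", key)
      if (!tk %in% names(cfg$toggles)) stop("unknown toggle: ", tk)
      cfg$toggles[[tk]] <- isTRUE(parsed)
    } else {
      if (!key %in% names(cfg)) stop("unknown config key: ", key)
      if (is.integer(cfg[[key]])) parsed <- as.integer(parsed)
      cfg[[key]] <- parsed
    }
  }
  cfg
}

# per-stage derived geometry used throughout the encoder
stage_geometry <- function(cfg, input_size = cfg$input_size) {
  side0 <- input_size %/% cfg$patch_size
  list(sides = side0 %/% 2L^(0:3),
       dims = cfg$base_dim * 2L^(0:3))
}
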