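# Synthetic lesion/polyp-like fixtures: single smooth blob-shaped foreground
# regions (perturbed ellipses with low-order Fourier radial modulation) over
# textured backgrounds, with binary masks. Deterministic given a seed, so
# every pipeline stage is testable without external image downloads.

# smooth low-frequency texture field in [-1, 1]
texture_field <- function(size, n_waves = 3L) {
  xs <- matrix(rep(seq_len(size), size), size, size)
  ys <- t(xs)
  f <- matrix(0, size, size)
  for (k in seq_len(n_waves)) {
    fr <- stats::runif(1, 1, 3) * 2 * pi / size
    th <- stats::runif(1, 0, 2 * pi)
    ph <- stats::runif(1, 0, 2 * pi)
    f <- f + sin(fr * (cos(th) * xs + sin(th) * ys) + ph) / k
  }
  f / max(abs(f))
}

# blob mask: ellipse with radius modulated by a truncated Fourier series
blob_mask <- function(size, area_frac, n_harmonics = 4L) {
  cx <- stats::runif(1, 0.35, 0.65) * size
  cy <- stats::runif(1, 0.35, 0.65) * size
  ecc <- stats::runif(1, 0.7, 1.4)          # axis ratio
  rot <- stats::runif(1, 0, pi)
  ck <- stats::rnorm(n_harmonics, 0, 0.08 / seq_len(n_harmonics))
  ph <- stats::runif(n_harmonics, 0, 2 * pi)
  xs <- matrix(rep(seq_len(size), size), size, size) - cx
  ys <- t(matrix(rep(seq_len(size), size), size, size)) - cy
  xr <- cos(rot) * xs + sin(rot) * ys
  yr <- (-sin(rot) * xs + cos(rot) * ys) * ecc
  rr <- sqrt(xr^2 + yr^2)
  th <- atan2(yr, xr)
  mod <- 1 + Reduce(`+`, lapply(seq_len(n_harmonics), function(k) {
    ck[k] * cos(k * th + ph[k])
  }))
  r0 <- size * sqrt(area_frac * sqrt(ecc) / pi)
  # rescale the base radius until the rasterised area hits the target
  for (it in 1:8) {
    mask <- (rr <= r0 * mod) * 1L
    frac <- mean(mask)
    if (frac > 0 && abs(frac / area_frac - 1) < 0.02) break
    r0 <- r0 * sqrt(area_frac / max(frac, 1e-4))
  }
  list(mask = mask, center = c(cx, cy), area_frac = mean(mask))
}

#' Generate a synthetic segmentation dataset
#'
#' Each sample is an RGB image in `[0, 1]` containing one smooth random
#' blob (a perturbed ellipse) whose colour differs from the textured
#' background by at least `margin` in mean intensity, plus pixel noise,
#' together with the exact binary mask. Bitwise deterministic given
#' `seed`.
#'
#' @param n number of samples.
#' @param size square image side in pixels (divisible by 32, the model's
#'   overall reduction factor).
#' @param area_range admissible range for the foreground area fraction.
#' @param texture_strength amplitude of the low-frequency background and
#'   foreground texture.
#' @param noise_sd standard deviation of the per-pixel Gaussian noise.
#' @param margin minimum mean-intensity separation between foreground and
#'   background colours.
#' @param seed integer seed.
#' @return list of samples, each `list(image, mask, meta)`.
#' @export
generate_dataset <- function(n, size = 64L, area_range = c(0.05, 0.20),
                             texture_strength = 0.1, noise_sd = 0.02,
                             margin = 0.25, seed = 1L) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  size <- as.integer(size)
  if (size < 32L || size %% 32L != 0L) {
    stop("size must be a positive multiple of 32", call. = FALSE)
  }
  set.seed(seed)
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    target <- stats::runif(1, area_range[1], area_range[2])
    bl <- blob_mask(size, target)
    tries <- 0L
    while ((bl$area_frac < area_range[1] || bl$area_frac > area_range[2] ||
            bl$area_frac == 0) && tries < 20L) {
      bl <- blob_mask(size, target)
      tries <- tries + 1L
    }
    mask <- bl$mask
    bg_col <- stats::runif(3, 0.25, 0.75)
    # push the foreground colour away from the background by >= margin
    dir <- if (mean(bg_col) > 0.5) -1 else 1
    fg_col <- pmin(pmax(bg_col + dir * stats::runif(3, margin, margin + 0.25),
                        0.02), 0.98)
    img <- array(0, c(size, size, 3L))
    tex_bg <- texture_field(size)
    tex_fg <- texture_field(size)
    for (ch in 1:3) {
      base <- bg_col[ch] + texture_strength * tex_bg
      fg <- fg_col[ch] + texture_strength * tex_fg
      img[, , ch] <- base * (1 - mask) + fg * mask
    }
    img <- img + array(stats::rnorm(size * size * 3L, 0, noise_sd),
                       c(size, size, 3L))
    img <- pmin(pmax(img, 0), 1)
    samples[[i]] <- list(image = img, mask = mask,
                         meta = list(seed = seed, index = i,
                                     area_frac = bl$area_frac,
                                     center = bl$center))
  }
  samples
}

#' Split samples into train / validation / test subsets
#'
#' A seeded shuffle followed by a disjoint, exhaustive split. With
#' fractional `ratios`, validation and test sizes are floored and the
#' remainder goes to training.
#'
#' @param samples list of samples.
#' @param ratios numeric vector of 3 fractions summing to 1
#'   (train, val, test).
#' @param counts integer vector of 3 subset sizes summing to
#'   `length(samples)`; overrides `ratios`.
#' @param seed shuffle seed.
#' @return `list(train =, val =, test =)`.
#' @export
split_dataset <- function(samples, ratios = c(0.6, 0.2, 0.2), counts = NULL,
                          seed = 1L) {
  n <- length(samples)
  if (!is.null(counts)) {
    if (length(counts) != 3L || sum(counts) != n) {
      stop("counts must be 3 sizes summing to length(samples)", call. = FALSE)
    }
    sizes <- as.integer(counts)
  } else {
    if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-9) {
      stop("ratios must be 3 fractions summing to 1", call. = FALSE)
    }
    nv <- floor(ratios[2] * n)
    nt <- floor(ratios[3] * n)
    sizes <- c(n - nv - nt, nv, nt)
  }
  set.seed(seed)
  ord <- sample.int(n)
  cuts <- cumsum(sizes)
  list(train = samples[ord[seq_len(sizes[1])]],
       val = if (sizes[2] > 0) samples[ord[(cuts[1] + 1):cuts[2]]] else list(),
       test = if (sizes[3] > 0) samples[ord[(cuts[2] + 1):cuts[3]]] else list())
}
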