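# Dataset I/O in the standard image-dir + mask-dir layout (name-matched
# PNG files, masks stored as 8-bit {0, 255}).

#' Write samples to an image/mask directory layout
#'
#' Creates `images/*.png` (RGB) and `masks/*.png` (8-bit, values 0 and
#' 255) under `dir`, name-matched.
#'
#' @param samples list of samples (`$image`, `$mask`).
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(samples, dir, prefix = "sample") {
  img_dir <- file.path(dir, "images")
  msk_dir <- file.path(dir, "masks")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(msk_dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(samples)) {
    nm <- sprintf("%s_%04d.png", prefix, i)
    png::writePNG(samples[[i]]$image, file.path(img_dir, nm))
    png::writePNG(samples[[i]]$mask * 1.0, file.path(msk_dir, nm))
  }
  invisible(dir)
}

# bilinear image resize via separable interpolation matrices
resize_image <- function(img, side) {
  d <- dim(img)
  if (d[1] == side && d[2] == side) return(img)
  x <- img
  dim(x) <- c(1L, d)
  out <- bilinear_fwd(x, side, side)$y
  dim(out) <- c(side, side, d[3])
  out
}

#' Load an image/mask dataset from disk
#'
#' Every image must have a name-matched mask; unmatched files raise an
#' error naming the offenders. Images are decoded from PNG and resized
#' bilinearly to `target_size`; masks are resized nearest-neighbour and
#' binarised at 0.5 so they stay exactly binary.
#'
#' @param image_dir,mask_dir directories of name-matched PNG files.
#' @param target_size optional square side to resize to (multiple of 32).
#' @return list of samples (`$image`, `$mask`, `$meta` with the file name).
#' @export
load_dataset <- function(image_dir, mask_dir, target_size = NULL) {
  imgs <- sort(list.files(image_dir, pattern = "\\.png$", ignore.case = TRUE))
  msks <- sort(list.files(mask_dir, pattern = "\\.png$", ignore.case = TRUE))
  missing_m <- setdiff(imgs, msks)
  missing_i <- setdiff(msks, imgs)
  if (length(missing_m) || length(missing_i)) {
    stop("unmatched files - images without masks: [",
         paste(missing_m, collapse = ", "), "]; masks without images: [",
         paste(missing_i, collapse = ", "), "]", call. = FALSE)
  }
  if (!length(imgs)) stop("no PNG images found in ", image_dir, call. = FALSE)
  lapply(imgs, function(nm) {
    img <- png::readPNG(file.path(image_dir, nm))
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    if (dim(img)[3] > 3L) img <- img[, , 1:3]
    msk <- png::readPNG(file.path(mask_dir, nm))
    if (length(dim(msk)) == 3L) msk <- msk[, , 1]
    if (!is.null(target_size)) {
      img <- resize_image(img, target_size)
      msk <- nearest_resize(msk, target_size, target_size)
    }
    msk <- (msk >= 0.5) * 1L
    list(image = img, mask = msk, meta = list(file = nm))
  })
}
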