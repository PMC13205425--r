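# Image representation: plain numeric matrices, rows = image height (x in the
# descriptor's coordinate convention), columns = width (y), intensities on the
# 0-255 scale. Binary masks are 0/1 matrices of the same shape.

#' ITU-R BT.601 luminance weights
#'
#' Default RGB-to-grayscale weights used throughout the package.
#' @export
grayscale_weights_bt601 <- c(r = 0.299, g = 0.587, b = 0.114)

#' Convert an RGB image to grayscale
#'
#' Collapses an `H x W x 3` (or `H x W x 4`; alpha is ignored) intensity array
#' to a single-channel matrix by a weighted channel sum. A matrix input is
#' returned unchanged (already grayscale).
#'
#' @param img numeric matrix or 3-d array with channels in the third
#'   dimension, intensities on any common scale.
#' @param weights length-3 channel weights; defaults to BT.601 luminance.
#' @return numeric matrix of the same height and width.
#' @export
to_grayscale <- function(img, weights = grayscale_weights_bt601) {
  if (is.matrix(img)) {
    if (nrow(img) < 1L || ncol(img) < 1L) stop("empty image")
    return(img + 0)
  }
  if (!(is.array(img) && length(dim(img)) == 3L)) {
    stop("`img` must be a matrix or an H x W x C array")
  }
  d <- dim(img)
  if (d[1] < 1L || d[2] < 1L) stop("empty image")
  if (d[3] == 1L) return(img[, , 1L])
  if (d[3] < 3L) stop("image must have 1, 3, or 4 channels, got ", d[3])
  stopifnot(length(weights) == 3L, all(is.finite(weights)))
  out <- img[, , 1L] * weights[[1L]] + img[, , 2L] * weights[[2L]] +
    img[, , 3L] * weights[[3L]]
  matrix(out, d[1], d[2])  # 1-pixel-wide slices drop dims otherwise
}

#' Rescale an image or mask to a target resolution
#'
#' Images are interpolated bilinearly; binary masks use nearest-neighbour
#' resampling and are re-thresholded at `threshold` so they stay in `{0, 1}`.
#' The default target is the standard working resolution of the pipeline,
#' 720 x 480 (width x height).
#'
#' @param img numeric matrix (grayscale image or 0/1 mask).
#' @param width,height target size in pixels.
#' @param binary logical; treat `img` as a binary mask.
#' @param threshold mask re-binarization threshold (on the 0-1 mask scale).
#' @return numeric matrix with `height` rows and `width` columns.
#' @export
rescale_image <- function(img, width = 720L, height = 480L,
                          binary = FALSE, threshold = 0.5) {
  stopifnot(is.matrix(img))
  if (nrow(img) < 1L || ncol(img) < 1L) stop("empty image")
  if (width < 1L || height < 1L) stop("zero-area rescale target")
  filt <- if (binary) "none" else "bilinear"
  # EBImage stores images width-first, hence the transposes
  out <- t(EBImage::imageData(EBImage::resize(
    EBImage::Image(t(img)), w = width, h = height, filter = filt)))
  if (binary) out <- (out >= threshold) + 0
  out
}

#' Mask an image and crop to the lesion bounding box
#'
#' Sets every pixel outside the mask support to 0, then crops to the tight
#' bounding box of the mask. The cropped dimensions become the `M x N` frame
#' over which all response statistics are computed, so background pixels that
#' fall inside the bounding box (value 0) do participate in the mean/sd
#' features.
#'
#' @param img numeric matrix.
#' @param mask 0/1 matrix of the same dimensions.
#' @return numeric matrix cropped to the mask bounding box.
#' @export
apply_mask_and_crop <- function(img, mask) {
  stopifnot(is.matrix(img), is.matrix(mask))
  if (!identical(dim(img), dim(mask))) {
    stop("image (", paste(dim(img), collapse = "x"), ") and mask (",
         paste(dim(mask), collapse = "x"), ") dimensions differ")
  }
  if (!all(mask %in% c(0, 1))) stop("mask must be binary (0/1)")
  if (sum(mask) == 0) stop("no lesion region: mask is empty")
  masked <- img * mask
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  masked[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
}

# Read an image file as a grayscale 0-255 matrix. PNG goes through the png
# package; anything else through EBImage (JPEG/TIFF).
read_image_gray <- function(path, weights = grayscale_weights_bt601) {
  if (!file.exists(path)) stop("image file not found: ", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    px <- png::readPNG(path)
  } else {
    ei <- EBImage::readImage(path)
    a <- EBImage::imageData(ei)
    px <- if (length(dim(a)) == 3L) aperm(a, c(2L, 1L, 3L)) else t(a)
  }
  to_grayscale(px * 255, weights = weights)
}

#' Load a labeled image/mask dataset
#'
#' Reads a labels table (CSV path or data frame with columns `id`,
#' `image_path`, `mask_path`, `label`), loads each image and mask, and applies
#' the fixed preprocessing order: grayscale conversion, rescaling to the
#' working resolution, then mask-and-crop. Samples are returned in stable
#' order, sorted by `id`.
#'
#' @param labels CSV file path or data frame. Extra columns are ignored,
#'   except `split` which is used when `split` is requested.
#' @param root optional directory that relative image/mask paths are resolved
#'   against; defaults to the directory of the labels CSV (or `"."`).
#' @param target_size `c(width, height)` for rescaling, or `NULL` to keep
#'   native resolution.
#' @param mask_threshold binarization threshold for mask files (0-1 scale).
#' @param weights grayscale conversion weights.
#' @param split optional value to filter the `split` column on (e.g.
#'   `"train"`).
#' @return list of samples, each a list with `id`, `image` (cropped grayscale
#'   matrix) and `label` (0 or 1).
#' @export
load_dataset <- function(labels, root = NULL, target_size = c(720L, 480L),
                         mask_threshold = 0.5,
                         weights = grayscale_weights_bt601, split = NULL) {
  if (is.character(labels)) {
    if (is.null(root)) root <- dirname(labels)
    labels <- read.csv(labels, stringsAsFactors = FALSE)
  }
  if (is.null(root)) root <- "."
  req <- c("id", "image_path", "mask_path", "label")
  if (!all(req %in% names(labels))) {
    stop("labels table must have columns: ", paste(req, collapse = ", "))
  }
  if (!is.null(split)) {
    if (!"split" %in% names(labels)) stop("labels table has no `split` column")
    labels <- labels[labels$split == split, , drop = FALSE]
  }
  if (nrow(labels) == 0L) return(list())
  if (!all(labels$label %in% c(0L, 1L))) {
    bad <- unique(labels$label[!labels$label %in% c(0L, 1L)])
    stop("labels must be 0 or 1; found: ", paste(bad, collapse = ", "))
  }
  labels <- labels[order(labels$id), , drop = FALSE]
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(root, p))
  out <- vector("list", nrow(labels))
  for (i in seq_len(nrow(labels))) {
    img <- read_image_gray(resolve(labels$image_path[i]), weights = weights)
    msk <- (read_image_gray(resolve(labels$mask_path[i])) / 255 >=
              mask_threshold) + 0
    if (!is.null(target_size)) {
      img <- rescale_image(img, target_size[1], target_size[2])
      msk <- rescale_image(msk, target_size[1], target_size[2],
                           binary = TRUE, threshold = mask_threshold)
    }
    if (!identical(dim(img), dim(msk))) {
      stop("sample ", labels$id[i], ": image/mask dimension mismatch")
    }
    out[[i]] <- list(id = labels$id[i],
                     image = apply_mask_and_crop(img, msk),
                     label = as.integer(labels$label[i]))
  }
  out
}

#' Preprocess in-memory samples
#'
#' Applies the same fixed preprocessing as [load_dataset()] (grayscale,
#' optional rescale, mask-and-crop) to samples held in memory, e.g. those
#' produced by [generate_dataset()].
#'
#' @param samples list of lists with `image`, `mask`, `label` and optionally
#'   `id`.
#' @param target_size `c(width, height)` or `NULL` to keep native size.
#' @param mask_threshold mask re-binarization threshold after rescaling.
#' @return list of samples with cropped `image` and `label`.
#' @export
preprocess_samples <- function(samples, target_size = NULL,
                               mask_threshold = 0.5) {
  lapply(samples, function(s) {
    img <- to_grayscale(s$image)
    msk <- s$mask
    if (!is.null(target_size)) {
      img <- rescale_image(img, target_size[1], target_size[2])
      msk <- rescale_image(msk, target_size[1], target_size[2],
                           binary = TRUE, threshold = mask_threshold)
    }
    list(id = s$id %||% NA_character_,
         image = apply_mask_and_crop(img, msk),
         label = as.integer(s$label))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
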