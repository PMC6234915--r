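#' Convert an RGB image to grayscale
#'
#' Deterministic Rec. 601 luminance weighting
#' `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param img RGB `image_grid`.
#' @return Single-plane `image_grid` (channel kind `"gray"`) of the same
#'   size.
#' @export
to_grayscale <- function(img) {
  img <- as_image_grid(img)
  if (!is_rgb(img)) stop("to_grayscale expects an rgb image", call. = FALSE)
  p <- img$pixels
  g <- 0.299 * p[, , 1] + 0.587 * p[, , 2] + 0.114 * p[, , 3]
  image_grid(clamp01(g), modality = img$modality, channel_kind = "gray")
}

sobel_gx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # d/dx (columns)
sobel_gy <- t(sobel_gx)

# 3x3 convolution with replicated borders (direct, small kernel).
conv3_replicate <- function(m, k) {
  nr <- nrow(m); nc <- ncol(m)
  pidx_r <- c(1, seq_len(nr), nr)
  pidx_c <- c(1, seq_len(nc), nc)
  p <- m[pidx_r, pidx_c]
  out <- matrix(0, nr, nc)
  for (i in 1:3) for (j in 1:3) {
    out <- out + k[i, j] * p[(i - 1) + seq_len(nr), (j - 1) + seq_len(nc)]
  }
  out
}

#' Color-edge map of an RGB image
#'
#' Phase correlation relies heavily on edge information, so an edge variant
#' of both modalities is provided as an alternative registration input.
#' Per channel, a Sobel gradient magnitude is computed (replicated
#' borders); the per-pixel maximum over the three channels is then min-max
#' rescaled to `[0, 1]`. A constant image maps to all zeros.
#'
#' @param img RGB `image_grid`.
#' @return Single-plane `image_grid` with channel kind `"edge"`.
#' @export
color_edges <- function(img) {
  img <- as_image_grid(img)
  if (!is_rgb(img)) stop("color_edges expects an rgb image", call. = FALSE)
  mag <- matrix(0, img$height, img$width)
  for (k in 1:3) {
    ch <- img$pixels[, , k]
    gx <- conv3_replicate(ch, sobel_gx)
    gy <- conv3_replicate(ch, sobel_gy)
    mag <- pmax(mag, sqrt(gx^2 + gy^2))
  }
  rng <- range(mag)
  mag <- if (diff(rng) > 0) (mag - rng[1]) / diff(rng) else mag * 0
  image_grid(mag, modality = img$modality, channel_kind = "edge")
}

#' Remove blue-dominant background pixels
#'
#' Zeroes pixels classified as blue-dominant (the blue mat used to raise
#' contrast in top-view images of small plants): a pixel is blue-dominant
#' iff `B > R + delta` and `B > G + delta`. All other pixels are unchanged.
#'
#' @param img RGB `image_grid`.
#' @param delta Dominance margin, default 0.05.
#' @return RGB `image_grid` with blue-dominant pixels set to 0.
#' @export
remove_blue_background <- function(img, delta = 0.05) {
  img <- as_image_grid(img)
  if (!is_rgb(img))
    stop("remove_blue_background expects an rgb image", call. = FALSE)
  p <- img$pixels
  blue <- p[, , 3] > p[, , 1] + delta & p[, , 3] > p[, , 2] + delta
  for (k in 1:3) {
    ch <- p[, , k]
    ch[blue] <- 0
    p[, , k] <- ch
  }
  image_grid(p, modality = img$modality, channel_kind = "rgb")
}

#' Uniformly pre-scale an image to a target height
#'
#' FLU images are pre-scaled to the height of the corresponding VIS image
#' before any registration, preserving aspect ratio: the new width is
#' `round(width * target_height / height)` (at least 1 column, and at least
#' 2 to satisfy the image invariants). Intensity images are resampled
#' bilinearly (with antialiasing when downscaling); binary masks use
#' nearest-neighbour so they stay binary.
#'
#' @param flu `image_grid` of any channel kind.
#' @param target_height Target number of rows (>= 2).
#' @return Rescaled `image_grid`.
#' @export
prescale_to_height <- function(flu, target_height) {
  flu <- as_image_grid(flu)
  if (!is.numeric(target_height) || target_height < 2)
    stop("target_height must be at least 2", call. = FALSE)
  target_height <- as.integer(round(target_height))
  if (target_height == flu$height) return(flu)
  new_w <- max(2L, as.integer(round(flu$width * target_height / flu$height)))
  resample_to(flu, c(target_height, new_w))
}

# Resample an image_grid to (rows, cols) via EBImage; masks use
# nearest-neighbour, intensities bilinear with antialiasing on downscale.
resample_to <- function(img, shape) {
  img <- as_image_grid(img)
  down <- shape[1] < img$height || shape[2] < img$width
  do_plane <- function(m, mask) {
    if (mask) {
      r <- EBImage::resize(m, w = shape[1], h = shape[2], filter = "none")
      round(r)
    } else {
      clamp01(EBImage::resize(m, w = shape[1], h = shape[2],
                              filter = "bilinear", antialias = down))
    }
  }
  if (is_rgb(img)) {
    out <- array(0, c(shape, 3))
    for (k in 1:3) out[, , k] <- do_plane(img$pixels[, , k], FALSE)
  } else {
    out <- do_plane(img$pixels, img$channel_kind == "binary_mask")
  }
  image_grid(out, modality = img$modality, channel_kind = img$channel_kind)
}

#' Bounding boxes
#'
#' Boxes are 0-based with half-open upper bounds:
#' rows `[row_min, row_max)`, columns `[col_min, col_max)`.
#'
#' @param row_min,col_min,row_max,col_max Integer pixel bounds.
#' @return A `bounding_box`.
#' @export
bounding_box <- function(row_min, col_min, row_max, col_max) {
  b <- list(row_min = as.integer(row_min), col_min = as.integer(col_min),
            row_max = as.integer(row_max), col_max = as.integer(col_max))
  if (b$row_min < 0 || b$col_min < 0 || b$row_min >= b$row_max ||
      b$col_min >= b$col_max)
    stop("invalid bounding box: need 0 <= min < max", call. = FALSE)
  structure(b, class = "bounding_box")
}

#' Crop an image to a bounding box
#'
#' @param img `image_grid`.
#' @param box `bounding_box` within the image bounds.
#' @return `image_grid` of the box extents, pixel values preserved exactly.
#' @export
crop_to_bbox <- function(img, box) {
  img <- as_image_grid(img)
  if (box$row_max > img$height || box$col_max > img$width)
    stop("bounding box exceeds image bounds", call. = FALSE)
  ri <- (box$row_min + 1):box$row_max
  ci <- (box$col_min + 1):box$col_max
  p <- if (is_rgb(img)) img$pixels[ri, ci, , drop = FALSE]
       else img$pixels[ri, ci, drop = FALSE]
  image_grid(p, modality = img$modality, channel_kind = img$channel_kind)
}

#' Tight bounding box of a binary mask
#'
#' @param mask `image_grid` with channel kind `"binary_mask"` (or 0/1
#'   matrix).
#' @param pad Padding in pixels added on each side, clipped to the image
#'   bounds.
#' @return A `bounding_box` containing every foreground pixel.
#' @export
plant_bbox <- function(mask, pad = 0) {
  mask <- as_image_grid(mask, channel_kind = "binary_mask")
  m <- mask$pixels
  fg <- which(m == 1, arr.ind = TRUE)
  if (nrow(fg) == 0) stop("empty mask: no foreground pixels", call. = FALSE)
  bounding_box(
    max(0L, min(fg[, 1]) - 1L - pad),
    max(0L, min(fg[, 2]) - 1L - pad),
    min(mask$height, max(fg[, 1]) + pad),
    min(mask$width, max(fg[, 2]) + pad)
  )
}

#' Threshold segmentation of a single-plane image
#'
#' Global thresholding stand-in for manual plant segmentation: the mask is
#' 1 where intensity strictly exceeds the threshold. The default threshold
#' is Otsu's method on the input histogram.
#'
#' @param img Single-plane `image_grid`.
#' @param threshold Intensity cut-off in `[0, 1]`; `NULL` (default) uses
#'   Otsu's threshold.
#' @return `image_grid` with channel kind `"binary_mask"`.
#' @export
threshold_segment <- function(img, threshold = NULL) {
  img <- as_image_grid(img)
  m <- pixel_matrix(img)
  if (is.null(threshold)) threshold <- EBImage::otsu(m)
  image_grid((m > threshold) + 0, modality = img$modality,
             channel_kind = "binary_mask")
}

#' Apply a named preprocessing variant to an RGB image
#'
#' Produces the registration input variants compared in the package:
#' the cross of feature type (`gray` or `edge`), frame (`full` or
#' `cropped` to the plant bounding box) and background handling (`raw` or
#' `filtered`, i.e. blue-mat removal before feature extraction).
#'
#' @param img RGB `image_grid`.
#' @param feature `"gray"` or `"edge"`.
#' @param frame `"full"` or `"cropped"`.
#' @param background `"raw"` or `"filtered"`.
#' @param mask Optional plant `binary_mask` used for the crop box (required
#'   when `frame = "cropped"`).
#' @param blue_delta Dominance margin for [remove_blue_background()].
#' @param crop_pad Padding for [plant_bbox()].
#' @return Single-plane `image_grid`.
#' @export
preprocess_variant <- function(img, feature = c("gray", "edge"),
                               frame = c("full", "cropped"),
                               background = c("raw", "filtered"),
                               mask = NULL, blue_delta = 0.05, crop_pad = 0) {
  feature <- match.arg(feature)
  frame <- match.arg(frame)
  background <- match.arg(background)
  img <- as_image_grid(img)
  if (background == "filtered") img <- remove_blue_background(img, blue_delta)
  out <- if (feature == "gray") to_grayscale(img) else color_edges(img)
  if (frame == "cropped") {
    if (is.null(mask))
      stop("cropped variants need a plant mask for the bounding box",
           call. = FALSE)
    out <- crop_to_bbox(out, plant_bbox(mask, pad = crop_pad))
  }
  out
}
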