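#' Image grid container
#'
#' An `image_grid` is a thin wrapper around a numeric matrix (single-plane
#' images) or an `height x width x 3` array (RGB images) with intensities in
#' `[0, 1]`. It carries a modality tag (`"VIS"`, `"FLU"` or `"synthetic"`)
#' and a channel kind (`"rgb"`, `"gray"`, `"edge"` or `"binary_mask"`).
#'
#' Coordinate convention, fixed package-wide: rows increase downward, columns
#' rightward, origin at the top-left pixel. Pixel coordinates used by
#' transforms are 0-based `(x, y) = (col - 1, row - 1)`.
#'
#' @param pixels Numeric matrix (gray/edge/mask) or 3-d array with third
#'   dimension 3 (rgb), values in `[0, 1]`.
#' @param modality One of `"VIS"`, `"FLU"`, `"synthetic"`.
#' @param channel_kind One of `"rgb"`, `"gray"`, `"edge"`, `"binary_mask"`.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(pixels, modality = "synthetic", channel_kind = NULL) {
  if (is.null(channel_kind)) {
    channel_kind <- if (length(dim(pixels)) == 3L) "rgb" else "gray"
  }
  modality <- match.arg(modality, c("VIS", "FLU", "synthetic"))
  channel_kind <- match.arg(channel_kind, c("rgb", "gray", "edge", "binary_mask"))
  if (channel_kind == "rgb") {
    if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
      stop("rgb images need a height x width x 3 array", call. = FALSE)
  } else {
    if (!is.matrix(pixels))
      stop("single-plane images need a numeric matrix", call. = FALSE)
  }
  d <- dim(pixels)
  if (d[1] < 2L || d[2] < 2L)
    stop("image must be at least 2 x 2 pixels", call. = FALSE)
  if (!all(is.finite(pixels)))
    stop("image intensities must be finite", call. = FALSE)
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("image intensities must lie in [0, 1]", call. = FALSE)
  if (channel_kind == "binary_mask" && !all(pixels %in% c(0, 1)))
    stop("binary_mask pixels must be 0 or 1", call. = FALSE)
  structure(
    list(pixels = pixels, height = d[1], width = d[2],
         modality = modality, channel_kind = channel_kind),
    class = "image_grid"
  )
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("<image_grid> %d x %d  modality=%s  channels=%s\n",
              x$height, x$width, x$modality, x$channel_kind))
  invisible(x)
}

#' @export
dim.image_grid <- function(x) c(x$height, x$width)

#' Coerce to image_grid
#'
#' Matrices and 3-plane arrays pass through [image_grid()]; an existing
#' `image_grid` is returned unchanged.
#' @param x Matrix, array or `image_grid`.
#' @inheritParams image_grid
#' @return An `image_grid`.
#' @export
as_image_grid <- function(x, modality = "synthetic", channel_kind = NULL) {
  if (inherits(x, "image_grid")) return(x)
  image_grid(x, modality = modality, channel_kind = channel_kind)
}

is_rgb <- function(img) inherits(img, "image_grid") && img$channel_kind == "rgb"

is_single_plane <- function(img)
  inherits(img, "image_grid") && img$channel_kind != "rgb"

# Raw pixel matrix of a single-plane image (errors on rgb).
pixel_matrix <- function(img) {
  img <- as_image_grid(img)
  if (is_rgb(img))
    stop("expected a single-plane image, got rgb", call. = FALSE)
  img$pixels
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Bilinear sampling at fractional pixel coordinates
#'
#' Samples a matrix at 0-based fractional coordinates; locations outside the
#' domain contribute 0. Used by the warping and log-polar resampling steps.
#'
#' @param m Numeric matrix.
#' @param x,y Numeric vectors of 0-based column / row coordinates.
#' @return Numeric vector of sampled values.
#' @keywords internal
bilinear_sample <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  gather <- function(yy, xx) {
    v <- numeric(length(xx))
    ok <- xx >= 0 & xx <= nc - 1 & yy >= 0 & yy <= nr - 1
    v[ok] <- m[cbind(yy[ok] + 1, xx[ok] + 1)]
    v
  }
  v00 <- gather(y0, x0)
  v01 <- gather(y0, x0 + 1)
  v10 <- gather(y0 + 1, x0)
  v11 <- gather(y0 + 1, x0 + 1)
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

# Nearest-neighbour sampling at 0-based coordinates, 0 outside the domain.
nearest_sample <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  xi <- round(x); yi <- round(y)
  v <- numeric(length(xi))
  ok <- xi >= 0 & xi <= nc - 1 & yi >= 0 & yi <= nr - 1
  v[ok] <- m[cbind(yi[ok] + 1, xi[ok] + 1)]
  v
}

# Zero-pad a matrix to (nr, nc), top-left anchored.
pad_topleft <- function(m, nr, nc) {
  out <- matrix(0, nr, nc)
  out[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  out
}

# Circular shift of a matrix by (dr, dc); positive shifts move content
# down / right.
circshift <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  dr <- ((dr %% nr) + nr) %% nr
  dc <- ((dc %% nc) + nc) %% nc
  ri <- c(seq_len(nr)[(nr - dr + 1):nr], seq_len(nr)[seq_len(nr - dr)])
  if (dr == 0) ri <- seq_len(nr)
  ci <- c(seq_len(nc)[(nc - dc + 1):nc], seq_len(nc)[seq_len(nc - dc)])
  if (dc == 0) ci <- seq_len(nc)
  m[ri, ci, drop = FALSE]
}
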