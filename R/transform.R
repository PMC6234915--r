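#' 2-D affine (similarity) transforms
#'
#' Transforms map 0-based FLU pixel coordinates `(x, y)` into VIS pixel
#' coordinates via a 3 x 3 homogeneous matrix `M` acting on column vectors
#' `(x, y, 1)'`, so the bottom row is `(0, 0, 1)`. The linear block holds the
#' rotation/scale, the third column the translation. Component names follow
#' the convention common in the phenotyping literature, where points are row
#' vectors and the translation sits in the third matrix row: `T11`, `T12`
#' are the diagonal and off-diagonal linear entries and `T31`, `T32` the x/y
#' translations. [transform_components()] returns them under those names.
#'
#' @param matrix 3 x 3 numeric homogeneous matrix, bottom row `(0, 0, 1)`.
#' @param det_tol Transforms with `|det(linear block)|` below this are
#'   rejected as singular.
#' @return An object of class `affine_transform2d` with elements `matrix`,
#'   `rotation_deg`, `scale`, `shift_x`, `shift_y`.
#' @export
affine_transform2d <- function(matrix, det_tol = 1e-8) {
  m <- base::matrix(as.numeric(matrix), 3, 3)
  if (!all(is.finite(m)))
    stop("transform matrix must be finite", call. = FALSE)
  if (max(abs(m[3, ] - c(0, 0, 1))) > 1e-9)
    stop("bottom row of a homogeneous 2-D transform must be (0, 0, 1)",
         call. = FALSE)
  L <- m[1:2, 1:2]
  dt <- det(L)
  if (abs(dt) < det_tol)
    stop("transform is singular (|det| < det_tol)", call. = FALSE)
  dec <- decompose_similarity(m)
  structure(
    list(matrix = m,
         rotation_deg = dec$rotation_deg, scale = dec$scale,
         shift_x = dec$shift_x, shift_y = dec$shift_y),
    class = "affine_transform2d"
  )
}

#' @export
print.affine_transform2d <- function(x, ...) {
  cat(sprintf(
    "<affine_transform2d> scale=%.4f rot=%.2f deg shift=(%.2f, %.2f)\n",
    x$scale, x$rotation_deg, x$shift_x, x$shift_y))
  invisible(x)
}

# Decompose the similarity part of a homogeneous matrix. For a pure
# similarity the linear block is s * [cos t, -sin t; sin t, cos t]; for a
# general matrix this returns the closest similarity reading.
decompose_similarity <- function(m) {
  L <- m[1:2, 1:2]
  s <- sqrt(abs(det(L)))
  rot <- atan2(L[2, 1] - L[1, 2], L[1, 1] + L[2, 2]) * 180 / pi
  list(scale = s, rotation_deg = rot, shift_x = m[1, 3], shift_y = m[2, 3])
}

#' Build a similarity transform
#'
#' Composes isotropic scale, rotation (about an optional centre) and a
#' translation into one homogeneous matrix: points are scaled/rotated about
#' `center` and then shifted by `(shift_x, shift_y)`. Angles are degrees;
#' positive rotation turns the +x axis toward +y (downward in image
#' coordinates).
#'
#' @param scale Isotropic scale factor (> 0).
#' @param rotation_deg Rotation angle in degrees.
#' @param shift_x,shift_y Translation in pixels.
#' @param center Length-2 `(x, y)` centre of rotation/scaling, default origin.
#' @return An `affine_transform2d`.
#' @export
similarity_transform <- function(scale = 1, rotation_deg = 0,
                                 shift_x = 0, shift_y = 0,
                                 center = c(0, 0)) {
  th <- rotation_deg * pi / 180
  L <- scale * base::matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  t0 <- c(shift_x, shift_y) + center - L %*% center
  m <- rbind(cbind(L, t0), c(0, 0, 1))
  affine_transform2d(m)
}

#' Transform matrix components under field naming
#'
#' @param transform An `affine_transform2d`.
#' @return Named numeric vector with `T11`, `T12` (linear part) and `T31`,
#'   `T32` (x and y translation).
#' @export
transform_components <- function(transform) {
  m <- transform$matrix
  c(T11 = m[1, 1], T12 = m[1, 2], T31 = m[1, 3], T32 = m[2, 3])
}

#' Compose and invert transforms
#'
#' `compose_transforms(a, b)` applies `b` first, then `a`;
#' `invert_transform(a)` is the matrix inverse.
#' @param a,b `affine_transform2d` objects.
#' @return An `affine_transform2d`.
#' @export
compose_transforms <- function(a, b) {
  affine_transform2d(a$matrix %*% b$matrix)
}

#' @rdname compose_transforms
#' @export
invert_transform <- function(a) {
  affine_transform2d(solve(a$matrix))
}

#' Apply a transform to points
#'
#' @param transform An `affine_transform2d`.
#' @param xy Two-column matrix of `(x, y)` coordinates (or length-2 vector).
#' @return Two-column matrix of mapped coordinates.
#' @export
apply_transform <- function(transform, xy) {
  if (is.null(dim(xy))) xy <- base::matrix(xy, ncol = 2)
  p <- transform$matrix %*% rbind(t(xy), 1)
  t(p[1:2, , drop = FALSE])
}

#' Warp an image through an affine transform
#'
#' Resamples `img` into a target frame so that the warped image is `img`
#' moved forward by `transform` (inverse mapping with interpolation).
#' Out-of-domain pixels are 0. Masks should use nearest-neighbour
#' interpolation, intensity images bilinear.
#'
#' @param img Single-plane or rgb `image_grid` (or matrix).
#' @param transform An `affine_transform2d` mapping input to output pixels.
#' @param out_shape Target `(rows, cols)`; default the input shape.
#' @param interpolation `"bilinear"` or `"nearest"`; default `"nearest"` for
#'   binary masks and `"bilinear"` otherwise.
#' @return An `image_grid` in the target frame, same channel kind.
#' @export
warp_image <- function(img, transform, out_shape = NULL,
                       interpolation = NULL) {
  img <- as_image_grid(img)
  if (is.null(out_shape)) out_shape <- c(img$height, img$width)
  if (is.null(interpolation)) {
    interpolation <- if (img$channel_kind == "binary_mask") "nearest" else "bilinear"
  }
  interpolation <- match.arg(interpolation, c("bilinear", "nearest"))
  Tinv <- solve(transform$matrix)
  nr <- out_shape[1]; nc <- out_shape[2]
  xo <- rep(seq_len(nc) - 1, each = nr)
  yo <- rep(seq_len(nr) - 1, times = nc)
  xs <- Tinv[1, 1] * xo + Tinv[1, 2] * yo + Tinv[1, 3]
  ys <- Tinv[2, 1] * xo + Tinv[2, 2] * yo + Tinv[2, 3]
  sample_fun <- if (interpolation == "nearest") nearest_sample else bilinear_sample
  warp_plane <- function(m) base::matrix(sample_fun(m, xs, ys), nr, nc)
  if (is_rgb(img)) {
    out <- array(0, c(nr, nc, 3))
    for (k in 1:3) out[, , k] <- clamp01(warp_plane(img$pixels[, , k]))
  } else {
    out <- clamp01(warp_plane(img$pixels))
    if (img$channel_kind == "binary_mask") out <- round(out)
  }
  image_grid(out, modality = img$modality, channel_kind = img$channel_kind)
}
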