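#' Read a PNG or TIFF raster as an image grid
#'
#' 8- and 16-bit inputs are normalized to `[0, 1]`. Grayscale files yield a
#' single-plane image, color files an RGB image (any alpha plane is
#' dropped).
#'
#' @param path Path to a `.png`, `.tif` or `.tiff` file.
#' @param modality Modality tag for the result.
#' @param as_mask Read as a binary mask (values rounded to 0/1).
#' @return An `image_grid`.
#' @export
read_image <- function(path, modality = "synthetic", as_mask = FALSE) {
  if (!file.exists(path)) stop("cannot read image: ", path, call. = FALSE)
  img <- EBImage::readImage(path)
  d <- dim(img)
  a <- EBImage::imageData(img)
  if (length(d) == 2) {
    px <- t(a)
  } else {
    nch <- d[3]
    if (nch >= 3) {
      px <- array(0, c(d[2], d[1], 3))
      for (k in 1:3) px[, , k] <- t(a[, , k])
    } else {
      px <- t(a[, , 1])
    }
  }
  px <- clamp01(px)
  if (as_mask) {
    if (length(dim(px)) == 3) px <- px[, , 1]
    return(image_grid(round(px), modality = modality,
                      channel_kind = "binary_mask"))
  }
  image_grid(px, modality = modality)
}

#' Write a binary mask as a PNG (0/255)
#'
#' @param path Output `.png` path.
#' @param mask `binary_mask` `image_grid` or 0/1 matrix.
#' @return `path`, invisibly.
#' @export
write_mask <- function(path, mask) {
  mask <- as_image_grid(mask, channel_kind = "binary_mask")
  EBImage::writeImage(EBImage::Image(t(mask$pixels)), path)
  invisible(path)
}

#' Write an intensity or RGB image as PNG/TIFF
#'
#' @param path Output path (`.png` or `.tif`).
#' @param img `image_grid`.
#' @return `path`, invisibly.
#' @export
write_image <- function(path, img) {
  img <- as_image_grid(img)
  if (is_rgb(img)) {
    a <- array(0, c(img$width, img$height, 3))
    for (k in 1:3) a[, , k] <- t(img$pixels[, , k])
    e <- EBImage::Image(a, colormode = "Color")
  } else {
    e <- EBImage::Image(t(img$pixels))
  }
  EBImage::writeImage(e, path)
  invisible(path)
}

#' Write / read a tabular report as CSV
#'
#' @param path CSV path.
#' @param report Data frame (e.g. a tidied sweep or evaluation table).
#' @return `write_report`: `path` invisibly; `read_report`: a tibble.
#' @export
write_report <- function(path, report) {
  readr::write_csv(report, path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Serialize a registration result to JSON
#'
#' Record layout: `matrix` (9 floats, row-major), `rotation_deg`, `scale`,
#' `shift_x`, `shift_y`, `H`, `valid`, `scale_factor`.
#'
#' @param result A `registration_result`.
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_transform_json <- function(result, path) {
  tr <- result$transform
  rec <- list(
    matrix = if (is.null(tr)) rep(NA_real_, 9) else as.vector(t(tr$matrix)),
    rotation_deg = if (is.null(tr)) NA_real_ else tr$rotation_deg,
    scale = if (is.null(tr)) NA_real_ else tr$scale,
    shift_x = if (is.null(tr)) NA_real_ else tr$shift_x,
    shift_y = if (is.null(tr)) NA_real_ else tr$shift_y,
    H = result$peak_height, valid = result$valid,
    scale_factor = result$scale_factor)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a registration result from JSON
#'
#' @param path `.json` path written by [write_transform_json()].
#' @return A `registration_result`.
#' @export
read_transform_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  tr <- if (all(is.finite(rec$matrix)))
    affine_transform2d(matrix(rec$matrix, 3, 3, byrow = TRUE)) else NULL
  registration_result(tr, rec$H, isTRUE(rec$valid), rec$scale_factor)
}
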