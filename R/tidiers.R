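#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a registration result
#'
#' @param x A `registration_result`.
#' @param ... Unused.
#' @return One-row tibble with the scale factor, peak height, validity and
#'   the transform components `T11`, `T12`, `T31`, `T32` plus the
#'   similarity decomposition.
#' @export
tidy.registration_result <- function(x, ...) {
  if (is.null(x$transform)) {
    comp <- c(T11 = NA_real_, T12 = NA_real_, T31 = NA_real_, T32 = NA_real_)
    dec <- list(rotation_deg = NA_real_, scale = NA_real_,
                shift_x = NA_real_, shift_y = NA_real_)
  } else {
    comp <- transform_components(x$transform)
    dec <- x$transform
  }
  tibble::tibble(
    scale_factor = x$scale_factor,
    H = if (is.finite(x$peak_height)) x$peak_height else NA_real_,
    valid = isTRUE(x$valid),
    T11 = comp[["T11"]], T12 = comp[["T12"]],
    T31 = comp[["T31"]], T32 = comp[["T32"]],
    rotation_deg = dec$rotation_deg, scale_est = dec$scale,
    shift_x = dec$shift_x, shift_y = dec$shift_y)
}

#' Tidy a sweep outcome
#'
#' One row per swept scale with the per-scale peak height, validity flag
#' and full-resolution transform components (column naming as in sweep
#' reports: `scale`, `H`, `valid`, `T11`, `T12`, `T31`, `T32`).
#'
#' @param x A `sweep_outcome`.
#' @param ... Unused.
#' @return A tibble with one row per scale.
#' @export
tidy.sweep_outcome <- function(x, ...) {
  tab <- dplyr::bind_rows(lapply(x$results, tidy))
  tab <- dplyr::rename(tab, scale = "scale_factor")
  tab
}

#' @rdname tidy.sweep_outcome
#' @export
glance.sweep_outcome <- function(x, ...) {
  tibble::tibble(
    n_scales = length(x$results),
    n_valid = x$n_valid,
    success = x$success,
    mask_area = if (is.null(x$integrated_mask)) NA_real_
                else sum(x$integrated_mask$pixels))
}

#' Tidy an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return The per-pair tibble (pair, group, success, n_valid, or).
#' @export
tidy.evaluation_report <- function(x, ...) x$per_pair

#' @rdname tidy.evaluation_report
#' @export
glance.evaluation_report <- function(x, ...) x$overall

#' Plot per-scale transform components and peak heights
#'
#' Faceted view of the diagonal (`T11`), off-diagonal (`T12`) and
#' translational (`T31`, `T32`) components of the recovered transform, and
#' the peak height `H`, as functions of the downscaling factor. Variation
#' of the components across scales reflects the ambiguity of affine
#' alignment for structurally non-identical images.
#'
#' @param object A `sweep_outcome`.
#' @param ... Unused.
#' @return A `ggplot` object.
#' @export
autoplot.sweep_outcome <- function(object, ...) {
  tab <- tidy(object)
  long <- tab |>
    dplyr::select("scale", "H", "T11", "T12", "T31", "T32", "valid") |>
    tidyr_pivot_components()
  ggplot2::ggplot(long, ggplot2::aes(x = .data$scale, y = .data$value)) +
    ggplot2::geom_line(color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$valid), size = 1.6) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4)) +
    ggplot2::facet_wrap(~component, scales = "free_y") +
    ggplot2::labs(x = "downscaling factor", y = NULL, shape = "valid") +
    ggplot2::theme_minimal()
}

# manual pivot (wide -> long) so tidyr is not a hard dependency
tidyr_pivot_components <- function(tab) {
  comps <- c("H", "T11", "T12", "T31", "T32")
  dplyr::bind_rows(lapply(comps, function(cc) {
    tibble::tibble(scale = tab$scale, component = cc,
                   value = tab[[cc]], valid = tab$valid)
  }))
}

#' Plot an integrated mask over the reference
#'
#' Pixel classes: covered reference (mask and reference), missed reference
#' and excess mask area.
#'
#' @param outcome A `sweep_outcome` with an integrated mask.
#' @param reference Reference `binary_mask` in the VIS frame.
#' @return A `ggplot` object.
#' @export
plot_mask_overlap <- function(outcome, reference) {
  stopifnot(!is.null(outcome$integrated_mask))
  reg <- outcome$integrated_mask$pixels
  ref <- as_image_grid(reference, channel_kind = "binary_mask")
  ref <- resample_to(ref, dim(reg))$pixels
  cls <- matrix("background", nrow(reg), ncol(reg))
  cls[reg == 1 & ref == 1] <- "covered"
  cls[reg == 0 & ref == 1] <- "missed"
  cls[reg == 1 & ref == 0] <- "excess"
  d <- tibble::tibble(
    row = rep(seq_len(nrow(reg)), times = ncol(reg)),
    col = rep(seq_len(ncol(reg)), each = nrow(reg)),
    class = as.vector(cls))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = -.data$row,
                                  fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(
      background = "grey95", covered = "#2b8a3e",
      missed = "#c92a2a", excess = "#f8d568")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
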