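#' Success rate of a set of registrations
#'
#' SR = ns / n, the number of registrations passing the validity gate
#' divided by the total number attempted.
#'
#' @param results List of `registration_result`s (or logical vector of
#'   validity flags).
#' @return SR in `[0, 1]`.
#' @export
success_rate <- function(results) {
  if (length(results) == 0) stop("empty result list", call. = FALSE)
  if (is.logical(results)) return(mean(results))
  mean(vapply(results, function(r) isTRUE(r$valid), logical(1)))
}

#' Overlap ratio of a registered mask against a reference
#'
#' OR = ar / a: the reference plant area covered by the registered mask
#' (`ar`, pixels where both masks are 1) divided by the total reference
#' plant area (`a`).
#'
#' @param registered_mask,reference_mask Equal-shape `binary_mask`
#'   `image_grid`s (or 0/1 matrices).
#' @return OR in `[0, 1]`.
#' @export
overlap_ratio <- function(registered_mask, reference_mask) {
  reg <- as_image_grid(registered_mask, channel_kind = "binary_mask")$pixels
  ref <- as_image_grid(reference_mask, channel_kind = "binary_mask")$pixels
  if (!identical(dim(reg), dim(ref)))
    stop("masks must have equal dimensions", call. = FALSE)
  a <- sum(ref)
  if (a == 0) stop("empty reference mask", call. = FALSE)
  sum(reg * ref) / a
}

#' Segment a VIS image through a registered mask
#'
#' Segmentation-via-registration: VIS pixels are retained where the
#' (registered FLU) mask is 1 and zeroed elsewhere.
#'
#' @param vis `image_grid` (rgb or single-plane).
#' @param mask `binary_mask` `image_grid` of the same height/width.
#' @return `image_grid` like `vis`.
#' @export
segment_via_mask <- function(vis, mask) {
  vis <- as_image_grid(vis)
  mask <- as_image_grid(mask, channel_kind = "binary_mask")
  if (!identical(dim(vis), dim(mask)))
    stop("vis image and mask must have equal dimensions", call. = FALSE)
  if (is_rgb(vis)) {
    p <- vis$pixels
    for (k in 1:3) p[, , k] <- p[, , k] * mask$pixels
  } else {
    p <- vis$pixels * mask$pixels
  }
  image_grid(p, modality = vis$modality, channel_kind = vis$channel_kind)
}

#' Batch evaluation of registration over image pairs
#'
#' Registers every FLU/VIS pair and aggregates the two evaluation criteria:
#' the success rate SR (fraction of pairs passing the validity gate) and
#' the overlap ratio OR against reference masks where available. Pairs can
#' be `synthetic_pair`s (their ground-truth VIS mask is the reference) or
#' lists with elements `flu`, `vis` and optionally `ref_mask`. A failing
#' pair counts against SR but does not abort the batch.
#'
#' @param pairs List of pairs.
#' @param cfg A [scale_sweep_config()].
#' @param groups Optional character/factor vector of group labels (e.g.
#'   growth phase), one per pair, for stratified reporting.
#' @param mode `"integrative"` (scale sweep + mask integration; success
#'   means at least one valid scale) or `"single"` (one full-resolution
#'   registration; success means that registration is valid).
#' @return An `evaluation_report`: list with `per_pair` (tibble: pair, group,
#'   success, n_valid, or), `overall` (one-row tibble with n, ns, SR,
#'   mean/median OR) and `by_group` (same statistics per label;
#'   grouped summaries conventionally read off the median).
#' @export
batch_evaluate <- function(pairs, cfg = scale_sweep_config(), groups = NULL,
                           mode = c("integrative", "single")) {
  mode <- match.arg(mode)
  if (length(pairs) == 0) stop("empty pair list", call. = FALSE)
  if (is.null(groups)) groups <- rep(NA_character_, length(pairs))
  stopifnot(length(groups) == length(pairs))
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    ref <- if (inherits(p, "synthetic_pair")) p$vis_mask else p$ref_mask
    out <- tryCatch(
      evaluate_one(p$flu, p$vis, cfg, ref, mode),
      error = function(e) list(success = FALSE, n_valid = 0L,
                               or = NA_real_, h = NA_real_))
    tibble::tibble(pair = i, group = as.character(groups[i]),
                   success = out$success, n_valid = out$n_valid,
                   or = out$or, peak_height = out$h)
  })
  per_pair <- dplyr::bind_rows(rows)
  summarize_block <- function(d) {
    tibble::tibble(
      n = nrow(d), ns = sum(d$success), sr = sum(d$success) / nrow(d),
      or_mean = mean(d$or, na.rm = TRUE),
      or_median = stats::median(d$or, na.rm = TRUE))
  }
  overall <- summarize_block(per_pair)
  by_group <- NULL
  if (any(!is.na(per_pair$group))) {
    by_group <- per_pair |>
      dplyr::group_by(.data$group) |>
      dplyr::group_modify(~ summarize_block(.x)) |>
      dplyr::ungroup()
  }
  structure(list(per_pair = per_pair, overall = overall, by_group = by_group,
                 mode = mode),
            class = "evaluation_report")
}

evaluate_one <- function(flu, vis, cfg, ref, mode) {
  if (mode == "single") {
    prep <- function(img) {
      img <- as_image_grid(img)
      if (!is_rgb(img)) return(img)
      preprocess_variant(img, feature = cfg$variant,
                         background = if (cfg$filter_blue) "filtered" else "raw")
    }
    flu_p <- prep(flu); vis_p <- prep(vis)
    flu_p <- prescale_to_height(flu_p, vis_p$height)
    res <- register_affine(flu_p, vis_p, h_threshold = cfg$h_threshold,
                           bounds = cfg$bounds)
    or <- NA_real_
    if (!is.null(ref) && isTRUE(res$valid) && !is.null(res$transform)) {
      flu_gray <- if (is_rgb(as_image_grid(flu))) to_grayscale(flu) else as_image_grid(flu)
      fm <- threshold_segment(prescale_to_height(flu_gray, vis_p$height))
      wm <- warp_image(fm, res$transform, out_shape = dim(vis_p),
                       interpolation = "nearest")
      ref_rs <- resample_to(as_image_grid(ref, channel_kind = "binary_mask"),
                            dim(vis_p))
      or <- overlap_ratio(wm, ref_rs)
    }
    list(success = isTRUE(res$valid), n_valid = as.integer(isTRUE(res$valid)),
         or = or, h = res$peak_height)
  } else {
    out <- register_integrative(flu, vis, cfg)
    or <- NA_real_
    if (out$success && !is.null(ref)) {
      ref_rs <- resample_to(as_image_grid(ref, channel_kind = "binary_mask"),
                            out$vis_dim)
      or <- overlap_ratio(out$integrated_mask, ref_rs)
    }
    hmax <- suppressWarnings(max(vapply(out$results, function(r)
      r$peak_height, numeric(1)), na.rm = TRUE))
    list(success = out$success, n_valid = out$n_valid, or = or, h = hmax)
  }
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> mode=%s  n=%d  SR=%.3f  median OR=%s\n",
              x$mode, x$overall$n, x$overall$sr,
              format(x$overall$or_median, digits = 3)))
  invisible(x)
}
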