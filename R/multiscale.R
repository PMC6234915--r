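#' Scale-sweep configuration
#'
#' The integrative registration strategy runs single-step registrations on
#' image pairs downscaled by every factor of an inclusive grid from
#' `scale_min` to `scale_max` (defaults 0.1 to 1.0 in steps of 0.02, i.e.
#' 46 scales). Downscaling effectively smooths the images, and different
#' factors lock onto different locally optimal alignments; their masks are
#' later combined by [integrate_masks()].
#'
#' @param scale_min,scale_max,step Sweep grid, `0 < scale_min <= scale_max
#'   <= 1`, `step > 0`; `scale_max` is always included.
#' @param variant Preprocessing feature used by [register_integrative()]:
#'   `"gray"` or `"edge"`.
#' @param h_threshold Peak-height gate, see [validate_transform()].
#' @param bounds Transform admissibility bounds, see [default_bounds()].
#' @param filter_blue Remove blue-dominant background before feature
#'   extraction.
#' @param min_side Scales at which either image would fall below this many
#'   pixels per side are skipped (recorded as failure results).
#' @return A `scale_sweep_config` list.
#' @export
scale_sweep_config <- function(scale_min = 0.1, scale_max = 1.0, step = 0.02,
                               variant = c("gray", "edge"),
                               h_threshold = 0.03,
                               bounds = default_bounds(),
                               filter_blue = FALSE, min_side = 16) {
  variant <- match.arg(variant)
  if (!(scale_min > 0 && scale_min <= scale_max && scale_max <= 1))
    stop("need 0 < scale_min <= scale_max <= 1", call. = FALSE)
  if (step <= 0) stop("step must be positive", call. = FALSE)
  structure(
    list(scale_min = scale_min, scale_max = scale_max, step = step,
         variant = variant, h_threshold = h_threshold, bounds = bounds,
         filter_blue = filter_blue, min_side = min_side),
    class = "scale_sweep_config"
  )
}

#' Scale factors of a sweep grid
#'
#' Inclusive grid `scale_min, scale_min + step, ...` capped at and always
#' including `scale_max`.
#' @param cfg A `scale_sweep_config`.
#' @return Numeric vector of scale factors.
#' @export
scale_grid <- function(cfg) {
  s <- seq(cfg$scale_min, cfg$scale_max, by = cfg$step)
  if (cfg$scale_max - s[length(s)] > 1e-9) s <- c(s, cfg$scale_max)
  s
}

#' Run single-step registration across the scale sweep
#'
#' For each scale factor `s` both images are downscaled by `s`
#' (anti-aliased), registered with [register_affine()], and the recovered
#' transform is mapped back to full-resolution coordinates (linear part
#' unchanged, translation divided by the realized per-axis factor). One
#' result is returned per scale, tagged with its factor; invalid
#' registrations are retained with `valid = FALSE`, and scales at which an
#' image would shrink below `cfg$min_side` pixels per side are recorded as
#' skipped failure results.
#'
#' @param flu,vis Preprocessed single-plane images; `flu` already
#'   pre-scaled to the VIS height.
#' @param cfg A [scale_sweep_config()].
#' @return List of `registration_result`, one per grid scale.
#' @export
sweep_scales <- function(flu, vis, cfg = scale_sweep_config()) {
  flu <- as_image_grid(flu); vis <- as_image_grid(vis)
  vis_dim <- dim(vis)
  lapply(scale_grid(cfg), function(s) {
    df <- pmax(2L, round(dim(flu) * s))
    dv <- pmax(2L, round(dim(vis) * s))
    if (min(df, dv) < cfg$min_side) {
      r <- registration_result(NULL, -Inf, FALSE, s,
                               diagnostics = list(reason = "skipped: image below min_side at this scale"),
                               vis_dim = vis_dim)
      return(r)
    }
    flu_s <- resample_to(flu, df)
    vis_s <- resample_to(vis, dv)
    res <- register_affine(flu_s, vis_s, h_threshold = cfg$h_threshold,
                           bounds = cfg$bounds)
    res$scale_factor <- s
    if (is.null(res$transform)) {
      res$vis_dim <- vis_dim
      return(res)
    }
    # map back to full resolution: T_full = S^-1 T_s S with the realized
    # per-axis factors (sx, sy)
    sx <- dv[2] / vis_dim[2]; sy <- dv[1] / vis_dim[1]
    Sm <- diag(c(sx, sy, 1))
    res$transform <- affine_transform2d(solve(Sm) %*% res$transform$matrix %*%
                                          diag(c(df[2] / dim(flu)[2],
                                                 df[1] / dim(flu)[1], 1)))
    res$vis_dim <- vis_dim
    res$valid <- validate_transform(res, cfg$bounds, cfg$h_threshold)
    res
  })
}

#' Integrate per-scale registrations into one mask
#'
#' Warps the FLU plant mask into the VIS frame by the transform of every
#' valid registration (nearest-neighbour) and combines the warped masks by
#' pixelwise union. The union compensates non-uniform leaf motion that no
#' single similarity transform captures: each locally optimal registration
#' covers a different part of the plant and the integrated mask covers them
#' all.
#'
#' @param flu_mask `binary_mask` `image_grid` in the (pre-scaled) FLU frame.
#' @param results List of `registration_result` (e.g. from
#'   [sweep_scales()]); only valid ones contribute.
#' @param vis_shape Target `(rows, cols)` of the VIS frame.
#' @param rule `"union"` (default) or `"majority"` (pixel set where more
#'   than half of the valid warps agree).
#' @return `binary_mask` `image_grid` of dimensions `vis_shape`.
#' @export
integrate_masks <- function(flu_mask, results, vis_shape,
                            rule = c("union", "majority")) {
  rule <- match.arg(rule)
  flu_mask <- as_image_grid(flu_mask, channel_kind = "binary_mask")
  valid <- Filter(function(r) isTRUE(r$valid), results)
  if (length(valid) == 0) {
    reasons <- vapply(results, function(r)
      r$diagnostics$reason %||% sprintf("H=%.4g below gate or out of bounds",
                                        r$peak_height), character(1))
    stop(structure(
      class = c("phasefuse_no_valid_registration", "error", "condition"),
      list(message = "no valid registration to integrate",
           call = sys.call(-1), diagnostics = reasons)))
  }
  acc <- matrix(0, vis_shape[1], vis_shape[2])
  for (r in valid) {
    w <- warp_image(flu_mask, r$transform, out_shape = vis_shape,
                    interpolation = "nearest")
    acc <- acc + w$pixels
  }
  m <- if (rule == "union") (acc > 0) + 0 else (acc > length(valid) / 2) + 0
  image_grid(m, modality = "VIS", channel_kind = "binary_mask")
}

#' End-to-end integrative registration
#'
#' Full pipeline on a raw FLU/VIS RGB pair: preprocess both images per the
#' configured variant, pre-scale the FLU image to the VIS height, segment
#' the FLU image (Otsu threshold, or a supplied mask) to obtain the plant
#' mask, run the scale sweep, and integrate the valid per-scale
#' registrations into a single mask in the VIS frame.
#'
#' An all-invalid sweep yields a failure outcome (`success = FALSE`,
#' `integrated_mask = NULL`) with per-scale diagnostics rather than an
#' error.
#'
#' @param flu_rgb,vis_rgb RGB `image_grid`s (single-plane inputs are used
#'   as-is).
#' @param cfg A [scale_sweep_config()].
#' @param flu_mask Optional externally supplied plant mask in the original
#'   FLU frame (pre-scaled internally); default is Otsu segmentation of the
#'   pre-scaled FLU grayscale.
#' @return A `sweep_outcome`: list with `results` (per-scale
#'   `registration_result`s), `integrated_mask`, `n_valid`, `flu_mask`
#'   (pre-scaled), `vis_dim`, `success` and the `config` used.
#' @export
register_integrative <- function(flu_rgb, vis_rgb,
                                 cfg = scale_sweep_config(),
                                 flu_mask = NULL) {
  flu_rgb <- as_image_grid(flu_rgb); vis_rgb <- as_image_grid(vis_rgb)
  prep <- function(img) {
    if (!is_rgb(img)) return(img)
    preprocess_variant(img, feature = cfg$variant,
                       background = if (cfg$filter_blue) "filtered" else "raw")
  }
  flu_p <- prep(flu_rgb)
  vis_p <- prep(vis_rgb)
  flu_p <- prescale_to_height(flu_p, vis_p$height)
  if (is.null(flu_mask)) {
    flu_gray <- if (is_rgb(flu_rgb)) to_grayscale(flu_rgb) else flu_rgb
    flu_mask <- threshold_segment(prescale_to_height(flu_gray, vis_p$height))
  } else {
    flu_mask <- as_image_grid(flu_mask, channel_kind = "binary_mask")
    flu_mask <- prescale_to_height(flu_mask, vis_p$height)
  }
  results <- sweep_scales(flu_p, vis_p, cfg)
  n_valid <- sum(vapply(results, function(r) isTRUE(r$valid), logical(1)))
  im <- NULL
  if (n_valid > 0) {
    im <- integrate_masks(flu_mask, results, dim(vis_p))
  }
  structure(
    list(results = results, integrated_mask = im, n_valid = n_valid,
         flu_mask = flu_mask, vis_dim = dim(vis_p),
         success = n_valid > 0, config = cfg),
    class = "sweep_outcome"
  )
}

#' @export
print.sweep_outcome <- function(x, ...) {
  cat(sprintf("<sweep_outcome> %d scales, %d valid, success=%s\n",
              length(x$results), x$n_valid, x$success))
  invisible(x)
}
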