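#' Synthetic multi-modal scene specification
#'
#' Describes a plant-like scene rendered into a FLU/VIS image pair with
#' exact ground truth. The plant is a rosette of filled elliptical leaves
#' attached to a common base point (optionally plus a thin stem rectangle),
#' laid out in the VIS frame. The FLU view is the same geometry mapped
#' through the inverse of `global_transform` onto a smaller canvas
#' (emulating the lower FLU camera resolution); the VIS view additionally
#' applies per-leaf extra rotations about each leaf base (non-uniform leaf
#' motion, a non-rigid effect no single similarity transform captures) and
#' contains background structures present only in that modality (carrier
#' edge lines, an illumination gradient, optionally a blue mat).
#'
#' @param canvas_shape VIS canvas `(rows, cols)`.
#' @param flu_scale Linear size of the FLU canvas relative to VIS (default
#'   0.6, echoing the typical FLU/VIS camera resolution gap).
#' @param leaves Data frame with one row per leaf: columns `angle_deg`
#'   (direction from the plant centre), `length`, `width` (ellipse axes in
#'   VIS pixels) and `motion_deg` (extra VIS-only rotation about the leaf
#'   base).
#' @param center Plant centre `(x, y)` in VIS pixels.
#' @param stem `NULL` or `c(width, height)` of a thin vertical stem
#'   rectangle rising from the centre.
#' @param rel_scale,rot_deg,shift VIS-frame residual similarity of the true
#'   FLU-to-VIS transform beyond the canvas resolution ratio: after
#'   pre-scaling the FLU image to the VIS height, the remaining
#'   misalignment is approximately this scale/rotation/shift.
#' @param clutter Number of VIS-only high-contrast carrier-edge lines.
#' @param blue_mat Use a blue mat background in VIS (exercises blue-pixel
#'   removal).
#' @param noise_sigma Additive Gaussian noise level on both images.
#' @param seed Integer seed fixing all generator randomness.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(canvas_shape = c(180, 180), flu_scale = 0.6,
                       leaves = default_leaves(), center = NULL,
                       stem = NULL, rel_scale = 1, rot_deg = 0,
                       shift = c(0, 0), clutter = 2, blue_mat = FALSE,
                       noise_sigma = 0.05, seed = 1) {
  if (is.null(center)) center <- c((canvas_shape[2] - 1) / 2,
                                   (canvas_shape[1] - 1) / 2)
  stopifnot(is.data.frame(leaves),
            all(c("angle_deg", "length", "width", "motion_deg") %in%
                  names(leaves)))
  structure(
    list(canvas_shape = canvas_shape, flu_scale = flu_scale,
         leaves = leaves, center = center, stem = stem,
         rel_scale = rel_scale, rot_deg = rot_deg, shift = shift,
         clutter = clutter, blue_mat = blue_mat,
         noise_sigma = noise_sigma, seed = as.integer(seed)),
    class = "scene_spec"
  )
}

default_leaves <- function(n = 5) {
  tibble::tibble(
    angle_deg = seq(0, 360, length.out = n + 1)[seq_len(n)] + 18,
    length = c(52, 44, 58, 40, 48)[((seq_len(n) - 1) %% 5) + 1],
    width = c(20, 16, 22, 15, 18)[((seq_len(n) - 1) %% 5) + 1],
    motion_deg = 0)
}

# Ellipse description: list(center = c(x, y), axes = c(a, b), phi_deg).
leaf_ellipses <- function(spec, frame = c("vis_ideal", "vis", "flu")) {
  frame <- match.arg(frame)
  G <- true_transform(spec)
  lv <- spec$leaves
  base_vis <- spec$center
  out <- lapply(seq_len(nrow(lv)), function(i) {
    a <- lv$angle_deg[i] * pi / 180
    ctr <- base_vis + lv$length[i] / 2 * c(cos(a), sin(a))
    e <- list(center = ctr, axes = c(lv$length[i] / 2, lv$width[i] / 2),
              phi_deg = lv$angle_deg[i], base = base_vis)
    if (frame == "vis" && lv$motion_deg[i] != 0) {
      e <- rotate_ellipse_about(e, e$base, lv$motion_deg[i])
    }
    if (frame == "flu") e <- map_ellipse(e, invert_transform(G))
    e
  })
  out
}

rotate_ellipse_about <- function(e, pivot, deg) {
  th <- deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  e$center <- as.vector(pivot + R %*% (e$center - pivot))
  e$phi_deg <- e$phi_deg + deg
  e
}

map_ellipse <- function(e, tr) {
  e$center <- as.vector(apply_transform(tr, e$center))
  e$base <- as.vector(apply_transform(tr, e$base))
  e$axes <- e$axes * tr$scale
  e$phi_deg <- e$phi_deg + tr$rotation_deg
  e
}

#' Ground-truth FLU-to-VIS transform of a scene
#'
#' Similarity mapping FLU pixel coordinates onto VIS pixel coordinates:
#' the canvas resolution ratio times the residual `rel_scale` / `rot_deg` /
#' `shift` of the spec, about the VIS plant centre.
#'
#' @param spec A `scene_spec`.
#' @return An `affine_transform2d`.
#' @export
true_transform <- function(spec) {
  flu_shape <- round(spec$canvas_shape * spec$flu_scale)
  s_canvas <- spec$canvas_shape[1] / flu_shape[1]
  # FLU coords -> nominal VIS coords (pure canvas upscaling about origin),
  # then the residual similarity about the plant centre
  up <- similarity_transform(scale = s_canvas)
  resid <- similarity_transform(scale = spec$rel_scale,
                                rotation_deg = spec$rot_deg,
                                shift_x = spec$shift[1],
                                shift_y = spec$shift[2],
                                center = spec$center)
  compose_transforms(resid, up)
}

render_mask <- function(shape, ellipses, stem_rect = NULL) {
  nr <- shape[1]; nc <- shape[2]
  xs <- matrix(rep(seq_len(nc) - 1, each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr) - 1, times = nc), nr, nc)
  m <- matrix(0, nr, nc)
  for (e in ellipses) {
    th <- e$phi_deg * pi / 180
    dx <- xs - e$center[1]; dy <- ys - e$center[2]
    u <- (dx * cos(th) + dy * sin(th)) / e$axes[1]
    v <- (-dx * sin(th) + dy * cos(th)) / e$axes[2]
    m[u^2 + v^2 <= 1] <- 1
  }
  if (!is.null(stem_rect)) {
    m[xs >= stem_rect$x0 & xs <= stem_rect$x1 &
        ys >= stem_rect$y0 & ys <= stem_rect$y1] <- 1
  }
  m
}

stem_rect_for <- function(spec, frame) {
  if (is.null(spec$stem)) return(NULL)
  w <- spec$stem[1]; h <- spec$stem[2]
  ctr <- spec$center
  r <- list(x0 = ctr[1] - w / 2, x1 = ctr[1] + w / 2,
            y0 = ctr[2] - h / 2, y1 = ctr[2] + h / 2)
  if (frame == "flu") {
    Ginv <- invert_transform(true_transform(spec))
    p0 <- apply_transform(Ginv, c(r$x0, r$y0))
    p1 <- apply_transform(Ginv, c(r$x1, r$y1))
    r <- list(x0 = min(p0[1], p1[1]), x1 = max(p0[1], p1[1]),
              y0 = min(p0[2], p1[2]), y1 = max(p0[2], p1[2]))
  }
  r
}

#' Generate a synthetic FLU/VIS pair with ground truth
#'
#' Renders the scene into a high-contrast FLU image (bright plant on a dark
#' chlorophyll-free background), a VIS image (green plant on a mat
#' background with VIS-only clutter: carrier-edge lines and a smooth
#' illumination gradient), the exact binary plant masks of both frames, and
#' the true FLU-to-VIS transform. All randomness (noise, clutter placement)
#' derives from `spec$seed`; regeneration is bit-identical and the caller's
#' RNG state is left untouched.
#'
#' @param spec A [scene_spec()].
#' @return A `synthetic_pair`: list with `flu`, `vis` (rgb `image_grid`s),
#'   `flu_mask`, `vis_mask`, `true_transform`, `spec`.
#' @export
generate_pair <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  flu_shape <- round(spec$canvas_shape * spec$flu_scale)
  vis_shape <- spec$canvas_shape
  e_flu <- leaf_ellipses(spec, "flu")
  e_vis <- leaf_ellipses(spec, "vis")
  ok <- function(es, shape) all(vapply(es, function(e) {
    e$center[1] >= 0 && e$center[1] <= shape[2] - 1 &&
      e$center[2] >= 0 && e$center[2] <= shape[1] - 1
  }, logical(1)))
  if (!ok(e_flu, flu_shape) || !ok(e_vis, vis_shape))
    stop("scene spec places leaves outside the canvas", call. = FALSE)
  flu_mask <- render_mask(flu_shape, e_flu, stem_rect_for(spec, "flu"))
  vis_mask <- render_mask(vis_shape, e_vis, stem_rect_for(spec, "vis"))
  withr::with_seed(spec$seed, {
    nz <- spec$noise_sigma
    # FLU: strong chlorophyll fluorescence signal, dark background
    shade <- 1 - 0.25 * ((matrix(rep(seq_len(flu_shape[2]) - 1,
                                     each = flu_shape[1]),
                                 flu_shape[1], flu_shape[2])) /
                           max(1, flu_shape[2] - 1))
    flu <- array(0, c(flu_shape, 3))
    flu[, , 1] <- 0.04 + 0.86 * flu_mask * shade
    flu[, , 2] <- 0.03 + 0.30 * flu_mask * shade
    flu[, , 3] <- 0.03 + 0.08 * flu_mask
    if (nz > 0) flu <- flu + array(stats::rnorm(length(flu), 0, nz), dim(flu))
    # VIS: mat background + illumination gradient + carrier edges + plant
    vis <- array(0, c(vis_shape, 3))
    bg <- if (spec$blue_mat) c(0.25, 0.35, 0.78) else c(0.45, 0.44, 0.42)
    gx <- matrix(rep(seq_len(vis_shape[2]) - 1, each = vis_shape[1]),
                 vis_shape[1], vis_shape[2]) / max(1, vis_shape[2] - 1)
    gy <- matrix(rep(seq_len(vis_shape[1]) - 1, times = vis_shape[2]),
                 vis_shape[1], vis_shape[2]) / max(1, vis_shape[1] - 1)
    grad <- 0.10 * (gx + gy) / 2
    for (k in 1:3) vis[, , k] <- bg[k] + grad
    if (spec$clutter > 0) {
      for (j in seq_len(spec$clutter)) {
        horizontal <- stats::runif(1) < 0.5
        pos <- 1 + floor(stats::runif(1) * 0.9 *
                           vis_shape[if (horizontal) 1 else 2])
        wdt <- sample(2:3, 1)
        lvl <- if (stats::runif(1) < 0.5) 0.05 else 0.92
        idx <- pos:min(pos + wdt - 1,
                       vis_shape[if (horizontal) 1 else 2])
        for (k in 1:3) {
          if (horizontal) vis[idx, , k] <- lvl else vis[, idx, k] <- lvl
        }
      }
    }
    leafshade <- 0.75 + 0.25 * (1 - gx)
    plant_col <- c(0.20, 0.52, 0.24)
    for (k in 1:3) {
      vis[, , k] <- vis[, , k] * (1 - vis_mask) +
        vis_mask * plant_col[k] * leafshade
    }
    if (nz > 0) vis <- vis + array(stats::rnorm(length(vis), 0, nz), dim(vis))
    flu <- clamp01(flu); vis <- clamp01(vis)
  })
  structure(
    list(flu = image_grid(flu, modality = "FLU", channel_kind = "rgb"),
         vis = image_grid(vis, modality = "VIS", channel_kind = "rgb"),
         flu_mask = image_grid(flu_mask, modality = "FLU",
                               channel_kind = "binary_mask"),
         vis_mask = image_grid(vis_mask, modality = "VIS",
                               channel_kind = "binary_mask"),
         true_transform = true_transform(spec), spec = spec),
    class = "synthetic_pair"
  )
}

#' @export
print.synthetic_pair <- function(x, ...) {
  cat(sprintf("<synthetic_pair> FLU %dx%d / VIS %dx%d  %d leaves  seed=%d\n",
              x$flu$height, x$flu$width, x$vis$height, x$vis$width,
              nrow(x$spec$leaves), x$spec$seed))
  invisible(x)
}

#' Named difficulty presets
#'
#' Reproducible scene specifications spanning the difficulty axes observed
#' in multi-modal phenotyping imagery: `adult_structured` (well-developed
#' rosette with distinct leaves), `young_thin_line` (a thin near-vertical
#' shoot of non-specific shape, the hard case for phase correlation),
#' `rosette_selfsimilar` (several near-identical leaves causing ambiguous
#' correlation peaks), `nonuniform_motion` (two of five leaves rotated by
#' up to +/- 10 degrees between the exposures), and `cluttered_vis` (heavy
#' VIS-only background structure).
#'
#' @param name Preset name.
#' @param seed Integer seed; jitters leaf geometry and the residual
#'   transform reproducibly, so a batch over seeds yields a population of
#'   comparable scenes.
#' @param canvas_shape VIS canvas, default `c(180, 180)`.
#' @return A `scene_spec`.
#' @export
scene_preset <- function(name = c("adult_structured", "young_thin_line",
                                  "rosette_selfsimilar", "nonuniform_motion",
                                  "cluttered_vis"),
                         seed = 1, canvas_shape = c(180, 180)) {
  name <- match.arg(name)
  withr::with_seed(seed + 211L, {
    jit <- function(x, a) x + stats::runif(length(x), -a, a)
    resid <- list(rel_scale = stats::runif(1, 0.96, 1.04),
                  rot_deg = stats::runif(1, -3, 3),
                  shift = stats::runif(2, -8, 8))
    lv <- default_leaves()
    lv$angle_deg <- jit(lv$angle_deg, 12)
    lv$length <- jit(lv$length, 5)
    lv$width <- jit(lv$width, 2)
    spec <- switch(
      name,
      adult_structured = scene_spec(
        canvas_shape = canvas_shape, leaves = lv, clutter = 2,
        rel_scale = resid$rel_scale, rot_deg = resid$rot_deg,
        shift = resid$shift, noise_sigma = 0.05, seed = seed),
      young_thin_line = {
        thin <- lv[0, ]
        scene_spec(
          canvas_shape = canvas_shape, leaves = thin,
          stem = c(3 * canvas_shape[1] / 108, 70 * canvas_shape[1] / 180),
          clutter = 3, rel_scale = resid$rel_scale,
          rot_deg = resid$rot_deg, shift = resid$shift,
          noise_sigma = 0.05, seed = seed)
      },
      rosette_selfsimilar = {
        lv$length <- rep(mean(lv$length), nrow(lv))
        lv$width <- rep(mean(lv$width), nrow(lv))
        scene_spec(
          canvas_shape = canvas_shape, leaves = lv, clutter = 2,
          rel_scale = resid$rel_scale, rot_deg = resid$rot_deg,
          shift = resid$shift, noise_sigma = 0.05, seed = seed)
      },
      nonuniform_motion = {
        moving <- sample(nrow(lv), 2)
        lv$motion_deg[moving] <- stats::runif(2, 5, 10) *
          sample(c(-1, 1), 2, replace = TRUE)
        scene_spec(
          canvas_shape = canvas_shape, leaves = lv, clutter = 2,
          rel_scale = resid$rel_scale, rot_deg = resid$rot_deg,
          shift = resid$shift, noise_sigma = 0.05, seed = seed)
      },
      cluttered_vis = scene_spec(
        canvas_shape = canvas_shape, leaves = lv, clutter = 6,
        blue_mat = TRUE, rel_scale = resid$rel_scale,
        rot_deg = resid$rot_deg, shift = resid$shift,
        noise_sigma = 0.05, seed = seed)
    )
    spec
  })
}

#' All difficulty presets for one seed
#'
#' @param seed Integer seed passed to every preset.
#' @param canvas_shape VIS canvas.
#' @return Named list of `scene_spec`s.
#' @export
difficulty_presets <- function(seed = 1, canvas_shape = c(180, 180)) {
  names <- c("adult_structured", "young_thin_line", "rosette_selfsimilar",
             "nonuniform_motion", "cluttered_vis")
  stats::setNames(lapply(names, scene_preset, seed = seed,
                         canvas_shape = canvas_shape), names)
}
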