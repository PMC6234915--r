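#' Log-polar resampling of the Fourier magnitude spectrum
#'
#' Applies a Hann window, takes the centred FFT magnitude, suppresses the
#' low-frequency core with a radially symmetric high-emphasis filter
#' `(1 - X)(2 - X)` with `X = cos(pi xi) cos(pi eta)`, and resamples the
#' result onto a log-polar grid (rows = angle over `[0, 180)` degrees,
#' columns = log-radius). Because the magnitude spectrum is invariant to
#' translation, a rotation of the input becomes a circular shift along the
#' angle axis and an isotropic scaling a shift along the log-radius axis,
#' which a second phase correlation can then measure.
#'
#' @param img Single-plane image (`image_grid` or matrix).
#' @param n_theta Number of angle bins; default `2 * max(dim)` so one bin
#'   spans `90 / max(dim)` degrees.
#' @param n_r Number of log-radius bins; default `max(dim)`.
#' @return An `image_grid` (channel kind `"gray"`) of size
#'   `n_theta x n_r`, rescaled to `[0, 1]`, with attributes `log_base`
#'   (radius ratio between adjacent bins) and `theta_bin_deg`.
#' @export
logpolar_magnitude <- function(img, n_theta = NULL, n_r = NULL) {
  m <- pixel_matrix(as_image_grid(img))
  if (all(m == 0)) stop("degenerate input: all-zero image", call. = FALSE)
  nr <- nrow(m); nc <- ncol(m)
  mag <- Mod(stats::fft(m * hann2d(nr, nc)))
  mag <- circshift(mag, floor(nr / 2), floor(nc / 2))  # DC to the centre
  eta <- (seq_len(nr) - 1 - floor(nr / 2)) / nr
  xi <- (seq_len(nc) - 1 - floor(nc / 2)) / nc
  X <- cos(pi * eta) %o% cos(pi * xi)
  mag <- mag * (1 - X) * (2 - X)
  if (is.null(n_theta)) n_theta <- 2L * max(nr, nc)
  if (is.null(n_r)) n_r <- max(2L, max(nr, nc))
  r_max <- min(nr, nc) / 2
  base <- r_max^(1 / (n_r - 1))
  cy <- floor(nr / 2); cx <- floor(nc / 2)  # 0-based centre after the shift
  theta <- pi * (seq_len(n_theta) - 1) / n_theta
  radius <- base^(seq_len(n_r) - 1)
  xs <- cx + outer(cos(theta), radius)
  ys <- cy + outer(sin(theta), radius)
  lp <- base::matrix(bilinear_sample(mag, as.vector(xs), as.vector(ys)),
                     n_theta, n_r)
  rng <- range(lp)
  lp <- if (diff(rng) > 0) (lp - rng[1]) / diff(rng) else lp * 0
  out <- image_grid(lp, modality = "synthetic", channel_kind = "gray")
  attr(out, "log_base") <- base
  attr(out, "theta_bin_deg") <- 180 / n_theta
  out
}

# k highest local maxima of a correlation surface (3x3-neighbourhood
# maxima, circular indexing), as (row, col, height), strongest first.
top_peaks <- function(surf, k = 3) {
  nr <- nrow(surf); nc <- ncol(surf)
  is_max <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    is_max <- is_max & (surf >= circshift(surf, dr, dc))
  }
  idx <- which(is_max)
  ord <- order(surf[idx], decreasing = TRUE)
  idx <- idx[ord][seq_len(min(k, length(idx)))]
  data.frame(row = (idx - 1) %% nr + 1, col = (idx - 1) %/% nr + 1,
             height = surf[idx])
}

# Full rotation/scale/translation chain on padded single-plane matrices.
# The log-polar correlation of structurally non-identical images is noisy:
# besides the half-plane 180-degree ambiguity, the global maximum may sit
# on a background-driven alignment. The top `n_peaks` local maxima are
# therefore each expanded into both rotation candidates and scored by the
# height of their subsequent translation-stage correlation peak; the best
# scoring candidate wins.
fm_orient <- function(a, b, n_theta = NULL, n_r = NULL, n_peaks = 5) {
  lp_a <- logpolar_magnitude(a, n_theta, n_r)
  lp_b <- logpolar_magnitude(b, n_theta, n_r)
  ps <- phase_correlation(lp_a, lp_b)
  base <- attr(lp_a, "log_base")
  bin_deg <- attr(lp_a, "theta_bin_deg")
  nth <- nrow(ps$values); nrad <- ncol(ps$values)
  pk <- top_peaks(ps$values, n_peaks)
  center <- c((ncol(a) - 1) / 2, (nrow(a) - 1) / 2)
  candidates <- list()
  for (i in seq_len(nrow(pk))) {
    dth <- pk$row[i] - 1; if (dth > nth / 2) dth <- dth - nth
    drad <- pk$col[i] - 1; if (drad > nrad / 2) drad <- drad - nrad
    rot_i <- dth * bin_deg                  # angle axis is rows
    scl_i <- base^(-drad)                   # log-radius axis is columns
    if (scl_i < 0.2 || scl_i > 5) next      # physically implausible spectra
    for (th in c(rot_i, rot_i + 180)) {
      th <- ((th + 180) %% 360) - 180
      rs <- similarity_transform(scale = scl_i, rotation_deg = th,
                                 center = center)
      warped <- warp_image(image_grid(a), rs, out_shape = dim(a),
                           interpolation = "bilinear")
      pt <- tryCatch(phase_correlation(warped, b, window = TRUE),
                     error = function(e) NULL)
      candidates[[length(candidates) + 1]] <-
        list(rotation_deg = th, scale = scl_i, transform_rs = rs, pc = pt,
             H = if (is.null(pt)) -Inf else pt$peak_height)
    }
  }
  if (length(candidates) == 0)
    stop("no admissible rotation/scale candidate", call. = FALSE)
  Hs <- vapply(candidates, `[[`, numeric(1), "H")
  best <- candidates[[which.max(Hs)]]
  list(rotation_deg = unname(best$rotation_deg), scale = unname(best$scale),
       H_rs = ps$peak_height, best = best, candidates = candidates,
       H_candidates = Hs, center = center)
}

#' Estimate relative rotation and isotropic scale
#'
#' Phase-correlates the log-polar magnitude spectra of `A` and `B`. The
#' half-plane angle axis leaves a 180-degree ambiguity, which is resolved by
#' testing both candidate rotations and keeping the one whose subsequent
#' translation-stage phase-correlation peak is higher.
#'
#' @param A,B Single-plane images of equal dimensions.
#' @inheritParams logpolar_magnitude
#' @return List with `rotation_deg`, `scale`, and `H_rs` (the log-polar PC
#'   peak height).
#' @export
estimate_rotation_scale <- function(A, B, n_theta = NULL, n_r = NULL) {
  a <- pixel_matrix(as_image_grid(A)); b <- pixel_matrix(as_image_grid(B))
  if (!identical(dim(a), dim(b)))
    stop("rotation/scale estimation needs images of equal dimensions",
         call. = FALSE)
  o <- fm_orient(a, b, n_theta, n_r)
  list(rotation_deg = o$rotation_deg, scale = o$scale, H_rs = o$H_rs)
}

#' Registration validity bounds
#'
#' Default admissibility bounds on the recovered similarity transform used
#' by the validity gate alongside the peak-height threshold. The defaults
#' are package choices for "reasonable" plant-imaging transforms and are
#' fully configurable.
#'
#' @param scale_min,scale_max Admissible isotropic scale range.
#' @param rot_max_deg Maximum absolute rotation, degrees.
#' @param shift_max_frac Maximum displacement of the image centre as a
#'   fraction of the larger image side.
#' @return Named list of bounds.
#' @export
default_bounds <- function(scale_min = 0.5, scale_max = 2.0,
                           rot_max_deg = 30, shift_max_frac = 0.5) {
  list(scale_min = scale_min, scale_max = scale_max,
       rot_max_deg = rot_max_deg, shift_max_frac = shift_max_frac)
}

#' Validity gate for a registration
#'
#' A registration is accepted iff its translation-stage peak height exceeds
#' `h_threshold` (strict inequality; default 0.03) and the recovered
#' similarity parameters lie within the admissibility bounds: scale within
#' `[scale_min, scale_max]`, absolute rotation at most `rot_max_deg`, and
#' displacement of the image centre at most `shift_max_frac` times the
#' larger side of the target image. Low peaks typically indicate that phase
#' correlation failed, e.g. for structurally dissimilar content.
#'
#' @param result A `registration_result` (or a list with `transform`,
#'   `peak_height` and `vis_dim`).
#' @param bounds See [default_bounds()].
#' @param h_threshold Minimum admissible peak height (strict).
#' @return Logical.
#' @export
validate_transform <- function(result, bounds = default_bounds(),
                               h_threshold = 0.03) {
  tr <- result$transform
  if (is.null(tr)) return(FALSE)
  h <- result$peak_height
  if (!is.finite(h) || h <= h_threshold) return(FALSE)
  if (!all(is.finite(tr$matrix))) return(FALSE)
  if (tr$scale < bounds$scale_min || tr$scale > bounds$scale_max) return(FALSE)
  if (abs(tr$rotation_deg) > bounds$rot_max_deg) return(FALSE)
  dim_ref <- result$vis_dim
  if (is.null(dim_ref)) dim_ref <- c(2, 2) / bounds$shift_max_frac
  ctr <- c((dim_ref[2] - 1) / 2, (dim_ref[1] - 1) / 2)
  disp <- apply_transform(tr, ctr) - ctr
  max(abs(disp)) <= bounds$shift_max_frac * max(dim_ref)
}

# Construct a registration_result.
registration_result <- function(transform, peak_height, valid,
                                scale_factor = 1, diagnostics = list(),
                                vis_dim = NULL) {
  structure(
    list(transform = transform, peak_height = peak_height, valid = valid,
         scale_factor = scale_factor, diagnostics = diagnostics,
         vis_dim = vis_dim),
    class = "registration_result"
  )
}

#' @export
print.registration_result <- function(x, ...) {
  if (is.null(x$transform)) {
    cat(sprintf("<registration_result> FAILED (%s)\n",
                x$diagnostics$reason %||% "unknown"))
  } else {
    cat(sprintf(
      "<registration_result> H=%.4f valid=%s scale_factor=%.2f  %s\n",
      x$peak_height, x$valid, x$scale_factor,
      sprintf("scale=%.3f rot=%.2f shift=(%.1f, %.1f)",
              x$transform$scale, x$transform$rotation_deg,
              x$transform$shift_x, x$transform$shift_y)))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Single-step Fourier-Mellin registration
#'
#' Full similarity-registration chain mapping a (pre-scaled, single-plane)
#' FLU image into the VIS frame: both images are zero-padded to a common
#' FFT-friendly size (top-left anchored, so pixel coordinates are
#' preserved), relative rotation and isotropic scale are recovered from
#' phase correlation of log-polar spectral magnitudes, the FLU image is
#' unrotated/unscaled, and the residual translation is recovered by a
#' Cartesian phase correlation. The reported peak height `H` is the
#' translation-stage peak; the `valid` flag applies [validate_transform()].
#'
#' Degenerate inputs or a non-finite transform yield a failure result with
#' `valid = FALSE` rather than an error.
#'
#' @param flu,vis Single-plane images; `flu` is mapped into the frame of
#'   `vis`.
#' @param h_threshold,bounds Gate parameters, see [validate_transform()].
#' @param n_theta,n_r Log-polar grid resolution, see
#'   [logpolar_magnitude()].
#' @return A `registration_result` whose `transform` maps FLU pixel
#'   coordinates to VIS pixel coordinates.
#' @export
register_affine <- function(flu, vis, h_threshold = 0.03,
                            bounds = default_bounds(),
                            n_theta = NULL, n_r = NULL) {
  flu <- as_image_grid(flu); vis <- as_image_grid(vis)
  a <- pixel_matrix(flu); b <- pixel_matrix(vis)
  vis_dim <- dim(b)
  fail <- function(reason, diag = list()) {
    registration_result(NULL, -Inf, FALSE, 1,
                        diagnostics = c(list(reason = reason), diag),
                        vis_dim = vis_dim)
  }
  p <- pad_to_common(a, b)
  o <- tryCatch(fm_orient(p$a, p$b, n_theta, n_r),
                error = function(e) conditionMessage(e))
  if (is.character(o)) return(fail(o))
  # compose each scored candidate; prefer the highest-H one that passes
  # the admissibility bounds, else fall back to the overall best peak
  scored <- list()
  for (cand in o$candidates) {
    if (is.null(cand$pc)) next
    sh <- cand$pc$shift
    tr <- tryCatch(
      compose_transforms(
        similarity_transform(shift_x = sh["dx"], shift_y = sh["dy"]),
        cand$transform_rs),
      error = function(e) NULL)
    if (is.null(tr)) next
    r <- registration_result(tr, cand$H, FALSE, 1, vis_dim = vis_dim)
    r$valid <- validate_transform(r, bounds, h_threshold)
    scored[[length(scored) + 1]] <- r
  }
  if (length(scored) == 0) return(fail("translation stage degenerate"))
  Hs <- vapply(scored, `[[`, numeric(1), "peak_height")
  ok <- vapply(scored, `[[`, logical(1), "valid")
  res <- if (any(ok)) scored[[which(ok)[which.max(Hs[ok])]]]
         else scored[[which.max(Hs)]]
  res$diagnostics <- list(H_rs = o$H_rs, H_candidates = o$H_candidates)
  res
}
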