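#' Normalized cross-power spectrum
#'
#' Elementwise `alpha * Conj(beta) / |alpha * Conj(beta)|` of two equally
#' sized complex spectra. Where the modulus falls below `eps` the output is
#' set to 0 instead of dividing by (near) zero; everywhere else the result
#' has unit modulus.
#'
#' @param alpha,beta Complex matrices of equal dimensions (2-D DFTs).
#' @param eps Modulus guard; entries with `|alpha * Conj(beta)| < eps`
#'   become 0.
#' @return Complex matrix of the same dimensions.
#' @export
cross_power_spectrum <- function(alpha, beta, eps = 1e-12) {
  if (!identical(dim(alpha), dim(beta)))
    stop("spectra entering a cross-power spectrum must have equal dimensions",
         call. = FALSE)
  prod <- alpha * Conj(beta)
  mod <- Mod(prod)
  out <- prod
  small <- mod < eps
  out[!small] <- prod[!small] / mod[!small]
  out[small] <- 0 + 0i
  out
}

# Separable 2-D Hann (raised cosine) window.
hann_window <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / (n - 1))
}

hann2d <- function(nr, nc) outer(hann_window(nr), hann_window(nc))

#' Phase correlation of two equally sized images
#'
#' Computes the inverse Fourier transform of the normalized cross-power
#' spectrum of `A` and `B`. For two structurally identical images related by
#' a circular shift the surface is a delta at that shift; the global maximum
#' localizes the relative translation and its value `H` (the peak height)
#' serves as a reliability score. The normalization is chosen so that
#' identical images give `H = 1`; the default `H > 0.03` registration gate
#' refers to this scaling.
#'
#' The reported shift `(dx, dy)` satisfies "B is A moved right by dx and
#' down by dy", wrapped into the signed range (|dx| <= width/2,
#' |dy| <= height/2). Ties on the maximum resolve to the smallest
#' `(row, col)` in lexicographic order.
#'
#' @param A,B Single-plane images (`image_grid` or matrix) of equal size.
#' @param window Apply a Hann window to both images before the FFTs
#'   (default `FALSE`; the registration chain enables it to suppress
#'   wrap-around edges of non-periodic scenes).
#' @param subpixel Refine the peak with a 3 x 3 centre-of-mass around the
#'   integer maximum (default `FALSE`).
#' @param eps Modulus guard passed to [cross_power_spectrum()].
#' @return A `correlation_surface`: list with `values`, `peak_row`,
#'   `peak_col` (1-based), `peak_height`, and `shift = c(dx, dy)`.
#' @export
phase_correlation <- function(A, B, window = FALSE, subpixel = FALSE,
                              eps = 1e-12) {
  a <- pixel_matrix(as_image_grid(A))
  b <- pixel_matrix(as_image_grid(B))
  if (!identical(dim(a), dim(b)))
    stop("phase correlation needs images of equal dimensions", call. = FALSE)
  if (all(a == 0) || all(b == 0))
    stop("degenerate input: all-zero image", call. = FALSE)
  if (window) {
    w <- hann2d(nrow(a), ncol(a))
    a <- a * w
    b <- b * w
    if (all(a == 0) || all(b == 0))
      stop("degenerate input: image vanishes under the window", call. = FALSE)
  }
  # Conj(F(A)) * F(B) puts the delta at the forward shift of B relative to A
  cps <- cross_power_spectrum(stats::fft(b), stats::fft(a), eps = eps)
  surf <- Re(stats::fft(cps, inverse = TRUE)) / length(cps)
  nr <- nrow(surf); nc <- ncol(surf)
  hmax <- max(surf)
  idx <- which(surf == hmax)
  rows <- (idx - 1) %% nr + 1
  cols <- (idx - 1) %/% nr + 1
  pick <- order(rows, cols)[1]
  pr <- rows[pick]; pc <- cols[pick]
  dy <- pr - 1; dx <- pc - 1
  if (subpixel) {
    com <- peak_center_of_mass(surf, pr, pc)
    dy <- com[1] - 1; dx <- com[2] - 1
  }
  if (dy > nr / 2) dy <- dy - nr
  if (dx > nc / 2) dx <- dx - nc
  structure(
    list(values = surf, peak_row = pr, peak_col = pc,
         peak_height = hmax, shift = c(dx = dx, dy = dy)),
    class = "correlation_surface"
  )
}

#' @export
print.correlation_surface <- function(x, ...) {
  cat(sprintf("<correlation_surface> %d x %d  peak H=%.4f at shift (%.2f, %.2f)\n",
              nrow(x$values), ncol(x$values), x$peak_height,
              x$shift[1], x$shift[2]))
  invisible(x)
}

# 3x3 centre-of-mass refinement around an integer peak (circular indexing).
peak_center_of_mass <- function(surf, pr, pc) {
  nr <- nrow(surf); nc <- ncol(surf)
  rr <- ((pr - 2):(pr)) %% nr + 1
  cc <- ((pc - 2):(pc)) %% nc + 1
  w <- pmax(surf[rr, cc], 0)
  if (sum(w) == 0) return(c(pr, pc))
  dr <- sum(rowSums(w) * (-1:1)) / sum(w)
  dc <- sum(colSums(w) * (-1:1)) / sum(w)
  c(pr + dr, pc + dc)
}

# Pad two single-plane images to a common FFT-friendly size (multiples of
# 2/3/5 at least the elementwise max of the two shapes), top-left anchored.
pad_to_common <- function(a, b) {
  nr <- stats::nextn(max(nrow(a), nrow(b)), c(2, 3, 5))
  nc <- stats::nextn(max(ncol(a), ncol(b)), c(2, 3, 5))
  list(a = pad_topleft(a, nr, nc), b = pad_topleft(b, nr, nc))
}
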