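# Shared deterministic fixtures. Registration tests need edge-rich,
# rotation-asymmetric content; a small rosette of ellipses provides that.

plant_fixture <- function(n = 128, ctr = c(0.47, 0.52) * n) {
  xs <- matrix(rep(0:(n - 1), each = n), n, n)
  ys <- t(xs)
  m <- matrix(0, n, n)
  lens <- c(38, 30, 42, 28, 34) * n / 128
  wids <- c(13, 10, 15, 9, 12) * n / 128
  for (i in 1:5) {
    a <- (i * 72 + 20) * pi / 180
    len <- lens[i] / 2; wd <- wids[i] / 2
    cx <- ctr[1] + len * cos(a); cy <- ctr[2] + len * sin(a)
    u <- ((xs - cx) * cos(a) + (ys - cy) * sin(a)) / len
    v <- (-(xs - cx) * sin(a) + (ys - cy) * cos(a)) / wd
    m[u^2 + v^2 <= 1] <- 1
  }
  pmin(pmax(0.05 + 0.85 * m, 0), 1)
}

# small deterministic RGB raster with distinct channel values
rgb_fixture <- function(nr = 4, nc = 5, seed = 1) {
  withr::with_seed(seed, {
    array(round(stats::runif(nr * nc * 3), 3), c(nr, nc, 3))
  })
}

# forward-warp a fixture by a similarity and clip, as a ground-truth pair
warped_pair <- function(img, scale = 1, rotation_deg = 0,
                        shift_x = 0, shift_y = 0) {
  n <- nrow(img)
  ctr <- c((ncol(img) - 1) / 2, (n - 1) / 2)
  tr <- similarity_transform(scale = scale, rotation_deg = rotation_deg,
                             shift_x = shift_x, shift_y = shift_y,
                             center = ctr)
  list(A = img,
       B = warp_image(image_grid(img), tr, interpolation = "bilinear")$pixels,
       transform = tr, center = ctr)
}

# brute-force circular cross-correlation argmax (independent spatial oracle)
ncc_argmax <- function(A, B) {
  nr <- nrow(A); nc <- ncol(A)
  best <- -Inf; arg <- c(0, 0)
  for (dy in 0:(nr - 1)) {
    for (dx in 0:(nc - 1)) {
      v <- sum(A * phasefuse:::circshift(B, -dy, -dx))
      if (v > best) {
        best <- v
        arg <- c(dx, dy)
      }
    }
  }
  if (arg[1] > nc / 2) arg[1] <- arg[1] - nc
  if (arg[2] > nr / 2) arg[2] <- arg[2] - nr
  arg
}

expect_transform_close <- function(est, true, pts, tol_px) {
  err <- max(abs(apply_transform(est, pts) - apply_transform(true, pts)))
  expect_lt(err, tol_px)
}
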