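test_that("grayscale conversion applies the documented luminance weights", {
  # uniform extremes
  white <- image_grid(array(1, c(4, 4, 3)), channel_kind = "rgb")
  black <- image_grid(array(0, c(4, 4, 3)), channel_kind = "rgb")
  expect_equal(to_grayscale(white)$pixels, matrix(1, 4, 4))
  expect_equal(to_grayscale(black)$pixels, matrix(0, 4, 4))
  # 2x2 raster, hand-computed weighted sums (0.299, 0.587, 0.114)
  a <- array(0, c(2, 2, 3))
  a[, , 1] <- matrix(c(1, 0.2, 0, 0.5), 2, 2)
  a[, , 2] <- matrix(c(0, 0.4, 1, 0.5), 2, 2)
  a[, , 3] <- matrix(c(0, 0.6, 0, 1.0), 2, 2)
  expected <- matrix(c(0.299 * 1,
                       0.299 * 0.2 + 0.587 * 0.4 + 0.114 * 0.6,
                       0.587 * 1,
                       0.299 * 0.5 + 0.587 * 0.5 + 0.114 * 1), 2, 2)
  expect_equal(to_grayscale(image_grid(a))$pixels, expected)
  expect_equal(to_grayscale(image_grid(a))$channel_kind, "gray")
  expect_error(to_grayscale(image_grid(matrix(0.5, 3, 3))), "rgb")
})

test_that("color edges vanish on uniform input and localize a step", {
  flat <- image_grid(array(0.7, c(8, 8, 3)))
  expect_equal(color_edges(flat)$pixels, matrix(0, 8, 8))
  # vertical two-tone step: maximal response at the step columns only
  a <- array(0.1, c(8, 8, 3))
  a[, 5:8, ] <- 0.9
  e <- color_edges(image_grid(a))$pixels
  expect_true(all(e[, 4:5] == 1))
  expect_lt(max(abs(e[, c(1:2, 7:8)])), 1e-12)
  expect_error(color_edges(image_grid(matrix(0, 4, 4))), "rgb")
})

test_that("color edges equal a brute-force per-channel Sobel oracle", {
  img <- rgb_fixture(5, 5, seed = 7)
  img[, , 2] <- matrix(rep(seq(0, 1, length.out = 5), each = 5), 5, 5)
  # independent oracle: explicit double loop over pixels and kernel taps,
  # replicated borders, per-channel magnitude, max over channels
  gx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gy <- t(gx)
  getpx <- function(ch, r, c) ch[min(max(r, 1), 5), min(max(c, 1), 5)]
  oracle <- matrix(0, 5, 5)
  for (k in 1:3) {
    ch <- img[, , k]
    for (r in 1:5) for (c in 1:5) {
      sx <- 0; sy <- 0
      for (i in -1:1) for (j in -1:1) {
        sx <- sx + gx[i + 2, j + 2] * getpx(ch, r + i, c + j)
        sy <- sy + gy[i + 2, j + 2] * getpx(ch, r + i, c + j)
      }
      oracle[r, c] <- max(oracle[r, c], sqrt(sx^2 + sy^2))
    }
  }
  oracle <- (oracle - min(oracle)) / (max(oracle) - min(oracle))
  expect_equal(color_edges(image_grid(img))$pixels, oracle, tolerance = 1e-12)
})

test_that("color edges are translation-equivariant away from borders", {
  img <- rgb_fixture(16, 16, seed = 3)
  e0 <- color_edges(image_grid(img))$pixels
  shifted <- array(0, c(16, 16, 3))
  for (k in 1:3) shifted[, , k] <- phasefuse:::circshift(img[, , k], 3, 2)
  e1 <- color_edges(image_grid(shifted))$pixels
  # the min-max rescale constant may differ when content wraps across the
  # border, so compare interiors up to their own normalization
  a <- e1[6:14, 5:13]
  b <- phasefuse:::circshift(e0, 3, 2)[6:14, 5:13]
  expect_equal(a / max(a), b / max(b), tolerance = 1e-9)
})

test_that("blue-dominant pixels are zeroed, others untouched", {
  blue <- array(0, c(3, 3, 3)); blue[, , 3] <- 1
  expect_equal(remove_blue_background(image_grid(blue))$pixels,
               array(0, c(3, 3, 3)))
  green <- array(0, c(3, 3, 3)); green[, , 2] <- 1
  expect_equal(remove_blue_background(image_grid(green))$pixels, green)
  # half blue / half green with exact expected zero count
  a <- array(0, c(4, 6, 3))
  a[, 1:3, 3] <- 0.9          # blue half
  a[, 4:6, 2] <- 0.9          # green half
  out <- remove_blue_background(image_grid(a))$pixels
  expect_equal(sum(apply(out, c(1, 2), sum) == 0), 4 * 3)
  expect_equal(out[, 4:6, ], a[, 4:6, ])
  # margin: B barely above G stays when within delta
  b <- array(0.5, c(2, 2, 3)); b[, , 3] <- 0.54
  expect_equal(remove_blue_background(image_grid(b), delta = 0.05)$pixels, b)
})

test_that("pre-scaling to a target height preserves aspect ratio", {
  img <- image_grid(matrix(0.5, 20, 40))
  out <- prescale_to_height(img, 5)
  expect_equal(dim(out), c(5, 10))
  # identity when already at target height
  expect_equal(dim(prescale_to_height(img, 20)), c(20, 40))
  # the documented VIS/FLU pairing: height 1234 to 2056
  skinny <- image_grid(matrix(0.5, 1234, 10))
  expect_equal(prescale_to_height(skinny, 2056)$height, 2056)
  expect_error(prescale_to_height(img, 1), "at least 2")
  # round trip recovers dimensions exactly
  up <- prescale_to_height(img, 60)
  expect_equal(dim(prescale_to_height(up, 20)), c(20, 40))
  # masks stay binary under rescaling
  mk <- image_grid((plant_fixture(32) > 0.5) + 0, channel_kind = "binary_mask")
  expect_true(all(prescale_to_height(mk, 48)$pixels %in% c(0, 1)))
})

test_that("bounding boxes crop exactly and are recovered from masks", {
  m <- matrix(runif(6 * 8), 6, 8)
  img <- image_grid(m)
  full <- bounding_box(0, 0, 6, 8)
  expect_equal(crop_to_bbox(img, full)$pixels, m)
  inner <- bounding_box(1, 1, 5, 7)
  expect_equal(crop_to_bbox(img, inner)$pixels, m[2:5, 2:7])
  expect_error(crop_to_bbox(img, bounding_box(0, 0, 7, 8)), "bounds")
  expect_error(bounding_box(2, 0, 2, 5), "invalid")

  # plant_bbox vs brute-force scan oracle on a random sparse mask
  withr::with_seed(11, {
    mask <- matrix(0, 12, 15)
    mask[cbind(sample(2:11, 6), sample(2:14, 6))] <- 1
  })
  fg <- which(mask == 1, arr.ind = TRUE)
  bb <- plant_bbox(image_grid(mask, channel_kind = "binary_mask"), pad = 0)
  expect_equal(c(bb$row_min, bb$col_min, bb$row_max, bb$col_max),
               c(min(fg[, 1]) - 1, min(fg[, 2]) - 1, max(fg[, 1]), max(fg[, 2])))
  # single pixel, zero pad
  one <- matrix(0, 5, 5); one[3, 4] <- 1
  bb1 <- plant_bbox(image_grid(one, channel_kind = "binary_mask"))
  expect_equal(c(bb1$row_min, bb1$col_min, bb1$row_max, bb1$col_max),
               c(2, 3, 3, 4))
  # full-foreground -> full box; padding clips at bounds
  allfg <- plant_bbox(image_grid(matrix(1, 4, 4), channel_kind = "binary_mask"),
                      pad = 3)
  expect_equal(c(allfg$row_min, allfg$col_min, allfg$row_max, allfg$col_max),
               c(0, 0, 4, 4))
  expect_error(plant_bbox(image_grid(matrix(0, 4, 4),
                                     channel_kind = "binary_mask")), "empty")
})

test_that("threshold segmentation follows the strict-inequality rule", {
  img <- image_grid(matrix(c(0.2, 0.2, 0.8, 0.8), 2, 2))
  expect_equal(threshold_segment(img, 1.0)$pixels, matrix(0, 2, 2))
  expect_equal(threshold_segment(img, 0.1)$pixels, matrix(1, 2, 2))
  expect_equal(threshold_segment(img, 0.5)$pixels,
               matrix(c(0, 0, 1, 1), 2, 2))
  # default Otsu separates a bimodal plant fixture
  pf <- plant_fixture(48)
  auto <- threshold_segment(image_grid(pf))
  expect_equal(auto$pixels, (pf > 0.5) + 0)
})

test_that("preprocessing variants compose feature, frame and background", {
  img <- rgb_fixture(20, 20, seed = 5)
  img[, , 3] <- 0  # nothing blue-dominant
  mask <- matrix(0, 20, 20); mask[5:15, 6:14] <- 1
  g <- preprocess_variant(image_grid(img), "gray", "full", "raw")
  expect_equal(g$channel_kind, "gray")
  e <- preprocess_variant(image_grid(img), "edge", "full", "raw")
  expect_equal(e$channel_kind, "edge")
  cropped <- preprocess_variant(image_grid(img), "gray", "cropped", "raw",
                                mask = mask)
  expect_equal(dim(cropped), c(11, 9))
  expect_error(preprocess_variant(image_grid(img), "gray", "cropped", "raw"),
               "mask")
  # grayscale of grayscale is an error by contract, but identity crop is
  # idempotent
  expect_equal(crop_to_bbox(g, bounding_box(0, 0, 20, 20))$pixels, g$pixels)
})
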