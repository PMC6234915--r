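test_that("the sweep grid is inclusive and reproduces documented counts", {
  expect_equal(length(scale_grid(scale_sweep_config())), 46)
  expect_equal(length(scale_grid(scale_sweep_config(step = 0.05))), 19)
  # scale_max always included even off-grid
  g <- scale_grid(scale_sweep_config(scale_min = 0.1, scale_max = 0.95,
                                     step = 0.3))
  expect_equal(g, c(0.1, 0.4, 0.7, 0.95))
  expect_error(scale_sweep_config(scale_min = 0), "scale_min")
  expect_error(scale_sweep_config(step = -1), "step")
})

test_that("an identical pair yields the identity at every swept scale", {
  A <- plant_fixture(180)
  results <- sweep_scales(A, A, scale_sweep_config())
  expect_length(results, 46)
  expect_true(all(vapply(results, `[[`, logical(1), "valid")))
  for (r in results) {
    expect_equal(r$transform$matrix, diag(3), tolerance = 1e-9)
  }
  expect_equal(vapply(results, `[[`, numeric(1), "scale_factor"),
               scale_grid(scale_sweep_config()))
})

test_that("tiny scales are skipped as failure results, not errors", {
  A <- plant_fixture(64)  # 64 * 0.1 = 6 px, below the 16 px floor
  results <- sweep_scales(A, A, scale_sweep_config())
  expect_length(results, 46)
  skipped <- vapply(results, function(r)
    !is.null(r$diagnostics$reason) &&
      grepl("min_side", r$diagnostics$reason), logical(1))
  expect_true(any(skipped))
  expect_true(all(!vapply(results[skipped], `[[`, logical(1), "valid")))
})

test_that("pure-translation estimates agree across scales within quantization", {
  A <- plant_fixture(180)
  tr <- similarity_transform(shift_x = 15, shift_y = -9)
  B <- warp_image(image_grid(A), tr, interpolation = "bilinear")$pixels
  results <- sweep_scales(A, B, scale_sweep_config(scale_min = 0.2))
  for (r in results) {
    if (!isTRUE(r$valid)) next
    # one downscaled pixel corresponds to 1/s full-resolution pixels
    tol <- 1 / r$scale_factor + 1
    expect_lte(abs(r$transform$shift_x - 15), tol)
    expect_lte(abs(r$transform$shift_y + 9), tol)
  }
  expect_gte(sum(vapply(results, `[[`, logical(1), "valid")), 35)
})

test_that("transforms recovered at moderate scales are mutually consistent", {
  # on a noise-free global-similarity pair the stable regime of the sweep
  # produces near-identical full-resolution transforms
  A <- plant_fixture(180)
  p <- warped_pair(A, scale = 1.05, rotation_deg = 4, shift_x = 10,
                   shift_y = 6)
  results <- sweep_scales(p$A, p$B, scale_sweep_config())
  sf <- vapply(results, `[[`, numeric(1), "scale_factor")
  ok <- vapply(results, `[[`, logical(1), "valid") & sf >= 0.3 & sf <= 0.6
  expect_gte(sum(ok), 5)
  rots <- vapply(results[ok], function(r) r$transform$rotation_deg,
                 numeric(1))
  scls <- vapply(results[ok], function(r) r$transform$scale, numeric(1))
  expect_lte(diff(range(rots)), 2 * attr(logpolar_magnitude(
    phasefuse:::resample_to(image_grid(A), c(54, 54))$pixels),
    "theta_bin_deg") + 2)
  expect_lte(diff(range(scls)), 0.1)
})

test_that("mask integration is the exact pixelwise union of valid warps", {
  mask <- matrix(0, 40, 40)
  mask[10:20, 12:22] <- 1
  mg <- image_grid(mask, channel_kind = "binary_mask")
  mkres <- function(tr, valid = TRUE) {
    r <- phasefuse:::registration_result(tr, 0.5, valid, 1,
                                         vis_dim = c(40, 40))
    r
  }
  t1 <- similarity_transform()                      # identity
  t2 <- similarity_transform(shift_x = 6, shift_y = 4)
  im <- integrate_masks(mg, list(mkres(t1), mkres(t2)), c(40, 40))
  # brute-force union oracle
  w1 <- mask
  w2 <- warp_image(mg, t2, interpolation = "nearest")$pixels
  expect_equal(im$pixels, (w1 | w2) + 0)
  expect_equal(sum(im$pixels), sum((w1 | w2)))
  # single identity result reproduces the mask
  only <- integrate_masks(mg, list(mkres(t1)), c(40, 40))
  expect_equal(only$pixels, mask)
  # invalid results are excluded
  with_invalid <- integrate_masks(mg, list(mkres(t1), mkres(t2, FALSE)),
                                  c(40, 40))
  expect_equal(with_invalid$pixels, mask)
  # zero valid results raise the dedicated condition with diagnostics
  err <- tryCatch(integrate_masks(mg, list(mkres(t1, FALSE)), c(40, 40)),
                  condition = function(c) c)
  expect_s3_class(err, "phasefuse_no_valid_registration")
  expect_length(err$diagnostics, 1)
})

test_that("union area grows monotonically as registrations accumulate", {
  mask <- (plant_fixture(60) > 0.5) + 0
  mg <- image_grid(mask, channel_kind = "binary_mask")
  withr::with_seed(41, {
    trs <- lapply(1:6, function(i)
      similarity_transform(shift_x = sample(-8:8, 1),
                           shift_y = sample(-8:8, 1),
                           rotation_deg = runif(1, -5, 5),
                           center = c(29.5, 29.5)))
  })
  results <- lapply(trs, function(tr)
    phasefuse:::registration_result(tr, 0.5, TRUE, 1, vis_dim = c(60, 60)))
  areas <- vapply(seq_along(results), function(k)
    sum(integrate_masks(mg, results[seq_len(k)], c(60, 60))$pixels),
    numeric(1))
  expect_true(all(diff(areas) >= 0))
})

test_that("end-to-end integrative registration is deterministic and covers", {
  pair <- generate_pair(scene_preset("nonuniform_motion", seed = 3))
  out1 <- register_integrative(pair$flu, pair$vis)
  out2 <- register_integrative(pair$flu, pair$vis)
  expect_true(out1$success)
  expect_identical(out1$integrated_mask$pixels, out2$integrated_mask$pixels)
  expect_equal(length(out1$results), 46)
  # coverage dominance: integrated OR at least the best single-scale OR
  or_int <- overlap_ratio(out1$integrated_mask, pair$vis_mask)
  ors <- vapply(out1$results, function(r) {
    if (!isTRUE(r$valid)) return(NA_real_)
    w <- warp_image(out1$flu_mask, r$transform, out_shape = out1$vis_dim,
                    interpolation = "nearest")
    overlap_ratio(w, pair$vis_mask)
  }, numeric(1))
  expect_gte(or_int, max(ors, na.rm = TRUE))
  # identical-pair pipeline: perfect overlap of its own mask
  g <- to_grayscale(pair$vis)
  selfmask <- threshold_segment(g)
  outs <- sweep_scales(g, g, scale_sweep_config())
  im <- integrate_masks(selfmask, outs, dim(g))
  expect_equal(overlap_ratio(im, selfmask), 1)
})

test_that("a global-similarity-only pair gains little from integration", {
  spec <- scene_preset("adult_structured", seed = 2)
  pair <- generate_pair(spec)
  out <- register_integrative(pair$flu, pair$vis)
  expect_true(out$success)
  or_int <- overlap_ratio(out$integrated_mask, pair$vis_mask)
  ors <- vapply(out$results, function(r) {
    if (!isTRUE(r$valid)) return(NA_real_)
    w <- warp_image(out$flu_mask, r$transform, out_shape = out$vis_dim,
                    interpolation = "nearest")
    overlap_ratio(w, pair$vis_mask)
  }, numeric(1))
  best_single <- max(ors, na.rm = TRUE)
  expect_gte(or_int, best_single)
  expect_gte(best_single, 0.85)  # a single scale already aligns well
})
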