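test_that("background estimation finds the clear-field mode", {
  blank <- matrix(3000L, 64, 64)
  expect_equal(estimate_background(blank), 3000)
  # bimodal image: dark objects must not capture the mode
  img <- matrix(3000L, 64, 64)
  img[20:40, 20:40] <- 240L
  expect_equal(estimate_background(img), 3000)
  expect_error(estimate_background(img, object_mask = matrix(TRUE, 64, 64)),
               "no background")
})

test_that("background estimate recovers the simulator's I0 under noise", {
  rend <- sim_plate(3)
  expect_lt(abs(estimate_background(rend$image) - rend$params$i0), 5)
})

test_that("the OD transform follows Beer-Lambert with clipping and capping", {
  img <- matrix(c(3000, 300, 3000 * 2, 0), 2, 2)
  m <- to_od(img, 3000)
  expect_equal(m$od[1, 1], 0)
  expect_equal(m$od[2, 1], 1.0)
  expect_equal(m$od[1, 2], 0)           # brighter than I0 clips to zero
  expect_equal(m$od[2, 2], log10(6000)) # zero counts capped at half a count
  expect_true(m$saturated[2, 2])
  expect_false(any(m$saturated[, 1]))
  # strictly decreasing in I on (0, I0]
  i <- seq(1, 3000, by = 1)
  od <- to_od(matrix(i, 1), 3000)$od
  expect_true(all(diff(as.numeric(od)) < 0))
})

test_that("integrated OD is invariant to a common exposure rescale", {
  rend <- sim_plate(3)
  mask <- matrix(FALSE, nrow(rend$image), ncol(rend$image))
  mask[rend$truth[[1]]$pixels] <- TRUE
  i0 <- estimate_background(rend$image)
  a <- integrate_iod(to_od(rend$image, i0, 0.065), mask)
  b <- integrate_iod(to_od(rend$image * 4, i0 * 4, 0.065), mask)
  expect_equal(a$iod, b$iod, tolerance = 1e-12)
})

test_that("linearity test reaches the published R^2 on the stepped filter", {
  tg <- render_calibration_targets(image_params(seed = 8))
  i0 <- estimate_background(tg$blank$image)
  odm <- to_od(tg$stepped$image, i0, 0.065)
  r2 <- linearity_test(tg$stepped$nominal_ods, tg$stepped$band_masks, odm)
  expect_gte(r2, 0.999)
  # noise-free steps are exactly linear
  tg0 <- render_calibration_targets(image_params(seed = 8, noise_sd = 0))
  odm0 <- to_od(tg0$stepped$image, image_params()$i0, 0.065)
  expect_gt(linearity_test(tg0$stepped$nominal_ods, tg0$stepped$band_masks,
                           odm0), 0.99999)
  # shuffling band labels destroys the fit
  r2s <- linearity_test(tg$stepped$nominal_ods,
                        tg$stepped$band_masks[c(6, 3, 9, 1, 11, 4, 8, 2, 10,
                                                5, 7)], odm)
  expect_lt(r2s, 0.9)
  expect_error(linearity_test(rep(0.5, 11), tg$stepped$band_masks, odm),
               "singular|identical")
})

test_that("uniformity CV is zero for a flat field and grows with gradient", {
  expect_equal(uniformity_test(matrix(1200, 64, 64)), 0)
  cvs <- vapply(c(0, 0.05, 0.10), function(a) {
    tg <- render_calibration_targets(image_params(seed = 2, gradient_amp = a))
    uniformity_test(tg$blank$image)
  }, 0)
  expect_lt(cvs[1], 3.0)
  expect_true(all(diff(cvs) > 0))
})

test_that("stability detection finds the warm-up plateau", {
  flat <- data.frame(t = 0:10, od = rep(1.1, 11))
  expect_equal(stability_test(flat)$time, 0)
  warm <- data.frame(t = 0:30, od = 1.1 * (1 - exp(-(0:30) / 4)))
  st <- stability_test(warm, window = 5, tol = 0.04)
  expect_true(st$stabilized)
  expect_equal(st$time, 12)
  drift <- data.frame(t = 0:30, od = 1.1 + 0.01 * (0:30))
  expect_false(stability_test(drift, window = 5, tol = 0.04)$stabilized)
})

test_that("16-bit TIFF containers round-trip count images", {
  rend <- sim_plate(3)
  path <- withr::local_tempfile(fileext = ".tif")
  write_grayscale_tiff(rend$image, path)
  back <- read_grayscale_image(path, bits = 16L)
  expect_identical(back, rend$image)
})
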