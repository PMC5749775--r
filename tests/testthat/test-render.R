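test_that("rendering is deterministic under a fixed seed", {
  sp <- single_pair_spec()
  p <- image_params(seed = 9, canvas_px = c(512L, 512L))
  r1 <- render_metaphase(sp, p)
  r2 <- render_metaphase(sp, p)
  expect_identical(r1$image, r2$image)
  expect_identical(r1$od_true, r2$od_true)
})

test_that("true integrated OD is proportional to true DNA with one constant", {
  rend <- sim_plate(3)
  ratio <- vapply(rend$truth, function(t) t$total_iod / t$total_mass_pg, 0)
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-12)
  expect_equal(mean(ratio), rend$params$iod_per_pg)
  # arm-level conservation: region IODs sum to the chromosome IOD
  for (t in rend$truth)
    expect_equal(sum(t$iod), t$total_iod, tolerance = 1e-12)
})

test_that("noise-free image inverts back to the true integrated OD", {
  sp <- single_pair_spec()
  r <- render_metaphase(sp, image_params(seed = 2, noise_sd = 0,
                                         canvas_px = c(512L, 512L)))
  px2 <- r$params$pixel_size_um^2
  for (t in r$truth) {
    od_rec <- log10(r$params$i0 / pmax(r$image[t$pixels], 0.5))
    expect_equal(sum(od_rec) * px2, t$total_iod,
                 tolerance = 0.01)
  }
})

test_that("homologs with identical geometry carry equal integrated OD", {
  rend <- sim_plate(3)
  by_pair <- split(rend$truth, vapply(rend$truth, `[[`, 0, "pair_id"))
  for (pr in by_pair) {
    expect_equal(pr[[1]]$total_iod, pr[[2]]$total_iod, tolerance = 1e-9)
    expect_equal(pr[[1]]$length_um, pr[[2]]$length_um, tolerance = 1e-9)
  }
})

test_that("raising a knob multiplier raises only that arm's IOD", {
  sp <- default_maize_spec()
  sp2 <- sp
  sp2$knobs$density_mult[sp2$knobs$pair_id == 3] <- 2.5
  p <- image_params(seed = 5, noise_sd = 0)
  g0 <- Filter(function(t) t$pair_id == 3, render_metaphase(sp, p)$truth)[[1]]
  g1 <- Filter(function(t) t$pair_id == 3, render_metaphase(sp2, p)$truth)[[1]]
  expect_gt(g1$iod[["L"]], g0$iod[["L"]])
  expect_equal(g1$iod[["S"]], g0$iod[["S"]], tolerance = 1e-12)
})

test_that("impossible placements fail with an explicit error", {
  sp <- default_maize_spec()
  expect_error(render_metaphase(sp, image_params(canvas_px = c(128L, 128L))),
               "placement failure")
})

test_that("calibration targets reproduce nominal band intensities", {
  p <- image_params(seed = 4, noise_sd = 0)
  tg <- render_calibration_targets(p)
  for (b in seq_along(tg$stepped$nominal_ods)) {
    nominal <- p$i0 * 10^(-tg$stepped$nominal_ods[b])
    got <- mean(tg$stepped$image[tg$stepped$band_masks[[b]]])
    expect_equal(got, round(nominal), tolerance = 0.51)
  }
  expect_equal(uniformity_test(tg$blank$image), 0)
})

test_that("degenerate flow mixture piles all counts in two channels", {
  h <- simulate_fcm_histogram(5.0, 6.0, cv_standard = 1e-6, cv_sample = 1e-6,
                              n_nuclei = 5000, standard_channel = 100,
                              seed = 1)
  expect_equal(sum(h$counts > 0), 2)
  expect_equal(which(h$counts > 0), c(100, 120))
})

test_that("flow simulator flags overlapping peaks", {
  h <- simulate_fcm_histogram(5.57, 6.10, 3.2, 3.8, n_nuclei = 1000, seed = 1)
  expect_true(h$metadata$overlap_warning)
  h2 <- simulate_fcm_histogram(2.0, 6.0, 2, 2, n_nuclei = 1000,
                               standard_channel = 100, seed = 1)
  expect_false(h2$metadata$overlap_warning)
})
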