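# synthetic capsule mask: horizontal bar with optional width dip
bar_mask <- function(len_px, w_px, nr = 80, nc = 220,
                     dip_at = NULL, dip_depth = 0.4, dip_sd = 6) {
  m <- matrix(FALSE, nr, nc)
  x0 <- (nc - len_px) / 2; y0 <- nr / 2
  for (x in seq_len(nc)) {
    if (x < x0 || x > x0 + len_px) next
    w <- w_px
    if (!is.null(dip_at))
      w <- w * (1 - dip_depth * exp(-(x - (x0 + dip_at))^2 / (2 * dip_sd^2)))
    m[abs(seq_len(nr) - y0) <= w / 2, x] <- TRUE
  }
  m
}

test_that("axis length and width recover simple rectangle geometry", {
  # 10 um x 1 um bar at 0.1 um/px
  m <- bar_mask(100, 10)
  prof <- medial_axis_profile(m, 0.1)
  expect_equal(prof$total_length_um, 10, tolerance = 0.2)
  mid <- seq(floor(length(prof$width_um) * 0.3),
             ceiling(length(prof$width_um) * 0.7))
  expect_equal(median(prof$width_um[mid]), 1.0, tolerance = 0.15)
})

test_that("axis extraction rejects degenerate masks", {
  m <- bar_mask(100, 10)
  m2 <- m
  m2[, 100:110] <- FALSE  # split into two components
  expect_error(medial_axis_profile(m2, 0.1), "connected")
  expect_error(medial_axis_profile(matrix(FALSE, 10, 10) |
                                     rbind(matrix(TRUE, 3, 10),
                                           matrix(FALSE, 7, 10)), 0.1),
               "too small|connected")
  blob <- outer(1:60, 1:60, function(i, j) (i - 30)^2 + (j - 30)^2 < 625)
  expect_error(medial_axis_profile(blob, 0.1), "ambiguous")
})

test_that("measured axis length tracks the generator's arc length", {
  dat <- measured_plate(3)
  rel <- vapply(seq_along(dat$meas), function(k)
    abs(dat$meas[[k]]$total_length_um - dat$gt[[k]]$length_um) /
      dat$gt[[k]]$length_um, 0)
  expect_lt(median(rel), 0.03)
  expect_lt(max(rel), 0.06)
})

test_that("centromere localisation finds the width minimum", {
  m <- bar_mask(160, 24, dip_at = 80)
  prof <- medial_axis_profile(m, 0.1)
  cen <- locate_centromere(prof$width_um)
  # symmetric dip at the midpoint: CI = 50
  ci <- 100 * prof$s_um[cen] / prof$s_um[length(prof$s_um)]
  expect_equal(ci, 50, tolerance = 3)
  # monotone wedge has no constriction
  wedge <- matrix(FALSE, 80, 220)
  for (x in 20:200)
    wedge[abs(seq_len(80) - 40) <= 4 + x / 12, x] <- TRUE
  pw <- medial_axis_profile(wedge, 0.1)
  expect_error(locate_centromere(pw$width_um), "no constriction")
  expect_error(locate_centromere(rep(1, 5)), "too short")
})

test_that("submetacentric chromosomes recover their centromeric index", {
  # single pair with arm ratio 2 and no satellite/knobs: CI = 33.3
  sp0 <- default_maize_spec()
  p <- sp0$pairs[2, ]
  p$short_um <- 2.2; p$long_um <- 4.4; p$sat_um <- 0
  sp <- karyotype_spec(p)
  r <- render_metaphase(sp, image_params(seed = 6, canvas_px = c(512L, 512L)))
  odm <- plate_od(r)
  masks <- segment_chromosomes(odm)
  for (m in masks) {
    mm <- measure_chromosome(odm, m)
    expect_equal(mm$ci, 100 / 3, tolerance = 2)
    expect_equal(mm$class, "sm")
  }
})

test_that("secondary constriction is found on pair 6 and only there", {
  dat <- measured_plate(3)
  for (k in seq_along(dat$meas)) {
    mm <- dat$meas[[k]]
    if (dat$gt[[k]]$pair_id == 6) {
      expect_false(is.na(mm$sat_boundary))
      sat_len <- mm$portions$length_um[mm$portions$portion == "SAT"]
      expect_equal(sat_len, 1.0, tolerance = 0.2)
    } else {
      expect_true(is.na(mm$sat_boundary))
    }
  }
})

test_that("arm submasks partition the chromosome mask exactly", {
  dat <- measured_plate(3)
  for (k in seq_along(dat$meas)) {
    mm <- dat$meas[[k]]
    arms <- mm$arms
    u <- Reduce(`|`, arms)
    expect_identical(u, dat$masks[[k]])
    for (i in seq_along(arms))
      for (j in seq_len(i - 1))
        expect_false(any(arms[[i]] & arms[[j]]))
    # IOD additivity over the partition
    expect_equal(sum(mm$portions$iod), mm$iod, tolerance = 1e-9)
    # CI complement identity
    s <- mm$portions$length_um[mm$portions$portion == "S"]
    l <- mm$portions$length_um[mm$portions$portion == "L"]
    expect_equal(mm$ci + 100 * l / (s + l), 100, tolerance = 1e-9)
  }
})

test_that("class thresholds follow the revised Levan table", {
  expect_equal(classify_class(1.00), "M")
  expect_equal(classify_class(1.49), "m")
  expect_equal(classify_class(1.50), "sm")
  expect_equal(classify_class(2.0), "sm")
  expect_equal(classify_class(2.99), "sm")
  expect_equal(classify_class(3.00), "st")
  expect_equal(classify_class(7.0), "t")
  expect_error(classify_class(0.8), "mislabelled")
  # thresholds are configurable
  expect_equal(classify_class(2.0, thresholds = c(sm = 2.5, st = 4, t = 8)),
               "m")
})

test_that("the full simulated karyotype classifies as 2 m + 8 sm pairs", {
  dat <- measured_plate(3)
  cls <- vapply(dat$meas, function(m) m$class, "")
  pid <- vapply(dat$gt, `[[`, 0, "pair_id")
  per_pair <- vapply(split(cls, pid), function(x) x[1], "")
  expect_equal(sum(per_pair == "m"), 2)
  expect_equal(sum(per_pair == "sm"), 8)
  expect_equal(unname(per_pair[c("1", "5")]), c("m", "m"))
})

test_that("knob bands are detected where and only where simulated", {
  sp0 <- default_maize_spec()
  p <- sp0$pairs[3, ]
  base_knob <- data.frame(pair_id = p$pair_id, arm = "L", rel_pos = 0.5,
                          length_um = 1.0, density_mult = 2.0)
  # uniform chromosome: no blocks
  sp_u <- karyotype_spec(p)
  r_u <- render_metaphase(sp_u, image_params(seed = 4,
                                             canvas_px = c(512L, 512L)))
  odm_u <- plate_od(r_u)
  masks_u <- segment_chromosomes(odm_u)
  prof_u <- medial_axis_profile(masks_u[[1]], 0.065)
  expect_equal(nrow(knob_band_profile(odm_u, masks_u[[1]], prof_u)), 0)
  # knobbed chromosome: one block near the simulated position
  sp_k <- karyotype_spec(p, base_knob)
  r_k <- render_metaphase(sp_k, image_params(seed = 4,
                                             canvas_px = c(512L, 512L)))
  odm_k <- plate_od(r_k)
  masks_k <- segment_chromosomes(odm_k)
  found <- 0
  for (m in masks_k) {
    prof <- medial_axis_profile(m, 0.065)
    bl <- knob_band_profile(odm_k, m, prof)
    found <- found + nrow(bl)
    if (nrow(bl)) {
      gt <- match_truth(m, r_k$truth)
      # knob centre at rel_pos 0.5 of the long arm, in axis coordinates
      knob_centre <- gt$centromere_s_um + 0.5 * p$long_um
      centre <- (bl$start_um[1] + bl$end_um[1]) / 2
      dist_direct <- abs(centre - knob_centre)
      dist_flip <- abs((prof$s_um[length(prof$s_um)] - centre) - knob_centre)
      expect_lt(min(dist_direct, dist_flip), 0.6)
    }
  }
  expect_equal(found, 2)  # one block per homolog
})
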