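test_that("IOD equals area times mean OD, and matches the published example", {
  # 4652 px at 0.001 um^2/px give exactly the published chromosome-10 area
  od <- matrix(0, 80, 80)
  mask <- matrix(FALSE, 80, 80)
  mask[seq_len(4652)] <- TRUE
  od[mask] <- 1.117
  m <- integrate_iod(structure(list(od = od, pixel_size_um = sqrt(0.001),
                                    i0 = 3000,
                                    saturated = matrix(FALSE, 80, 80)),
                               class = "od_map"), mask)
  expect_equal(m$area_um2, 4.652, tolerance = 1e-12)
  expect_equal(m$mean_od, 1.117)
  expect_equal(round(m$iod, 3), 5.196)
  expect_equal(m$iod, m$area_um2 * m$mean_od, tolerance = 1e-12)
})

test_that("integrate_iod equals a per-pixel brute-force oracle", {
  dat <- measured_plate(3)
  px2 <- dat$odm$pixel_size_um^2
  for (k in seq_along(dat$masks)) {
    mask <- dat$masks[[k]]
    got <- integrate_iod(dat$odm, mask)
    # naive loop over pixels
    acc <- 0; npx <- 0
    for (i in which(mask)) { acc <- acc + dat$odm$od[i]; npx <- npx + 1 }
    expect_equal(got$iod, acc * px2, tolerance = 1e-9)
    expect_equal(got$area_um2, npx * px2, tolerance = 1e-12)
    expect_equal(got$iod, got$area_um2 * got$mean_od, tolerance = 1e-9)
  }
  # zero-density mask
  z <- structure(list(od = matrix(0, 8, 8), pixel_size_um = 1, i0 = 1,
                      saturated = matrix(FALSE, 8, 8)), class = "od_map")
  expect_equal(integrate_iod(z, matrix(TRUE, 8, 8))$iod, 0)
  expect_error(integrate_iod(z, matrix(FALSE, 8, 8)), "empty")
})

test_that("pair aggregation averages homolog sums across metaphases", {
  one <- data.frame(metaphase = 1, pair_id = 1, homolog = c(1, 2),
                    portion = "L", iod = c(3.0, 3.2))
  agg <- aggregate_pair_iod(one)
  expect_equal(agg$pairs$iod_c, 6.2)
  expect_equal(agg$pairs$n, 1)
  # duplicating the metaphase leaves the mean unchanged
  two <- rbind(one, transform(one, metaphase = 2))
  agg2 <- aggregate_pair_iod(two)
  expect_equal(agg2$pairs$iod_c, 6.2)
  expect_equal(agg2$pairs$n, 2)
  # a missing homolog drops that metaphase for that pair, with a warning
  broken <- rbind(two, data.frame(metaphase = 3, pair_id = 1, homolog = 1,
                                  portion = "L", iod = 99))
  expect_warning(agg3 <- aggregate_pair_iod(broken), "missing homolog")
  expect_equal(agg3$pairs$iod_c, 6.2)
})

test_that("aggregated pair IODs match an independent per-record average", {
  dat <- measured_plate(3)
  rec <- do.call(rbind, lapply(seq_along(dat$meas), function(k) {
    data.frame(metaphase = 1, pair_id = dat$gt[[k]]$pair_id,
               homolog = dat$gt[[k]]$homolog,
               portion = dat$meas[[k]]$portions$portion,
               iod = dat$meas[[k]]$portions$iod)
  }))
  agg <- aggregate_pair_iod(rec)
  # brute-force oracle over the raw record list
  for (p in unique(rec$pair_id)) {
    manual <- sum(rec$iod[rec$pair_id == p])
    expect_equal(agg$pairs$iod_c[agg$pairs$pair_id == p], manual,
                 tolerance = 1e-12)
  }
  expect_equal(sum(agg$portions$iod_b), sum(rec$iod), tolerance = 1e-12)
})

test_that("proportional allocation conserves the nuclear amount exactly", {
  al <- allocate_2c(6.10, stats::setNames(rep(2.5, 10), 1:10))
  expect_equal(al$pairs$dna_2c_pg, rep(0.610, 10))
  expect_equal(sum(al$pairs$dna_2c_pg), 6.10, tolerance = 1e-12)
  # invariance to rescaling all IODs
  al2 <- allocate_2c(6.10, stats::setNames(rep(25, 10), 1:10))
  expect_equal(al2$pairs$dna_2c_pg, al$pairs$dna_2c_pg, tolerance = 1e-12)
  expect_error(allocate_2c(6.10, c(1, 0, 2)), "positive")
})

test_that("reference-proportional IODs reproduce the published table", {
  t1 <- maize_table1()
  # arm IODs proportional to the published arm DNA values
  arm_iods <- data.frame(pair_id = t1$chromosome, portion = t1$portion,
                         iod_b = t1$dna_2c_pg * 3.5)
  al <- allocate_arm_2c(6.0986, arm_iods)  # nuclear = table grand total
  pt <- al$portions
  expect_equal(
    round(pt$dna_2c_pg[pt$pair_id == 6 & pt$portion == "SAT"], 3), 0.053)
  expect_equal(round(al$pairs$dna_2c_pg[al$pairs$pair_id == 9], 3), 0.561)
  # arms sum to pairs and pairs to the nuclear value, exactly
  expect_equal(sum(al$pairs$dna_2c_pg), 6.0986, tolerance = 1e-12)
  arm_sums <- tapply(pt$dna_2c_pg, pt$pair_id, sum)
  expect_equal(as.numeric(arm_sums), al$pairs$dna_2c_pg, tolerance = 1e-12)
  # 40/60 split sanity case
  a2 <- allocate_arm_2c(1.0, data.frame(pair_id = 1, portion = c("S", "L"),
                                        iod_b = c(0.4, 0.6)))
  expect_equal(a2$portions$dna_2c_pg[a2$portions$portion == "S"], 0.4)
  expect_equal(a2$portions$dna_2c_pg[a2$portions$portion == "L"], 0.6)
})

test_that("a knobbed arm draws more DNA than its length share", {
  sp <- default_maize_spec()
  m <- spec_portion_masses(sp)
  m3 <- m[m$pair_id == 3, ]
  len_share <- m3$length_um / sum(m3$length_um)
  dna_share <- m3$mass_pg / sum(m3$mass_pg)
  expect_gt(dna_share[m3$portion == "L"], len_share[m3$portion == "L"])
})

test_that("pg/bp and 2C/1C conversions match the published values", {
  expect_equal(round(pg_to_bp(two_c_to_one_c(0.376)) / 1e9, 3), 0.184)
  expect_equal(round(pg_to_bp(two_c_to_one_c(0.803)) / 1e9, 3), 0.393)
  expect_equal(round(pg_to_bp(two_c_to_one_c(0.053)) / 1e9, 3), 0.026)
  expect_equal(pg_to_bp(0), 0)
  expect_error(pg_to_bp(-1), "non-negative")
  expect_error(two_c_to_one_c(-0.1), "non-negative")
})
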