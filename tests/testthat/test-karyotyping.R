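test_that("duplicated objects pair with their duplicates", {
  feat <- data.frame(length_um = rep(seq(4, 9, length.out = 10), each = 2),
                     ci = rep(seq(25, 48, length.out = 10), each = 2),
                     iod = rep(seq(5, 11, length.out = 10), each = 2))
  pr <- pair_homologs(feat)
  expect_equal(nrow(pr), 10)
  expect_true(all(pr$member2 - pr$member1 == 1))
  expect_true(all(pr$member1 %% 2 == 1))
  expect_error(pair_homologs(feat[1:5, ]), "odd number")
})

test_that("degenerate identical pairs are matched but flagged ambiguous", {
  feat <- data.frame(length_um = rep(5, 4), ci = rep(40, 4), iod = rep(7, 4))
  pr <- pair_homologs(feat)
  expect_equal(nrow(pr), 2)
  expect_true(any(pr$ambiguous))
})

test_that("simulated metaphases pair homologs correctly", {
  correct <- 0; total <- 0
  for (s in c(3, 4)) {
    dat <- measured_plate(s)
    pid <- vapply(dat$gt, `[[`, 0, "pair_id")
    pr <- pair_homologs(dat$meas)
    correct <- correct + sum(pid[pr$member1] == pid[pr$member2])
    total <- total + nrow(pr)
  }
  expect_gte(correct / total, 0.95)
})

test_that("numbering is a bijection in both modes, honouring conventions", {
  dat <- measured_plate(3)
  pid <- vapply(dat$gt, `[[`, 0, "pair_id")
  pr <- pair_homologs(dat$meas)
  by_len <- assign_numbers(pr, dat$meas, mode = "by_length")
  expect_setequal(by_len$number, 1:10)
  ref <- assign_numbers(pr, dat$meas, mode = "reference_map",
                        reference = maize_reference_karyotable())
  expect_setequal(ref$number, 1:10)
  # reference numbering recovers the true pair identities
  true_of_pair <- pid[ref$member1]
  expect_equal(ref$number, true_of_pair)
  # pair 9 outsizes pair 8 in the complement: conventional numbering keeps
  # 9, and the length-rank disagreement is flagged
  expect_true(all(ref$inverted[ref$number %in% c(8, 9)]))
  expect_error(assign_numbers(pr, dat$meas, mode = "reference_map",
                              reference = maize_reference_karyotable()[1:4, ]),
               "reference table")
})

test_that("by_length numbering uses deterministic tie-breaks", {
  feat <- data.frame(length_um = c(5, 5, 5, 5), ci = c(40, 40, 30, 30),
                     iod = c(7, 7, 6, 6))
  pr <- pair_homologs(feat)
  nb <- assign_numbers(pr, feat, mode = "by_length")
  # equal lengths: the higher-CI pair comes first
  expect_equal(nb$ci[nb$number == 1], 40)
})

test_that("karyogram tables aggregate and normalise correctly", {
  rec <- data.frame(metaphase = rep(1:2, each = 2),
                    number = rep(1:2, 2),
                    length_um = c(8, 6, 8.2, 6.2),
                    s_um = c(3.6, 2.0, 3.7, 2.1),
                    l_um = c(4.4, 4.0, 4.5, 4.1),
                    sat_um = 0, iod = c(20, 15, 21, 15.5))
  k <- build_karyogram(rec)
  expect_equal(k$length_um, c(8.1, 6.1))
  expect_equal(sum(k$rel_length_pct), 100, tolerance = 1e-9)
  expect_equal(k$class, c("m", "sm"))
  # a single metaphase reproduces its own values
  k1 <- build_karyogram(rec[rec$metaphase == 1, ])
  expect_equal(k1$length_um, c(8, 6))
  expect_equal(k1$iod, c(20, 15))
})

test_that("ideograms carry one bar per pair with satellite on pair 6", {
  rec <- do.call(rbind, lapply(1:10, function(n)
    data.frame(metaphase = 1, number = n, length_um = 11 - n,
               s_um = (11 - n) / 3, l_um = 2 * (11 - n) / 3,
               sat_um = ifelse(n == 6, 0.8, 0), iod = 30 - n)))
  k <- build_karyogram(rec)
  ideo <- build_ideogram(k)
  # two arm rectangles per pair + one satellite rectangle
  expect_equal(lengths(regmatches(ideo$svg, gregexpr("<rect", ideo$svg))), 21)
  expect_match(ideo$svg, "r=2.00 \\(sm\\)")
  path <- withr::local_tempfile(fileext = ".svg")
  write_ideogram_svg(ideo, path)
  expect_match(readLines(path, n = 1), "<svg")
})

test_that("cross-study comparisons reproduce the published percentages", {
  cmp <- compare_to_reference(
    data.frame(chromosome = 1, value = 0.393),
    data.frame(chromosome = 1, value = 0.365))
  expect_equal(round(cmp$pct_vs_reference, 2), 7.67)
  cmp10 <- compare_to_reference(
    data.frame(chromosome = 10, value = 0.189),
    data.frame(chromosome = 10, value = 0.150))
  expect_equal(round(cmp10$pct_vs_reference, 2), 26.00)
  same <- compare_to_reference(data.frame(chromosome = 2, value = 1),
                               data.frame(chromosome = 2, value = 1))
  expect_equal(same$pct_vs_reference, 0)
  expect_equal(same$pct_vs_query, 0)
  expect_error(compare_to_reference(
    data.frame(chromosome = 3, value = 1),
    data.frame(chromosome = 1, value = 1)), "missing chromosome")
})
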