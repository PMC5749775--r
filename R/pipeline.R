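#' Build (or read) a pipeline configuration
#'
#' @param n_metaphases number of metaphase plates to simulate and analyse.
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it deterministically.
#' @param spec a [karyotype_spec()] (default: [default_maize_spec()]).
#' @param params an [image_params()]; its seed field is overridden per
#'   metaphase from `seed`.
#' @param fcm list of flow-simulation settings: `standard_2c`,
#'   `standard_channel`, `cv_standard`, `cv_sample`, `n_nuclei`,
#'   `replicates`.
#' @param out_dir optional output directory for tables, SVG and manifest.
#' @param write_images also write the simulated TIFF images (slower).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_metaphases = 5, seed = 1L,
                            spec = default_maize_spec(),
                            params = image_params(),
                            fcm = list(standard_2c = 5.57,
                                       standard_channel = 200,
                                       cv_standard = 3.2, cv_sample = 3.8,
                                       n_nuclei = 10000, replicates = 5),
                            out_dir = NULL, write_images = FALSE) {
  structure(list(n_metaphases = as.integer(n_metaphases),
                 seed = as.integer(seed), spec = spec, params = params,
                 fcm = fcm, out_dir = out_dir,
                 write_images = isTRUE(write_images)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised top-level keys: `n_metaphases`, `seed`, `fcm` (mapping),
#' `params` (mapping of [image_params()] arguments), `out_dir`,
#' `write_images`. The karyotype is the default maize-like complement.
#'
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  par <- do.call(image_params, y$params %||% list())
  base <- pipeline_config()
  pipeline_config(n_metaphases = y$n_metaphases %||% base$n_metaphases,
                  seed = y$seed %||% base$seed,
                  params = par,
                  fcm = utils::modifyList(base$fcm, y$fcm %||% list()),
                  out_dir = y$out_dir,
                  write_images = y$write_images %||% FALSE)
}

#' Run the full chromosomal DNA-sizing pipeline on simulated inputs
#'
#' Executes, in order: calibration-target rendering and qualification
#' (linearity, uniformity, stability), flow-histogram simulation and
#' nuclear 2C estimation over replicates, per-metaphase rendering,
#' background estimation, OD transform, segmentation, chromosome
#' measurement, homolog pairing and numbering, pair/arm IOD aggregation,
#' proportional DNA allocation, karyogram and ideogram assembly, and
#' comparison against the bundled published table.
#'
#' @param config a [pipeline_config()].
#' @return A manifest list with per-stage results; written as
#'   `manifest.json` (plus CSV/SVG outputs) when `out_dir` is set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  spec <- config$spec
  par0 <- config$params
  log_stage <- function(...) message("[icmkaryo] ", sprintf(...))

  # --- calibrate ------------------------------------------------------
  log_stage("calibrate: rendering targets and running qualification tests")
  cal_par <- par0; cal_par$seed <- config$seed * 1000L + 1L
  targets <- render_calibration_targets(cal_par)
  i0_cal <- estimate_background(targets$blank$image)
  od_step <- to_od(targets$stepped$image, i0_cal, par0$pixel_size_um)
  r2 <- linearity_test(targets$stepped$nominal_ods,
                       targets$stepped$band_masks, od_step)
  ucv <- uniformity_test(targets$blank$image)
  warmup <- data.frame(t = 0:30,
                       od = 1.1 * (1 - exp(-(0:30) / 4)))
  stab <- stability_test(warmup, window = 5, tol = 0.04)
  calibration <- list(linearity_r2 = r2, uniformity_cv = ucv,
                      stabilized = stab$stabilized,
                      stabilization_min = stab$time,
                      um_per_px = par0$pixel_size_um, i0 = i0_cal)

  # --- fcm ------------------------------------------------------------
  log_stage("fcm: %d replicate histograms", config$fcm$replicates)
  reps <- vapply(seq_len(config$fcm$replicates), function(r) {
    h <- simulate_fcm_histogram(
      standard_2c = config$fcm$standard_2c, sample_2c = spec$nuclear_2c,
      cv_standard = config$fcm$cv_standard, cv_sample = config$fcm$cv_sample,
      n_nuclei = config$fcm$n_nuclei,
      standard_channel = config$fcm$standard_channel,
      seed = config$seed * 1000L + 100L + r)
    pk <- suppressWarnings(find_g1_peaks(h, 2))
    estimate_2c_from_peaks(pk[[1]]$mean_channel, pk[[2]]$mean_channel,
                           config$fcm$standard_2c)
  }, 0)
  nuclear <- mean_over_replicates(reps)

  # --- measure --------------------------------------------------------
  rec <- NULL
  kary_rec <- NULL
  renders <- list()
  ref_tab <- maize_reference_karyotable()
  for (m in seq_len(config$n_metaphases)) {
    log_stage("measure: metaphase %d/%d", m, config$n_metaphases)
    pm <- par0; pm$seed <- config$seed * 1000L + 200L + m
    rend <- render_metaphase(spec, pm)
    renders[[m]] <- rend
    i0 <- estimate_background(rend$image)
    odm <- to_od(rend$image, i0, pm$pixel_size_um)
    masks <- segment_chromosomes(odm, expected_n = 2L * nrow(spec$pairs))
    meas <- lapply(masks, function(mask)
      measure_chromosome(odm, mask, sat_search = "auto"))
    pairs <- pair_homologs(meas)
    pairs <- assign_numbers(pairs, meas, mode = "reference_map",
                            reference = ref_tab)
    for (k in seq_len(nrow(pairs))) {
      mem <- c(pairs$member1[k], pairs$member2[k])
      for (h in 1:2) {
        mm <- meas[[mem[h]]]
        pt <- mm$portions
        rec <- rbind(rec, data.frame(
          metaphase = m, pair_id = pairs$number[k], homolog = h,
          portion = pt$portion, iod = pt$iod))
      }
      mm1 <- meas[[mem[1]]]; mm2 <- meas[[mem[2]]]
      mean_port <- function(mm, p)
        if (p %in% mm$portions$portion)
          mm$portions$length_um[mm$portions$portion == p] else 0
      kary_rec <- rbind(kary_rec, data.frame(
        metaphase = m, number = pairs$number[k],
        length_um = (mm1$total_length_um + mm2$total_length_um) / 2,
        s_um = (mean_port(mm1, "S") + mean_port(mm2, "S")) / 2,
        l_um = (mean_port(mm1, "L") + mean_port(mm2, "L")) / 2,
        sat_um = (mean_port(mm1, "SAT") + mean_port(mm2, "SAT")) / 2,
        iod = mm1$iod + mm2$iod))
    }
  }

  # --- allocate -------------------------------------------------------
  log_stage("allocate: proportional DNA distribution")
  agg <- aggregate_pair_iod(rec)
  alloc_pairs <- allocate_2c(nuclear, agg)
  alloc_arms <- allocate_arm_2c(nuclear, agg)
  conservation <- c(
    pair_sum_err = abs(sum(alloc_pairs$pairs$dna_2c_pg) - nuclear$mean_2c),
    arm_sum_err = max(abs(
      stats::aggregate(dna_2c_pg ~ pair_id, alloc_arms$portions, sum)$dna_2c_pg -
        alloc_pairs$pairs$dna_2c_pg[order(alloc_pairs$pairs$pair_id)])))

  # --- karyotype ------------------------------------------------------
  kary <- build_karyogram(kary_rec)
  kary$dna_2c_pg <- alloc_pairs$pairs$dna_2c_pg[
    match(kary$number, alloc_pairs$pairs$pair_id)]
  ideo <- build_ideogram(kary)

  # --- compare --------------------------------------------------------
  t1 <- maize_pair_totals()
  cmp <- compare_to_reference(
    data.frame(chromosome = alloc_pairs$pairs$pair_id,
               value = alloc_pairs$pairs$dna_2c_pg),
    data.frame(chromosome = t1$chromosome, value = t1$dna_2c_pg))

  manifest <- list(
    config = list(n_metaphases = config$n_metaphases, seed = config$seed,
                  nuclear_2c_true = spec$nuclear_2c),
    calibration = calibration,
    fcm = list(replicate_2c = nuclear$replicate_2c, mean_2c = nuclear$mean_2c,
               sd = nuclear$sd),
    segmentation = list(
      chromosomes_per_metaphase = as.numeric(table(kary_rec$metaphase)) * 2),
    pairs = alloc_pairs$pairs,
    portions = alloc_arms$portions,
    karyogram = as.data.frame(kary),
    class_counts = as.list(table(kary$class)),
    conservation = as.list(conservation),
    comparison_vs_reference_table = cmp)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(allocation_table(alloc_arms),
                     file.path(config$out_dir, "allocation.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(kary),
                     file.path(config$out_dir, "karyogram.csv"),
                     row.names = FALSE)
    write_ideogram_svg(ideo, file.path(config$out_dir, "ideogram.svg"))
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (config$write_images)
      for (m in seq_along(renders))
        write_grayscale_tiff(renders[[m]]$image,
                             file.path(config$out_dir,
                                       sprintf("metaphase_%02d.tif", m)))
  }
  manifest
}

#' Recompute the published reference quantities from bundled fixtures
#'
#' A self-check: every headline number of the reference study that follows
#' arithmetically from its printed inputs is recomputed with the package's
#' own functions and compared at printed precision.
#'
#' @return Data frame with `check`, `value`, `expected`, `tol`, `pass`.
#' @export
reference_value_checks <- function() {
  fc <- maize_fcm_reference()
  t1 <- maize_table1()
  tot <- maize_pair_totals()
  refs <- maize_reference_1c()

  two_c <- estimate_2c_from_peaks(fc$standard_channel, fc$sample_channel,
                                  fc$standard_2c)
  intra <- 100 * (round(two_c, 2) - fc$standard_2c) / fc$standard_2c
  chr9 <- tot$dna_2c_pg[tot$chromosome == 9]
  complement <- sum(tot$dna_2c_pg)
  iod10 <- 4.652 * 1.117
  conv_1s <- pg_to_bp(two_c_to_one_c(
    t1$dna_2c_pg[t1$chromosome == 1 & t1$portion == "S"])) / 1e9
  conv_sat <- pg_to_bp(two_c_to_one_c(
    t1$dna_2c_pg[t1$portion == "SAT"])) / 1e9
  chr1_1c <- pg_to_bp(two_c_to_one_c(
    tot$dna_2c_pg[tot$chromosome == 1])) / 1e9
  chr10_1c <- pg_to_bp(two_c_to_one_c(
    tot$dna_2c_pg[tot$chromosome == 10])) / 1e9
  cmp1 <- compare_to_reference(
    data.frame(chromosome = 1, value = round(chr1_1c, 3)),
    data.frame(chromosome = 1,
               value = refs$one_c_bp_e9[refs$study == "flow_karyotyping"]))
  cmp10 <- compare_to_reference(
    data.frame(chromosome = 10, value = round(chr10_1c, 3)),
    data.frame(chromosome = 10,
               value = refs$one_c_bp_e9[refs$study == "sequencing" &
                                          refs$chromosome == 10]))

  out <- data.frame(
    check = c("nuclear 2C from peak ratio (pg)",
              "intraspecific difference (%)",
              "chromosome 9 pair 2C (pg)",
              "complement 2C total (pg)",
              "chromosome 10 IOD (area x OD)",
              "chr1 S arm 1C (1e9 bp)",
              "chr6 satellite 1C (1e9 bp)",
              "chr1 1C (1e9 bp)",
              "vs flow karyotyping chr1 (%)",
              "vs sequencing chr10 (%)"),
    value = c(two_c, intra, chr9, complement, iod10, conv_1s, conv_sat,
              chr1_1c, cmp1$pct_vs_reference, cmp10$pct_vs_reference),
    expected = c(6.10, 9.52, 0.561, 6.10, 5.196, 0.184, 0.026, 0.393,
                 7.67, 26.00),
    tol = c(0.005, 0.005, 0.0005, 0.005, 0.0005, 0.0005, 0.0005, 0.0005,
            0.005, 0.005))
  out$pass <- abs(out$value - out$expected) <= out$tol
  out
}
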