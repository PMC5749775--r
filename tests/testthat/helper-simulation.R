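# shared simulated fixtures, cached per session to keep the suite fast
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) assign(key, expr, envir = .sim_cache)
  get(key, envir = .sim_cache)
}

sim_plate <- function(seed = 3, ...) {
  cached(paste0("plate_", seed, "_", paste(c(...), collapse = "_")),
         render_metaphase(default_maize_spec(),
                          image_params(seed = seed, ...)))
}

plate_od <- function(rend) {
  to_od(rend$image, estimate_background(rend$image),
        rend$params$pixel_size_um)
}

# best-overlap ground-truth record for a segmented mask
match_truth <- function(mask, truth) {
  mi <- which(mask)
  ov <- vapply(truth, function(t) length(intersect(mi, t$pixels)), 0)
  truth[[which.max(ov)]]
}

mask_iou <- function(mask, gt) {
  mi <- which(mask)
  length(intersect(mi, gt$pixels)) / length(union(mi, gt$pixels))
}

# segmentation + per-chromosome measurement for one plate, cached
measured_plate <- function(seed) {
  cached(paste0("meas_", seed), {
    rend <- sim_plate(seed)
    odm <- plate_od(rend)
    masks <- suppressWarnings(segment_chromosomes(odm, expected_n = 20))
    meas <- lapply(masks, function(m) measure_chromosome(odm, m))
    gt <- lapply(masks, match_truth, truth = rend$truth)
    list(rend = rend, odm = odm, masks = masks, meas = meas, gt = gt)
  })
}

# single-pair spec (pair 3 geometry) used for constructed fixtures
single_pair_spec <- function(pair = 3) {
  sp <- default_maize_spec()
  karyotype_spec(sp$pairs[sp$pairs$pair_id == pair, ],
                 sp$knobs[sp$knobs$pair_id == pair, ])
}
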