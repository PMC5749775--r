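#' Construct a karyotype specification for the metaphase simulator
#'
#' A karyotype spec fixes, per homolog pair, the axis lengths of the short
#' arm, long arm and (optional) satellite, the pair's total 2C DNA amount,
#' and any heterochromatic knob blocks. Knobs multiply the local DNA density
#' of the arm they sit on; the pair's DNA mass is spread along the
#' chromosome at a uniform baseline linear density modulated by the knobs,
#' so a knob carries proportionally more of the pair's DNA than its length
#' share.
#'
#' @param pairs data frame with columns `pair_id` (1..n, unique),
#'   `short_um`, `long_um` (> 0), `sat_um` (>= 0, satellite axis length,
#'   distal on the short arm) and `dna_2c_pg` (> 0, DNA of the homolog
#'   pair).
#' @param knobs data frame with columns `pair_id`, `arm` (`"S"` or `"L"`),
#'   `rel_pos` (block centre as a fraction 0-1 of the arm, measured from
#'   the centromere), `length_um` and `density_mult` (>= 1). May have zero
#'   rows.
#' @param width_um chromatid width (capsule diameter) in micrometres.
#' @param dip_depth fractional width reduction at constrictions (0-1).
#' @param dip_sd_um Gaussian s.d. of the constriction width dip, in
#'   micrometres.
#' @return An object of class `karyotype_spec`.
#' @export
karyotype_spec <- function(pairs, knobs = NULL, width_um = 1.2,
                           dip_depth = 0.4, dip_sd_um = 0.3) {
  stopifnot(is.data.frame(pairs),
            all(c("pair_id", "short_um", "long_um", "sat_um", "dna_2c_pg")
                %in% names(pairs)))
  if (anyDuplicated(pairs$pair_id)) stop("pair_id values must be unique")
  if (any(pairs$short_um <= 0) || any(pairs$long_um <= 0))
    stop("arm lengths must be positive")
  if (any(pairs$sat_um < 0)) stop("satellite lengths must be non-negative")
  if (any(pairs$dna_2c_pg <= 0)) stop("pair DNA amounts must be positive")
  if (is.null(knobs))
    knobs <- data.frame(pair_id = integer(), arm = character(),
                        rel_pos = numeric(), length_um = numeric(),
                        density_mult = numeric())
  stopifnot(all(c("pair_id", "arm", "rel_pos", "length_um", "density_mult")
                %in% names(knobs)))
  if (nrow(knobs)) {
    if (!all(knobs$arm %in% c("S", "L"))) stop("knob arm must be 'S' or 'L'")
    if (!all(knobs$pair_id %in% pairs$pair_id))
      stop("knob pair_id not present in pairs")
    if (any(knobs$density_mult < 1)) stop("knob density_mult must be >= 1")
    if (any(knobs$rel_pos < 0 | knobs$rel_pos > 1))
      stop("knob rel_pos must lie in [0, 1]")
  }
  pairs <- pairs[order(pairs$pair_id), , drop = FALSE]
  # baseline linear DNA density (pg/um) is frozen at construction: the
  # pair's stated DNA spread over its knob-weighted effective length.
  # Editing a knob on an existing spec afterwards adds (or removes) DNA
  # mass on that arm alone, leaving the other arm untouched.
  eff <- portion_eff(pairs, knobs)
  eff_tot <- tapply(eff$eff_um, eff$pair_id, sum)
  pairs$rho_pg_um <- pairs$dna_2c_pg /
    (2 * as.numeric(eff_tot[as.character(pairs$pair_id)]))
  structure(list(pairs = pairs, knobs = knobs, width_um = width_um,
                 dip_depth = dip_depth, dip_sd_um = dip_sd_um,
                 nuclear_2c = sum(pairs$dna_2c_pg)),
            class = "karyotype_spec")
}

# knob-weighted (effective) portion lengths, one row per portion
portion_eff <- function(pairs, knobs) {
  do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
    p <- pairs[i, ]
    kn <- knobs[knobs$pair_id == p$pair_id, , drop = FALSE]
    extra <- function(arm, arm_len) {
      k <- kn[kn$arm == arm, , drop = FALSE]
      if (!nrow(k)) return(0)
      sum(pmin(k$length_um, arm_len) * (k$density_mult - 1))
    }
    len <- c(SAT = p$sat_um, S = p$short_um, L = p$long_um)
    eff <- c(SAT = p$sat_um,
             S = p$short_um + extra("S", p$short_um),
             L = p$long_um + extra("L", p$long_um))
    keep <- len > 0
    data.frame(pair_id = p$pair_id, portion = names(len)[keep],
               length_um = unname(len[keep]), eff_um = unname(eff[keep]))
  }))
}

#' @export
print.karyotype_spec <- function(x, ...) {
  cat(sprintf("karyotype_spec: %d pairs, 2n = %d, nuclear 2C = %.3f pg\n",
              nrow(x$pairs), 2L * nrow(x$pairs), x$nuclear_2c))
  cat(sprintf("  satellited pairs: %s; knob blocks: %d\n",
              paste(x$pairs$pair_id[x$pairs$sat_um > 0], collapse = ","),
              nrow(x$knobs)))
  invisible(x)
}

#' Default maize-like karyotype specification
#'
#' Returns the simulator's standard complement: 2n = 2x = 20 with two
#' metacentric pairs (1 and 5, arm ratio < 1.5), eight submetacentric pairs
#' (2-4 and 6-10, arm ratio 1.5-3.0), a satellite on the short arm of
#' pair 6, and one interstitial knob block on the long arm of each of pairs
#' 2-9. Pair 2C DNA amounts equal the per-chromosome totals of
#' [maize_table1()] (summing to the published nuclear 2C of 6.10 pg at
#' printed precision). Axis lengths are scaled so that rendered chromosome
#' areas match the published mean areas (9.478 um^2 for chromosome 1 down
#' to 4.652 um^2 for chromosome 10) at the default chromatid width.
#'
#' @param seed unused; accepted for interface symmetry with the stochastic
#'   generators (the default complement is a fixed study condition).
#' @return A [karyotype_spec()].
#' @export
default_maize_spec <- function(seed = 0L) {
  totals <- maize_pair_totals()
  # mean single-chromosome areas (um^2): published for 1, 8, 9, 10;
  # remaining values interpolated monotonically between them
  areas <- c(9.478, 8.90, 8.40, 7.90, 7.50, 7.10, 6.90, 6.342, 6.672, 4.652)
  width <- 1.2
  len <- areas / (width * 0.96)  # 0.96: area lost to tip taper + dips
  ratio <- c(1.20, 1.70, 1.86, 1.65, 1.30, 2.14, 2.40, 2.60, 1.61, 1.95)
  sat <- c(0, 0, 0, 0, 0, 1.0, 0, 0, 0, 0)
  arms <- len - sat
  short <- arms / (1 + ratio)
  long <- arms - short
  pairs <- data.frame(pair_id = 1:10, short_um = short, long_um = long,
                      sat_um = sat, dna_2c_pg = totals$dna_2c_pg)
  knob_pairs <- 2:9
  knobs <- data.frame(pair_id = knob_pairs, arm = "L",
                      rel_pos = c(0.45, 0.55, 0.40, 0.60, 0.50, 0.45,
                                  0.55, 0.50),
                      length_um = 0.8, density_mult = 1.8)
  karyotype_spec(pairs, knobs)
}

#' Per-homolog arm and satellite DNA masses implied by a karyotype spec
#'
#' The pair's 2C DNA is spread at the spec's frozen baseline linear
#' density, with knob blocks weighted by their density multiplier:
#' `mass = rho * effective length` per portion and homolog. For an
#' unmodified spec, portion masses sum to `dna_2c_pg / 2` per homolog;
#' raising a knob multiplier after construction adds mass to that arm
#' only.
#'
#' @param spec a [karyotype_spec()].
#' @return Data frame with columns `pair_id`, `portion` (`"S"`, `"L"`,
#'   `"SAT"`), `length_um` (axis length), `eff_um` (knob-weighted length)
#'   and `mass_pg` (per homolog).
#' @export
spec_portion_masses <- function(spec) {
  stopifnot(inherits(spec, "karyotype_spec"))
  out <- portion_eff(spec$pairs, spec$knobs)
  rho <- stats::setNames(spec$pairs$rho_pg_um, spec$pairs$pair_id)
  out$mass_pg <- out$eff_um * rho[as.character(out$pair_id)]
  rownames(out) <- NULL
  out
}

#' Imaging parameters for the metaphase renderer
#'
#' @param bits camera bit depth (12 or 16); pixel values occupy
#'   `0 .. 2^bits - 1` in a 16-bit container.
#' @param i0 clear-field (background) intensity in counts; must be below
#'   `2^bits`.
#' @param pixel_size_um pixel pitch at the specimen, micrometres per pixel.
#' @param noise_sd Gaussian read-noise s.d. in counts.
#' @param poisson logical; add Poisson shot noise on the expected counts.
#' @param gradient_amp peak-to-peak relative amplitude of a linear
#'   illumination gradient across the field (0 = flat).
#' @param iod_per_pg stain calibration: integrated optical density
#'   (OD x um^2) deposited per picogram of DNA. One constant per simulated
#'   slide, mirroring stoichiometric Feulgen staining.
#' @param canvas_px integer c(rows, cols) canvas size.
#' @param margin_px clearance kept between placed chromosomes, pixels.
#' @param touching_pairs pairs with `pair_id` up to this value are placed
#'   with their homologs in tip-to-tip contact (stress input for the
#'   watershed splitter); 0 renders a fully isolated spread.
#' @param max_attempts placement rejection-sampling attempts per chromosome.
#' @param seed RNG seed controlling placement, curvature and noise.
#' @return A list of class `image_params`.
#' @export
image_params <- function(bits = 12L, i0 = 3000, pixel_size_um = 0.065,
                         noise_sd = 25, poisson = FALSE, gradient_amp = 0,
                         iod_per_pg = 26.6, canvas_px = c(1024L, 1024L),
                         margin_px = 8L, touching_pairs = 0L,
                         max_attempts = 300L, seed = 1L) {
  stopifnot(bits %in% c(12L, 16L), i0 > 0, i0 < 2^bits, pixel_size_um > 0,
            noise_sd >= 0, iod_per_pg > 0, length(canvas_px) == 2)
  structure(list(bits = as.integer(bits), i0 = i0,
                 pixel_size_um = pixel_size_um, noise_sd = noise_sd,
                 poisson = isTRUE(poisson), gradient_amp = gradient_amp,
                 iod_per_pg = iod_per_pg, canvas_px = as.integer(canvas_px),
                 margin_px = as.integer(margin_px),
                 touching_pairs = as.integer(touching_pairs),
                 max_attempts = as.integer(max_attempts),
                 seed = as.integer(seed)),
            class = "image_params")
}
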