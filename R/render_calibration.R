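#' Render synthetic calibration-target images
#'
#' Produces the two images used to qualify a densitometry setup: a stepped
#' density filter (11 homogeneous vertical bands of strictly increasing
#' nominal optical density, for the linearity test) and a blank clear
#' field (for the uniformity test). Band intensity follows Beer-Lambert:
#' `I0 * 10^(-OD_k)` plus noise; the blank field is `I0` times the
#' illumination gradient plus noise.
#'
#' @param params an [image_params()].
#' @param step_ods strictly increasing nominal band optical densities
#'   (default 11 equal steps, 0.1 to 1.1).
#' @return A list with elements `stepped` (list: `image`, `nominal_ods`,
#'   `band_masks` - logical matrices, one per band) and `blank` (list:
#'   `image`).
#' @export
render_calibration_targets <- function(params = image_params(),
                                       step_ods = seq(0.1, 1.1, by = 0.1)) {
  stopifnot(inherits(params, "image_params"), length(step_ods) >= 3,
            all(diff(step_ods) > 0))
  with_local_seed(params$seed + 1L, {
    nr <- params$canvas_px[1]; nc <- params$canvas_px[2]
    nb <- length(step_ods)
    band_of_col <- pmin(nb, 1L + (seq_len(nc) - 1L) %/% ceiling(nc / nb))
    odimg <- matrix(rep(step_ods[band_of_col], each = nr), nr, nc)
    quantise <- function(expected) {
      img <- expected
      if (params$noise_sd > 0)
        img <- img + matrix(stats::rnorm(nr * nc, 0, params$noise_sd), nr, nc)
      img <- round(pmin(pmax(img, 0), 2^params$bits - 1))
      storage.mode(img) <- "integer"
      img
    }
    g <- matrix(rep(1 + params$gradient_amp * (seq_len(nc) / nc - 0.5),
                    each = nr), nr, nc)
    stepped <- quantise(params$i0 * 10^(-odimg))
    blank <- quantise(params$i0 * g)
    masks <- lapply(seq_len(nb), function(b) {
      m <- matrix(FALSE, nr, nc)
      m[, band_of_col == b] <- TRUE
      m
    })
    list(stepped = list(image = stepped, nominal_ods = step_ods,
                        band_masks = masks),
         blank = list(image = blank))
  })
}

#' Simulate a two-population G0/G1 flow-cytometry histogram
#'
#' Draws fluorescence values for an internal standard and a sample from a
#' two-component Gaussian mixture whose component means are proportional to
#' the two 2C DNA amounts (the standard lands at `standard_channel`) and
#' whose standard deviations are `mean * cv / 100`, then bins them into
#' integer channels. An optional uniform debris floor can be added.
#'
#' @param standard_2c,sample_2c 2C DNA amounts in pg.
#' @param cv_standard,cv_sample peak coefficients of variation, percent.
#' @param n_nuclei nuclei drawn per population.
#' @param n_channels number of histogram channels (>= 256).
#' @param standard_channel channel at which the standard peak is centred.
#' @param debris_frac fraction of additional events spread uniformly over
#'   channels (debris floor).
#' @param seed RNG seed.
#' @return An `fcm_histogram` object (see [fcm_histogram()]). The
#'   `overlap_warning` metadata flag is set when the two component means
#'   are closer than twice the sum of their standard deviations.
#' @export
simulate_fcm_histogram <- function(standard_2c, sample_2c,
                                   cv_standard = 3.2, cv_sample = 3.8,
                                   n_nuclei = 10000, n_channels = 512,
                                   standard_channel = 200,
                                   debris_frac = 0, seed = 1L) {
  stopifnot(cv_standard > 0, cv_sample > 0, n_channels >= 256,
            standard_2c > 0, sample_2c > 0)
  with_local_seed(seed, {
    mu1 <- standard_channel
    mu2 <- standard_channel * sample_2c / standard_2c
    sd1 <- mu1 * cv_standard / 100
    sd2 <- mu2 * cv_sample / 100
    v <- c(stats::rnorm(n_nuclei, mu1, sd1), stats::rnorm(n_nuclei, mu2, sd2))
    if (debris_frac > 0)
      v <- c(v, stats::runif(round(debris_frac * 2 * n_nuclei), 1, n_channels))
    ch <- pmin(pmax(round(v), 1L), n_channels)
    counts <- tabulate(ch, nbins = n_channels)
    fcm_histogram(seq_len(n_channels), counts,
                  metadata = list(standard_2c = standard_2c,
                                  true_means = c(mu1, mu2),
                                  true_cvs = c(cv_standard, cv_sample),
                                  overlap_warning =
                                    abs(mu2 - mu1) < 2 * (sd1 + sd2)))
  })
}
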