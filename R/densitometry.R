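#' Estimate the clear-field background intensity of a metaphase image
#'
#' Background is the mode of the non-object pixel intensities, computed on
#' a unit-count histogram. When no object mask is given, a coarse Otsu
#' threshold separates dark (stained) objects from the bright field first,
#' so dark-object modes cannot capture the estimate.
#'
#' @param image numeric/integer matrix of counts.
#' @param object_mask optional logical matrix flagging object pixels to
#'   exclude.
#' @return Background intensity `I0` in counts.
#' @export
estimate_background <- function(image, object_mask = NULL) {
  stopifnot(is.matrix(image))
  v <- as.numeric(image)
  if (is.null(object_mask)) {
    rng <- range(v)
    if (diff(rng) > 0) {
      thr <- EBImage::otsu(EBImage::Image((image - rng[1]) / diff(rng)),
                           range = c(0, 1))
      bg <- v[(v - rng[1]) / diff(rng) > thr]
      # if the "bright" side is tiny the image is essentially blank
      if (length(bg) < length(v) * 0.05) bg <- v
    } else bg <- v
  } else {
    stopifnot(is.logical(object_mask), all(dim(object_mask) == dim(image)))
    bg <- v[!object_mask]
  }
  if (!length(bg)) stop("no background pixels available to estimate I0")
  counts <- table(round(bg))
  as.numeric(names(counts)[which.max(counts)])
}

#' Convert a calibrated intensity image to an optical-density map
#'
#' Beer-Lambert inverse: `OD(p) = log10(I0 / I(p))`. Negative densities
#' (pixels brighter than the background) are clipped to zero; zero-count
#' pixels are capped at the density of half a count and flagged in the
#' saturation mask.
#'
#' @param image numeric/integer matrix of counts.
#' @param i0 background intensity in counts (> 0), e.g. from
#'   [estimate_background()].
#' @param pixel_size_um pixel pitch, micrometres per pixel.
#' @return An object of class `od_map`: list with `od` (matrix),
#'   `pixel_size_um`, `i0` and `saturated` (logical matrix).
#' @export
to_od <- function(image, i0, pixel_size_um = 1) {
  stopifnot(is.matrix(image), i0 > 0, pixel_size_um > 0)
  sat <- image <= 0
  od <- log10(i0 / pmax(image, 0.5))
  od[od < 0] <- 0
  structure(list(od = od, pixel_size_um = pixel_size_um, i0 = i0,
                 saturated = sat),
            class = "od_map")
}

#' @export
print.od_map <- function(x, ...) {
  cat(sprintf("od_map: %d x %d px (%.3f um/px), I0 = %g, max OD = %.3f\n",
              nrow(x$od), ncol(x$od), x$pixel_size_um, x$i0, max(x$od)))
  invisible(x)
}

#' Densitometric linearity test against a stepped density filter
#'
#' Regresses measured mean band optical density on the nominal band
#' densities (ordinary least squares) and returns the coefficient of
#' determination. A well-calibrated system yields R^2 >= 0.999.
#'
#' @param nominal_ods nominal optical densities of the filter steps
#'   (>= 3 distinct values).
#' @param band_masks list of logical matrices, one per step.
#' @param od_map an [to_od()] map of the stepped-filter image.
#' @return R^2 of the measured-vs-nominal fit.
#' @export
linearity_test <- function(nominal_ods, band_masks, od_map) {
  stopifnot(inherits(od_map, "od_map"), length(nominal_ods) >= 3,
            length(band_masks) == length(nominal_ods))
  if (length(unique(nominal_ods)) < 2)
    stop("nominal densities are identical; linearity fit is singular")
  measured <- vapply(band_masks, function(m) mean(od_map$od[m]), 0)
  fit <- stats::lm(measured ~ nominal_ods)
  summary(fit)$r.squared
}

#' Field-uniformity test on a blank image
#'
#' Coefficient of variation (percent) of per-tile mean intensity over an
#' `tiles x tiles` grid. Tile averaging suppresses pixel shot noise so the
#' statistic tracks illumination non-uniformity.
#'
#' @param image blank-field intensity matrix (or an `od_map`, whose
#'   intensities are reconstructed from `I0 * 10^-OD`).
#' @param tiles grid size per side (default 8).
#' @return CV in percent.
#' @export
uniformity_test <- function(image, tiles = 8) {
  if (inherits(image, "od_map")) image <- image$i0 * 10^(-image$od)
  stopifnot(is.matrix(image), nrow(image) >= tiles, ncol(image) >= tiles)
  ri <- cut(seq_len(nrow(image)), tiles, labels = FALSE)
  ci <- cut(seq_len(ncol(image)), tiles, labels = FALSE)
  tile_means <- tapply(as.numeric(image),
                       list(ri[row(image)], ci[col(image)]), mean)
  m <- mean(tile_means)
  if (m == 0) stop("zero mean intensity; uniformity CV undefined")
  100 * stats::sd(as.numeric(tile_means)) / m
}

#' Instrument warm-up stability test
#'
#' Finds the first time point from which the rolling range of the mean-OD
#' trace stays within `tol` over windows of `window` minutes, i.e. the time
#' after which the optical signal is considered stable.
#'
#' @param trace data frame (or 2-column matrix) of time (minutes) and mean
#'   OD, >= 3 points, times increasing.
#' @param window rolling-window length in minutes.
#' @param tol maximum allowed OD range within the window.
#' @return List with `stabilized` (logical) and `time` (minutes; `NA` when
#'   never stable).
#' @export
stability_test <- function(trace, window = 5, tol = 0.005) {
  trace <- as.data.frame(trace)
  stopifnot(ncol(trace) >= 2, nrow(trace) >= 3)
  t <- trace[[1]]; v <- trace[[2]]
  stopifnot(all(diff(t) > 0))
  for (i in seq_along(t)) {
    # the stable period must cover at least one full window
    if (t[length(t)] - t[i] < window) break
    stable <- TRUE
    for (j in i:length(t)) {
      sel <- t >= max(t[i], t[j] - window) & t <= t[j] & t >= t[i]
      if (diff(range(v[sel])) > tol) { stable <- FALSE; break }
    }
    if (stable) return(list(stabilized = TRUE, time = t[i]))
  }
  list(stabilized = FALSE, time = NA_real_)
}

#' Read an 8/12/16-bit grayscale TIFF or PNG as a count matrix
#'
#' @param path image file (`.tif`, `.tiff` or `.png`).
#' @param bits bit depth used to rescale the normalised values returned by
#'   the readers back to counts.
#' @return Integer matrix of counts.
#' @export
read_grayscale_image <- function(path, bits = 16L) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png_read(path),
                stop("unsupported image format: ", ext))
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  img <- round(arr * (2^bits - 1))
  storage.mode(img) <- "integer"
  img
}

png_read <- function(path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required to read PNG images")
  png::readPNG(path)
}

#' Write a count matrix as a 16-bit grayscale TIFF
#'
#' @param image integer/numeric matrix of counts (0 .. 2^16 - 1; 12-bit
#'   data occupy the low 4096 values, as acquired).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_grayscale_tiff <- function(image, path) {
  stopifnot(is.matrix(image), all(image >= 0), all(image <= 65535))
  tiff::writeTIFF(image / 65535, path, bits.per.sample = 16L,
                  compression = "none")
  invisible(path)
}
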