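#' Flow-cytometry histogram container
#'
#' @param channels strictly increasing integer channel indices.
#' @param counts non-negative event counts, same length as `channels`.
#' @param metadata optional list (stain, standard name, standard 2C, ...).
#' @return An object of class `fcm_histogram`.
#' @export
fcm_histogram <- function(channels, counts, metadata = list()) {
  channels <- as.integer(channels)
  stopifnot(length(channels) == length(counts), all(diff(channels) > 0),
            all(counts >= 0))
  structure(list(channels = channels, counts = as.numeric(counts),
                 metadata = metadata),
            class = "fcm_histogram")
}

#' @export
print.fcm_histogram <- function(x, ...) {
  cat(sprintf("fcm_histogram: %d channels, %g events\n",
              length(x$channels), sum(x$counts)))
  invisible(x)
}

#' Read a flow histogram from a channel,count CSV export
#'
#' @param path CSV file with two columns (channel, count); a header row is
#'   detected and skipped automatically.
#' @param metadata optional metadata list attached to the result.
#' @return An [fcm_histogram()].
#' @export
read_fcm_csv <- function(path, metadata = list()) {
  first <- readLines(path, n = 1)
  has_header <- !grepl("^\\s*[0-9]", first)
  df <- utils::read.csv(path, header = has_header)
  fcm_histogram(df[[1]], df[[2]], metadata)
}

#' Write a flow histogram as a channel,count CSV
#' @param hist an [fcm_histogram()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fcm_csv <- function(hist, path) {
  stopifnot(inherits(hist, "fcm_histogram"))
  utils::write.csv(data.frame(channel = hist$channels, count = hist$counts),
                   path, row.names = FALSE)
  invisible(path)
}

#' Locate and fit G0/G1 peaks in a flow histogram
#'
#' Candidate peaks are local maxima of the lightly smoothed counts that
#' exceed both an absolute floor (5% of the histogram maximum) and three
#' times the median channel count (which rejects structureless noise).
#' Each candidate is refined by a Gaussian fit on a window of +/- 2.5
#' initial standard deviations around the maximum. When fit windows
#' overlap, all overlapping peaks are refitted jointly as a sum of
#' Gaussians (and the result carries `overlap = TRUE`), since with peak
#' CVs of a few percent the standard and sample G0/G1 peaks share tails.
#'
#' @param hist an [fcm_histogram()].
#' @param n_expected number of G0/G1 peaks expected (default 2:
#'   internal standard + sample).
#' @param min_height_frac candidate floor as a fraction of the maximum
#'   count.
#' @return A list of `n_expected` peak fits, sorted by mean channel; each
#'   is a list with `mean_channel`, `sd_channel`, `cv` (percent), `height`,
#'   `window` (channel range used) and `overlap`.
#' @export
find_g1_peaks <- function(hist, n_expected = 2, min_height_frac = 0.05) {
  stopifnot(inherits(hist, "fcm_histogram"))
  ch <- hist$channels; y <- hist$counts
  if (sum(y) == 0) stop("peaks not found: empty histogram")
  ys <- smooth_ma(y, 5)
  n <- length(ys)
  floor_abs <- max(min_height_frac * max(ys), 3 * stats::median(y))
  is_max <- ys >= floor_abs
  is_max[2:(n - 1)] <- is_max[2:(n - 1)] &
    ys[2:(n - 1)] >= ys[1:(n - 2)] & ys[2:(n - 1)] >= ys[3:n]
  is_max[c(1, n)] <- FALSE
  cand <- which(is_max)
  # merge flat-top plateaus
  if (length(cand) > 1) cand <- cand[c(TRUE, diff(cand) > 3)]
  # keep the n_expected tallest, in channel order
  if (length(cand) < n_expected)
    stop(sprintf("peaks not found: expected %d, found %d candidate(s)",
                 n_expected, length(cand)))
  cand <- sort(cand[order(-ys[cand])][seq_len(n_expected)])

  init <- lapply(seq_along(cand), function(k) {
    i <- cand[k]
    # width where the smoothed profile stays above 85% of the peak: less
    # prone than half-max to bridging the valley between close peaks
    lev <- 0.85 * ys[i]
    lo <- i; while (lo > 1 && ys[lo] > lev) lo <- lo - 1
    hi <- i; while (hi < n && ys[hi] > lev) hi <- hi + 1
    sd0 <- max((ch[hi] - ch[lo]) / 1.14, 0.7)
    if (length(cand) > 1) {
      gap <- min(abs(ch[cand[-k]] - ch[i]))
      sd0 <- min(sd0, 0.6 * gap)
    }
    list(mu = ch[i], sd = sd0, h = ys[i])
  })
  windows <- lapply(init, function(p) c(p$mu - 2.5 * p$sd, p$mu + 2.5 * p$sd))

  # group peaks whose windows overlap
  groups <- list(); cur <- 1
  if (n_expected > 1) {
    grp <- c(1)
    for (k in 2:n_expected) {
      if (windows[[k]][1] <= windows[[k - 1]][2]) grp <- c(grp, k)
      else { groups[[length(groups) + 1]] <- grp; grp <- c(k) }
    }
    groups[[length(groups) + 1]] <- grp
  } else groups <- list(1)

  fits <- vector("list", n_expected)
  for (grp in groups) {
    overlap <- length(grp) > 1
    if (overlap)
      warning("overlapping peak fit windows; refitting jointly")
    win <- c(min(vapply(grp, function(k) windows[[k]][1], 0)),
             max(vapply(grp, function(k) windows[[k]][2], 0)))
    sel <- ch >= win[1] & ch <= win[2]
    res <- fit_gaussians(ch[sel], y[sel], init[grp])
    for (m in seq_along(grp)) {
      p <- res[[m]]
      fits[[grp[m]]] <- list(mean_channel = p$mu, sd_channel = p$sd,
                             cv = 100 * p$sd / p$mu, height = p$h,
                             window = win, overlap = overlap)
    }
  }
  fits[order(vapply(fits, function(f) f$mean_channel, 0))]
}

# least-squares fit of a sum of Gaussians; falls back to (iterated)
# windowed moments if the nonlinear fit fails
fit_gaussians <- function(x, y, init) {
  k <- length(init)
  start <- unlist(lapply(init, function(p) c(p$h, p$mu, log(p$sd))))
  names(start) <- paste0(rep(c("h", "mu", "lsd"), k), rep(seq_len(k), each = 3))
  model <- function(par) {
    yy <- 0
    for (m in seq_len(k)) {
      h <- par[3 * m - 2]; mu <- par[3 * m - 1]; sd <- exp(par[3 * m])
      yy <- yy + h * exp(-(x - mu)^2 / (2 * sd^2))
    }
    yy
  }
  fit <- try(minpack.lm::nls.lm(par = start,
                                fn = function(par) y - model(par),
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 200)),
             silent = TRUE)
  if (!inherits(fit, "try-error") && fit$info %in% 1:4) {
    par <- fit$par
    res <- lapply(seq_len(k), function(m)
      list(h = par[[3 * m - 2]], mu = par[[3 * m - 1]],
           sd = exp(par[[3 * m]])))
    # accept only if every component stayed near its candidate peak with a
    # positive height and a plausible spread; otherwise the joint fit has
    # collapsed onto a spurious optimum
    ok <- all(vapply(seq_len(k), function(m) {
      p <- res[[m]]; q <- init[[m]]
      p$h > 0 && abs(p$mu - q$mu) <= 2.5 * q$sd && p$sd <= 2.5 * q$sd
    }, TRUE))
    if (ok) return(res)
  }
  # moment fallback, iterated on a +/-2.5 sd window per peak
  lapply(init, function(p) {
    mu <- p$mu; sd <- p$sd
    for (it in 1:10) {
      sel <- x >= mu - 2.5 * sd & x <= mu + 2.5 * sd & y > 0
      if (!any(sel)) break
      w <- y[sel]
      mu_new <- sum(w * x[sel]) / sum(w)
      sd_new <- sqrt(sum(w * (x[sel] - mu_new)^2) / sum(w)) / 0.9571
      if (abs(mu_new - mu) < 1e-6 && abs(sd_new - sd) < 1e-6) break
      mu <- mu_new; sd <- max(sd_new, 0.3)
    }
    list(h = max(y[which.min(abs(x - mu))], 0), mu = mu, sd = sd)
  })
}

#' Nuclear 2C DNA amount from the internal-standard peak ratio
#'
#' The sample's 2C value is the standard's known 2C scaled by the ratio of
#' the two G0/G1 peak channels:
#' `2C_sample = 2C_standard * channel_sample / channel_standard`.
#'
#' @param standard_peak_channel,sample_peak_channel mean G0/G1 peak
#'   channels of the internal standard and of the sample.
#' @param standard_2c known 2C DNA amount of the standard, pg.
#' @return Sample 2C DNA amount, pg.
#' @export
estimate_2c_from_peaks <- function(standard_peak_channel, sample_peak_channel,
                                   standard_2c) {
  if (standard_peak_channel <= 0 || sample_peak_channel <= 0)
    stop("peak channels must be positive")
  if (standard_2c <= 0) stop("standard 2C must be positive")
  standard_2c * sample_peak_channel / standard_peak_channel
}

#' Average replicate 2C estimates into a nuclear DNA estimate
#'
#' @param values replicate 2C estimates, pg (length r >= 1).
#' @return A list of class `nuclear_dna_estimate` with `replicate_2c`, `r`,
#'   `mean_2c` (the arithmetic mean over replicates) and `sd` (0 for a
#'   single replicate).
#' @export
mean_over_replicates <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("at least one replicate 2C value is required")
  structure(list(replicate_2c = values, r = length(values),
                 mean_2c = mean(values),
                 sd = if (length(values) > 1) stats::sd(values) else 0),
            class = "nuclear_dna_estimate")
}

#' @export
print.nuclear_dna_estimate <- function(x, ...) {
  cat(sprintf("nuclear 2C = %.3f +/- %.3f pg (r = %d replicates)\n",
              x$mean_2c, x$sd, x$r))
  invisible(x)
}
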