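#' Medial axis and width profile of a segmented chromosome
#'
#' The axis is the centre-weighted geodesic between the two most distant
#' points of the mask: mask pixels form an 8-connected graph whose edge
#' weights divide the step length by the local distance-transform value,
#' pulling the shortest path onto the ridge of the shape. The raw pixel
#' path is smoothed (running mean, two passes, window of one chromatid
#' width) and resampled at one-pixel spacing; the width at each axis point
#' is twice the interpolated distance-transform value.
#'
#' @param mask logical matrix, one connected object of >= 50 px.
#' @param um_per_px pixel pitch, micrometres.
#' @return List with `axis` (data frame `x`, `y`, pixel coordinates),
#'   `s_um` (arc-length positions), `width_um` and `total_length_um`.
#' @export
medial_axis_profile <- function(mask, um_per_px) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)), um_per_px > 0)
  mask <- mask > 0
  npx <- sum(mask)
  if (npx < 50) stop("mask too small for axis extraction (< 50 px)")
  lab <- EBImage::bwlabel(mask)
  if (max(lab) != 1) stop("mask must be a single connected component")

  dm <- EBImage::distmap(mask)
  nr <- nrow(mask)
  idx <- which(mask)
  node <- integer(length(mask)); node[idx] <- seq_along(idx)
  rr <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L

  edges <- NULL; wts <- NULL
  for (d in list(c(1L, 0L, 1), c(0L, 1L, 1), c(1L, 1L, sqrt(2)),
                 c(-1L, 1L, sqrt(2)))) {
    r2 <- rr + d[1]; c2 <- cc + d[2]
    ok <- r2 >= 1 & r2 <= nr & c2 >= 1 & c2 <= ncol(mask)
    tgt <- (c2[ok] - 1L) * nr + r2[ok]
    ok2 <- which(ok)[mask[tgt]]
    tgt <- tgt[mask[tgt]]
    if (!length(tgt)) next
    edges <- rbind(edges, cbind(node[idx[ok2]], node[tgt]))
    wts <- c(wts, d[3] / (dm[idx[ok2]] + dm[tgt] + 0.1))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  # farthest-pair heuristic: two sweeps of unweighted BFS distances
  d1 <- igraph::distances(g, v = 1, weights = NA)[1, ]
  e1 <- which.max(d1)
  d2 <- igraph::distances(g, v = e1, weights = NA)[1, ]
  e2 <- which.max(d2)
  if (d2[e2] < 3 * max(dm))
    stop("ambiguous axis: no dominant elongation in mask")
  path <- igraph::shortest_paths(g, from = e1, to = e2,
                                 weights = wts)$vpath[[1]]
  pi_ <- idx[as.integer(path)]
  pxy <- cbind(x = (pi_ - 1L) %/% nr + 1L, y = (pi_ - 1L) %% nr + 1L)

  w_med <- stats::median(2 * dm[pi_])
  win <- max(5L, as.integer(w_med) %/% 2L * 2L + 1L)
  sx <- pxy[, 1]; sy <- pxy[, 2]
  for (pass in 1:2) { sx <- smooth_ma(sx, win); sy <- smooth_ma(sy, win) }
  # smoothing retracts the path from the tapered tips; extend each end
  # along its tangent to the mask boundary
  ext <- extend_to_boundary(sx, sy, mask)
  sx <- ext$x; sy <- ext$y
  seg <- sqrt(diff(sx)^2 + diff(sy)^2)
  s <- c(0, cumsum(seg))
  n_out <- max(10L, ceiling(s[length(s)]))
  s_out <- seq(0, s[length(s)], length.out = n_out)
  ax <- cbind(stats::approx(s, sx, xout = s_out)$y,
              stats::approx(s, sy, xout = s_out)$y)
  # width per axis sample: twice the largest distance-transform value in
  # the sample's cross-section slab (robust to the axis sitting slightly
  # off-ridge after smoothing); empty slabs fall back to the axis point
  d2 <- outer(cc, ax[, 1], "-")^2 + outer(rr, ax[, 2], "-")^2
  near <- max.col(-d2, ties.method = "first")
  wmax <- rep(NA_real_, n_out)
  agg <- tapply(dm[idx], near, max)
  wmax[as.integer(names(agg))] <- agg
  fallback <- bilinear_at(dm, ax[, 1], ax[, 2])
  wmax[is.na(wmax)] <- fallback[is.na(wmax)]
  # dt measures to background pixel centres; the physical edge sits half a
  # pixel closer on each side
  width <- pmax(2 * wmax - 1, 0.5) * um_per_px
  list(axis = data.frame(x = ax[, 1], y = ax[, 2]),
       s_um = s_out * um_per_px, width_um = width,
       total_length_um = s[length(s)] * um_per_px)
}

# prolong a smoothed axis polyline from both ends, along the local end
# tangent, until it exits the mask
extend_to_boundary <- function(sx, sy, mask) {
  n <- length(sx)
  nr <- nrow(mask); nc <- ncol(mask)
  inside <- function(x, y) {
    xi <- round(x); yi <- round(y)
    xi >= 1 && xi <= nc && yi >= 1 && yi <= nr && mask[yi, xi]
  }
  grow <- function(x0, y0, dx, dy) {
    nrm <- sqrt(dx^2 + dy^2)
    if (nrm == 0) return(NULL)
    dx <- dx / nrm; dy <- dy / nrm
    pts <- NULL
    for (k in seq(0.5, max(nr, nc), by = 0.5)) {
      x <- x0 + k * dx; y <- y0 + k * dy
      if (!inside(x, y)) break
      pts <- rbind(pts, c(x, y))
    }
    pts
  }
  a <- max(1, n - 6)
  tail_pts <- grow(sx[n], sy[n], sx[n] - sx[a], sy[n] - sy[a])
  b <- min(n, 7)
  head_pts <- grow(sx[1], sy[1], sx[1] - sx[b], sy[1] - sy[b])
  if (!is.null(head_pts))
    head_pts <- head_pts[rev(seq_len(nrow(head_pts))), , drop = FALSE]
  col_or_empty <- function(m, j) if (is.null(m)) numeric(0) else m[, j]
  list(x = c(col_or_empty(head_pts, 1), sx, col_or_empty(tail_pts, 1)),
       y = c(col_or_empty(head_pts, 2), sy, col_or_empty(tail_pts, 2)))
}

# bilinear interpolation of matrix m at (col = x, row = y), both 1-based
bilinear_at <- function(m, x, y) {
  x <- pmin(pmax(x, 1), ncol(m)); y <- pmin(pmax(y, 1), nrow(m))
  x0 <- pmin(floor(x), ncol(m) - 1L); y0 <- pmin(floor(y), nrow(m) - 1L)
  fx <- x - x0; fy <- y - y0
  m[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    m[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    m[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    m[cbind(y0 + 1, x0 + 1)] * fx * fy
}

#' Locate the primary constriction (centromere) on a width profile
#'
#' Global minimum of the smoothed width profile restricted to the central
#' portion of the axis, which excludes the telomeric taper at both ends.
#'
#' @param width_profile width values along the axis (micrometres).
#' @param central_frac fraction of the axis searched, centred (default
#'   0.6).
#' @param min_dip minimum relative dip (vs the median central width) for a
#'   constriction to be accepted.
#' @return Axis index of the centromere.
#' @export
locate_centromere <- function(width_profile, central_frac = 0.6,
                              min_dip = 0.05) {
  n <- length(width_profile)
  if (n < 10) stop("width profile too short (< 10 samples)")
  w <- smooth_ma(width_profile, 7)
  lo <- max(1L, ceiling(n * (1 - central_frac) / 2))
  hi <- min(n, floor(n * (1 + central_frac) / 2))
  ref <- stats::median(w[lo:hi])
  i <- lo - 1L + which.min(w[lo:hi])
  if ((ref - w[i]) / ref < min_dip || i %in% c(lo, hi))
    stop("no constriction: width profile is flat within the search window")
  i
}

#' Locate a secondary constriction on the short arm
#'
#' Searches the short-arm side of the width profile (distal of the
#' centromere, excluding the telomeric taper and the primary-dip
#' neighbourhood) for a local minimum at least half as deep as the primary
#' constriction. The segment distal to it is the satellite.
#'
#' @param width_profile width values along the axis (micrometres).
#' @param centromere centromere axis index from [locate_centromere()].
#' @param s_um arc-length positions of the profile samples (micrometres).
#' @param enabled logical; when `FALSE` the search is skipped (returns
#'   `NA`). Use for chromosomes that are not satellite candidates.
#' @param tip_margin_um region next to the chromosome tip excluded from the
#'   search (telomeric taper).
#' @param cen_margin_um region next to the centromere excluded from the
#'   search (primary dip).
#' @return Axis index of the secondary constriction, or `NA` when absent.
#' @export
locate_secondary_constriction <- function(width_profile, centromere, s_um,
                                          enabled = TRUE,
                                          tip_margin_um = 0.45,
                                          cen_margin_um = 0.6) {
  if (!isTRUE(enabled)) return(NA_integer_)
  n <- length(width_profile)
  w <- smooth_ma(width_profile, 7)
  total <- s_um[n]
  s_cen <- s_um[centromere]
  short_first <- s_cen <= total - s_cen
  if (short_first) {
    sel <- which(s_um >= tip_margin_um & s_um <= s_cen - cen_margin_um)
  } else {
    sel <- which(s_um >= s_cen + cen_margin_um & s_um <= total - tip_margin_um)
  }
  if (length(sel) < 3) return(NA_integer_)
  ref <- stats::median(w[pmin(pmax(seq_len(n), 1), n)][sel])
  primary_depth <- ref - w[centromere]
  i <- sel[which.min(w[sel])]
  # require an interior local minimum, not the edge of the search window
  if (i %in% range(sel)) return(NA_integer_)
  if ((ref - w[i]) < 0.5 * primary_depth) return(NA_integer_)
  i
}

#' Partition a chromosome mask into arm (and satellite) submasks
#'
#' Each mask pixel is assigned to the axis side of its nearest axis sample:
#' the cut at the centromere (and at the satellite boundary, when present)
#' is thereby perpendicular to the local axis direction. The submasks are
#' disjoint and cover the mask exactly. Short/long labels are assigned by
#' arm length (the satellite counts toward neither arm); length ties are
#' broken by the lower integrated density (`S`).
#'
#' @param mask logical matrix.
#' @param axis axis data frame (`x`, `y`) from [medial_axis_profile()].
#' @param centromere centromere axis index.
#' @param sat_boundary optional secondary-constriction axis index.
#' @param od optional OD matrix used only for the tie-break.
#' @return Named list of logical matrices: `S`, `L` and optionally `SAT`,
#'   plus attribute `short_first` (TRUE when the short arm occupies the
#'   low-index end of the axis).
#' @export
partition_arms <- function(mask, axis, centromere, sat_boundary = NULL,
                           od = NULL) {
  mask <- mask > 0
  n_ax <- nrow(axis)
  if (centromere <= 1 || centromere >= n_ax)
    stop("centromere must be strictly interior to the axis")
  idx <- which(mask)
  nr <- nrow(mask)
  pxx <- (idx - 1L) %/% nr + 1L
  pxy <- (idx - 1L) %% nr + 1L
  d2 <- outer(pxx, axis$x, "-")^2 + outer(pxy, axis$y, "-")^2
  j <- max.col(-d2, ties.method = "first")

  if (!is.null(sat_boundary) && is.na(sat_boundary)) sat_boundary <- NULL
  sat_first <- !is.null(sat_boundary) && sat_boundary < centromere
  side_a_len <- centromere - 1L
  side_b_len <- n_ax - centromere
  if (!is.null(sat_boundary)) {
    if (sat_first) side_a_len <- centromere - sat_boundary
    else side_b_len <- sat_boundary - centromere
  }
  lab <- ifelse(j < centromere, "A", ifelse(j == centromere,
                                            NA_character_, "B"))
  # centromere-sample pixels join the nearer side deterministically
  lab[is.na(lab)] <- if (side_a_len <= side_b_len) "A" else "B"
  if (!is.null(sat_boundary)) {
    if (sat_first) lab[j <= sat_boundary] <- "SAT"
    else lab[j >= sat_boundary] <- "SAT"
  }
  short_is_a <- if (side_a_len != side_b_len) side_a_len < side_b_len else {
    if (!is.null(od)) {
      ia <- sum(od[idx[lab == "A"]]); ib <- sum(od[idx[lab == "B"]])
      ia <= ib
    } else TRUE
  }
  to_mask <- function(which_lab) {
    m <- matrix(FALSE, nrow(mask), ncol(mask))
    m[idx[lab == which_lab]] <- TRUE
    m
  }
  out <- list(S = to_mask(if (short_is_a) "A" else "B"),
              L = to_mask(if (short_is_a) "B" else "A"))
  if (!is.null(sat_boundary)) out$SAT <- to_mask("SAT")
  attr(out, "short_first") <- short_is_a
  out
}

#' Chromosome class from the arm ratio
#'
#' Levan-style classification with the revised threshold table:
#' `M` (r = 1.00), `m` (1 < r < 1.5), `sm` (1.5 <= r < 3), `st`
#' (3 <= r < 7), `t` (r >= 7). Thresholds are configurable.
#'
#' @param arm_ratio long/short arm length ratio, >= 1.
#' @param thresholds named numeric vector giving the lower bounds of `sm`,
#'   `st` and `t`.
#' @return Class label, one of `"M"`, `"m"`, `"sm"`, `"st"`, `"t"`.
#' @export
classify_class <- function(arm_ratio, thresholds = c(sm = 1.5, st = 3, t = 7)) {
  if (any(arm_ratio < 1)) stop("arm ratio < 1: arms are mislabelled")
  vapply(arm_ratio, function(r) {
    if (r == 1) "M"
    else if (r < thresholds[["sm"]]) "m"
    else if (r < thresholds[["st"]]) "sm"
    else if (r < thresholds[["t"]]) "st"
    else "t"
  }, "")
}

#' Axis-integrated density profile and knob-band detection
#'
#' Integrates optical density per unit axis length (OD x um^2 / um) and
#' reports blocks where the linear density exceeds `ratio` times the
#' chromosome's median linear density over at least `min_len_um` - the
#' densitometric signature of heterochromatic knobs.
#'
#' @param od_map an [to_od()] map (or plain OD matrix with `um_per_px`).
#' @param mask chromosome mask.
#' @param axis_profile result of [medial_axis_profile()].
#' @param ratio detection threshold relative to the median linear density.
#' @param min_len_um minimum block length, micrometres.
#' @param um_per_px pixel pitch; taken from `od_map` when available.
#' @return Data frame with one row per block: `start_um`, `end_um`,
#'   `peak_ratio`.
#' @export
knob_band_profile <- function(od_map, mask, axis_profile, ratio = 1.3,
                              min_len_um = 0.5, um_per_px = NULL) {
  if (inherits(od_map, "od_map")) {
    um_per_px <- od_map$pixel_size_um
    od <- od_map$od
  } else od <- od_map
  stopifnot(!is.null(um_per_px))
  axis <- axis_profile$axis
  s_um <- axis_profile$s_um
  idx <- which(mask > 0)
  nr <- nrow(od)
  pxx <- (idx - 1L) %/% nr + 1L
  pxy <- (idx - 1L) %% nr + 1L
  d2 <- outer(pxx, axis$x, "-")^2 + outer(pxy, axis$y, "-")^2
  j <- max.col(-d2, ties.method = "first")
  ds <- mean(diff(s_um))
  lin <- vapply(seq_len(nrow(axis)), function(k)
    sum(od[idx[j == k]]) * um_per_px^2 / ds, 0)
  lin_s <- smooth_ma(lin, 5)
  med <- stats::median(lin_s)
  above <- lin_s > ratio * med
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  blocks <- data.frame(start_um = numeric(), end_um = numeric(),
                       peak_ratio = numeric())
  for (b in which(r$values)) {
    len <- s_um[ends[b]] - s_um[starts[b]]
    if (len >= min_len_um)
      blocks <- rbind(blocks, data.frame(
        start_um = s_um[starts[b]], end_um = s_um[ends[b]],
        peak_ratio = max(lin_s[starts[b]:ends[b]]) / med))
  }
  blocks
}

#' Measure one segmented chromosome end to end
#'
#' Convenience wrapper running [medial_axis_profile()],
#' [locate_centromere()], [locate_secondary_constriction()] (when
#' `sat_search = TRUE` or `"auto"`), [partition_arms()] and
#' [integrate_iod()] on each portion.
#'
#' @param od_map an [to_od()] map.
#' @param mask logical chromosome mask.
#' @param sat_search `TRUE`, `FALSE` or `"auto"` (search and keep the
#'   boundary only when a qualifying secondary dip exists).
#' @return A list of class `chromosome_measurement`: axis profile,
#'   `centromere`, `sat_boundary`, arm submasks, per-portion measurements
#'   (`portions` data frame: portion, length_um, area_um2, mean_od, iod),
#'   `total_length_um`, `area_um2`, `iod`, `arm_ratio`, `ci`, `class`.
#' @export
measure_chromosome <- function(od_map, mask, sat_search = "auto") {
  stopifnot(inherits(od_map, "od_map"))
  px <- od_map$pixel_size_um
  prof <- medial_axis_profile(mask, px)
  cen <- locate_centromere(prof$width_um)
  sat <- locate_secondary_constriction(
    prof$width_um, cen, prof$s_um,
    enabled = !identical(sat_search, FALSE))
  arms <- partition_arms(mask, prof$axis, cen,
                         sat_boundary = if (!is.na(sat)) sat else NULL,
                         od = od_map$od)
  short_first <- attr(arms, "short_first")

  arm_len <- function(portion) {
    n <- length(prof$s_um); total <- prof$s_um[n]
    s_cen <- prof$s_um[cen]
    s_sat <- if (!is.na(sat)) prof$s_um[sat] else NA
    if (portion == "S") {
      if (short_first) s_cen - (if (!is.na(sat)) s_sat else 0)
      else total - s_cen - (if (!is.na(sat)) total - s_sat else 0)
    } else if (portion == "L") {
      if (short_first) total - s_cen else s_cen
    } else {
      if (short_first) s_sat else total - s_sat
    }
  }
  portions <- names(arms)
  meas <- do.call(rbind, lapply(portions, function(p) {
    m <- integrate_iod(od_map, arms[[p]])
    data.frame(portion = p, length_um = arm_len(p), area_um2 = m$area_um2,
               mean_od = m$mean_od, iod = m$iod, saturated = m$saturated)
  }))
  tot <- integrate_iod(od_map, mask)
  s_len <- meas$length_um[meas$portion == "S"]
  l_len <- meas$length_um[meas$portion == "L"]
  r <- l_len / s_len
  structure(list(profile = prof, centromere = cen, sat_boundary = sat,
                 arms = arms, portions = meas,
                 total_length_um = prof$total_length_um,
                 area_um2 = tot$area_um2, mean_od = tot$mean_od,
                 iod = tot$iod, saturated = tot$saturated,
                 arm_ratio = r, ci = 100 * s_len / (s_len + l_len),
                 class = classify_class(max(r, 1))),
            class = "chromosome_measurement")
}

#' @export
print.chromosome_measurement <- function(x, ...) {
  cat(sprintf(paste0("chromosome_measurement: L = %.2f um, area = %.2f um^2,",
                     " IOD = %.3f, r = %.2f, CI = %.1f, class %s%s\n"),
              x$total_length_um, x$area_um2, x$iod, x$arm_ratio, x$ci,
              x$class, if (!is.na(x$sat_boundary)) " (+SAT)" else ""))
  invisible(x)
}
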