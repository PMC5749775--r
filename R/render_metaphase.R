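#' Render a synthetic metaphase plate with exact ground truth
#'
#' Draws each chromosome of a [karyotype_spec()] as a curved capsule on a
#' clear field. The chromosome axis follows a sinusoidally varying heading
#' (unit speed, so arc length is exact); the width profile narrows by
#' `dip_depth` at the primary constriction (and at the satellite boundary
#' where a satellite is present) and tapers elliptically to zero at the
#' telomeres. Stain follows Beer-Lambert absorbance: the rendered optical
#' density integrates, per arm/satellite region, to exactly
#' `iod_per_pg x` the region's true DNA mass (see
#' [spec_portion_masses()]), and pixel intensity is
#' `I0 * g(p) * 10^(-OD(p))` plus noise, quantised to the camera bit depth.
#'
#' Chromosomes are placed by rejection sampling with a clearance margin
#' (isolated, cytoplasm-free spread); `touching_pairs > 0` instead places
#' that many homolog pairs in tip-to-tip contact to stress downstream
#' object splitting.
#'
#' @param spec a [karyotype_spec()].
#' @param params an [image_params()].
#' @return A list of class `metaphase_render` with elements
#'   \describe{
#'     \item{image}{integer matrix of counts (16-bit container).}
#'     \item{od_true}{matrix of noise-free true optical density.}
#'     \item{truth}{ground truth: one record per rendered chromosome with
#'       pair id, homolog index, global pixel indices and their
#'       arm/satellite region labels, axis polyline (pixel coordinates),
#'       arc lengths, centromere and satellite boundary positions, and true
#'       per-region DNA masses (pg) and integrated optical densities.}
#'     \item{params, spec}{the inputs.}
#'   }
#' @export
render_metaphase <- function(spec, params = image_params()) {
  stopifnot(inherits(spec, "karyotype_spec"), inherits(params, "image_params"))
  with_local_seed(params$seed, render_metaphase_impl(spec, params))
}

render_metaphase_impl <- function(spec, params) {
  px <- params$pixel_size_um
  nr <- params$canvas_px[1]; nc <- params$canvas_px[2]
  masses <- spec_portion_masses(spec)
  K <- params$iod_per_pg
  ds <- px / 2

  # per-chromosome templates (local coordinates, micrometres)
  chroms <- list()
  for (i in seq_len(nrow(spec$pairs))) {
    p <- spec$pairs[i, ]
    for (h in 1:2) {
      chroms[[length(chroms) + 1]] <-
        chromosome_template(p, spec, ds)
    }
  }
  ord <- order(-vapply(chroms, function(ch) ch$ltot, 0))
  meta <- data.frame(idx = ord)
  meta$pair_id <- rep(spec$pairs$pair_id, each = 2)[ord]
  meta$homolog <- rep(1:2, nrow(spec$pairs))[ord]

  # placement: rejection sampling of centre + orientation
  placed <- vector("list", length(chroms))
  boxes <- list()
  touch_anchor <- list()  # pair_id -> placed homolog-1 info
  wpx <- spec$width_um / px
  for (k in seq_along(ord)) {
    ch <- chroms[[ord[k]]]
    pid <- meta$pair_id[k]; hom <- meta$homolog[k]
    is_touch <- pid <= params$touching_pairs
    ok <- FALSE
    for (att in seq_len(params$max_attempts)) {
      if (is_touch && hom == 2 && !is.null(touch_anchor[[as.character(pid)]])) {
        anc <- touch_anchor[[as.character(pid)]]
        # widen the contact angle progressively if placements keep failing
        jit <- 0.3 + 1.2 * att / params$max_attempts
        theta <- anc$end_heading + stats::runif(1, -jit, jit)
        rot <- rotate_axis(ch, theta)
        rx <- rot$x / px; ry <- rot$y / px
        # start tip slightly overlapping the anchor's end tip
        shift <- anc$end_xy - 0.02 * wpx *
          c(cos(anc$end_heading), sin(anc$end_heading)) - c(rx[1], ry[1])
        gx <- rx + shift[1]; gy <- ry + shift[2]
        skip_box <- anc$box_id
      } else {
        theta <- stats::runif(1, 0, 2 * pi)
        rot <- rotate_axis(ch, theta)
        rx <- rot$x / px; ry <- rot$y / px
        pad <- wpx / 2 + params$margin_px + 2
        spanx <- range(rx); spany <- range(ry)
        if (diff(spanx) + 2 * pad >= nc || diff(spany) + 2 * pad >= nr) next
        cx <- stats::runif(1, pad - spanx[1], nc - pad - spanx[2])
        cy <- stats::runif(1, pad - spany[1], nr - pad - spany[2])
        gx <- rx + cx; gy <- ry + cy
        skip_box <- 0L
      }
      if (min(gx) < 2 || min(gy) < 2 || max(gx) > nc - 1 || max(gy) > nr - 1) next
      box <- c(min(gx), max(gx), min(gy), max(gy)) +
        c(-1, 1, -1, 1) * (wpx / 2 + params$margin_px)
      clash <- FALSE
      for (b in seq_along(boxes)) {
        if (b == skip_box) next
        o <- boxes[[b]]
        if (box[1] <= o[2] && o[1] <= box[2] && box[3] <= o[4] && o[3] <= box[4]) {
          clash <- TRUE; break
        }
      }
      if (clash) next
      boxes[[length(boxes) + 1]] <- box
      nhead <- length(gx)
      end_heading <- atan2(gy[nhead] - gy[nhead - 1], gx[nhead] - gx[nhead - 1])
      placed[[k]] <- list(x = gx, y = gy, ch = ch)
      if (is_touch && hom == 1)
        touch_anchor[[as.character(pid)]] <-
          list(end_xy = c(gx[nhead], gy[nhead]), end_heading = end_heading,
               box_id = length(boxes))
      ok <- TRUE
      break
    }
    if (!ok)
      stop(sprintf(paste0("placement failure: chromosome pair %d does not fit ",
                          "a %dx%d canvas without contact; enlarge canvas_px ",
                          "or reduce margin_px"), pid, nr, nc))
  }

  # rasterise
  od <- matrix(0, nr, nc)
  truth <- vector("list", length(placed))
  for (k in seq_along(placed)) {
    pl <- placed[[k]]; ch <- pl$ch
    pid <- meta$pair_id[k]
    ras <- rasterize_chromosome(pl$x, pl$y, ch, spec, px, nr, nc)
    m <- masses[masses$pair_id == pid, , drop = FALSE]
    iods <- numeric(length(ras$idx))
    reg_mass <- stats::setNames(m$mass_pg, m$portion)
    reg_iod <- stats::setNames(rep(0, nrow(m)), m$portion)
    for (rg in m$portion) {
      sel <- ras$region == rg
      tot <- sum(ras$od[sel]) * px^2
      if (tot <= 0) stop("degenerate region in rasterisation: ", rg)
      f <- K * reg_mass[[rg]] / tot
      iods[sel] <- ras$od[sel] * f
      reg_iod[[rg]] <- K * reg_mass[[rg]]
    }
    od[ras$idx] <- od[ras$idx] + iods
    truth[[k]] <- list(
      pair_id = pid, homolog = meta$homolog[k],
      pixels = ras$idx, region = ras$region,
      axis_x = pl$x, axis_y = pl$y, s_um = ch$s,
      sat_s_um = ch$sat_s, centromere_s_um = ch$cen_s,
      length_um = ch$ltot,
      portion_length_um = stats::setNames(m$length_um, m$portion),
      mass_pg = reg_mass, iod = reg_iod,
      total_mass_pg = sum(reg_mass), total_iod = sum(reg_iod))
  }

  # intensity with illumination gradient, noise, quantisation
  g <- matrix(rep(1 + params$gradient_amp * (seq_len(nc) / nc - 0.5),
                  each = nr), nr, nc)
  expected <- params$i0 * g * 10^(-od)
  img <- if (params$poisson) {
    matrix(stats::rpois(nr * nc, lambda = expected), nr, nc)
  } else expected
  if (params$noise_sd > 0)
    img <- img + matrix(stats::rnorm(nr * nc, 0, params$noise_sd), nr, nc)
  img <- round(pmin(pmax(img, 0), 2^params$bits - 1))
  storage.mode(img) <- "integer"

  structure(list(image = img, od_true = od, truth = truth,
                 params = params, spec = spec),
            class = "metaphase_render")
}

# axis samples, width and density-multiplier profiles for one chromosome
# (local coordinates centred on the axis centroid)
chromosome_template <- function(pair, spec, ds) {
  ltot <- pair$sat_um + pair$short_um + pair$long_um
  s <- seq(0, ltot, by = ds)
  lambda <- ltot * stats::runif(1, 1.3, 2.5)
  bend <- stats::runif(1, 0.15, 0.55) * sample(c(-1, 1), 1)
  phase <- stats::runif(1, 0, 2 * pi)
  heading <- bend * sin(2 * pi * s / lambda + phase)
  x <- cumsum(cos(heading)) * ds; x <- x - mean(x)
  y <- cumsum(sin(heading)) * ds; y <- y - mean(y)

  W <- spec$width_um
  sat_s <- if (pair$sat_um > 0) pair$sat_um else NA_real_
  cen_s <- pair$sat_um + pair$short_um
  w <- rep(1, length(s))
  w <- w - spec$dip_depth * exp(-(s - cen_s)^2 / (2 * spec$dip_sd_um^2))
  if (!is.na(sat_s))
    w <- w - spec$dip_depth * exp(-(s - sat_s)^2 / (2 * spec$dip_sd_um^2))
  tl <- W / 2
  dtip <- pmin(s, ltot - s)
  tap <- ifelse(dtip < tl, sqrt(pmax(0, 1 - ((tl - dtip) / tl)^2)), 1)
  w <- pmax(W * w * tap, 0)

  mult <- rep(1, length(s))
  kn <- spec$knobs[spec$knobs$pair_id == pair$pair_id, , drop = FALSE]
  if (nrow(kn)) {
    for (j in seq_len(nrow(kn))) {
      if (kn$arm[j] == "L") {
        ctr <- cen_s + kn$rel_pos[j] * pair$long_um
        lo <- max(cen_s, ctr - kn$length_um[j] / 2)
        hi <- min(ltot, lo + kn$length_um[j])
      } else {
        ctr <- cen_s - kn$rel_pos[j] * pair$short_um
        hi <- min(cen_s, ctr + kn$length_um[j] / 2)
        lo <- max(pair$sat_um, hi - kn$length_um[j])
      }
      mult[s >= lo & s < hi] <- mult[s >= lo & s < hi] + (kn$density_mult[j] - 1)
    }
  }
  region <- ifelse(s < pair$sat_um, "SAT", ifelse(s < cen_s, "S", "L"))
  list(s = s, x = x, y = y, w = w, mult = mult, region = region,
       ltot = ltot, sat_s = sat_s, cen_s = cen_s)
}

rotate_axis <- function(ch, theta) {
  # template coordinates stay in micrometres; caller converts to pixels
  list(x = ch$x * cos(theta) - ch$y * sin(theta),
       y = ch$x * sin(theta) + ch$y * cos(theta))
}

# nearest-axis-sample rasterisation of one placed chromosome
rasterize_chromosome <- function(gx_um, gy_um, ch, spec, px, nr, nc) {
  ax <- gx_um; ay <- gy_um  # already in pixel units by placement convention
  half_w_px <- ch$w / (2 * px)
  x0 <- max(1L, floor(min(ax) - max(half_w_px) - 2))
  x1 <- min(nc, ceiling(max(ax) + max(half_w_px) + 2))
  y0 <- max(1L, floor(min(ay) - max(half_w_px) - 2))
  y1 <- min(nr, ceiling(max(ay) + max(half_w_px) + 2))
  pxs <- rep(x0:x1, each = y1 - y0 + 1)
  pys <- rep(y0:y1, times = x1 - x0 + 1)
  d2 <- outer(pxs, ax, "-")^2
  d2 <- d2 + outer(pys, ay, "-")^2
  j <- max.col(-d2, ties.method = "first")
  dmin <- d2[cbind(seq_along(j), j)]
  keep <- dmin <= half_w_px[j]^2 & half_w_px[j] > 0
  j <- j[keep]
  rows <- pys[keep]; cols <- pxs[keep]
  odv <- ch$mult[j]  # relative areal density; renormalised per region later
  list(idx = (cols - 1L) * nr + rows, od = odv, region = ch$region[j],
       nearest_s = ch$s[j])
}
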