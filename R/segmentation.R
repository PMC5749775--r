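#' Segment individual chromosomes from an optical-density map
#'
#' Global Otsu threshold on the density map, connected-component labelling,
#' then marker-based watershed splitting (on the distance transform) of any
#' component larger than 1.6 times the median component area - the
#' signature of touching chromosomes - followed by a minimum-size filter.
#'
#' @param od_map an [to_od()] map (or a plain OD matrix).
#' @param min_area_px discard objects smaller than this, pixels.
#' @param max_objects keep at most this many objects (largest first).
#' @param expected_n optional expected chromosome count (2n); a differing
#'   count raises a warning.
#' @return List of logical mask matrices, one per object, ordered by
#'   decreasing area.
#' @export
segment_chromosomes <- function(od_map, min_area_px = 200,
                                max_objects = Inf, expected_n = NULL) {
  od <- if (inherits(od_map, "od_map")) od_map$od else od_map
  stopifnot(is.matrix(od), all(is.finite(od)))
  rng <- range(od)
  if (diff(rng) == 0) stop("no objects: optical density map is constant")
  if (rng[2] < 0.1)
    stop("no objects: maximum optical density below the detection floor")
  thr <- EBImage::otsu(EBImage::Image((od - rng[1]) / diff(rng)),
                       range = c(0, 1))
  bin <- EBImage::fillHull((od - rng[1]) / diff(rng) > thr)
  lab <- EBImage::bwlabel(bin)
  nlab <- max(lab)
  if (nlab == 0) stop("no objects found above the density threshold")
  areas <- tabulate(lab[lab > 0], nbins = nlab)
  med <- stats::median(areas[areas >= min_area_px])
  if (is.na(med)) med <- stats::median(areas)
  oversized <- areas > 1.6 * med
  # when fewer components than expected chromosomes, the deficit must sit
  # in merged components: nominate the largest ones for splitting too
  if (!is.null(expected_n) && nlab < expected_n) {
    extra <- setdiff(order(-areas), which(oversized))
    need <- min(expected_n - nlab, length(extra))
    if (need > 0) oversized[extra[seq_len(need)]] <- TRUE
  }

  masks <- list()
  for (l in seq_len(nlab)) {
    m <- lab == l
    if (oversized[l]) {
      dm <- EBImage::distmap(m)
      # start conservative and lower the merge tolerance until the blob
      # splits; contact necks are thinner than primary constrictions, so
      # they give way first
      ws <- m * 0L
      for (tf in c(0.5, 0.4, 0.3, 0.2)) {
        ws <- EBImage::watershed(dm, tolerance = tf * max(dm), ext = 3)
        if (max(ws) >= 2) break
      }
      for (w in seq_len(max(ws))) {
        sub <- ws == w
        if (sum(sub) >= min_area_px) masks[[length(masks) + 1]] <- sub
      }
    } else if (areas[l] >= min_area_px) {
      masks[[length(masks) + 1]] <- m
    }
  }
  if (!length(masks)) stop("no objects remain after size filtering")
  masks <- masks[order(-vapply(masks, sum, 0))]
  if (is.finite(max_objects) && length(masks) > max_objects)
    masks <- masks[seq_len(max_objects)]
  if (!is.null(expected_n) && length(masks) != expected_n)
    warning(sprintf("segmented %d objects but expected %d",
                    length(masks), expected_n))
  masks
}
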