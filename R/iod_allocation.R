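#' Integrated optical density of a masked object
#'
#' `area = n_px * um^2/px`, `mean_od` = mean density over the mask, and
#' `iod = sum(OD) * um^2/px`, so `iod = area * mean_od` holds identically.
#'
#' @param od_map an [to_od()] map.
#' @param mask logical matrix, non-empty.
#' @return List with `area_um2`, `mean_od`, `iod` and `saturated` (TRUE if
#'   any capped pixel falls inside the mask).
#' @export
integrate_iod <- function(od_map, mask) {
  stopifnot(inherits(od_map, "od_map"))
  mask <- mask > 0
  n <- sum(mask)
  if (n == 0) stop("empty mask")
  a_px <- od_map$pixel_size_um^2
  vals <- od_map$od[mask]
  list(area_um2 = n * a_px, mean_od = mean(vals), iod = sum(vals) * a_px,
       saturated = any(od_map$saturated[mask]))
}

#' Aggregate per-homolog IODs into pair-level records across metaphases
#'
#' The pair-level 2C IOD of a chromosome is the mean over metaphases of
#' the summed IOD of its two homologs; the same rule per arm/satellite
#' portion gives the portion-level IOD, so portions sum to their pair
#' exactly in every metaphase and in the aggregate. Metaphases missing a
#' homolog of a pair are excluded for that pair (with a warning).
#'
#' @param records data frame with columns `metaphase`, `pair_id`,
#'   `homolog` (1/2), `portion` (`"S"`, `"L"`, `"SAT"`) and `iod`.
#' @return A list of class `iod_record`: `pairs` (pair_id, iod_c, n),
#'   `portions` (pair_id, portion, iod_b), `per_metaphase` (metaphase,
#'   pair_id, iod_pair) and per-metaphase portion detail
#'   `per_metaphase_portions`.
#' @export
aggregate_pair_iod <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("metaphase", "pair_id", "homolog", "portion", "iod")
                %in% names(records)))
  if (any(records$iod < 0)) stop("negative IOD in records")
  # completeness: both homologs of a pair in a metaphase
  hom <- unique(records[, c("metaphase", "pair_id", "homolog")])
  n_hom <- stats::aggregate(homolog ~ metaphase + pair_id, hom,
                            FUN = function(h) length(unique(h)))
  bad <- n_hom[n_hom$homolog != 2, , drop = FALSE]
  if (nrow(bad)) {
    warning(sprintf("excluding %d metaphase/pair combination(s) with a missing homolog",
                    nrow(bad)))
    for (b in seq_len(nrow(bad)))
      records <- records[!(records$metaphase == bad$metaphase[b] &
                             records$pair_id == bad$pair_id[b]), ]
  }
  if (!nrow(records)) stop("no complete pairs remain")

  pm_port <- stats::aggregate(iod ~ metaphase + pair_id + portion, records, sum)
  pm <- stats::aggregate(iod ~ metaphase + pair_id, pm_port, sum)
  names(pm)[3] <- "iod_pair"
  pairs <- stats::aggregate(iod_pair ~ pair_id, pm, mean)
  names(pairs)[2] <- "iod_c"
  nmet <- stats::aggregate(metaphase ~ pair_id, pm,
                           FUN = function(m) length(unique(m)))
  pairs$n <- nmet$metaphase[match(pairs$pair_id, nmet$pair_id)]
  portions <- stats::aggregate(iod ~ pair_id + portion, pm_port, mean)
  names(portions)[3] <- "iod_b"
  portions <- portions[order(portions$pair_id, portions$portion), ]
  structure(list(pairs = pairs[order(pairs$pair_id), ],
                 portions = portions,
                 per_metaphase = pm, per_metaphase_portions = pm_port),
            class = "iod_record")
}

#' Allocate the nuclear 2C DNA amount over chromosome pairs
#'
#' Proportional allocation: `2C_c = 2C_n * IOD_c / IOD_t` with
#' `IOD_t = sum(IOD_c)`, so the pair values conserve the nuclear amount
#' exactly. When per-metaphase records are available the same allocation
#' is computed within each metaphase and the across-metaphase standard
#' deviation is reported.
#'
#' @param nuclear a [mean_over_replicates()] estimate or a plain 2C value
#'   in pg.
#' @param pair_iods an [aggregate_pair_iod()] record, or a numeric vector
#'   of pair-level IODs named by pair id.
#' @return A list of class `dna_allocation` with `pairs` (data frame:
#'   pair_id, iod_c, dna_2c_pg, sd_pg, one_c_bp_e9), `iod_t` and
#'   `nuclear_2c`.
#' @export
allocate_2c <- function(nuclear, pair_iods) {
  n2c <- if (inherits(nuclear, "nuclear_dna_estimate")) nuclear$mean_2c
         else as.numeric(nuclear)
  stopifnot(length(n2c) == 1, n2c > 0)
  if (inherits(pair_iods, "iod_record")) {
    agg <- pair_iods
    iod_c <- stats::setNames(agg$pairs$iod_c, agg$pairs$pair_id)
  } else {
    agg <- NULL
    iod_c <- pair_iods
    if (is.null(names(iod_c))) names(iod_c) <- seq_along(iod_c)
  }
  if (any(iod_c <= 0)) stop("all pair IODs must be positive")
  iod_t <- sum(iod_c)
  dna <- n2c * iod_c / iod_t
  sds <- rep(NA_real_, length(dna))
  if (!is.null(agg)) {
    pm <- agg$per_metaphase
    tot <- tapply(pm$iod_pair, pm$metaphase, sum)
    alloc_m <- n2c * pm$iod_pair / as.numeric(tot[as.character(pm$metaphase)])
    sds <- as.numeric(tapply(alloc_m, factor(pm$pair_id, names(iod_c)),
                             stats::sd))
  }
  pairs <- data.frame(pair_id = as.integer(names(iod_c)),
                      iod_c = as.numeric(iod_c),
                      dna_2c_pg = as.numeric(dna), sd_pg = sds,
                      one_c_bp_e9 = pg_to_bp(two_c_to_one_c(dna)) / 1e9)
  structure(list(pairs = pairs, iod_t = iod_t, nuclear_2c = n2c),
            class = "dna_allocation")
}

#' Allocate the nuclear 2C DNA amount over arms and satellites
#'
#' Portion-level proportional allocation against the whole-complement IOD:
#' `2C_b = 2C_n * IOD_b / IOD_t`. Because the portion IODs partition each
#' pair's IOD, portion values sum to the pair value and pair values sum to
#' the nuclear 2C, both exactly.
#'
#' @param nuclear as in [allocate_2c()].
#' @param arm_iods an [aggregate_pair_iod()] record, or a data frame with
#'   columns `pair_id`, `portion`, `iod_b`.
#' @return A list of class `dna_allocation` with `portions` and `pairs`
#'   data frames (columns as in [allocate_2c()] plus `portion`), `iod_t`
#'   and `nuclear_2c`.
#' @export
allocate_arm_2c <- function(nuclear, arm_iods) {
  n2c <- if (inherits(nuclear, "nuclear_dna_estimate")) nuclear$mean_2c
         else as.numeric(nuclear)
  stopifnot(length(n2c) == 1, n2c > 0)
  if (inherits(arm_iods, "iod_record")) {
    agg <- arm_iods
    pt <- agg$portions
  } else {
    agg <- NULL
    pt <- as.data.frame(arm_iods)
    stopifnot(all(c("pair_id", "portion", "iod_b") %in% names(pt)))
  }
  if (any(pt$iod_b <= 0)) stop("all portion IODs must be positive")
  iod_t <- sum(pt$iod_b)
  pt$dna_2c_pg <- n2c * pt$iod_b / iod_t
  pt$sd_pg <- NA_real_
  if (!is.null(agg)) {
    pmp <- agg$per_metaphase_portions
    tot <- tapply(pmp$iod, pmp$metaphase, sum)
    alloc_m <- n2c * pmp$iod / as.numeric(tot[as.character(pmp$metaphase)])
    key <- paste(pmp$pair_id, pmp$portion)
    sd_by <- tapply(alloc_m, key, stats::sd)
    pt$sd_pg <- as.numeric(sd_by[paste(pt$pair_id, pt$portion)])
  }
  pt$one_c_bp_e9 <- pg_to_bp(two_c_to_one_c(pt$dna_2c_pg)) / 1e9
  pair_sum <- stats::aggregate(dna_2c_pg ~ pair_id, pt, sum)
  pair_iod <- stats::aggregate(iod_b ~ pair_id, pt, sum)
  pairs <- data.frame(pair_id = pair_sum$pair_id,
                      iod_c = pair_iod$iod_b,
                      dna_2c_pg = pair_sum$dna_2c_pg,
                      one_c_bp_e9 = pg_to_bp(two_c_to_one_c(pair_sum$dna_2c_pg)) / 1e9)
  structure(list(portions = pt[order(pt$pair_id, pt$portion), ],
                 pairs = pairs[order(pairs$pair_id), ],
                 iod_t = iod_t, nuclear_2c = n2c),
            class = "dna_allocation")
}

#' @export
print.dna_allocation <- function(x, ...) {
  cat(sprintf("dna_allocation: %d pairs, nuclear 2C = %.3f pg, IOD_t = %.3f\n",
              nrow(x$pairs), x$nuclear_2c, x$iod_t))
  invisible(x)
}

#' Convert a DNA mass in picograms to base pairs
#'
#' Uses the standard equivalence 1 pg = 0.978e9 bp.
#'
#' @param pg DNA amount in pg (>= 0).
#' @return DNA amount in base pairs.
#' @export
pg_to_bp <- function(pg) {
  if (any(pg < 0)) stop("DNA amount must be non-negative")
  pg * 0.978e9
}

#' Halve a 2C DNA amount to its 1C value
#' @param pg 2C DNA amount in pg (>= 0).
#' @return 1C DNA amount in pg.
#' @export
two_c_to_one_c <- function(pg) {
  if (any(pg < 0)) stop("DNA amount must be non-negative")
  pg / 2
}

#' Format an arm-level allocation like the published reference table
#'
#' @param alloc a [allocate_arm_2c()] result.
#' @return Data frame with columns `chromosome`, `portion`, `dna_2c_pg`
#'   (3 decimals), `sd_pg`, `one_c_bp_e9` (3 decimals); portions ordered
#'   SAT, S, L within each chromosome.
#' @export
allocation_table <- function(alloc) {
  stopifnot(inherits(alloc, "dna_allocation"), !is.null(alloc$portions))
  pt <- alloc$portions
  ord <- order(pt$pair_id, match(pt$portion, c("SAT", "S", "L")))
  pt <- pt[ord, ]
  data.frame(chromosome = pt$pair_id, portion = pt$portion,
             dna_2c_pg = round(pt$dna_2c_pg, 3),
             sd_pg = round(pt$sd_pg, 3),
             one_c_bp_e9 = round(pt$one_c_bp_e9, 3))
}
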