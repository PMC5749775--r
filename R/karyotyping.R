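#' Pair homologous chromosomes within a metaphase
#'
#' Greedy minimum-weight matching on the Euclidean distance over z-scored
#' features (total length, centromeric index, IOD): the closest unpaired
#' couple is matched first, repeatedly. Chromosomal DNA amount (through
#' IOD) is what disambiguates morphologically similar pairs. Ties are
#' broken deterministically by object index, and tied matchings are
#' flagged ambiguous.
#'
#' @param measurements list of [measure_chromosome()] objects (or a data
#'   frame with columns `length_um`, `ci`, `iod`), of even length.
#' @param weights feature weights applied after z-scoring.
#' @return Data frame with one row per pair: `member1`, `member2` (indices
#'   into `measurements`), `distance`, `ambiguous`.
#' @export
pair_homologs <- function(measurements,
                          weights = c(length = 1, ci = 1, iod = 1)) {
  feat <- homolog_features(measurements)
  n <- nrow(feat)
  if (n %% 2 != 0) stop("odd number of chromosomes; cannot pair homologs")
  z <- scale(as.matrix(feat[, c("length_um", "ci", "iod")]))
  z[is.nan(z)] <- 0
  z <- sweep(z, 2, sqrt(weights[c("length", "ci", "iod")]), `*`)
  d <- as.matrix(stats::dist(z))
  diag(d) <- Inf
  out <- NULL
  alive <- rep(TRUE, n)
  while (any(alive)) {
    dd <- d
    dd[!alive, ] <- Inf; dd[, !alive] <- Inf
    best <- min(dd)
    hits <- which(dd == best, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    ambiguous <- nrow(hits) > 1
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    out <- rbind(out, data.frame(member1 = i, member2 = j, distance = best,
                                 ambiguous = ambiguous))
    alive[c(i, j)] <- FALSE
  }
  out
}

homolog_features <- function(measurements) {
  if (is.data.frame(measurements)) {
    stopifnot(all(c("length_um", "ci", "iod") %in% names(measurements)))
    out <- measurements[, c("length_um", "ci", "iod")]
    out$sat_um <- measurements$sat_um %||% 0
    return(out)
  }
  data.frame(
    length_um = vapply(measurements, function(m) m$total_length_um, 0),
    ci = vapply(measurements, function(m) m$ci, 0),
    iod = vapply(measurements, function(m) m$iod, 0),
    sat_um = vapply(measurements, function(m) {
      p <- m$portions
      if ("SAT" %in% p$portion) p$length_um[p$portion == "SAT"] else 0
    }, 0))
}

#' Assign karyotype numbers to homolog pairs
#'
#' `by_length` numbers pairs by descending mean total length (ties broken
#' by centromeric index, then pair order). `reference_map` instead maps
#' each pair to the nearest entry of a reference table of (length, CI),
#' preserving conventional numbering even where it is not strictly
#' size-ordered; any rank inversion between the two modes is flagged.
#'
#' @param pairs result of [pair_homologs()].
#' @param measurements the measurement list/data frame used for pairing.
#' @param mode `"by_length"` or `"reference_map"`.
#' @param reference data frame with columns `number`, `length_um`, `ci`
#'   (required for `reference_map`; must have one row per pair).
#' @return `pairs` with added columns `length_um`, `ci`, `iod` (pair
#'   means), `number`, and `inverted` (TRUE where `reference_map`
#'   numbering disagrees with the length ranking).
#' @export
assign_numbers <- function(pairs, measurements,
                           mode = c("by_length", "reference_map"),
                           reference = NULL) {
  mode <- match.arg(mode)
  feat <- homolog_features(measurements)
  pairs$length_um <- (feat$length_um[pairs$member1] +
                        feat$length_um[pairs$member2]) / 2
  pairs$ci <- (feat$ci[pairs$member1] + feat$ci[pairs$member2]) / 2
  pairs$iod <- (feat$iod[pairs$member1] + feat$iod[pairs$member2]) / 2
  np <- nrow(pairs)
  rank_len <- order(-pairs$length_um, -pairs$ci, seq_len(np))
  by_len_number <- integer(np)
  by_len_number[rank_len] <- seq_len(np)
  if (mode == "by_length") {
    pairs$number <- by_len_number
    pairs$inverted <- FALSE
  } else {
    if (is.null(reference) || nrow(reference) != np)
      stop(sprintf("reference table must have exactly %d rows", np))
    q <- cbind(pairs$length_um, pairs$ci)
    r <- cbind(reference$length_um, reference$ci)
    mu <- colMeans(rbind(q, r)); sdv <- apply(rbind(q, r), 2, stats::sd)
    sdv[sdv == 0] <- 1
    qz <- sweep(sweep(q, 2, mu), 2, sdv, "/")
    rz <- sweep(sweep(r, 2, mu), 2, sdv, "/")
    d <- outer(seq_len(np), seq_len(np), Vectorize(function(i, j)
      sqrt(sum((qz[i, ] - rz[j, ])^2))))
    # satellite presence is (nearly) categorical: penalise mismatches
    if (!is.null(reference$sat_um)) {
      q_sat <- (feat$sat_um[pairs$member1] + feat$sat_um[pairs$member2]) / 2
      d <- d + 4 * abs(outer(q_sat > 0.1, reference$sat_um > 0.1, `!=`))
    }
    number <- integer(np)
    taken_q <- rep(FALSE, np); taken_r <- rep(FALSE, np)
    for (k in seq_len(np)) {
      dd <- d
      dd[taken_q, ] <- Inf; dd[, taken_r] <- Inf
      hit <- which(dd == min(dd), arr.ind = TRUE)[1, ]
      number[hit[1]] <- reference$number[hit[2]]
      taken_q[hit[1]] <- TRUE; taken_r[hit[2]] <- TRUE
    }
    pairs$number <- number
    pairs$inverted <- by_len_number != number
  }
  pairs[order(pairs$number), ]
}

#' Reference morphometry of the default maize-like complement
#'
#' Length/CI table of [default_maize_spec()] used by
#' [assign_numbers()]'s `reference_map` mode to keep conventional
#' chromosome numbers.
#'
#' @return Data frame with `number`, `length_um`, `ci`.
#' @export
maize_reference_karyotable <- function() {
  sp <- default_maize_spec()$pairs
  len <- sp$sat_um + sp$short_um + sp$long_um
  s_side <- sp$short_um
  data.frame(number = sp$pair_id, length_um = len,
             ci = 100 * s_side / (s_side + sp$long_um),
             sat_um = sp$sat_um)
}

#' Assemble a karyogram summary table across metaphases
#'
#' @param records data frame with one row per chromosome pair per
#'   metaphase: columns `metaphase`, `number`, `length_um`, `s_um`,
#'   `l_um`, `sat_um` (0 when absent), `iod` and optionally `dna_2c_pg`.
#' @return A data frame of class `karyogram_table`, one row per pair:
#'   means of the morphometric columns, `arm_ratio`, `ci`, `class`,
#'   `rel_length_pct` (summing to 100), `iod`, and `dna_2c_pg` when
#'   supplied.
#' @export
build_karyogram <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("metaphase", "number", "length_um", "s_um", "l_um",
                  "sat_um", "iod") %in% names(records)))
  agg <- function(col) {
    a <- stats::aggregate(records[[col]], list(number = records$number), mean)
    a$x[order(a$number)]
  }
  numbers <- sort(unique(records$number))
  out <- data.frame(number = numbers,
                    length_um = agg("length_um"), s_um = agg("s_um"),
                    l_um = agg("l_um"), sat_um = agg("sat_um"),
                    iod = agg("iod"))
  sd_len <- stats::aggregate(records$length_um,
                             list(number = records$number), stats::sd)
  out$length_sd_um <- sd_len$x[order(sd_len$number)]
  out$arm_ratio <- out$l_um / out$s_um
  out$ci <- 100 * out$s_um / (out$s_um + out$l_um)
  out$class <- classify_class(pmax(out$arm_ratio, 1))
  out$rel_length_pct <- 100 * out$length_um / sum(out$length_um)
  if ("dna_2c_pg" %in% names(records)) out$dna_2c_pg <- agg("dna_2c_pg")
  class(out) <- c("karyogram_table", "data.frame")
  out
}

#' Draw an ideogram of a karyogram table as SVG
#'
#' One vertical bar per pair, split at the centromere, satellite drawn
#' distal on the short arm where present, annotated with relative arm
#' length and arm ratio.
#'
#' @param karyogram a [build_karyogram()] table.
#' @param px_per_um vertical scale.
#' @return A list of class `ideogram_svg` with `svg` (character scalar).
#' @export
build_ideogram <- function(karyogram, px_per_um = 18) {
  k <- karyogram
  bar_w <- 26; gap <- 64; top <- 40
  height <- top + max(k$length_um) * px_per_um + 70
  width <- gap * nrow(k) + 40
  el <- c(sprintf(
    paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" ',
           'font-family="sans-serif" font-size="9">'),
    round(width), round(height)))
  base_y <- top + max(k$length_um) * px_per_um
  for (i in seq_len(nrow(k))) {
    x <- 20 + (i - 1) * gap
    l_px <- k$l_um[i] * px_per_um
    s_px <- k$s_um[i] * px_per_um
    sat_px <- k$sat_um[i] * px_per_um
    # long arm sits below the centromere line, short arm (+ satellite) above
    cen_y <- base_y - l_px
    el <- c(el,
      sprintf('<rect x="%g" y="%g" width="%d" height="%g" rx="6" fill="#555"/>',
              x, cen_y, bar_w, l_px),
      sprintf('<rect x="%g" y="%g" width="%d" height="%g" rx="6" fill="#999"/>',
              x, cen_y - s_px - 2, bar_w, s_px))
    if (sat_px > 0)
      el <- c(el, sprintf(
        '<rect x="%g" y="%g" width="%d" height="%g" rx="3" fill="#bbb"/>',
        x, cen_y - s_px - sat_px - 6, bar_w, sat_px))
    el <- c(el,
      sprintf('<text x="%g" y="%g" text-anchor="middle">%d</text>',
              x + bar_w / 2, base_y + 14, k$number[i]),
      sprintf('<text x="%g" y="%g" text-anchor="middle">%.1f%%</text>',
              x + bar_w / 2, base_y + 28, k$rel_length_pct[i]),
      sprintf('<text x="%g" y="%g" text-anchor="middle">r=%.2f (%s)</text>',
              x + bar_w / 2, base_y + 42, k$arm_ratio[i], k$class[i]))
  }
  el <- c(el, "</svg>")
  structure(list(svg = paste(el, collapse = "\n"), table = k),
            class = "ideogram_svg")
}

#' @export
print.ideogram_svg <- function(x, ...) {
  cat(sprintf("ideogram_svg: %d pairs, %d bytes of SVG\n",
              nrow(x$table), nchar(x$svg)))
  invisible(x)
}

#' Write an ideogram to an SVG file
#' @param ideogram a [build_ideogram()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ideogram_svg <- function(ideogram, path) {
  stopifnot(inherits(ideogram, "ideogram_svg"))
  writeLines(ideogram$svg, path)
  invisible(path)
}

#' Compare chromosomal DNA values against a reference study
#'
#' Per-chromosome percent differences, reported explicitly in both
#' directions: `pct_vs_reference = 100 * (query - reference) / reference`
#' (the reference value is the denominator) and the converse
#' `pct_vs_query`.
#'
#' @param query data frame with columns `chromosome` and `value`.
#' @param reference data frame with columns `chromosome` and `value`;
#'   every query chromosome must be present.
#' @return Data frame with `chromosome`, `query`, `reference`,
#'   `pct_vs_reference`, `pct_vs_query`.
#' @export
compare_to_reference <- function(query, reference) {
  stopifnot(all(c("chromosome", "value") %in% names(query)),
            all(c("chromosome", "value") %in% names(reference)))
  m <- match(query$chromosome, reference$chromosome)
  if (anyNA(m))
    stop("reference is missing chromosome(s): ",
         paste(query$chromosome[is.na(m)], collapse = ", "))
  ref <- reference$value[m]
  data.frame(chromosome = query$chromosome, query = query$value,
             reference = ref,
             pct_vs_reference = 100 * (query$value - ref) / ref,
             pct_vs_query = 100 * (ref - query$value) / query$value)
}
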