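#' Write / read a karyotype spec as JSON
#'
#' @param spec a [karyotype_spec()].
#' @param path JSON file.
#' @return `path` invisibly; `read_karyotype_spec_json()` returns the
#'   reconstructed [karyotype_spec()] (round-trips exactly).
#' @export
write_karyotype_spec_json <- function(spec, path) {
  stopifnot(inherits(spec, "karyotype_spec"))
  jsonlite::write_json(list(pairs = spec$pairs, knobs = spec$knobs,
                            width_um = spec$width_um,
                            dip_depth = spec$dip_depth,
                            dip_sd_um = spec$dip_sd_um),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_karyotype_spec_json
#' @export
read_karyotype_spec_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  kn <- x$knobs
  if (is.null(kn) || !NROW(kn))
    kn <- NULL
  karyotype_spec(as.data.frame(x$pairs), knobs = kn,
                 width_um = x$width_um, dip_depth = x$dip_depth,
                 dip_sd_um = x$dip_sd_um)
}

#' Write the ground truth of a rendered metaphase as JSON
#'
#' Pixel masks are stored as 1-based linear indices into the image matrix.
#'
#' @param render a [render_metaphase()] result.
#' @param path JSON file.
#' @param include_pixels store per-chromosome pixel indices and region
#'   labels (larger files).
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(render, path, include_pixels = FALSE) {
  stopifnot(inherits(render, "metaphase_render"))
  gt <- lapply(render$truth, function(ch) {
    out <- ch[c("pair_id", "homolog", "length_um", "sat_s_um",
                "centromere_s_um", "total_mass_pg", "total_iod")]
    out$mass_pg <- as.list(ch$mass_pg)
    out$iod <- as.list(ch$iod)
    out$portion_length_um <- as.list(ch$portion_length_um)
    if (include_pixels) {
      out$pixels <- ch$pixels
      out$region <- ch$region
    }
    out
  })
  jsonlite::write_json(list(iod_per_pg = render$params$iod_per_pg,
                            canvas_px = render$params$canvas_px,
                            chromosomes = gt),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
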