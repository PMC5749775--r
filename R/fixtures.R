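#' Published maize chromosomal DNA amounts (per arm and satellite)
#'
#' Transcription of the reference table of mean 2C DNA amounts (pg, with
#' standard deviations) and 1C values (bp x 1e9) measured by Feulgen image
#' cytometry for each *Zea mays* 'AL Bandeirante' chromosome arm and for the
#' satellite of chromosome 6.
#'
#' @return A data frame with columns `chromosome` (1-10), `portion`
#'   (`"S"`, `"L"` or `"SAT"`), `dna_2c_pg`, `sd_pg` and `one_c_bp_e9`
#'   (printed 1C value in units of 1e9 bp).
#' @seealso [maize_pair_totals()], [maize_reference_1c()]
#' @export
maize_table1 <- function() {
  df <- data.frame(
    chromosome = c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5, 6, 6, 6, 7, 7, 8, 8, 9, 9, 10, 10),
    portion = c("S", "L", "S", "L", "S", "L", "S", "L", "S", "L",
                "SAT", "S", "L", "S", "L", "S", "L", "S", "L", "S", "L"),
    dna_2c_pg = c(0.376, 0.427, 0.269, 0.456, 0.237, 0.440, 0.239, 0.395,
                  0.271, 0.355, 0.053, 0.171, 0.366, 0.156, 0.408, 0.131,
                  0.402, 0.215, 0.346, 0.131, 0.255),
    sd_pg = c(0.027, 0.017, 0.023, 0.030, 0.024, 0.040, 0.031, 0.040,
              0.019, 0.020, 0.009, 0.021, 0.035, 0.023, 0.026, 0.013,
              0.030, 0.025, 0.028, 0.008, 0.013),
    one_c_bp_e9 = c(0.184, 0.209, 0.132, 0.223, 0.116, 0.215, 0.117, 0.193,
                    0.133, 0.174, 0.026, 0.084, 0.179, 0.076, 0.200, 0.064,
                    0.197, 0.105, 0.169, 0.064, 0.125)
  )
  df
}

#' Per-chromosome 2C totals implied by the published arm table
#'
#' Sums the arm and satellite 2C values of [maize_table1()] per chromosome
#' pair. The grand total is the published nuclear 2C amount (6.10 pg at the
#' printed precision).
#'
#' @return A data frame with columns `chromosome` and `dna_2c_pg`.
#' @export
maize_pair_totals <- function() {
  t1 <- maize_table1()
  agg <- stats::aggregate(dna_2c_pg ~ chromosome, data = t1, FUN = sum)
  agg[order(agg$chromosome), , drop = FALSE]
}

#' Cross-study chromosomal 1C reference values for maize
#'
#' 1C DNA amounts (in units of 1e9 bp) used for cross-study comparison of
#' image-cytometry sizing: flow-karyotyping of chromosome 1, genome
#' sequencing values for chromosomes 1 and 10, and a previous
#' image-cytometry study ('Black Mexican Sweet Corn') chromosome 10.
#'
#' @return A data frame with columns `study`, `chromosome`, `one_c_bp_e9`.
#' @export
maize_reference_1c <- function() {
  data.frame(
    study = c("flow_karyotyping", "sequencing", "sequencing", "icm_bmsc"),
    chromosome = c(1, 1, 10, 10),
    one_c_bp_e9 = c(0.365, 0.301, 0.150, 0.234)
  )
}

#' Published flow-cytometry anchor values for maize nuclear sizing
#'
#' Internal-standard configuration for nuclear 2C estimation: the
#' 'CE-777' standard (2C = 5.57 pg) peaking at channel 200 and the
#' 'AL Bandeirante' sample peaking at channel 219, with the reported
#' peak coefficients of variation.
#'
#' @return A list with `standard_2c_pg`, `standard_channel`,
#'   `sample_channel`, `cv_standard`, `cv_sample`.
#' @export
maize_fcm_reference <- function() {
  list(standard_2c_pg = 5.57, standard_channel = 200, sample_channel = 219,
       cv_standard = 3.20, cv_sample = 3.80)
}
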