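#' Reference median current-density pairs
#'
#' Published per-participant median current densities (A/m^2) for a
#' sixteen-subject older-adult cohort simulated with both idealized and
#' as-placed electrode models under a frontal bilateral montage, together
#' with the reported percent differences. Shipped as a plain-text table and
#' used to validate the percent-difference arithmetic against the printed
#' values.
#'
#' @return data.frame with columns `participant`,
#'   `whole_head_artificial`, `whole_head_real`, `whole_head_pd`,
#'   `brain_artificial`, `brain_real`, `brain_pd`.
#' @export
reference_median_pairs <- function() {
  path <- system.file("extdata", "reference_median_pairs.csv",
                      package = "tdcsflow", mustWork = TRUE)
  utils::read.csv(path)
}
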