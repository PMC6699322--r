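#' Per-slice parameter means for one malignant breast-cancer case
#'
#' Reference per-slice means of the five decay parameters (ADC, slope, D,
#' D* and PF) over the detected lesion of a single malignant case, slices
#' 10-22 of a 12-b-value breast acquisition. Diffusivities are in
#' 1e-3 mm^2/s; `pf_percent` is the perfusion fraction in percent. Useful
#' as a worked example for [case_average()] and [histogram_stats()].
#'
#' @return A tibble with columns `slice`, `adc`, `slope`, `d`, `dstar`,
#'   `pf_percent`.
#' @examples
#' case_average(example_case_slices())
#' @export
example_case_slices <- function() {
  path <- system.file("extdata", "example_case_slices.csv",
                      package = "ivimhsi", mustWork = TRUE)
  as_tibble(utils::read.csv(path))
}
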