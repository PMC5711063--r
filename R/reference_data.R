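#' Bundled reference measurements
#'
#' Small plain-text tables of the bench and human-experiment reference
#' measurements shipped with the package: per-patient displacement summaries
#' of the fluoroscopy verification experiments, the film isodose areas of
#' the seven-group dose verification, the in-field gamma passing rates, and
#' the bench position/compensating errors.  They serve as worked-example
#' inputs (the kinematic and dosimetric formulas are applied to them) and
#' as ordering references for the simulation.
#'
#' @param name one of `"human_verification"`, `"isodose_areas"`,
#'   `"gamma_pass_rates"`, `"compensating_errors"`.
#' @return A data frame.
#' @examples
#' hv <- reference_measurements("human_verification")
#' compensation_rate(hv$sim_mean_mm[1], hv$tgt_mean_mm[1])
#' @export
reference_measurements <- function(name = c("human_verification",
                                            "isodose_areas",
                                            "gamma_pass_rates",
                                            "compensating_errors")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"), package = "respcomp",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
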