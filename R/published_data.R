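#' Printed EC50 comparison table of the emulated study
#'
#' The package ships the printed observed/predicted EC50 comparison table of
#' the crossed clothianidin x prochloraz x temperature study that its
#' defaults emulate: one row per condition with the observed EC50, the
#' predicted EC50, and the printed MDR under each model (CA, EA, SAM).
#' Control rows carry `NA` predictions. The table is used by the report
#' arithmetic checks and as a realistic worked-example input; the model code
#' never reads it.
#'
#' @param design Optional filter: `"mixture"` or `"multiple"`.
#' @return A tibble with columns `design`, `population`, `temperature`,
#'   `prochloraz_conc`, `observed_ec50`, `predicted_ec50`, `mdr_ca`,
#'   `mdr_ea`, `mdr_sam`.
#' @export
published_predictions <- function(design = NULL) {
  path <- system.file("extdata", "published_ec50_predictions.csv",
                      package = "multistress", mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(design)) {
    design <- match.arg(design, c("mixture", "multiple"))
    out <- dplyr::filter(out, .data$design == !!design)
  }
  out
}
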