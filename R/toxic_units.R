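#' Toxic units from measured concentrations
#'
#' Converts measured environmental concentrations into toxic units on the
#' log10 scale: `tu_log10 = log10(measured_conc / reference_ec50)`, where the
#' reference is the acute LC50/EC50 of the most sensitive standard test
#' species for that compound. A measured concentration of zero is below
#' detection: the row is kept but flagged (`below_detection = TRUE`,
#' `tu_log10 = NA`) rather than mapped to minus infinity, and flagged rows
#' are excluded from maxima.
#'
#' @param data Data frame with columns `compound`, `measured_conc` (µg/L,
#'   >= 0) and `reference_ec50` (µg/L, > 0); any identifier columns such as
#'   `sample_id`, `site_id` or `campaign` are carried through.
#' @return The input as a tibble with `tu_log10` and `below_detection` added.
#' @examples
#' toxic_unit(data.frame(compound = "clothianidin",
#'                       measured_conc = 1, reference_ec50 = 1000))
#' @export
toxic_unit <- function(data) {
  req <- c("compound", "measured_conc", "reference_ec50")
  miss <- setdiff(req, names(data))
  if (length(miss))
    ms_abort(paste0("missing column(s): ", paste(miss, collapse = ", ")),
             "multistress_schema_error")
  if (any(!is.finite(data$reference_ec50)) || any(data$reference_ec50 <= 0))
    ms_abort("`reference_ec50` must be positive and finite.",
             "multistress_validation_error")
  if (any(!is.finite(data$measured_conc)) || any(data$measured_conc < 0))
    ms_abort("`measured_conc` must be non-negative and finite.",
             "multistress_validation_error")
  dplyr::mutate(tibble::as_tibble(data),
                below_detection = .data$measured_conc == 0,
                tu_log10 = ifelse(.data$below_detection, NA_real_,
                                  log10(.data$measured_conc / .data$reference_ec50)))
}

#' Per-sample maximum toxic unit
#'
#' For each sample, returns the single compound row with the highest
#' `tu_log10` (TU_max). Flagged (below-detection) rows are excluded; ties are
#' broken by compound name order. A sample in which every compound is below
#' detection raises an error.
#'
#' @param results Output of [toxic_unit()]; grouped per sample via `by`.
#' @param by Column(s) identifying a sample (default `"sample_id"` when
#'   present, otherwise the whole input is one sample).
#' @return Tibble with one row per sample.
#' @export
tu_max <- function(results, by = intersect("sample_id", names(results))) {
  if (!"tu_log10" %in% names(results))
    ms_abort("`results` must come from toxic_unit().", "multistress_schema_error")
  ok <- dplyr::filter(results, !.data$below_detection)
  grouped <- if (length(by)) dplyr::group_by(ok, dplyr::across(dplyr::all_of(by))) else ok
  out <- dplyr::slice_head(
    dplyr::arrange(grouped, dplyr::desc(.data$tu_log10), .data$compound,
                   .by_group = length(by) > 0),
    n = 1)
  out <- dplyr::ungroup(out)
  n_samples <- if (length(by)) nrow(dplyr::distinct(results, dplyr::across(dplyr::all_of(by))))
               else 1L
  if (nrow(out) < n_samples)
    ms_abort("at least one sample has no detected compound (all rows flagged).",
             "multistress_validation_error")
  out
}

#' Aggregate TU_max values to site level
#'
#' Aggregation rule (documented stand-in, recorded in the output): within each
#' sampling campaign the maximum per-sample TU_max is taken, and the site
#' value is the arithmetic mean (on the log10 scale) of the campaign maxima
#' across campaigns/years. Both intermediate layers are retained.
#'
#' @param results Output of [toxic_unit()] with `site_id`, `campaign` and
#'   `sample_id` columns.
#' @return A list with tibbles `samples` (per-sample TU_max), `campaigns`
#'   (per-campaign maxima) and `sites` (per-site mean of campaign maxima,
#'   column `site_tu_log10`); the aggregation rule is stored in
#'   `attr(, "aggregation")`.
#' @export
aggregate_site_tu <- function(results) {
  req <- c("site_id", "campaign", "sample_id")
  miss <- setdiff(req, names(results))
  if (length(miss))
    ms_abort(paste0("missing column(s): ", paste(miss, collapse = ", ")),
             "multistress_schema_error")
  samples <- tu_max(results, by = c("site_id", "campaign", "sample_id"))
  campaigns <- dplyr::summarise(
    dplyr::group_by(samples, .data$site_id, .data$campaign),
    campaign_tu_log10 = max(.data$tu_log10), .groups = "drop")
  sites <- dplyr::summarise(
    dplyr::group_by(campaigns, .data$site_id),
    site_tu_log10 = mean(.data$campaign_tu_log10),
    n_campaigns = dplyr::n(), .groups = "drop")
  structure(list(samples = samples, campaigns = campaigns, sites = sites),
            aggregation = "max within campaign, mean of campaign maxima across campaigns",
            class = "site_tu_summary")
}

#' @export
print.site_tu_summary <- function(x, ...) {
  cat("<site_tu_summary> ", attr(x, "aggregation"), "\n", sep = "")
  print(x$sites)
  invisible(x)
}

#' Most sensitive reference EC50 per compound
#'
#' Helper for building the reference-toxicity table: given candidate reference
#' EC50s from several standard test species, keeps the minimum (most
#' sensitive) per compound.
#'
#' @param candidates Data frame with `compound` and `reference_ec50` columns
#'   (one row per compound x species candidate).
#' @return Tibble with one row per compound.
#' @export
select_reference_ec50 <- function(candidates) {
  if (!all(c("compound", "reference_ec50") %in% names(candidates)))
    ms_abort("need `compound` and `reference_ec50` columns.",
             "multistress_schema_error")
  if (any(!is.finite(candidates$reference_ec50)) || any(candidates$reference_ec50 <= 0))
    ms_abort("`reference_ec50` must be positive and finite.",
             "multistress_validation_error")
  dplyr::summarise(dplyr::group_by(candidates, .data$compound),
                   reference_ec50 = min(.data$reference_ec50), .groups = "drop")
}

#' Linear-scale toxic unit accessor
#'
#' @param tu_log10 Toxic unit(s) on the log10 scale.
#' @return `10^tu_log10`.
#' @export
tu_linear <- function(tu_log10) 10^tu_log10
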