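# Column schema for trial tables. Headers are resolved case-insensitively;
# a bare `dose` column is accepted for `clothianidin_conc`.
trial_columns <- c(
  clothianidin_conc = "clothianidin_conc",
  dose = "clothianidin_conc",
  prochloraz_conc = "prochloraz_conc",
  temperature = "temperature",
  population = "population",
  n_exposed = "n_exposed",
  n_immobile = "n_immobile",
  duration_h = "duration_h",
  replicate = "replicate"
)

required_trial_columns <- c("clothianidin_conc", "prochloraz_conc",
                            "temperature", "population",
                            "n_exposed", "n_immobile")

#' Read a treatment-level trial table
#'
#' Reads a delimited text file (comma by default, tab accepted) with one row
#' per treatment (or replicate): clothianidin concentration (µg/L),
#' prochloraz concentration (µg/L), temperature (°C), population label,
#' number exposed and number immobile at the end of the exposure. Header
#' names are matched case-insensitively; `dose` is accepted as an alias for
#' `clothianidin_conc`. A missing `duration_h` column defaults to 48 h;
#' `replicate` is optional. All record invariants are validated and row order
#' is preserved; duplicate condition rows are allowed (replicates).
#'
#' @param path Path to a CSV/TSV file.
#' @param delim Field delimiter; `NULL` (default) chooses tab for `.tsv`/
#'   `.tab` files and comma otherwise.
#' @return A validated tibble of trial records.
#' @export
read_trial_table <- function(path, delim = NULL) {
  if (!file.exists(path))
    ms_abort(paste0("file not found: ", path), "multistress_io_error")
  delim <- delim %||% if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  names(raw) <- tolower(trimws(names(raw)))
  hits <- trial_columns[names(trial_columns) %in% names(raw)]
  out <- raw
  names(out)[match(names(hits), names(out))] <- unname(hits)
  out <- out[, !duplicated(names(out)), drop = FALSE]
  miss <- setdiff(required_trial_columns, names(out))
  if (length(miss))
    ms_abort(paste0("trial table is missing required column(s): ",
                    paste(miss, collapse = ", ")),
             "multistress_schema_error")
  if (!"duration_h" %in% names(out)) out$duration_h <- 48
  validate_trial_table(tibble::as_tibble(out))
}

#' Validate a trial table
#'
#' Checks every record invariant: concentrations finite and non-negative,
#' counts non-negative integers with `n_immobile <= n_exposed`. Violations
#' are reported with their row indices.
#'
#' @param data Trial-table data frame.
#' @return The data, invisibly validated, as a tibble.
#' @export
validate_trial_table <- function(data) {
  data <- tibble::as_tibble(data)
  miss <- setdiff(required_trial_columns, names(data))
  if (length(miss))
    ms_abort(paste0("trial table is missing required column(s): ",
                    paste(miss, collapse = ", ")),
             "multistress_schema_error")
  bad <- function(cond, what) {
    idx <- which(cond)
    if (length(idx))
      ms_abort(paste0(what, " at row(s) ", paste(head(idx, 10), collapse = ", ")),
               "multistress_validation_error")
  }
  bad(!is.finite(data$clothianidin_conc) | data$clothianidin_conc < 0,
      "clothianidin_conc must be finite and non-negative")
  bad(!is.finite(data$prochloraz_conc) | data$prochloraz_conc < 0,
      "prochloraz_conc must be finite and non-negative")
  bad(!is.finite(data$temperature), "temperature must be finite")
  bad(!is.finite(data$n_exposed) | data$n_exposed < 1 |
        data$n_exposed != round(data$n_exposed),
      "n_exposed must be a positive integer")
  bad(!is.finite(data$n_immobile) | data$n_immobile < 0 |
        data$n_immobile != round(data$n_immobile),
      "n_immobile must be a non-negative integer")
  bad(data$n_immobile > data$n_exposed, "n_immobile exceeds n_exposed")
  data
}

#' Write a trial table
#'
#' @param data Trial-table data frame (validated before writing).
#' @param path Output path; delimiter chosen as in [read_trial_table()].
#' @param delim Optional explicit delimiter.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(data, path, delim = NULL) {
  data <- validate_trial_table(data)
  delim <- delim %||% if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  readr::write_delim(data, path, delim = delim)
  invisible(path)
}

#' Read a reference-toxicity table
#'
#' Columns: `compound`, `measured_conc` (µg/L), `reference_ec50` (µg/L; acute
#' LC50/EC50 of the most sensitive standard species), plus optional
#' `sample_id`, `site_id`, `campaign` identifiers.
#'
#' @inheritParams read_trial_table
#' @return A validated tibble.
#' @export
read_reference_toxicity <- function(path, delim = NULL) {
  if (!file.exists(path))
    ms_abort(paste0("file not found: ", path), "multistress_io_error")
  delim <- delim %||% if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  out <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  names(out) <- tolower(trimws(names(out)))
  miss <- setdiff(c("compound", "measured_conc", "reference_ec50"), names(out))
  if (length(miss))
    ms_abort(paste0("reference-toxicity table is missing column(s): ",
                    paste(miss, collapse = ", ")),
             "multistress_schema_error")
  if (any(!is.finite(out$reference_ec50)) || any(out$reference_ec50 <= 0))
    ms_abort("`reference_ec50` must be positive.", "multistress_validation_error")
  if (any(!is.finite(out$measured_conc)) || any(out$measured_conc < 0))
    ms_abort("`measured_conc` must be non-negative.", "multistress_validation_error")
  tibble::as_tibble(out)
}

#' Write a prediction report
#'
#' Writes one row per prediction record (observed EC50, predicted EC50, MDR,
#' classification), with numeric columns rounded half-to-even at the
#' configured number of decimals; raw unrounded ratios stay available in the
#' in-memory records.
#'
#' @param records Non-empty tibble of prediction records, e.g. from
#'   [run_design()].
#' @param path Output CSV path.
#' @param digits Decimal places for report rounding (default 2).
#' @return `path`, invisibly.
#' @export
write_report <- function(records, path, digits = 2) {
  if (is.null(records) || !is.data.frame(records) || nrow(records) == 0)
    ms_abort("`records` must be a non-empty data frame; no file written.",
             "multistress_validation_error")
  out <- dplyr::mutate(tibble::as_tibble(records),
                       dplyr::across(dplyr::where(is.numeric),
                                     ~ round(.x, digits)))
  tryCatch(readr::write_csv(out, path),
           error = function(e) ms_abort(paste0("cannot write report to ", path,
                                               ": ", conditionMessage(e)),
                                        "multistress_io_error"))
  invisible(path)
}

#' Read back a prediction report
#'
#' @param path CSV path written by [write_report()].
#' @return Tibble of report rows.
#' @export
read_report <- function(path) {
  if (!file.exists(path))
    ms_abort(paste0("file not found: ", path), "multistress_io_error")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' Run configuration
#'
#' Bundles the knobs shared across the pipeline: the stress-capacity shape
#' parameters, the effect level x for ECx, the ECx convention, report
#' rounding, control-normalisation behaviour and the random seed.
#'
#' @param capacity_alpha,capacity_beta Beta shape parameters of the
#'   stress-capacity distribution (> 0).
#' @param effect_level ECx level in percent, in (0, 100); default 50.
#' @param ecx_type `"relative"` (rescaled between asymptotes, default) or
#'   `"absolute"`.
#' @param report_digits Decimal places for report rounding.
#' @param normalize_to_control Express SAM effects relative to the stressed
#'   control (`TRUE`, default) or the unstressed control.
#' @param seed Integer random seed for simulation stages.
#' @return A `multistress_config` list.
#' @export
multistress_config <- function(capacity_alpha = 3.2, capacity_beta = 3.2,
                               effect_level = 50,
                               ecx_type = c("relative", "absolute"),
                               report_digits = 2,
                               normalize_to_control = TRUE,
                               seed = 1L) {
  ecx_type <- match.arg(ecx_type)
  if (!is.numeric(capacity_alpha) || capacity_alpha <= 0 ||
      !is.numeric(capacity_beta) || capacity_beta <= 0)
    ms_abort("capacity shape parameters must be positive.",
             "multistress_validation_error")
  if (!is.numeric(effect_level) || effect_level <= 0 || effect_level >= 100)
    ms_abort("`effect_level` must lie in (0, 100).", "multistress_validation_error")
  structure(list(capacity_alpha = capacity_alpha,
                 capacity_beta = capacity_beta,
                 effect_level = effect_level,
                 ecx_type = ecx_type,
                 report_digits = report_digits,
                 normalize_to_control = isTRUE(normalize_to_control),
                 seed = as.integer(seed)),
            class = "multistress_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys take the [multistress_config()]
#' defaults.
#'
#' @param path YAML file path.
#' @return A `multistress_config` list.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    ms_abort("the `yaml` package is needed to read YAML configs.",
             "multistress_io_error")
  if (!file.exists(path))
    ms_abort(paste0("file not found: ", path), "multistress_io_error")
  vals <- yaml::read_yaml(path)
  known <- names(formals(multistress_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    ms_abort(paste0("unknown config key(s): ", paste(bad, collapse = ", ")),
             "multistress_validation_error")
  do.call(multistress_config, vals)
}

config_capacity <- function(config) {
  stress_capacity(config$capacity_alpha, config$capacity_beta)
}
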