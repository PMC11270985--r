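#' Comparison design: which condition is the control of which
#'
#' Two designs are supported, mirroring the two questions a crossed
#' pesticide x temperature experiment answers:
#'
#' * `mixture_toxicity` — interaction between the primary toxicant and the
#'   co-toxicant at each temperature: every condition with co-toxicant > 0 is
#'   compared against the co-toxicant-free condition at the *same*
#'   temperature (and population).
#' * `multiple_stress` — joint effect of co-toxicant and warming: every
#'   condition at an elevated temperature (any co-toxicant level) is compared
#'   against the best-case control at the reference temperature without
#'   co-toxicant (same population).
#'
#' @param mode `"mixture_toxicity"` or `"multiple_stress"`.
#' @param control_temperature Reference temperature of the multiple-stress
#'   control (default 16 °C).
#' @return A `comparison_design` object.
#' @export
comparison_design <- function(mode = c("mixture_toxicity", "multiple_stress"),
                              control_temperature = 16) {
  mode <- match.arg(mode)
  structure(list(mode = mode, control_temperature = control_temperature),
            class = "comparison_design")
}

# internal: label each condition row as control/test and attach its control key
design_map <- function(conditions, design) {
  if (design$mode == "mixture_toxicity") {
    dplyr::mutate(conditions,
      is_test = .data$prochloraz_conc > 0,
      ctrl_temperature = .data$temperature,
      ctrl_prochloraz = 0)
  } else {
    dplyr::mutate(conditions,
      is_test = .data$temperature > design$control_temperature,
      ctrl_temperature = design$control_temperature,
      ctrl_prochloraz = 0)
  }
}

#' Run a comparison design over a trial table
#'
#' Fits the dose-response of every condition (population x temperature x
#' co-toxicant level) on counts pooled per treatment ("group-averaged"
#' survival), then for every test condition of the design predicts the
#' combined EC50 from its control's curve under the requested null models and
#' computes observed EC50, predicted EC50, MDR and its classification.
#'
#' The co-stressor's marginal effect (for EA/CA) is estimated from the
#' zero-dose treatments of the test condition relative to the control's
#' zero-dose background; if no excess effect is resolvable it is set to 0
#' with a warning. The SAM prediction quantifies the co-stressor's
#' General-Stress from the test condition's own dose window via
#' [quantify_stressor_stress()].
#'
#' @param table Trial-table data frame (see [read_trial_table()]).
#' @param design A [comparison_design()].
#' @param models Character subset of `c("ca", "ea", "sam")`.
#' @param config A [multistress_config()].
#' @return A tibble of prediction records, one row per test condition and
#'   model, ordered by (population, temperature, prochloraz, model):
#'   `population`, `temperature`, `prochloraz_conc`, `model`,
#'   `observed_ec50`, `predicted_ec50`, `mdr`, `classification`, plus the
#'   quantified `s_env` for SAM rows. A table containing only control
#'   conditions yields an empty record list.
#' @export
run_design <- function(table, design = comparison_design(),
                       models = c("ca", "ea", "sam"),
                       config = multistress_config()) {
  models <- match.arg(models, c("ca", "ea", "sam"), several.ok = TRUE)
  table <- validate_trial_table(table)
  capacity <- config_capacity(config)

  conditions <- dplyr::distinct(table, .data$population, .data$temperature,
                                .data$prochloraz_conc)
  mapped <- design_map(conditions, design)
  tests <- dplyr::filter(mapped, .data$is_test)
  if (nrow(tests) == 0) {
    return(tibble::tibble(population = character(), temperature = numeric(),
                          prochloraz_conc = numeric(), model = character(),
                          observed_ec50 = numeric(), predicted_ec50 = numeric(),
                          mdr = numeric(),
                          classification = classify_mdr(1)[0],
                          s_env = numeric()))
  }
  orphan <- dplyr::anti_join(
    tests,
    conditions,
    by = c(population = "population", ctrl_temperature = "temperature",
           ctrl_prochloraz = "prochloraz_conc"))
  if (nrow(orphan) > 0)
    ms_abort(paste0("missing control condition for: ",
                    paste(sprintf("(%s, %g degC, prochloraz %g)",
                                  orphan$population, orphan$temperature,
                                  orphan$prochloraz_conc), collapse = "; ")),
             "multistress_config_error")

  subset_cond <- function(pop, temp, proc)
    dplyr::filter(table, .data$population == pop, .data$temperature == temp,
                  .data$prochloraz_conc == proc)

  fit_cache <- new.env(parent = emptyenv())
  get_fit <- function(pop, temp, proc) {
    key <- paste(pop, temp, proc, sep = "|")
    if (!is.null(fit_cache[[key]])) return(fit_cache[[key]])
    f <- fit_ll5(subset_cond(pop, temp, proc))
    fit_cache[[key]] <- f
    f
  }

  records <- purrr::pmap_dfr(
    tests[, c("population", "temperature", "prochloraz_conc",
              "ctrl_temperature", "ctrl_prochloraz")],
    function(population, temperature, prochloraz_conc,
             ctrl_temperature, ctrl_prochloraz) {
      ctrl_fit <- get_fit(population, ctrl_temperature, ctrl_prochloraz)
      cond_tab <- subset_cond(population, temperature, prochloraz_conc)
      cond_fit <- tryCatch(fit_ll5(cond_tab),
                           multistress_fit_error = function(e) NULL)
      if (is.null(cond_fit)) {
        warn(paste0("skipping condition (", population, ", ", temperature,
                    " degC, prochloraz ", prochloraz_conc,
                    "): dose-response fit failed."))
        return(NULL)
      }
      observed <- ec_x_dose(cond_fit, config$effect_level, config$ecx_type)
      e_c <- costressor_marginal_effect(cond_tab, ctrl_fit)

      purrr::map_dfr(models, function(m) {
        s_env <- NA_real_
        pred <- tryCatch({
          if (m == "sam") {
            sq <- muffle_floor(quantify_stressor_stress(ctrl_fit, cond_tab,
                                                        capacity))
            s_env <<- sq$value
            sam_predict_ec50(
              ctrl_fit, sq$value, capacity, config$effect_level,
              reference = if (config$normalize_to_control) "stressed" else "unstressed")
          } else {
            predict_ec50_with_costressor(ctrl_fit, e_c, m, config$effect_level)
          }
        }, multistress_domain_error = function(e) {
          warn(paste0("no finite ", toupper(m), " prediction for (",
                      population, ", ", temperature, " degC, prochloraz ",
                      prochloraz_conc, "): ", conditionMessage(e)))
          NA_real_
        })
        ratio <- if (is.finite(pred)) mdr(pred, observed) else NA_real_
        tibble::tibble(population = population, temperature = temperature,
                       prochloraz_conc = prochloraz_conc, model = m,
                       observed_ec50 = observed, predicted_ec50 = pred,
                       mdr = ratio,
                       classification = if (is.finite(ratio)) classify_mdr(ratio)
                                        else factor(NA, levels = levels(classify_mdr(1))),
                       s_env = s_env)
      })
    })
  dplyr::arrange(records, .data$population, .data$temperature,
                 .data$prochloraz_conc, .data$model)
}

# internal: silence the (expected, frequent under sampling noise) negative-
# stress floor warning inside pipeline aggregation; per-dose audits remain
muffle_floor <- function(expr) {
  withCallingHandlers(expr,
    multistress_floor_warning = function(w) invokeRestart("muffleWarning"))
}

# internal: Bliss-relative marginal effect of the co-stressor, from the
# zero-dose treatments of the test condition vs the control's background
costressor_marginal_effect <- function(cond_tab, ctrl_fit) {
  zero <- dplyr::filter(cond_tab, .data$clothianidin_conc == 0)
  if (nrow(zero) == 0 || sum(zero$n_exposed) == 0) {
    warn("no zero-dose treatment in the test condition; co-stressor effect set to 0.")
    return(0)
  }
  e_cond0 <- sum(zero$n_immobile) / sum(zero$n_exposed)
  e_ctrl0 <- ctrl_fit$par[["c"]]
  if (e_ctrl0 >= 1) return(0)
  e_c <- 1 - (1 - e_cond0) / (1 - e_ctrl0)
  if (e_c < 0) {
    return(0)
  }
  min(e_c, 1 - 1e-9)
}

#' Table-shaped prediction report
#'
#' Pivots the long record list of [run_design()] into the conventional
#' one-row-per-condition shape: observed EC50, the predicted EC50 (CA when
#' available, otherwise the first fitted model), and one MDR column per
#' model.
#'
#' @param records Output of [run_design()].
#' @return A wide tibble ordered by (population, temperature, prochloraz).
#' @export
report_table <- function(records) {
  if (nrow(records) == 0) return(records)
  wide <- tidyr::pivot_wider(
    dplyr::select(records, "population", "temperature", "prochloraz_conc",
                  "observed_ec50", "model", "predicted_ec50", "mdr"),
    names_from = "model", values_from = c("predicted_ec50", "mdr"))
  pred_col <- intersect(c("predicted_ec50_ca", "predicted_ec50_ea",
                          "predicted_ec50_sam"), names(wide))[1]
  wide$predicted_ec50 <- wide[[pred_col]]
  dplyr::select(wide, "population", "temperature", "prochloraz_conc",
                "observed_ec50", "predicted_ec50",
                dplyr::starts_with("mdr_"))
}

#' Total General-Stress and EA-synergism per multi-stress condition
#'
#' Builds the points relating total General-Stress to the strength of
#' synergism (EA-based MDR) across the multiple-stress conditions. For each
#' population and elevated condition (temperature T, co-toxicant P), total
#' stress sums three components on the General-Stress scale:
#'
#' * co-toxicant stress — quantified from (reference-temperature, P) against
#'   the population's best-case control curve;
#' * temperature stress — quantified from (T, co-toxicant 0) likewise;
#' * adaptation-cost stress (agricultural population only) — the excess
#'   observed stress of the agricultural population over the reference
#'   population under the same co-stressors, floored at 0. This isolates the
#'   fitness cost of pesticide adaptation as its own additive stressor; the
#'   rule is a documented package choice.
#'
#' @param table Trial table covering both populations and the full design.
#' @param config A [multistress_config()].
#' @param reference_population Population used as the no-adaptation baseline.
#' @return Tibble of synergy points: condition labels, the stress components,
#'   `total_stress` and `mdr_ea`.
#' @export
synergy_points <- function(table, config = multistress_config(),
                           reference_population = "reference") {
  table <- validate_trial_table(table)
  capacity <- config_capacity(config)
  design <- comparison_design("multiple_stress")
  records <- run_design(table, design, models = "ea", config = config)
  if (nrow(records) == 0) return(records)

  pops <- unique(records$population)
  ctrl_fit <- lapply(setNames(pops, pops), function(pop)
    fit_ll5(dplyr::filter(table, .data$population == pop,
                          .data$temperature == design$control_temperature,
                          .data$prochloraz_conc == 0)))

  quantify <- function(pop, temp, proc) {
    sub <- dplyr::filter(table, .data$population == pop,
                         .data$temperature == temp,
                         .data$prochloraz_conc == proc)
    if (nrow(sub) == 0) return(NA_real_)
    muffle_floor(quantify_stressor_stress(ctrl_fit[[pop]], sub, capacity)$value)
  }

  purrr::pmap_dfr(
    records[, c("population", "temperature", "prochloraz_conc", "mdr")],
    function(population, temperature, prochloraz_conc, mdr) {
      s_proc <- if (prochloraz_conc > 0)
        quantify(population, design$control_temperature, prochloraz_conc) else 0
      s_temp <- quantify(population, temperature, 0)
      s_adapt <- 0
      if (population != reference_population &&
          reference_population %in% pops) {
        s_self <- quantify(population, temperature, prochloraz_conc)
        s_ref <- quantify(reference_population, temperature, prochloraz_conc)
        if (is.finite(s_self) && is.finite(s_ref))
          s_adapt <- max(0, s_self - s_ref)
      }
      tibble::tibble(population = population, temperature = temperature,
                     prochloraz_conc = prochloraz_conc,
                     stress_cotoxicant = s_proc,
                     stress_temperature = s_temp,
                     stress_adaptation = s_adapt,
                     total_stress = s_proc + s_temp + s_adapt,
                     mdr_ea = mdr)
    })
}

#' Linear regression of synergism on total General-Stress
#'
#' Ordinary least squares of the EA-based MDR on the summed General-Stress,
#' reporting slope, intercept, adjusted R-squared (standard small-sample
#' correction), the F statistic, residual degrees of freedom (n - 2) and the
#' p value. The fitted `lm` object is attached as attribute `"model"`.
#'
#' @param points Data frame of synergy points.
#' @param x,y Column names of predictor and response (defaults
#'   `total_stress`, `mdr_ea`).
#' @return A one-row tibble of class `synergy_regression`.
#' @export
synergism_regression <- function(points, x = "total_stress", y = "mdr_ea") {
  ols_summary(points, x, y, class = "synergy_regression")
}

#' Site-level exposure-effect regression
#'
#' Generic OLS utility relating a site-level community index to log toxic
#' units (or any other site descriptor); same output shape as
#' [synergism_regression()].
#'
#' @param sites Data frame of site records.
#' @param x,y Column names (defaults `tu_log10`, `index`).
#' @return A one-row tibble of class `synergy_regression`.
#' @export
site_index_regression <- function(sites, x = "tu_log10", y = "index") {
  ols_summary(sites, x, y, class = "synergy_regression")
}

ols_summary <- function(data, x, y, class) {
  if (!all(c(x, y) %in% names(data)))
    ms_abort(paste0("columns `", x, "` and `", y, "` are required."),
             "multistress_schema_error")
  data <- data[complete.cases(data[, c(x, y)]), ]
  if (nrow(data) < 3)
    ms_abort("need at least 3 points for a regression.",
             "multistress_validation_error")
  if (var(data[[x]]) <= 0)
    ms_abort("degenerate predictor: no variance.", "multistress_validation_error")
  fml <- stats::reformulate(x, response = y)
  m <- lm(fml, data = data)
  sm <- summary(m)
  fstat <- sm$fstatistic
  out <- tibble::tibble(
    slope = unname(coef(m)[2]),
    intercept = unname(coef(m)[1]),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    f_statistic = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
    df_residual = m$df.residual,
    p_value = if (is.null(fstat)) NA_real_ else
      unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)),
    n = nrow(data))
  attr(out, "model") <- m
  class(out) <- c(class, class(out))
  out
}

#' @method tidy synergy_regression
#' @export
tidy.synergy_regression <- function(x, ...) {
  m <- attr(x, "model")
  cf <- summary(m)$coefficients
  tibble::tibble(term = rownames(cf), estimate = cf[, 1],
                 std.error = cf[, 2], statistic = cf[, 3], p.value = cf[, 4])
}

#' @method glance synergy_regression
#' @export
glance.synergy_regression <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Fold difference in tolerance
#'
#' Ratio of two EC50s, report-rounded to one decimal: how many times more
#' tolerant is group a than group b.
#'
#' @param ec50_a,ec50_b Positive EC50 values.
#' @return `round(ec50_a / ec50_b, 1)`.
#' @examples
#' fold_tolerance(148, 67) # 2.2
#' @export
fold_tolerance <- function(ec50_a, ec50_b) {
  if (any(!is.finite(ec50_a)) || any(!is.finite(ec50_b)) ||
      any(ec50_a <= 0) || any(ec50_b <= 0))
    ms_abort("EC50 values must be positive and finite.", "multistress_domain_error")
  round(ec50_a / ec50_b, 1)
}

#' Two-group comparison with variance pre-check
#'
#' Compares two groups of (typically EC50) values with a t test. The pooled
#' two-sample t test is used when an F-ratio variance test does not reject
#' equality at `var_alpha` (documented criterion); otherwise Welch's t test.
#' Values can be ln-transformed first (the usual normalising transform for
#' EC50s), and a paired mode compares within-pair differences.
#'
#' @param values_a,values_b Numeric vectors (equal length when `paired`).
#' @param paired Paired t test on differences.
#' @param log_transform Apply `log()` before testing.
#' @param var_alpha Significance level of the variance-equality pre-check.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `method`,
#'   `estimate` (mean difference on the analysis scale).
#' @export
compare_groups <- function(values_a, values_b, paired = FALSE,
                           log_transform = FALSE, var_alpha = 0.05) {
  if (length(values_a) < 2 || length(values_b) < 2)
    ms_abort("need at least 2 values per group.", "multistress_validation_error")
  if (paired && length(values_a) != length(values_b))
    ms_abort("paired mode requires equal-length groups.",
             "multistress_validation_error")
  if (log_transform) {
    if (any(values_a <= 0) || any(values_b <= 0))
      ms_abort("log transform requires positive values.",
               "multistress_domain_error")
    values_a <- log(values_a); values_b <- log(values_b)
  }
  if (paired) {
    tt <- t.test(values_a, values_b, paired = TRUE)
  } else {
    equal_var <- var.test(values_a, values_b)$p.value >= var_alpha
    tt <- t.test(values_a, values_b, var.equal = equal_var)
  }
  tibble::tibble(statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value,
                 method = trimws(tt$method),
                 estimate = unname(if (paired) tt$estimate
                                   else diff(rev(tt$estimate))))
}
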