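#' Stress-capacity distribution
#'
#' The stress addition model (SAM) assumes every individual carries a general
#' stress capacity drawn from a common distribution on \[0, 1\]. An individual
#' survives a total General-Stress level S if its capacity exceeds S, so the
#' population survival fraction at stress S is one minus the cumulative
#' capacity distribution at S. The capacity law is modelled as a two-parameter
#' beta distribution, which satisfies the SAM boundary conditions by
#' construction: survival is 1 at S = 0 and 0 at S >= 1.
#'
#' The default shape `alpha = beta = 3.2` is the symmetric capacity law used by
#' the established SAM software and literature; the model itself only requires
#' a strictly increasing cumulative function on (0, 1), and both shapes are
#' configurable.
#'
#' @param alpha,beta Positive shape parameters of the beta capacity law.
#'   `beta` defaults to `alpha`, giving a symmetric distribution.
#' @return An object of class `stress_capacity`.
#' @examples
#' cap <- stress_capacity()
#' stress_to_survival(c(0, 0.5, 1), cap)
#' @export
stress_capacity <- function(alpha = 3.2, beta = alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || !is.finite(alpha) || alpha <= 0)
    ms_abort("`alpha` must be a single positive number.", "multistress_domain_error")
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta) || beta <= 0)
    ms_abort("`beta` must be a single positive number.", "multistress_domain_error")
  structure(list(alpha = alpha, beta = beta), class = "stress_capacity")
}

#' @export
print.stress_capacity <- function(x, ...) {
  cat(sprintf("<stress_capacity> beta(%.3g, %.3g) on [0, 1]%s\n",
              x$alpha, x$beta,
              if (isTRUE(all.equal(x$alpha, x$beta))) " (symmetric)" else ""))
  invisible(x)
}

as_capacity <- function(capacity) {
  if (inherits(capacity, "stress_capacity")) return(capacity)
  if (is.numeric(capacity) && length(capacity) %in% 1:2)
    return(stress_capacity(capacity[[1]], capacity[[length(capacity)]]))
  ms_abort("`capacity` must be a stress_capacity object.", "multistress_domain_error")
}

#' Convert General-Stress to survival and back
#'
#' `stress_to_survival()` maps a General-Stress level S to the expected
#' surviving (mobile) fraction N(S) = 1 - F(S), where F is the cumulative
#' stress-capacity distribution; N(0) = 1 and N(S) = 0 for S >= 1.
#' `survival_to_stress()` is the exact inverse on \[0, 1\],
#' S = F^-1(1 - N). Both are vectorised.
#'
#' @param stress Non-negative General-Stress level(s). Values at or above 1
#'   exceed every individual's capacity and give zero survival.
#' @param survival Survival fraction(s) in \[0, 1\].
#' @param capacity A [stress_capacity()] distribution.
#' @return Numeric vector: survival fractions, or stress levels.
#' @examples
#' cap <- stress_capacity()
#' survival_to_stress(stress_to_survival(0.3, cap), cap) # 0.3
#' @export
stress_to_survival <- function(stress, capacity = stress_capacity()) {
  capacity <- as_capacity(capacity)
  if (!is.numeric(stress) || any(!is.finite(stress)))
    ms_abort("`stress` must be finite and numeric.", "multistress_domain_error")
  if (any(stress < 0))
    ms_abort("General-Stress must be non-negative.", "multistress_domain_error")
  1 - pbeta(pmin(stress, 1), capacity$alpha, capacity$beta)
}

#' @rdname stress_to_survival
#' @export
survival_to_stress <- function(survival, capacity = stress_capacity()) {
  capacity <- as_capacity(capacity)
  if (!is.numeric(survival) || any(!is.finite(survival)))
    ms_abort("`survival` must be finite and numeric.", "multistress_domain_error")
  if (any(survival < 0 | survival > 1))
    ms_abort("`survival` must lie in [0, 1].", "multistress_domain_error")
  qbeta(1 - survival, capacity$alpha, capacity$beta)
}

#' Total General-Stress of independently acting stressors
#'
#' Under SAM, independently acting stressors combine by plain addition of
#' their General-Stress levels. The empty set of stressors carries zero
#' stress.
#'
#' @param stresses Numeric vector of non-negative General-Stress levels.
#' @return A single non-negative General-Stress level.
#' @examples
#' total_general_stress(c(0.3, 0.2)) # 0.5
#' @export
total_general_stress <- function(stresses) {
  if (length(stresses) == 0) return(0)
  if (!is.numeric(stresses) || any(!is.finite(stresses)))
    ms_abort("stress levels must be finite and numeric.", "multistress_domain_error")
  if (any(stresses < 0))
    ms_abort("stress levels must be non-negative.", "multistress_domain_error")
  sum(stresses)
}

#' SAM forward prediction of a stressed dose-response curve
#'
#' Given a fitted dose-response for the toxicant alone and the General-Stress
#' `s_env` contributed by an additional, independently acting stressor,
#' the predicted survival at dose u is
#' `N_pred(u) = stress_to_survival(survival_to_stress(N_tox(u)) + s_env)`.
#' With `s_env = 0` the prediction is identical to the unstressed curve.
#'
#' `sam_predict_survival()` evaluates the prediction at given doses;
#' `sam_predict_curve()` returns the prediction as a function of dose.
#'
#' @param fit An [fit_ll5()] curve, or a plain function `dose -> survival`.
#' @param dose Non-negative dose(s).
#' @param s_env Non-negative General-Stress of the additional stressor.
#' @param capacity A [stress_capacity()] distribution.
#' @return Survival fraction(s), or for `sam_predict_curve()` a function.
#' @export
sam_predict_survival <- function(fit, dose, s_env, capacity = stress_capacity()) {
  capacity <- as_capacity(capacity)
  if (!is.numeric(s_env) || length(s_env) != 1 || !is.finite(s_env) || s_env < 0)
    ms_abort("`s_env` must be a single non-negative number.", "multistress_domain_error")
  surv_tox <- survival_function(fit)(dose)
  stress_to_survival(survival_to_stress(surv_tox, capacity) + s_env, capacity)
}

#' @rdname sam_predict_survival
#' @export
sam_predict_curve <- function(fit, s_env, capacity = stress_capacity()) {
  force(fit); force(s_env)
  capacity <- as_capacity(capacity)
  function(dose) sam_predict_survival(fit, dose, s_env, capacity)
}

# internal: coerce a curve-like object to a survival function of dose
survival_function <- function(fit) {
  if (inherits(fit, "ll5_fit")) return(function(dose) 1 - effect_at(fit, dose))
  if (is.function(fit)) return(fit)
  ms_abort("`fit` must be an ll5_fit or a function dose -> survival.",
           "multistress_domain_error")
}

#' SAM-predicted EC50 under an additional stressor
#'
#' The predicted combined EC50 is the dose at which the SAM-predicted survival
#' curve, rescaled between its own (stressed) control level and its lower
#' plateau, crosses the `effect_level` percent effect criterion. Effects are
#' thus expressed relative to the stressed control (the co-stressor-only
#' treatment); set `reference = "unstressed"` to rescale against the
#' unstressed control instead.
#'
#' @inheritParams sam_predict_survival
#' @param effect_level Percent effect in (0, 100); 50 gives the EC50.
#' @param reference Rescale the predicted curve to the `"stressed"` (default)
#'   or `"unstressed"` control before applying the effect criterion.
#' @param tol Relative root tolerance on the dose scale.
#' @return Predicted EC50 (same units as the fitted dose axis).
#' @export
sam_predict_ec50 <- function(fit, s_env, capacity = stress_capacity(),
                             effect_level = 50,
                             reference = c("stressed", "unstressed"),
                             tol = 1e-10) {
  capacity <- as_capacity(capacity)
  reference <- match.arg(reference)
  if (!is.numeric(effect_level) || length(effect_level) != 1 ||
      effect_level <= 0 || effect_level >= 100)
    ms_abort("`effect_level` must lie strictly between 0 and 100.",
             "multistress_domain_error")
  pred <- sam_predict_curve(fit, s_env, capacity)
  n0 <- pred(0)
  # lower plateau: survival at saturating dose
  big <- plateau_dose(fit)
  n_inf <- pred(big)
  top <- if (reference == "stressed") n0 else survival_function(fit)(0)
  if (top - n_inf <= tol)
    ms_abort(paste0("stressed control survival (", signif(n0, 4),
                    ") leaves no room for a ", effect_level,
                    "% effect; no finite predicted EC50."),
             "multistress_domain_error")
  target <- top - (effect_level / 100) * (top - n_inf)
  if (pred(0) <= target)
    ms_abort("stressed control is already below the effect criterion.",
             "multistress_domain_error")
  root_log_dose(function(u) pred(u) - target, fit, tol = tol)
}

# internal: a dose at which the curve has effectively reached its upper plateau
plateau_dose <- function(fit) {
  if (inherits(fit, "ll5_fit")) {
    p <- fit$par
    return(exp(log(p[["e"]]) + 60 / max(abs(p[["b"]]), 0.05)))
  }
  1e12
}

# internal: deterministic bracketing + uniroot on the log-dose axis
root_log_dose <- function(g, fit, tol = 1e-10) {
  centre <- if (inherits(fit, "ll5_fit")) log(fit$par[["e"]]) else 0
  half <- 10
  for (i in 1:8) {
    lo <- centre - half; hi <- centre + half
    glo <- g(exp(lo)); ghi <- g(exp(hi))
    if (is.finite(glo) && is.finite(ghi) && glo * ghi <= 0) {
      r <- uniroot(function(lu) g(exp(lu)), c(lo, hi), tol = tol)
      return(exp(r$root))
    }
    half <- half * 2
  }
  ms_abort("could not bracket the effect criterion on the dose axis.",
           "multistress_fit_error")
}

#' Quantify the General-Stress contributed by an additional stressor
#'
#' Compares survival under the toxicant alone with survival under
#' toxicant + additional stressor, in a dose window around the EC50 of the
#' toxicant alone, and expresses the drop on the General-Stress scale:
#' for each window dose, the stress difference
#' `survival_to_stress(surv_combined) - survival_to_stress(surv_alone)` is
#' computed, and the window mean is returned. A negative mean (combined
#' survival above the alone survival) is floored at 0 with a warning.
#'
#' The default window consists of the tested positive doses closest to the
#' fitted alone-EC50 on the log-dose axis (the nearest dose on each side where
#' available, otherwise the two nearest overall).
#'
#' @param alone_fit [fit_ll5()] curve of the toxicant-alone condition.
#' @param combined The co-stressed condition: either a trial-table data frame
#'   (observed pooled survival at tested doses is used), an `ll5_fit`, or a
#'   function `dose -> survival`.
#' @param capacity A [stress_capacity()] distribution.
#' @param window_doses Optional explicit numeric vector of doses to use.
#' @param floor_negative Floor a negative inferred stress at 0 (default TRUE).
#' @return An object of class `stress_quantification`: a list with `value`
#'   (the General-Stress level), `per_dose` (a tibble of per-dose
#'   contributions for audit) and `window` (the doses used).
#' @export
quantify_stressor_stress <- function(alone_fit, combined,
                                     capacity = stress_capacity(),
                                     window_doses = NULL,
                                     floor_negative = TRUE) {
  capacity <- as_capacity(capacity)
  if (!inherits(alone_fit, "ll5_fit"))
    ms_abort("`alone_fit` must be an ll5_fit.", "multistress_domain_error")
  ec50 <- ec_x_dose(alone_fit, 50)

  if (is.data.frame(combined)) {
    pooled <- pool_doses(combined)
    tested <- pooled$dose[pooled$dose > 0]
    window <- window_doses %||% default_stress_window(tested, ec50)
    if (length(window) == 0)
      ms_abort(paste0("empty dose window around EC50 = ", signif(ec50, 4),
                      "; tested doses: ", paste(signif(tested, 4), collapse = ", ")),
               "multistress_domain_error")
    idx <- match(window, pooled$dose)
    if (any(is.na(idx)))
      ms_abort("window doses must be present in the combined table.",
               "multistress_domain_error")
    surv_comb <- 1 - pooled$n_immobile[idx] / pooled$n_exposed[idx]
  } else {
    f_comb <- survival_function(combined)
    tested <- alone_doses(alone_fit)
    window <- window_doses %||% default_stress_window(tested, ec50)
    if (length(window) == 0)
      ms_abort(paste0("empty dose window around EC50 = ", signif(ec50, 4)),
               "multistress_domain_error")
    surv_comb <- f_comb(window)
  }

  surv_alone <- 1 - effect_at(alone_fit, window)
  s_alone <- survival_to_stress(surv_alone, capacity)
  surv_comb <- pmin(pmax(surv_comb, 0), 1)
  s_comb <- survival_to_stress(surv_comb, capacity)
  delta <- s_comb - s_alone
  # a fully immobilised combined treatment only bounds the stress from below
  # (the capacity transform is saturated); such doses are uninformative for a
  # point estimate and are excluded from the window mean
  informative <- surv_comb > 0
  if (!any(informative))
    ms_abort(paste0("combined survival is zero at every window dose (",
                    paste(signif(window, 4), collapse = ", "),
                    "); the additional stress is not identifiable there."),
             "multistress_domain_error")
  if (!all(informative))
    warn("dropping fully immobilised window dose(s) from the stress estimate.",
         class = "multistress_saturation_warning")
  value <- mean(delta[informative])
  if (value < 0 && floor_negative) {
    warn(paste0("inferred General-Stress was negative (", signif(value, 4),
                "); floored at 0."),
         class = "multistress_floor_warning")
    value <- 0
  }
  structure(list(
    value = value,
    per_dose = tibble::tibble(dose = window,
                              surv_alone = surv_alone,
                              surv_combined = unname(surv_comb),
                              stress_alone = s_alone,
                              stress_combined = unname(s_comb),
                              delta = unname(delta),
                              informative = informative),
    window = window,
    ec50_alone = ec50
  ), class = "stress_quantification")
}

#' @export
print.stress_quantification <- function(x, ...) {
  cat(sprintf("<stress_quantification> General-Stress = %.4g (window: %s; EC50 alone = %.4g)\n",
              x$value, paste(signif(x$window, 4), collapse = ", "), x$ec50_alone))
  invisible(x)
}

#' @export
as.double.stress_quantification <- function(x, ...) x$value

# internal: nearest tested dose on each side of the EC50 (log scale);
# falls back to the two nearest overall at the grid edges
default_stress_window <- function(tested, ec50) {
  tested <- sort(unique(tested[tested > 0 & is.finite(tested)]))
  if (length(tested) == 0) return(numeric(0))
  below <- tested[tested <= ec50]
  above <- tested[tested > ec50]
  w <- c(if (length(below)) max(below), if (length(above)) min(above))
  if (length(w) < 2 && length(tested) >= 2) {
    d <- abs(log(tested) - log(ec50))
    w <- tested[order(d)][1:2]
  }
  sort(w)
}

alone_doses <- function(fit) {
  d <- fit$data$dose
  d[d > 0]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
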