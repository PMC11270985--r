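#' Combined effect under effect addition (independent action)
#'
#' Effect addition (EA, Bliss independence) combines the effects of
#' dissimilarly acting stressors as
#' `E_mix = 1 - prod(1 - E_i)`. The operation is commutative, a singleton
#' returns its own effect, and adding a zero-effect component changes
#' nothing.
#'
#' @param effects Numeric vector of effect fractions in \[0, 1\].
#' @return Combined effect fraction.
#' @examples
#' ea_combined_effect(c(0.5, 0.2)) # 0.6
#' @export
ea_combined_effect <- function(effects) {
  if (length(effects) == 0) return(0)
  if (!is.numeric(effects) || any(!is.finite(effects)))
    ms_abort("`effects` must be finite and numeric.", "multistress_domain_error")
  if (any(effects < 0 | effects > 1))
    ms_abort("effect fractions must lie in [0, 1].", "multistress_domain_error")
  1 - prod(1 - effects)
}

#' Mixture ECx under concentration addition
#'
#' Concentration addition (CA, Loewe additivity) for a mixture with fixed
#' composition: if component i makes up relative concentration fraction `p_i`
#' of the mixture and alone requires `ECx_i` for x% effect, the total mixture
#' concentration producing x% effect is
#' `ECx_mix = 1 / sum(p_i / ECx_i)`.
#'
#' @param fraction Relative concentration fractions, summing to 1 (within
#'   1e-9).
#' @param ecx Component ECx values (same effect level x for all), all > 0.
#' @return The mixture ECx (same concentration units as `ecx`).
#' @examples
#' ca_combined_ecx(c(0.5, 0.5), c(100, 100)) # sham mixture: 100
#' @export
ca_combined_ecx <- function(fraction, ecx) {
  if (length(fraction) != length(ecx) || length(ecx) == 0)
    ms_abort("`fraction` and `ecx` must be non-empty and of equal length.",
             "multistress_domain_error")
  if (any(!is.finite(fraction)) || any(fraction < 0 | fraction > 1))
    ms_abort("fractions must lie in [0, 1].", "multistress_domain_error")
  if (abs(sum(fraction) - 1) > 1e-9)
    ms_abort("fractions must sum to 1 (within 1e-9).", "multistress_domain_error")
  if (any(!is.finite(ecx)) || any(ecx <= 0))
    ms_abort("component ECx values must be positive.", "multistress_domain_error")
  1 / sum(fraction / ecx)
}

#' Predicted EC50 of the primary toxicant in the presence of a co-stressor
#'
#' Predicts the dose of the primary toxicant producing 50% effect (relative to
#' the co-stressed control) when a second stressor is present at a fixed
#' intensity, under one of the two classical null models.
#'
#' * **EA** (effect addition / independent action): the combined effect at
#'   dose u is `1 - (1 - E_tox(u)) (1 - E_c)`; the predicted EC50 is the dose
#'   where this crosses 50% of its own range (from the co-stressed control to
#'   the co-stressed maximum), found by root bisection.
#' * **CA** (concentration addition / Loewe): the co-stressor's marginal
#'   effect `E_c` is converted into an equivalent dose of the primary
#'   toxicant through the inverse of the fitted curve, and the predicted EC50
#'   is the fitted ECx minus that equivalent dose (dose-equivalence form of
#'   the Loewe isobole).
#'
#' With `costressor_effect = 0` both models return the unmodified (relative)
#' EC50 of the fitted curve. A co-stressor whose own effect already reaches
#' the effect criterion admits no finite predicted EC50 and raises an error.
#'
#' @param fit `ll5_fit` of the primary toxicant alone (the control condition).
#' @param costressor_effect The co-stressor's marginal effect fraction in
#'   \[0, 1), typically estimated from the zero-dose treatments of the
#'   co-stressed condition.
#' @param model `"ea"` or `"ca"`.
#' @param effect_level Percent effect criterion (default 50).
#' @param tol Root tolerance (EA path).
#' @return Predicted EC50 (dose units of the fit).
#' @export
predict_ec50_with_costressor <- function(fit, costressor_effect,
                                         model = c("ea", "ca"),
                                         effect_level = 50, tol = 1e-10) {
  model <- match.arg(model)
  if (!inherits(fit, "ll5_fit"))
    ms_abort("`fit` must be an ll5_fit.", "multistress_domain_error")
  ec <- costressor_effect
  if (!is.numeric(ec) || length(ec) != 1 || !is.finite(ec) || ec < 0 || ec >= 1)
    ms_abort("`costressor_effect` must lie in [0, 1).", "multistress_domain_error")
  if (ec >= effect_level / 100)
    ms_abort(paste0("co-stressor effect ", signif(ec, 4), " alone reaches the ",
                    effect_level, "% criterion; no finite predicted EC50."),
             "multistress_domain_error")
  ecx_alone <- ec_x_dose(fit, effect_level)

  if (model == "ea") {
    comb <- function(u) ea_combined_effect_vec(effect_at(fit, u), ec)
    top <- comb(plateau_dose(fit))
    bottom <- comb(0)
    target <- bottom + (effect_level / 100) * (top - bottom)
    return(root_log_dose(function(u) comb(u) - target, fit, tol = tol))
  }

  # CA: clothianidin-equivalent dose of the co-stressor via the inverse curve
  p <- fit$par
  equiv <- if (ec <= p[["c"]]) 0 else {
    rel <- (ec - p[["c"]]) / (p[["d"]] - p[["c"]])
    exp(ll5_log_ecx(p, 100 * rel, "relative"))
  }
  pred <- ecx_alone - equiv
  if (!is.finite(pred) || pred <= 0)
    ms_abort("co-stressor potency exhausts the Loewe isobole; no finite predicted EC50.",
             "multistress_domain_error")
  pred
}

# vectorised-in-dose EA combination with one fixed co-stressor effect
ea_combined_effect_vec <- function(e_tox, e_c) 1 - (1 - e_tox) * (1 - e_c)

#' Model deviation ratio
#'
#' The MDR is the predicted EC50 divided by the observed EC50. Values near 1
#' mean the null model predicts the combined effect well; values above 1 mean
#' the observed toxicity is stronger than predicted (synergism), values below
#' 1 weaker (antagonism). No rounding is applied here; rounding happens only
#' in the report layer.
#'
#' @param predicted_ec50,observed_ec50 Positive EC50 values (vectorised).
#' @return `predicted_ec50 / observed_ec50`.
#' @examples
#' mdr(40.32, 25.41) # 1.586...
#' @export
mdr <- function(predicted_ec50, observed_ec50) {
  if (any(!is.finite(predicted_ec50)) || any(!is.finite(observed_ec50)) ||
      any(predicted_ec50 <= 0) || any(observed_ec50 <= 0))
    ms_abort("EC50 values must be positive and finite.", "multistress_domain_error")
  predicted_ec50 / observed_ec50
}

#' Classify a model deviation ratio
#'
#' Partitions the positive MDR axis with no gaps or overlaps:
#' below 0.5 antagonism; from 0.5 to 1 (inclusive) additive; above 1 up to
#' and including 2 weak synergism; above 2 strong synergism.
#'
#' @param mdr Positive MDR value(s).
#' @return Factor with levels `antagonism`, `additive`, `weak_synergism`,
#'   `strong_synergism`.
#' @examples
#' classify_mdr(c(0.4, 0.8, 1.59, 2.69))
#' @export
classify_mdr <- function(mdr) {
  if (any(!is.finite(mdr)) || any(mdr <= 0))
    ms_abort("`mdr` must be positive and finite.", "multistress_domain_error")
  lv <- c("antagonism", "additive", "weak_synergism", "strong_synergism")
  out <- ifelse(mdr < 0.5, lv[1],
         ifelse(mdr <= 1, lv[2],
         ifelse(mdr <= 2, lv[3], lv[4])))
  factor(out, levels = lv)
}
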