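#' Plot a fitted dose-response curve
#'
#' Observed pooled immobile fractions with the fitted five-parameter
#' log-logistic curve on a log dose axis. The control (dose 0) is drawn at a
#' pseudo-dose one log-decade below the lowest tested positive dose, the
#' usual convention for log-scaled dose-response plots.
#'
#' @param object An `ll5_fit`.
#' @param n_grid Number of curve evaluation points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ll5_fit
#' @export
autoplot.ll5_fit <- function(object, n_grid = 200, ...) {
  obs <- object$data
  pos <- obs$dose[obs$dose > 0]
  pseudo0 <- min(pos) / 10
  obs_plot <- dplyr::mutate(obs,
    plot_dose = ifelse(.data$dose == 0, pseudo0, .data$dose),
    prop = .data$n_immobile / .data$n_exposed)
  grid <- tibble::tibble(
    dose = exp(seq(log(pseudo0), log(max(pos)), length.out = n_grid)))
  grid$effect <- effect_at(object, grid$dose)
  ggplot2::ggplot(obs_plot, ggplot2::aes(x = .data$plot_dose)) +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(x = .data$dose, y = .data$effect),
                       colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$prop)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dose (µg/L, control at pseudo-dose)",
                  y = "immobile fraction",
                  title = "Five-parameter log-logistic fit") +
    ggplot2::theme_minimal()
}

#' Plot synergism against total General-Stress
#'
#' Scatter of EA-based MDR values against the summed General-Stress of the
#' contributing stressors, with the OLS trend and its confidence band.
#'
#' @param points Synergy points from [synergy_points()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_synergy <- function(points, ...) {
  ggplot2::ggplot(points, ggplot2::aes(x = .data$total_stress,
                                       y = .data$mdr_ea)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                         colour = "grey30", fill = "grey80") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$population)) +
    ggplot2::labs(x = "total General-Stress", y = "MDR (EA null model)",
                  title = "Synergism vs total stress") +
    ggplot2::theme_minimal()
}

#' @rdname plot_synergy
#' @param object Synergy points tibble.
#' @method autoplot synergy_regression
#' @export
autoplot.synergy_regression <- function(object, ...) {
  m <- attr(object, "model")
  df <- stats::setNames(tibble::as_tibble(m$model[, 1:2]),
                        c("mdr_ea", "total_stress"))
  df$population <- "all"
  plot_synergy(df)
}

#' Plot model deviation ratios per condition and model
#'
#' Dot plot of MDRs from [run_design()], faceted by population, with the
#' additivity band (0.5 to 2) and the strong-synergism threshold marked.
#'
#' @param records Prediction records from [run_design()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_mdr <- function(records, ...) {
  records <- dplyr::mutate(records,
    condition = sprintf("%g°C / %g µg/L", .data$temperature,
                        .data$prochloraz_conc))
  ggplot2::ggplot(records, ggplot2::aes(x = .data$condition, y = .data$mdr,
                                        colour = toupper(.data$model))) +
    ggplot2::geom_hline(yintercept = c(0.5, 1, 2), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_wrap(~ population) +
    ggplot2::labs(x = "condition (temperature / co-toxicant)", y = "MDR",
                  colour = "model") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
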