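#' Plot genetic and plastic effect means per origin x test cell
#'
#' Dot-and-interval panels of the residualized genetic (common-phase) and
#' plastic (field-minus-common) effect means from [effect_means()], one
#' point per test x origin combination. Intervals reported as absent are
#' drawn without error bars.
#'
#' @param object An `sa_effect_cells` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sa_effect_cells
#' @export
autoplot.sa_effect_cells <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(effect = "genetic", test = object$test,
                   origin = object$origin, mean = object$genetic_mean,
                   ci_low = object$genetic_ci_low,
                   ci_high = object$genetic_ci_high),
    tibble::tibble(effect = "plastic", test = object$test,
                   origin = object$origin, mean = object$plastic_mean,
                   ci_low = object$plastic_ci_low,
                   ci_high = object$plastic_ci_high)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$test, y = .data$mean,
                                     colour = .data$origin)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high),
                             position = ggplot2::position_dodge(width = 0.4),
                             na.rm = TRUE) +
    ggplot2::facet_wrap(~effect) +
    ggplot2::labs(x = "test environment", y = "residualized trait mean",
                  colour = "origin") +
    ggplot2::theme_minimal()
}

#' Original-vs-alternative scatter plot
#'
#' One point per population x alternative environment, the population's
#' sympatric mean on the x axis and the allopatric mean on the y axis.
#' Points below the identity line indicate a sympatric advantage (a
#' pattern of local adaptation when drawn from the common phase).
#'
#' @param data Output of [original_vs_alternative()].
#' @return A ggplot object.
#' @export
plot_original_vs_alternative <- function(data) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data$mean_original,
                                     y = .data$mean_alternative,
                                     colour = .data$origin,
                                     shape = .data$alt_env)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_alternative - .data$se_alternative,
                                        ymax = .data$mean_alternative + .data$se_alternative),
                           width = 0, na.rm = TRUE, alpha = 0.5) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$mean_original - .data$se_original,
                                         xmax = .data$mean_original + .data$se_original),
                            height = 0, na.rm = TRUE, alpha = 0.5) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "mean trait on original environment",
                  y = "mean trait on alternative environment",
                  colour = "origin", shape = "test environment") +
    ggplot2::theme_minimal()
}

#' Plot the SA estimates of a dual-generation fit
#'
#' Genetic and plastic SA estimates with approximate 95% intervals
#' (estimate +/- 1.96 SE).
#'
#' @param object An `sa_dual_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sa_dual_result
#' @export
autoplot.sa_dual_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$estimate - 1.96 * .data$se,
                                          ymax = .data$estimate + 1.96 * .data$se)) +
    ggplot2::labs(x = NULL, y = "sympatric - allopatric contrast",
                  title = paste0("SA effects (", object$meta$trait, ")")) +
    ggplot2::theme_minimal()
}

#' Plot rejection rates from a simulation study
#'
#' Power (or false-positive rate) for the genetic and plastic tests against
#' the injected plastic effect size, one line per design multiplier.
#'
#' @param object An `sa_power_result` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sa_power_result
#' @export
autoplot.sa_power_result <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("reject_rate_genetic", "reject_rate_plastic"),
                        names_to = "test", values_to = "rate",
                        names_prefix = "reject_rate_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sa_plastic_true, y = .data$rate,
                                     colour = factor(.data$design_multiplier),
                                     linetype = .data$test)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$alpha),
                        linetype = "dotted", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "true plastic SA effect", y = "rejection rate",
                  colour = "design scale", linetype = "test") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
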