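# ggplot2 autoplot() methods for the fitted result objects.

#' Plot a probit detection curve
#'
#' Observed detection fractions per level, the fitted probit dose-response
#' curve, and the LOD at the target detection probability.
#'
#' @param object A `probit_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.probit_fit <- function(object, ...) {
  rng <- range(object$fitted$level_percent)
  grid <- tibble::tibble(
    level_percent = exp(seq(log(rng[1] / 2), log(rng[2] * 1.5), length.out = 200))
  )
  grid$fitted <- predict(object, grid$level_percent)
  ggplot2::ggplot(object$fitted, ggplot2::aes(x = .data$level_percent)) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 2) +
    ggplot2::geom_hline(yintercept = object$target_probability, linetype = "dotted") +
    ggplot2::geom_vline(xintercept = object$lod, linetype = "dashed", colour = "firebrick") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Mutant allele (%)", y = "Detection probability",
      title = sprintf("Probit LOD = %.3f%% at %.0f%% detection",
                      object$lod, 100 * object$target_probability)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fitted standard curve
#'
#' @param object A `standard_curve` fitted with [fit_standard_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.standard_curve <- function(object, ...) {
  if (is.null(object$model)) {
    abort("This standard_curve has no stored points; fit it with `fit_standard_curve()`.")
  }
  d <- tibble::tibble(
    conc = object$model$model$conc,
    cq = object$model$model$cqv
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$conc, y = .data$cq)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "log10 relative concentration", y = "Cq",
      title = sprintf("Slope %.3f, efficiency %.1f%%, R² = %.3f",
                      object$slope, 100 * object$efficiency, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot of a method comparison
#'
#' Differences against pair means, with the bias (solid) and 95% limits of
#' agreement (dashed).
#'
#' @param object A `method_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.method_comparison <- function(object, ...) {
  d <- object$data
  d$mean_pair <- (d$reference + d$test) / 2
  ggplot2::ggplot(d, ggplot2::aes(x = .data$mean_pair, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$bias, colour = "steelblue") +
    ggplot2::geom_hline(yintercept = object$loa, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(
      x = "Mean of methods (%)", y = "Difference, test - reference (%)",
      title = sprintf("Bias %.2f%%, limits of agreement %.2f to %.2f",
                      object$bias, object$loa[1], object$loa[2])
    ) +
    ggplot2::theme_minimal()
}
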