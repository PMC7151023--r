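# broom-style tidiers: tidy() returns the per-row table of an analysis,
# glance() a one-row summary of its headline numbers.

#' @export
tidy.probit_fit <- function(x, ...) x$fitted

#' @export
glance.probit_fit <- function(x, ...) {
  tibble::tibble(
    intercept = x$intercept, slope = x$slope, dose_scale = x$dose_scale,
    lod = x$lod, lod_ci_low = x$lod_ci[1], lod_ci_high = x$lod_ci[2],
    target_probability = x$target_probability, converged = x$converged
  )
}

#' @export
tidy.standard_curve <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @export
glance.standard_curve <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept,
    r_squared = x$r_squared, efficiency = x$efficiency, n = x$n
  )
}

#' @export
tidy.slope_comparison <- function(x, ...) x$pairwise

#' @export
glance.slope_comparison <- function(x, ...) {
  tibble::tibble(
    p_value = x$p_value, f_statistic = x$f_statistic,
    df_num = x$df[1], df_den = x$df[2], n_series = nrow(x$slopes)
  )
}

#' @export
tidy.precision_result <- function(x, ...) x$components

#' @export
glance.precision_result <- function(x, ...) {
  tibble::tibble(
    mean = x$mean, cv_total = x$cv_total,
    cv_between_day = x$cv_between_day, cv_within_run = x$cv_within_run,
    n_days = x$n_days, n_replicates = x$n_replicates
  )
}

#' @export
tidy.method_comparison <- function(x, ...) x$data

#' @export
glance.method_comparison <- function(x, ...) {
  tibble::tibble(
    n = x$n, pearson_r = x$pearson_r, pearson_p = x$pearson_p,
    slope = x$slope, intercept = x$intercept, r_squared = x$r_squared,
    bias = x$bias, sd_diff = x$sd_diff,
    loa_low = x$loa[1], loa_high = x$loa[2],
    bias_ci_low = x$bias_ci[1], bias_ci_high = x$bias_ci[2]
  )
}

#' @export
tidy.loq_result <- function(x, ...) x$table

#' @export
glance.loq_result <- function(x, ...) {
  tibble::tibble(
    loq = x$loq, defined = x$defined,
    detection_rule = x$detection_rule, alpha = x$alpha
  )
}

#' @export
tidy.agreement_result <- function(x, ...) x$counts

#' @export
glance.agreement_result <- function(x, ...) {
  tibble::tibble(
    total_agreement = x$total_agreement,
    positive_agreement = x$positive_agreement,
    negative_agreement = x$negative_agreement,
    n = x$counts$n
  )
}
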