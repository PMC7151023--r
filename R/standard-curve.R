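#' Construct a qPCR standard-curve model
#'
#' A calibration line `Cq = slope * log10(concentration) + intercept`. The
#' amplification efficiency is derived from the slope: a perfectly doubling
#' assay loses 1/log10(2) = 3.32 cycles per decade of template.
#'
#' @param slope Cycles per log10(concentration); must be negative.
#' @param intercept Cq at log10(concentration) = 0.
#' @param r_squared Coefficient of determination of the fit, if known.
#' @return An object of class `standard_curve` with fields `slope`,
#'   `intercept`, `r_squared` and `efficiency` (fraction; 1 = 100%).
#' @examples
#' standard_curve(slope = -3.26, intercept = 29.75)
#' @export
standard_curve <- function(slope, intercept, r_squared = NA_real_) {
  if (!is.numeric(slope) || slope >= 0) {
    abort("`slope` must be negative for an amplifying assay.")
  }
  structure(
    list(
      slope = slope, intercept = intercept, r_squared = r_squared,
      efficiency = efficiency_from_slope(slope),
      n = NA_integer_, model = NULL
    ),
    class = "standard_curve"
  )
}

#' Amplification efficiency from a dilution-series slope
#'
#' `E = 10^(-1/slope) - 1`; `E = 1` is perfect per-cycle doubling.
#'
#' @param slope Standard-curve slope (cycles per log10 concentration),
#'   negative.
#' @return Efficiency as a fraction (multiply by 100 for percent).
#' @examples
#' efficiency_from_slope(-3.3219)  # 1.00
#' efficiency_from_slope(-3.5)     # 0.931
#' @export
efficiency_from_slope <- function(slope) {
  if (any(!is.finite(slope)) || any(slope >= 0)) {
    abort("`slope` must be finite and negative.")
  }
  10^(-1 / slope) - 1
}

#' Fit a standard curve to dilution-series Cq data
#'
#' Ordinary least squares of Cq on log10 relative concentration, the field's
#' standard treatment of a serial-dilution calibration experiment.
#'
#' @param data A data frame of dilution points.
#' @param conc <[`tidy-select`][dplyr::dplyr_tidy_select]> column holding
#'   log10 relative concentration (default `log10_conc`).
#' @param cq Column holding the Cq values (default `cq`).
#' @return A `standard_curve` object carrying the fitted `lm` and point count.
#' @examples
#' pts <- tibble::tibble(log10_conc = c(0, -1, -2), cq = c(30, 33.32, 36.64))
#' fit_standard_curve(pts)
#' @export
fit_standard_curve <- function(data, conc = log10_conc, cq = cq) {
  conc <- dplyr::pull(data, {{ conc }})
  cqv <- dplyr::pull(data, {{ cq }})
  keep <- is.finite(conc) & is.finite(cqv)
  conc <- conc[keep]; cqv <- cqv[keep]
  if (length(conc) < 3) abort("A standard curve needs at least 3 finite points.")
  if (diff(range(conc)) < 1) {
    abort("Dilution points must span at least one log10 of concentration.")
  }
  fit <- lm(cqv ~ conc)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) abort("Fitted slope is non-negative; not an amplifying dilution series.")
  out <- standard_curve(
    slope = slope,
    intercept = unname(coef(fit)[1]),
    # exact dilution points are legitimate; silence the perfect-fit notice
    r_squared = suppressWarnings(summary(fit)$r.squared)
  )
  out$n <- length(conc)
  out$model <- fit
  out
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("<standard_curve>\n")
  cat(sprintf("  Cq = %.4f * log10(conc) + %.4f\n", x$slope, x$intercept))
  cat(sprintf("  efficiency = %.1f%%", 100 * x$efficiency))
  if (!is.na(x$r_squared)) cat(sprintf("  R^2 = %.4f", x$r_squared))
  if (!is.na(x$n)) cat(sprintf("  (n = %d)", x$n))
  cat("\n")
  invisible(x)
}

#' Test equality of dilution-series slopes across assays
#'
#' The comparative Cq method presumes that all assays amplify with the same
#' efficiency, i.e. that their dilution-series slopes are parallel. This runs
#' an ANCOVA-style comparison: the global test is an extra-sum-of-squares F
#' between a common-slope model (`cq ~ series + conc`) and a separate-slopes
#' model (`cq ~ series * conc`); each pair of series additionally gets a
#' t-test on the slope difference with pooled residual variance.
#'
#' Noiseless designs are resolved exactly: identical slopes with zero
#' residual give p = 1, different slopes with zero residual give p = 0.
#'
#' @param data A data frame with one row per dilution point.
#' @param series Column identifying the dilution series (default `series`).
#' @param conc Column with log10 relative concentration (default `log10_conc`).
#' @param cq Column with Cq values (default `cq`).
#' @return An object of class `slope_comparison`: `p_value` (global F test),
#'   `f_statistic`, `df`, `pairwise` (tibble of per-pair slope differences and
#'   p-values) and `slopes` (per-series fitted slopes and efficiencies).
#' @examples
#' pts <- tidyr::crossing(series = c("wt", "mut"), log10_conc = c(0, -1, -2, -3))
#' pts$cq <- 30 - 3.32 * pts$log10_conc + ifelse(pts$series == "wt", 0, 0.5)
#' compare_slopes(pts)$p_value  # parallel: 1
#' @export
compare_slopes <- function(data, series = series, conc = log10_conc, cq = cq) {
  d <- tibble::tibble(
    series = as.character(dplyr::pull(data, {{ series }})),
    conc = dplyr::pull(data, {{ conc }}),
    cq = dplyr::pull(data, {{ cq }})
  )
  d <- dplyr::filter(d, is.finite(.data$conc), is.finite(.data$cq))
  counts <- dplyr::count(d, .data$series)
  if (nrow(counts) < 2) abort("`compare_slopes()` needs at least two series.")
  if (any(counts$n < 3)) {
    abort(paste0(
      "Each series needs >= 3 points; offending series: ",
      paste(counts$series[counts$n < 3], collapse = ", ")
    ))
  }
  span <- dplyr::summarise(
    dplyr::group_by(d, .data$series),
    span = diff(range(.data$conc)), .groups = "drop"
  )
  if (any(span$span <= 0)) abort("Degenerate series: no concentration span.")

  d$series <- factor(d$series)
  common <- lm(cq ~ series + conc, data = d)
  separate <- lm(cq ~ series * conc, data = d)
  rss_c <- sum(residuals_sq(common))
  rss_s <- sum(residuals_sq(separate))
  df_extra <- common$df.residual - separate$df.residual
  scale0 <- max(sum(d$cq^2), 1)
  if (rss_s / scale0 < 1e-20) {
    # exact fits: equal slopes iff dropping the interaction costs nothing
    p_global <- if ((rss_c - rss_s) / scale0 < 1e-20) 1 else 0
    f_stat <- NA_real_
  } else {
    f_stat <- ((rss_c - rss_s) / df_extra) / (rss_s / separate$df.residual)
    p_global <- stats::pf(f_stat, df_extra, separate$df.residual, lower.tail = FALSE)
  }

  slopes <- dplyr::summarise(
    dplyr::group_by(d, .data$series),
    slope = unname(coef(lm(cq ~ conc, data = dplyr::pick(dplyr::everything())))[2]),
    n = dplyr::n(),
    .groups = "drop"
  )
  slopes$efficiency <- ifelse(slopes$slope < 0, 10^(-1 / slopes$slope) - 1, NA_real_)

  lv <- levels(d$series)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    dd <- d[d$series %in% pr, , drop = FALSE]
    dd$series <- droplevels(dd$series)
    fit <- lm(cq ~ series * conc, data = dd)
    rss <- sum(residuals_sq(fit))
    dfres <- fit$df.residual
    b_diff <- unname(coef(fit)[4])
    if (rss / scale0 < 1e-20) {
      p <- if (abs(b_diff) < 1e-10) 1 else 0
      tstat <- NA_real_
    } else {
      se <- sqrt(diag(vcov(fit)))[4]
      tstat <- b_diff / se
      p <- 2 * pt(abs(tstat), dfres, lower.tail = FALSE)
    }
    tibble::tibble(
      series_1 = pr[1], series_2 = pr[2],
      slope_diff = b_diff, t = tstat, df = dfres, p_value = p
    )
  })

  structure(
    list(
      p_value = unname(p_global), f_statistic = unname(f_stat),
      df = c(df_extra, separate$df.residual),
      pairwise = pairwise, slopes = slopes
    ),
    class = "slope_comparison"
  )
}

residuals_sq <- function(fit) stats::residuals(fit)^2

#' @export
print.slope_comparison <- function(x, ...) {
  cat("<slope_comparison>\n")
  cat(sprintf(
    "  global equal-slope F test: p = %s\n",
    format.pval(x$p_value, digits = 3)
  ))
  print(x$slopes)
  invisible(x)
}
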