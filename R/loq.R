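#' One-sample t-test from summary statistics
#'
#' Tests whether an observed mean differs from an expected value using only
#' the summary triplet (mean, SD, n) — the form in which replicate dilution
#' results are usually tabulated.
#'
#' @param mean Observed mean (% mutant allele).
#' @param sd Observed standard deviation.
#' @param n Number of replicates (>= 2).
#' @param expected Expected (nominal) value under the null.
#' @return A tibble with columns `t`, `df`, `p_value`. With `sd = 0` the test
#'   is degenerate: p = 1 if the mean equals the expected value exactly,
#'   else p = 0.
#' @examples
#' one_sample_t_from_summary(1.03, 0.25, 9, 1.16)  # p ~ 0.16
#' @export
one_sample_t_from_summary <- function(mean, sd, n, expected) {
  stopifnot(n >= 2, sd >= 0)
  if (sd == 0) {
    p <- if (isTRUE(all.equal(mean, expected))) 1 else 0
    return(tibble::tibble(t = if (p == 1) 0 else Inf * sign(mean - expected),
                          df = n - 1, p_value = p))
  }
  t <- (mean - expected) / (sd / sqrt(n))
  tibble::tibble(t = t, df = n - 1, p_value = 2 * pt(abs(t), n - 1, lower.tail = FALSE))
}

#' Limit of quantification from a dilution-series accuracy experiment
#'
#' A level is *quantifiable* when (i) it was detected in enough replicates
#' (at least `ceiling(detection_rule * n)`, defaulting to about 8 of 9) and
#' (ii) a one-sample t-test finds no significant difference between the
#' observed replicate values and the nominal level (p > `alpha`). The LOQ is
#' the lowest quantifiable level below which every tested level fails —
#' i.e. the point where the assay's response stops being unbiased.
#'
#' @param levels A data frame with one of two layouts, both with a
#'   `level_percent` column (strictly decreasing levels):
#'   * replicate layout — a column `observed_percent` with one row per
#'     replicate (rows with `NA` count as not detected), or
#'   * summary layout — columns `mean`, `sd`, `n` and optionally
#'     `n_detected` (assumed `n` when absent).
#' @param detection_rule Minimum fraction of replicates that must be
#'   detected before a level is assessed quantitatively (default 0.85,
#'   generalising "at least eight of nine").
#' @param alpha Significance level of the accuracy t-test (default 0.05).
#' @return An object of class `loq_result`: `loq` (percent, or `NA` when no
#'   level qualifies), `defined` (logical) and `table` (per-level tibble with
#'   detection counts, t-test results and a `pass` flag).
#' @examples
#' printed <- tibble::tibble(
#'   level_percent = c(1.16, 0.58, 0.29, 0.15),
#'   mean = c(1.03, 0.19, 0.048, 0.0098),
#'   sd = c(0.25, 0.06, 0.037, 0.0053),
#'   n = 9
#' )
#' loq_assessment(printed)$loq  # 1.16
#' @export
loq_assessment <- function(levels, detection_rule = 0.85, alpha = 0.05) {
  stopifnot(detection_rule > 0, detection_rule <= 1, alpha > 0, alpha < 1)
  levels <- tibble::as_tibble(levels)
  if (!"level_percent" %in% names(levels)) {
    abort("`levels` needs a `level_percent` column.")
  }

  if ("observed_percent" %in% names(levels)) {
    tab <- dplyr::summarise(
      dplyr::group_by(levels, level_percent = .data$level_percent),
      n = dplyr::n(),
      n_detected = sum(!is.na(.data$observed_percent)),
      mean = base::mean(.data$observed_percent, na.rm = TRUE),
      sd = stats::sd(.data$observed_percent, na.rm = TRUE),
      .groups = "drop"
    )
    tab <- dplyr::arrange(tab, dplyr::desc(.data$level_percent))
  } else if (all(c("mean", "sd", "n") %in% names(levels))) {
    tab <- levels
    if (!"n_detected" %in% names(tab)) tab$n_detected <- tab$n
  } else {
    abort("`levels` must carry either `observed_percent` rows or `mean`, `sd`, `n` summaries.")
  }
  if (any(diff(tab$level_percent) >= 0)) abort("Levels must be strictly decreasing.")
  if (any(tab$n < 2)) abort("Each level needs at least 2 replicates.")

  tab$detection_ok <- tab$n_detected >= ceiling(detection_rule * tab$n)
  tt <- purrr::pmap_dfr(
    list(tab$mean, tab$sd, tab$n, tab$level_percent),
    function(m, s, n, exp) {
      if (!is.finite(m) || !is.finite(s)) {
        return(tibble::tibble(t = NA_real_, df = n - 1, p_value = NA_real_))
      }
      one_sample_t_from_summary(m, s, n, exp)
    }
  )
  tab <- dplyr::bind_cols(tab, tt)
  tab$pass <- tab$detection_ok & !is.na(tab$p_value) & tab$p_value > alpha

  loq <- NA_real_
  for (i in rev(seq_len(nrow(tab)))) {  # lowest level upwards
    if (tab$pass[i] && (i == nrow(tab) || !any(tab$pass[(i + 1):nrow(tab)]))) {
      loq <- tab$level_percent[i]
      break
    }
  }
  structure(
    list(loq = loq, defined = is.finite(loq), table = tab,
         detection_rule = detection_rule, alpha = alpha),
    class = "loq_result"
  )
}

#' @export
print.loq_result <- function(x, ...) {
  cat("<loq_result>\n")
  if (x$defined) {
    cat(sprintf("  LOQ: %g%% mutant allele\n", x$loq))
  } else {
    cat("  LOQ: undefined (no level passed the accuracy assessment)\n")
  }
  print(x$table)
  invisible(x)
}
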