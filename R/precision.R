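#' Precision analysis by one-way random-effects ANOVA
#'
#' Decomposes the variability of a day-by-replicate precision design (CLSI
#' EP05 style: the same sample measured in `r` replicates on each of `d`
#' days) into within-run and between-day components and reports them as
#' coefficients of variation:
#' * within-run variance = mean square within days (`MS_within`),
#' * between-day variance = `max(0, (MS_between - MS_within) / r)`,
#' * total variance = their sum,
#' * `CV_x = 100 * sqrt(var_x) / grand mean`.
#'
#' @param data A balanced data frame with columns `day`, `replicate` and
#'   `percent` (the measured mutant-allele percentage); at least 2 days and
#'   2 replicates per day.
#' @return An object of class `precision_result`: `mean`, `cv_total`,
#'   `cv_between_day`, `cv_within_run` (percent), the underlying variance
#'   `components` tibble and the design dimensions.
#' @examples
#' d <- tidyr::crossing(day = 1:2, replicate = 1:2)
#' d$percent <- c(10, 12, 14, 16)
#' precision_analysis(d)
#' @export
precision_analysis <- function(data) {
  req <- c("day", "replicate", "percent")
  if (!all(req %in% names(data))) {
    abort(paste0("`data` needs columns: ", paste(req, collapse = ", ")))
  }
  d <- tibble::as_tibble(data)
  if (any(!is.finite(d$percent))) abort("`percent` must be finite.")
  counts <- dplyr::count(d, .data$day)
  n_day <- nrow(counts)
  if (n_day < 2) abort("Need at least 2 days.")
  if (dplyr::n_distinct(counts$n) != 1 || counts$n[1] < 2) {
    abort("Design must be balanced with >= 2 replicates per day.")
  }
  n_rep <- counts$n[1]

  fit <- aov(percent ~ factor(day), data = d)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  ms_between <- ms[1]
  ms_within <- ms[2]
  var_within <- ms_within
  var_between <- max(0, (ms_between - ms_within) / n_rep)
  var_total <- var_within + var_between
  grand_mean <- mean(d$percent)
  cv <- function(v) 100 * sqrt(v) / grand_mean

  structure(
    list(
      mean = grand_mean,
      cv_total = cv(var_total),
      cv_between_day = cv(var_between),
      cv_within_run = cv(var_within),
      components = tibble::tibble(
        component = c("within_run", "between_day", "total"),
        variance = c(var_within, var_between, var_total),
        cv_percent = c(cv(var_within), cv(var_between), cv(var_total))
      ),
      n_days = n_day, n_replicates = n_rep
    ),
    class = "precision_result"
  )
}

#' @export
print.precision_result <- function(x, ...) {
  cat("<precision_result>\n")
  cat(sprintf("  %d days x %d replicates, mean %.2f%%\n", x$n_days, x$n_replicates, x$mean))
  cat(sprintf(
    "  CV total %.2f%%  between-day %.2f%%  within-run %.2f%%\n",
    x$cv_total, x$cv_between_day, x$cv_within_run
  ))
  invisible(x)
}
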