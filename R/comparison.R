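#' Quantitative method / specimen comparison
#'
#' The standard agreement workup for two quantitative measurements of the
#' same samples: Pearson correlation, ordinary least-squares regression of
#' the test method on the reference, and Bland-Altman analysis of the
#' differences `d = test - reference` — bias (mean difference), 95% limits
#' of agreement (`bias +/- 1.96 * SD(d)`, the interval expected to cover 95%
#' of individual differences) and a t-based confidence interval for the bias
#' itself. Positive bias means the test method (or specimen) reads higher.
#'
#' Optionally splits the cohort at a threshold (default 20% mutant allele)
#' and repeats the analysis per subgroup, which localises where two
#' specimens diverge.
#'
#' @param data A data frame of paired quantitative results.
#' @param reference Column with the reference-method values (default
#'   `reference`).
#' @param test Column with the test-method values (default `test`).
#' @param subgroup_threshold Percent threshold splitting the cohort for the
#'   subgroup analyses; `NULL` disables subgrouping (default 20).
#' @param subgroup_by Whether the split uses the `"reference"` (default) or
#'   the `"test"` values.
#' @return An object of class `method_comparison`: `n`, `pearson_r`,
#'   `pearson_p`, `slope`, `intercept`, `r_squared`, `bias`, `loa`
#'   (length-2 limits of agreement), `bias_ci` (length-2), `sd_diff`,
#'   `degenerate` (TRUE when a zero-variance input leaves r undefined),
#'   `data` (pairs + differences) and `subgroups` (tibble of per-subgroup
#'   summaries, when requested and populated).
#' @examples
#' pairs <- tibble::tibble(reference = c(10, 20, 30), test = c(12, 21, 33))
#' mc <- method_comparison(pairs, subgroup_threshold = NULL)
#' mc$bias  # 2
#' mc$loa   # 0.04 3.96
#' @export
method_comparison <- function(data, reference = reference, test = test,
                              subgroup_threshold = 20,
                              subgroup_by = c("reference", "test")) {
  subgroup_by <- match.arg(subgroup_by)
  ref <- dplyr::pull(data, {{ reference }})
  tst <- dplyr::pull(data, {{ test }})
  keep <- is.finite(ref) & is.finite(tst)
  ref <- ref[keep]; tst <- tst[keep]
  if (length(ref) < 3) abort("Need at least 3 complete quantitative pairs.")

  core <- comparison_core(ref, tst)

  subgroups <- NULL
  if (!is.null(subgroup_threshold)) {
    by <- if (subgroup_by == "reference") ref else tst
    idx <- list(
      below = by < subgroup_threshold,
      above = by >= subgroup_threshold
    )
    subgroups <- purrr::imap_dfr(idx, function(sel, nm) {
      if (sum(sel) < 3) {
        return(tibble::tibble(
          subgroup = nm, n = sum(sel), pearson_r = NA_real_,
          r_squared = NA_real_, bias = NA_real_,
          loa_low = NA_real_, loa_high = NA_real_
        ))
      }
      s <- comparison_core(ref[sel], tst[sel])
      tibble::tibble(
        subgroup = nm, n = s$n, pearson_r = s$pearson_r,
        r_squared = s$r_squared, bias = s$bias,
        loa_low = s$loa[1], loa_high = s$loa[2]
      )
    })
    subgroups$threshold <- subgroup_threshold
    subgroups$by <- subgroup_by
  }

  structure(
    c(core, list(
      data = tibble::tibble(reference = ref, test = tst, diff = tst - ref),
      subgroups = subgroups
    )),
    class = "method_comparison"
  )
}

comparison_core <- function(ref, tst) {
  n <- length(ref)
  d <- tst - ref
  bias <- mean(d)
  sd_d <- sd(d)
  loa <- bias + c(-1, 1) * 1.96 * sd_d
  bias_ci <- bias + c(-1, 1) * qt(0.975, n - 1) * sd_d / sqrt(n)

  degenerate <- sd(ref) == 0 || sd(tst) == 0
  if (degenerate) {
    r <- NA_real_; r_p <- NA_real_
    slope <- NA_real_; intercept <- NA_real_; r2 <- NA_real_
  } else {
    ct <- cor.test(ref, tst, method = "pearson")
    r <- unname(ct$estimate); r_p <- ct$p.value
    fit <- lm(tst ~ ref)
    slope <- unname(coef(fit)[2]); intercept <- unname(coef(fit)[1])
    r2 <- suppressWarnings(summary(fit)$r.squared)  # exact agreement is valid input
  }
  list(
    n = n, pearson_r = r, pearson_p = r_p,
    slope = slope, intercept = intercept, r_squared = r2,
    bias = bias, sd_diff = sd_d, loa = loa, bias_ci = bias_ci,
    degenerate = degenerate
  )
}

#' @export
print.method_comparison <- function(x, ...) {
  cat("<method_comparison>\n")
  if (x$degenerate) {
    cat(sprintf("  n = %d; correlation undefined (zero variance in an input)\n", x$n))
  } else {
    cat(sprintf(
      "  n = %d; Pearson r = %.3f (p = %s); test = %.3f * ref + %.3f (R^2 = %.3f)\n",
      x$n, x$pearson_r, format.pval(x$pearson_p, digits = 3),
      x$slope, x$intercept, x$r_squared
    ))
  }
  cat(sprintf(
    "  bias %.3f%% (95%% CI %.3f to %.3f), limits of agreement %.3f to %.3f\n",
    x$bias, x$bias_ci[1], x$bias_ci[2], x$loa[1], x$loa[2]
  ))
  if (!is.null(x$subgroups)) print(x$subgroups)
  invisible(x)
}

#' Qualitative (detected / not detected) agreement between two methods
#'
#' Summarises paired binary calls in the usual 2x2 form. Positive agreement
#' is the share of reference-positive samples also called positive by the
#' test method; negative agreement is the analogue among reference
#' negatives. A stratum with no reference samples leaves the corresponding
#' agreement `NA` (undefined, not zero).
#'
#' @param data A data frame of paired calls.
#' @param reference Column of reference calls (default `reference`); logical,
#'   or anything coercible via `as.logical()`, or the strings
#'   "positive"/"negative".
#' @param test Column of test calls (default `test`).
#' @return An object of class `agreement_result`: `total_agreement`,
#'   `positive_agreement`, `negative_agreement` (percent, `NA` when
#'   undefined) and `counts` (tp, fn, fp, tn).
#' @examples
#' calls <- tibble::tibble(
#'   reference = rep(c(TRUE, FALSE), c(10, 10)),
#'   test = rep(c(TRUE, FALSE, TRUE, FALSE), c(8, 2, 1, 9))
#' )
#' qualitative_agreement(calls)
#' @export
qualitative_agreement <- function(data, reference = reference, test = test) {
  ref <- as_binary_call(dplyr::pull(data, {{ reference }}), "reference")
  tst <- as_binary_call(dplyr::pull(data, {{ test }}), "test")
  keep <- !is.na(ref) & !is.na(tst)
  ref <- ref[keep]; tst <- tst[keep]
  n <- length(ref)
  if (n < 1) abort("Need at least one complete pair of calls.")

  tp <- sum(ref & tst); fn <- sum(ref & !tst)
  fp <- sum(!ref & tst); tn <- sum(!ref & !tst)
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_

  structure(
    list(
      total_agreement = 100 * (tp + tn) / n,
      positive_agreement = pct(tp, tp + fn),
      negative_agreement = pct(tn, tn + fp),
      counts = tibble::tibble(tp = tp, fn = fn, fp = fp, tn = tn, n = n)
    ),
    class = "agreement_result"
  )
}

as_binary_call <- function(x, what) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    lx <- tolower(x)
    out <- dplyr::case_when(
      lx %in% c("positive", "pos", "detected", "true", "t", "yes", "1") ~ TRUE,
      lx %in% c("negative", "neg", "not_detected", "false", "f", "no", "0") ~ FALSE,
      TRUE ~ NA
    )
    if (any(is.na(out) & !is.na(x))) {
      abort(sprintf("Unrecognised call value(s) in `%s`: %s",
                    what, paste(unique(x[is.na(out) & !is.na(x)]), collapse = ", ")))
    }
    return(out)
  }
  abort(sprintf("Cannot interpret `%s` as binary calls.", what))
}

#' @export
print.agreement_result <- function(x, ...) {
  cat("<agreement_result>\n")
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.1f%%", v)
  cat(sprintf(
    "  total %s  positive %s  negative %s\n",
    fmt(x$total_agreement), fmt(x$positive_agreement), fmt(x$negative_agreement)
  ))
  print(x$counts)
  invisible(x)
}
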