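#' Mutant-allele percentage from a Cq pair (comparative Cq, no reference)
#'
#' The two allele-specific reactions are run on aliquots of the same DNA, so
#' the difference of their quantification cycles measures the log2 ratio of
#' mutant to wild-type template. The mutant fraction follows directly:
#' \deqn{\%mut = 100 / (2^{-(Cq_{wt} - Cq_{mut})} + 1)}
#' Equal Cqs give exactly 50%; each extra cycle on the wild-type reaction
#' doubles the mutant:wild-type odds.
#'
#' @param cq_wt Cq of the wild-type-specific reaction (cycles). Vectorised.
#' @param cq_mut Cq of the mutant-specific reaction (cycles). Vectorised.
#' @return Percent mutant allele, strictly inside (0, 100).
#' @seealso [mutant_percent_corrected()] for the RNase P-normalised form,
#'   [classify_results()] for policy-aware calls on whole tables.
#' @examples
#' mutant_percent_simple(30, 30)   # 50
#' mutant_percent_simple(31, 30)   # 66.7: one extra wt cycle doubles the odds
#' @export
mutant_percent_simple <- function(cq_wt, cq_mut) {
  check_cq_numeric(cq_wt, "cq_wt")
  check_cq_numeric(cq_mut, "cq_mut")
  100 / (2^(-(cq_wt - cq_mut)) + 1)
}

#' Mutant-allele percentage from a Cq quartet (RNase P-corrected)
#'
#' Identical to [mutant_percent_simple()] but each allele-specific Cq is first
#' normalised to the RNase P Cq of its own tube, cancelling small differences
#' in DNA input between the two physically independent reactions (pipetting):
#' \deqn{\%mut = 100 / (2^{-\Delta\Delta Cq} + 1),\quad
#'   \Delta\Delta Cq = (Cq_{wt} - Cq_{RP,wt}) - (Cq_{mut} - Cq_{RP,mut})}
#' When the two reference Cqs are equal this reduces exactly to the simple
#' formula.
#'
#' @inheritParams mutant_percent_simple
#' @param cq_rp_wt RNase P Cq in the wild-type reaction tube (cycles).
#' @param cq_rp_mut RNase P Cq in the mutant reaction tube (cycles).
#' @return Percent mutant allele, strictly inside (0, 100).
#' @examples
#' mutant_percent_corrected(30, 30, 25, 25)  # 50
#' mutant_percent_corrected(30, 30, 25, 26)  # 66.7
#' @export
mutant_percent_corrected <- function(cq_wt, cq_mut, cq_rp_wt, cq_rp_mut) {
  check_cq_numeric(cq_wt, "cq_wt")
  check_cq_numeric(cq_mut, "cq_mut")
  check_cq_numeric(cq_rp_wt, "cq_rp_wt")
  check_cq_numeric(cq_rp_mut, "cq_rp_mut")
  ddcq <- (cq_wt - cq_rp_wt) - (cq_mut - cq_rp_mut)
  100 / (2^(-ddcq) + 1)
}

check_cq_numeric <- function(cq, what) {
  if (!is.numeric(cq)) {
    abort(sprintf("`%s` must be numeric (cycles).", what))
  }
  if (any(is_undetermined(cq), na.rm = TRUE)) {
    abort(sprintf(
      "`%s` contains undetermined Cq values; route records through `classify_results()` instead.",
      what
    ))
  }
  invisible(cq)
}

#' Classify AS-qPCR reaction pairs into mutant-fraction results
#'
#' Applies the full decision logic of the assay to a table of reaction-pair
#' records: the mutant-reaction Cq cutoff for unspecific amplification, the
#' detection and quantification limits, the choice between the simple and the
#' RNase P-corrected formula, and the RNase P quality checks.
#'
#' A sample whose wild-type reaction is `undetermined` (`Inf`) is an invalid
#' sample (no amplifiable template or inhibition) — this is an error, distinct
#' from a negative call. A mutant reaction that is `undetermined` or at/beyond
#' the Cq cutoff is `not_detected`. Otherwise the mutant percentage is
#' computed and bucketed: below the LOD it is `not_detected` (the percentage
#' is suppressed), between LOD and LOQ it is `detected_below_loq` (the
#' percentage is retained but flagged non-reportable as a quantity), at or
#' above the LOQ it is `quantified`.
#'
#' @param data A data frame with columns `sample_id`, `cq_wt`, `cq_mut` and
#'   optionally `specimen`, `cq_rp_wt`, `cq_rp_mut`. Cq columns are numeric
#'   cycles with `Inf` meaning `undetermined` (no amplification within the
#'   run) and `NA` meaning not measured.
#' @param policy A [qc_policy()].
#' @param formula `"auto"` uses the corrected formula when both RNase P Cqs
#'   are present and finite, else the simple one; `"rnasep_corrected"` and
#'   `"simple"` force a formula. Forcing the corrected formula on records
#'   without usable RNase P Cqs yields status `invalid_no_reference`.
#' @return A tibble with one row per input record: `sample_id`, `specimen`,
#'   `formula`, `delta_cq` (the Cq difference, or the double difference for
#'   the corrected formula), `percent`, `status` (factor with levels
#'   `not_detected`, `detected_below_loq`, `quantified`,
#'   `invalid_no_reference`) and `warnings` (comma-separated QC flags, `NA`
#'   when clean).
#' @examples
#' cqs <- tibble::tibble(
#'   sample_id = c("pos", "weak", "neg"),
#'   cq_wt  = c(30, 30, 27),
#'   cq_mut = c(31, 37.64, Inf),
#'   cq_rp_wt  = c(25.1, 25.2, 25.0),
#'   cq_rp_mut = c(25.1, 25.2, 25.0)
#' )
#' classify_results(cqs)
#' @export
classify_results <- function(data, policy = qc_policy(),
                             formula = c("auto", "rnasep_corrected", "simple")) {
  formula <- match.arg(formula)
  stopifnot(inherits(policy, "qc_policy"))
  req <- c("sample_id", "cq_wt", "cq_mut")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    abort(paste0("`data` is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)
  if (!"specimen" %in% names(data)) data$specimen <- "other"
  if (!"cq_rp_wt" %in% names(data)) data$cq_rp_wt <- NA_real_
  if (!"cq_rp_mut" %in% names(data)) data$cq_rp_mut <- NA_real_

  bad_wt <- is.na(data$cq_wt) | is_undetermined(data$cq_wt)
  if (any(bad_wt)) {
    abort(paste0(
      "Invalid sample(s) — wild-type reaction did not amplify (inhibition or no template), ",
      "which is distinct from a negative mutant call: ",
      paste(data$sample_id[bad_wt], collapse = ", ")
    ))
  }

  n <- nrow(data)
  out <- tibble::tibble(
    sample_id = data$sample_id,
    specimen = data$specimen,
    formula = NA_character_,
    delta_cq = NA_real_,
    percent = NA_real_,
    status = NA_character_,
    warnings = NA_character_
  )

  rp_ok <- !is.na(data$cq_rp_wt) & !is.na(data$cq_rp_mut) &
    !is_undetermined(data$cq_rp_wt) & !is_undetermined(data$cq_rp_mut)

  for (i in seq_len(n)) {
    use_corrected <- switch(formula,
      auto = rp_ok[i],
      rnasep_corrected = TRUE,
      simple = FALSE
    )
    out$formula[i] <- if (use_corrected) "rnasep_corrected" else "simple"

    flags <- character()
    if (rp_ok[i]) {
      rp_delta <- abs(data$cq_rp_wt[i] - data$cq_rp_mut[i])
      if (rp_delta > policy$rp_delta_warn) {
        flags <- c(flags, sprintf("rp_delta=%.2f", rp_delta))
      }
      if (max(data$cq_rp_wt[i], data$cq_rp_mut[i]) > policy$rp_max_cq) {
        flags <- c(flags, "rp_high_cq")
      }
    }

    if (use_corrected && !rp_ok[i]) {
      out$status[i] <- "invalid_no_reference"
      out$warnings[i] <- "missing_rnasep"
      next
    }

    cq_mut <- data$cq_mut[i]
    if (is.na(cq_mut) || is_undetermined(cq_mut) || cq_mut >= policy$cq_cutoff) {
      out$status[i] <- "not_detected"
    } else {
      if (use_corrected) {
        out$delta_cq[i] <- (data$cq_wt[i] - data$cq_rp_wt[i]) - (cq_mut - data$cq_rp_mut[i])
        pct <- mutant_percent_corrected(
          data$cq_wt[i], cq_mut, data$cq_rp_wt[i], data$cq_rp_mut[i]
        )
      } else {
        out$delta_cq[i] <- data$cq_wt[i] - cq_mut
        pct <- mutant_percent_simple(data$cq_wt[i], cq_mut)
      }
      if (pct < policy$lod_percent) {
        out$status[i] <- "not_detected"
      } else if (pct < policy$loq_percent) {
        out$status[i] <- "detected_below_loq"
        out$percent[i] <- pct
      } else {
        out$status[i] <- "quantified"
        out$percent[i] <- pct
      }
    }
    if (length(flags)) out$warnings[i] <- paste(flags, collapse = ";")
  }

  flagged <- !is.na(out$warnings) & out$status != "invalid_no_reference"
  if (any(flagged)) {
    warn(paste0(
      "RNase P QC flag(s) on sample(s): ",
      paste(unique(out$sample_id[flagged]), collapse = ", ")
    ))
  }
  out$status <- factor(
    out$status,
    levels = c("not_detected", "detected_below_loq", "quantified", "invalid_no_reference")
  )
  out
}

#' Template copies per reaction from a Cq and a standard curve
#'
#' Inverts the calibration line `Cq = slope * log10(copies) + intercept`.
#'
#' @param cq Observed Cq (cycles). Vectorised.
#' @param curve A [standard_curve()] (or the result of [fit_standard_curve()]).
#' @return Estimated template copies per reaction.
#' @examples
#' rp <- standard_curve(slope = -3.26, intercept = 29.75)
#' copies_from_cq(c(29.75, 23.23, 10.19), rp)
#' @export
copies_from_cq <- function(cq, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  check_cq_numeric(cq, "cq")
  10^((cq - curve$intercept) / curve$slope)
}

#' DNA concentration from a reference-target copy count
#'
#' Converts single-copy reference (RNase P) copies per reaction to an input
#' DNA concentration: copies times the haploid genome mass, divided by 2
#' because the calibrant is ssDNA, divided by the reaction input volume.
#'
#' @param copies Copies per reaction (non-negative). Vectorised.
#' @param constants A [genome_constants()].
#' @return Concentration in ng/uL.
#' @examples
#' dna_concentration_from_copies(1000)  # 0.33 ng/uL
#' @export
dna_concentration_from_copies <- function(copies, constants = genome_constants()) {
  stopifnot(inherits(constants, "genome_constants"))
  if (any(copies < 0, na.rm = TRUE)) abort("`copies` must be non-negative.")
  copies * constants$haploid_genome_ng / constants$ds_correction /
    constants$reaction_input_volume
}

#' Render a mutant-allele percentage for reporting
#'
#' Two decimal places at or above 1%, four significant digits below 1% (low
#' fractions such as 0.0015% keep their leading information). Internal
#' computation is always full precision; this is a display rule only.
#'
#' @param percent Numeric percentages.
#' @return Character vector; `NA` stays `NA`.
#' @examples
#' format_percent(c(52.4638, 0.0015259, NA))
#' @export
format_percent <- function(percent) {
  out <- rep(NA_character_, length(percent))
  big <- !is.na(percent) & percent >= 1
  small <- !is.na(percent) & percent < 1
  out[big] <- sprintf("%.2f", percent[big])
  out[small] <- formatC(signif(percent[small], 4), format = "fg", flag = "#", digits = 4)
  out
}
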