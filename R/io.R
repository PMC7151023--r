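#' Read a tidy Cq export into reaction-pair records
#'
#' Reads the package's instrument-neutral Cq export dialect: a comma-
#' separated, UTF-8 file with mandatory header and columns `sample_id`,
#' `specimen`, `reaction` (`wt` / `mut`), `target` (`allele` / `reference`)
#' and `cq`. A quantifiable sample contributes four rows (two reactions by
#' two targets); reference rows may be absent. The sentinel strings
#' `"Undetermined"` (case-insensitive), `"NA"` and `""` map to the
#' `undetermined` Cq (`Inf`); any other non-numeric value is an error naming
#' the offending row — never silently missing. Lines starting with `#` are
#' metadata comments.
#'
#' @param path Path to the CSV file.
#' @return A tibble with one row per sample, in order of first appearance:
#'   `sample_id`, `specimen`, `cq_wt`, `cq_mut`, `cq_rp_wt`, `cq_rp_mut`.
#' @examples
#' f <- system.file("extdata", "example_cq_export.csv", package = "asqpcr")
#' read_cq_export(f)
#' @export
read_cq_export <- function(path) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    comment = "#", na = character()
  )
  req <- c("sample_id", "specimen", "reaction", "target", "cq")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols)) {
    abort(paste0("Cq export is missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  raw$row <- seq_len(nrow(raw)) + 1L  # data rows start after the header

  bad_reaction <- !raw$reaction %in% c("wt", "mut")
  if (any(bad_reaction)) {
    abort(paste0(
      "Unknown `reaction` value(s) (expected wt/mut) at row(s): ",
      paste(raw$row[bad_reaction], collapse = ", ")
    ))
  }
  bad_target <- !raw$target %in% c("allele", "reference")
  if (any(bad_target)) {
    abort(paste0(
      "Unknown `target` value(s) (expected allele/reference) at row(s): ",
      paste(raw$row[bad_target], collapse = ", ")
    ))
  }

  dup <- duplicated(raw[, c("sample_id", "reaction", "target")])
  if (any(dup)) {
    d <- raw[dup, ]
    abort(paste0(
      "Duplicate (sample, reaction, target) row(s): ",
      paste(sprintf("row %d (%s/%s/%s)", d$row, d$sample_id, d$reaction, d$target),
            collapse = ", ")
    ))
  }

  raw$cq_num <- parse_cq(raw$cq, raw$row)

  raw$slot <- paste0(
    "cq_", ifelse(raw$target == "reference", "rp_", ""), raw$reaction
  )
  wide <- tidyr::pivot_wider(
    dplyr::select(raw, "sample_id", "specimen", "slot", "cq_num"),
    names_from = "slot", values_from = "cq_num"
  )
  for (col in c("cq_wt", "cq_mut", "cq_rp_wt", "cq_rp_mut")) {
    if (!col %in% names(wide)) wide[[col]] <- NA_real_
  }
  # preserve order of first appearance
  wide <- wide[match(unique(raw$sample_id), wide$sample_id), ]
  dplyr::select(wide, "sample_id", "specimen", "cq_wt", "cq_mut", "cq_rp_wt", "cq_rp_mut")
}

parse_cq <- function(x, rows) {
  und <- tolower(x) == "undetermined" | x == "NA" | x == ""
  out <- rep(NA_real_, length(x))
  out[und] <- Inf
  num <- suppressWarnings(as.numeric(x[!und]))
  bad <- is.na(num)
  if (any(bad)) {
    abort(paste0(
      "Non-numeric, non-sentinel Cq value(s): ",
      paste(sprintf("row %d (%s)", rows[!und][bad], x[!und][bad]), collapse = ", "),
      ". Accepted sentinels: \"Undetermined\", \"NA\", \"\"."
    ))
  }
  out[!und] <- num
  out
}

#' Write classified results to CSV
#'
#' Emits a stable-schema CSV (`sample_id`, `specimen`, `formula`, `delta_cq`,
#' `percent`, `status`, `warnings`) preceded by `#`-comment metadata lines
#' (schema version, package version, seed and an optional timestamp — off by
#' default so identical runs produce identical files). Percentages are
#' rendered with [format_percent()].
#'
#' @param results A tibble from [classify_results()].
#' @param path Output path.
#' @param seed Seed recorded in the metadata header (optional).
#' @param timestamp Include a timestamp comment (default `FALSE`).
#' @return The path, invisibly.
#' @export
write_results <- function(results, path, seed = NULL, timestamp = FALSE) {
  out <- tibble::tibble(
    sample_id = results$sample_id,
    specimen = results$specimen,
    formula = results$formula,
    delta_cq = ifelse(is.na(results$delta_cq), "", sprintf("%.4f", results$delta_cq)),
    percent = dplyr::coalesce(format_percent(results$percent), ""),
    status = as.character(results$status),
    warnings = dplyr::coalesce(results$warnings, "")
  )
  write_with_header(out, path, seed = seed, timestamp = timestamp)
}

#' Write a validation-analysis report
#'
#' Writes the tidy per-row table of a fitted validation object ([tidy()])
#' as CSV, with the object's one-row summary ([glance()]) folded into
#' `#`-comment header lines — so a probit report carries the detection
#' table with fitted probabilities plus the LOD and its CI, a precision
#' report carries the variance components and CVs, and so on.
#'
#' @param object A `probit_fit`, `precision_result`, `method_comparison`,
#'   `loq_result`, `slope_comparison`, `agreement_result` or
#'   `standard_curve`.
#' @param path Output path.
#' @param seed,timestamp Metadata header options, as in [write_results()].
#' @return The path, invisibly.
#' @export
write_validation_report <- function(object, path, seed = NULL, timestamp = FALSE) {
  g <- glance(object)
  extra <- sprintf("# %s=%s", names(g), vapply(g, format, character(1), digits = 10))
  write_with_header(tidy(object), path, seed = seed, timestamp = timestamp, extra = extra)
}

write_with_header <- function(tab, path, seed = NULL, timestamp = FALSE,
                              extra = character()) {
  header <- c(
    "# schema_version=1",
    sprintf("# asqpcr_version=%s", as.character(packageVersion("asqpcr"))),
    if (!is.null(seed)) sprintf("# seed=%s", seed),
    if (timestamp) sprintf("# written=%s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    extra
  )
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.csv(tab, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write reaction-pair records as a tidy Cq export
#'
#' Inverse of [read_cq_export()]: each record becomes four rows (two
#' reactions by two targets; reference rows are omitted when `NA`).
#' `undetermined` Cqs (`Inf`) are written as `"Undetermined"`.
#'
#' @param records A tibble with `sample_id`, `specimen` and the four Cq
#'   columns (e.g. from [simulate_reaction_pair()]).
#' @param path Output path.
#' @param seed,timestamp Metadata header options, as in [write_results()].
#' @return The path, invisibly.
#' @export
write_cq_export <- function(records, path, seed = NULL, timestamp = FALSE) {
  slots <- tibble::tribble(
    ~col,        ~reaction, ~target,
    "cq_wt",     "wt",      "allele",
    "cq_mut",    "mut",     "allele",
    "cq_rp_wt",  "wt",      "reference",
    "cq_rp_mut", "mut",     "reference"
  )
  long <- purrr::map_dfr(seq_len(nrow(records)), function(i) {
    purrr::map_dfr(seq_len(nrow(slots)), function(s) {
      col <- slots$col[s]
      if (!col %in% names(records) || is.na(records[[col]][i])) return(NULL)
      v <- records[[col]][i]
      tibble::tibble(
        sample_id = records$sample_id[i],
        specimen = if ("specimen" %in% names(records)) records$specimen[i] else "other",
        reaction = slots$reaction[s],
        target = slots$target[s],
        cq = if (is.infinite(v)) "Undetermined" else sprintf("%.4f", v)
      )
    })
  })
  write_with_header(long, path, seed = seed, timestamp = timestamp)
}
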