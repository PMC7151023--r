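#' Configuration of the mechanistic AS-qPCR simulator
#'
#' The simulator mirrors the physical structure of the assay. A reaction pair
#' draws `m ~ Binomial(N, p)` mutant alleles among the `N` genome equivalents
#' of the shared DNA extract (`m = N * p` when `sampling = "deterministic"`).
#' Each allele-specific reaction sees its own allele plus the wrong allele
#' attenuated by `2^-crosstalk_delta` (the delayed primer extension on the
#' mismatched template), and a template of `T` copies amplifying with
#' efficiency `E` crosses threshold at
#' `Cq = c0 - log(T) / log(1 + E) + noise`, where `c0` is the Cq of a single
#' copy and the noise is Gaussian on the cycle scale. Reactions with no
#' template, or whose Cq falls beyond `total_cycles`, report `undetermined`
#' (`Inf`). RNase P amplifies the total `N` copies with efficiency 1 from its
#' own single-copy Cq.
#'
#' @param true_mutant_fraction True mutant-allele fraction `p` in `[0, 1]`.
#' @param total_allele_copies Genome equivalents per reaction `N`
#'   (default 7576: a 25 ng DNA input at 0.0033 ng per haploid genome).
#' @param efficiency_wt,efficiency_mut Amplification efficiencies of the two
#'   allele-specific reactions (fractions; default 1 = perfect doubling).
#' @param single_copy_cq Cq at which a single JAK2 template copy would cross
#'   threshold (default 42).
#' @param rp_single_copy_cq Single-copy Cq of the RNase P reference
#'   (default 38; with the default `N` this puts RNase P near Cq 25).
#' @param noise_sd SD of the Gaussian Cq noise, cycles (default 0.15).
#' @param crosstalk_delta Cycle delay of wrong-allele amplification
#'   (default 18; `Inf` = perfectly allele-specific primers).
#' @param total_cycles Run length; later signals are censored to
#'   `undetermined` (default 45).
#' @param sampling `"stochastic"` (binomial allele sampling) or
#'   `"deterministic"` (expected counts; noise still applies unless
#'   `noise_sd = 0`).
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @return An object of class `sim_config` (a named list).
#' @examples
#' sim_config(0.1, seed = 1)
#' @export
sim_config <- function(true_mutant_fraction,
                       total_allele_copies = 7576,
                       efficiency_wt = 1, efficiency_mut = 1,
                       single_copy_cq = 42, rp_single_copy_cq = 38,
                       noise_sd = 0.15, crosstalk_delta = 18,
                       total_cycles = 45,
                       sampling = c("stochastic", "deterministic"),
                       seed = NULL) {
  sampling <- match.arg(sampling)
  stopifnot(
    true_mutant_fraction >= 0, true_mutant_fraction <= 1,
    total_allele_copies >= 1,
    efficiency_wt > 0, efficiency_mut > 0,
    noise_sd >= 0, crosstalk_delta > 0,
    single_copy_cq > 0, total_cycles > 0
  )
  structure(
    list(
      true_mutant_fraction = true_mutant_fraction,
      total_allele_copies = total_allele_copies,
      efficiency_wt = efficiency_wt, efficiency_mut = efficiency_mut,
      single_copy_cq = single_copy_cq, rp_single_copy_cq = rp_single_copy_cq,
      noise_sd = noise_sd, crosstalk_delta = crosstalk_delta,
      total_cycles = total_cycles, sampling = sampling, seed = seed
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  p = %g, N = %g, E(wt/mut) = %g/%g, c0 = %g, noise SD = %g, crosstalk +%g cycles, %s sampling\n",
    x$true_mutant_fraction, x$total_allele_copies, x$efficiency_wt,
    x$efficiency_mut, x$single_copy_cq, x$noise_sd, x$crosstalk_delta, x$sampling
  ))
  invisible(x)
}

# Cq of a template amplifying with efficiency E; Inf when empty or censored.
cq_from_template <- function(template, efficiency, c0, noise, total_cycles) {
  if (template <= 0) return(Inf)
  cq <- c0 - log(template) / log(1 + efficiency) + noise
  if (cq > total_cycles) Inf else cq
}

# One reaction pair given the current RNG state. Draw order (fixed contract):
# allele count, then noise for cq_wt, cq_mut, cq_rp_wt, cq_rp_mut.
sim_pair_draws <- function(cfg, n_copies = cfg$total_allele_copies,
                           p = cfg$true_mutant_fraction) {
  if (cfg$sampling == "stochastic") {
    m <- if (n_copies >= 1) rbinom(1, floor(n_copies), p) else 0
    w <- floor(n_copies) - m
  } else {
    m <- n_copies * p
    w <- n_copies - m
  }
  eps <- rnorm(4, 0, cfg$noise_sd)
  xt <- 2^(-cfg$crosstalk_delta)
  t_wt <- w + m * xt
  t_mut <- m + w * xt
  tibble::tibble(
    cq_wt = cq_from_template(t_wt, cfg$efficiency_wt, cfg$single_copy_cq,
                             eps[1], cfg$total_cycles),
    cq_mut = cq_from_template(t_mut, cfg$efficiency_mut, cfg$single_copy_cq,
                              eps[2], cfg$total_cycles),
    cq_rp_wt = cq_from_template(n_copies, 1, cfg$rp_single_copy_cq,
                                eps[3], cfg$total_cycles),
    cq_rp_mut = cq_from_template(n_copies, 1, cfg$rp_single_copy_cq,
                                 eps[4], cfg$total_cycles)
  )
}

#' Simulate AS-qPCR reaction pairs
#'
#' Generates `n` independent reaction-pair records (each an independent
#' aliquot of the configured sample) under the model described in
#' [sim_config()]. Identical configurations with the same seed give
#' identical output.
#'
#' @param config A [sim_config()].
#' @param n Number of reaction pairs (default 1).
#' @param specimen Specimen label stored in the records (default "other").
#' @param sample_prefix Prefix for the generated `sample_id`s.
#' @return A tibble with columns `sample_id`, `specimen`, `true_fraction`,
#'   `cq_wt`, `cq_mut`, `cq_rp_wt`, `cq_rp_mut` (`Inf` = undetermined).
#' @examples
#' ideal <- sim_config(0.1, sampling = "deterministic", noise_sd = 0,
#'                     crosstalk_delta = Inf)
#' rec <- simulate_reaction_pair(ideal)
#' mutant_percent_simple(rec$cq_wt, rec$cq_mut)  # exactly 10
#' @export
simulate_reaction_pair <- function(config, n = 1, specimen = "other",
                                   sample_prefix = "sim") {
  stopifnot(inherits(config, "sim_config"), n >= 1)
  if (!is.null(config$seed)) set.seed(config$seed)
  out <- purrr::map_dfr(seq_len(n), function(i) sim_pair_draws(config))
  dplyr::bind_cols(
    tibble::tibble(
      sample_id = sprintf("%s_%02d", sample_prefix, seq_len(n)),
      specimen = specimen,
      true_fraction = config$true_mutant_fraction
    ),
    out
  )
}

#' Simulate a serial-dilution series
#'
#' Rescales the template copy number by each dilution factor while keeping
#' the mutant fraction fixed, producing the input for
#' [fit_standard_curve()] and [compare_slopes()]. Dilutions below one copy
#' are emitted as records whose reactions fail to amplify (`undetermined`)
#' rather than as errors.
#'
#' @param config A [sim_config()].
#' @param dilution_factors Relative concentrations, strictly decreasing from
#'   1 (e.g. `c(1, 0.1, 0.01)`).
#' @param replicates Reaction pairs per dilution point (default 1).
#' @return A tibble with `rel_conc`, `log10_conc`, `replicate` and the
#'   reaction-pair Cq columns.
#' @examples
#' cfg <- sim_config(0.5, sampling = "deterministic", noise_sd = 0,
#'                   crosstalk_delta = Inf)
#' d <- simulate_dilution_series(cfg, c(1, 0.1, 0.01))
#' fit_standard_curve(d, log10_conc, cq_wt)$efficiency  # 1 (100%)
#' @export
simulate_dilution_series <- function(config, dilution_factors = c(1, 0.1, 0.01),
                                     replicates = 1) {
  stopifnot(inherits(config, "sim_config"))
  f <- dilution_factors
  if (any(f <= 0) || any(diff(f) >= 0) || f[1] > 1) {
    abort("`dilution_factors` must be positive, strictly decreasing, and start at <= 1.")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  purrr::map_dfr(f, function(fac) {
    purrr::map_dfr(seq_len(replicates), function(r) {
      n_copies <- config$total_allele_copies * fac
      dplyr::bind_cols(
        tibble::tibble(rel_conc = fac, log10_conc = log10(fac), replicate = r),
        sim_pair_draws(config, n_copies = n_copies)
      )
    })
  })
}

#' Simulate a limit-of-detection panel
#'
#' For each mutant fraction, simulates replicate reaction pairs and counts
#' how many are called detected. Because a LOD experiment is what
#' *establishes* the assay's detection limit, the detection call here is
#' amplification-based — the mutant reaction crossed threshold below the Cq
#' cutoff — implemented by classifying with the policy's percent thresholds
#' disabled and counting records not called `not_detected`.
#'
#' @param config A [sim_config()]; its `true_mutant_fraction` is overridden
#'   per level.
#' @param fractions Mutant-allele fractions (proportions in (0, 1), strictly
#'   decreasing), e.g. `0.0116 * 2^-(0:7)`.
#' @param replicates Replicates per level (default 9).
#' @param policy A [qc_policy()]; only the Cq cutoff and run length are used.
#' @return A [detection_table()] with `level_percent = 100 * fractions`.
#' @examples
#' cfg <- sim_config(0, seed = 7)
#' panel <- simulate_lod_panel(cfg, 0.0116 * 2^-(0:7), replicates = 9)
#' @export
simulate_lod_panel <- function(config, fractions, replicates = 9,
                               policy = qc_policy()) {
  stopifnot(inherits(config, "sim_config"), replicates >= 1)
  if (any(fractions <= 0) || any(fractions >= 1) || any(diff(fractions) >= 0)) {
    abort("`fractions` must be proportions in (0, 1), strictly decreasing.")
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  panel_policy <- qc_policy(
    cq_cutoff = policy$cq_cutoff, total_cycles = policy$total_cycles,
    lod_percent = 1e-9, loq_percent = 1e-9,
    rp_delta_warn = policy$rp_delta_warn, rp_max_cq = policy$rp_max_cq
  )
  counts <- purrr::map_int(fractions, function(p) {
    recs <- purrr::map_dfr(seq_len(replicates), function(r) {
      dplyr::bind_cols(
        tibble::tibble(sample_id = sprintf("p%g_r%d", p, r)),
        sim_pair_draws(config, p = p)
      )
    })
    res <- suppressWarnings(classify_results(recs, panel_policy, formula = "simple"))
    sum(res$status != "not_detected")
  })
  detection_table(100 * fractions, replicates, counts)
}

#' Simulate a paired whole-blood / serum cohort
#'
#' Emulates a paired-specimen comparison in which serum carries a modestly
#' enriched mutant fraction relative to whole blood. The enrichment is a
#' shift on the log-odds scale: `p_serum = plogis(qlogis(p) + logit_shift)`,
#' so it vanishes at 0% and 100% and is largest mid-range. Each subject
#' contributes one blood and one serum reaction pair drawn from the same
#' configuration.
#'
#' @param cohort A data frame with columns `subject_id` and `blood_fraction`
#'   (proportions in `[0, 1]`); an optional `logit_shift` column overrides
#'   the global shift per subject. See [example_paired_cohort()].
#' @param config A [sim_config()] providing the shared reaction parameters
#'   (its `true_mutant_fraction` and `seed` are ignored).
#' @param logit_shift Serum enrichment on the log-odds scale (default 0.25).
#' @param seed Integer seed for the whole cohort (subjects in row order,
#'   blood pair before serum pair within a subject).
#' @return A tibble of reaction-pair records with `subject_id`, `specimen`
#'   (`whole_blood` / `serum`) and `true_fraction` columns, ready for
#'   [classify_results()] / [summarise_paired_cohort()].
#' @examples
#' cohort <- example_paired_cohort(n_negative = 2, n_low = 2, n_high = 2)
#' sims <- simulate_paired_specimens(cohort, seed = 1)
#' @export
simulate_paired_specimens <- function(cohort, config = sim_config(0),
                                      logit_shift = 0.25, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  req <- c("subject_id", "blood_fraction")
  if (!all(req %in% names(cohort))) {
    abort(paste0("`cohort` needs columns: ", paste(req, collapse = ", ")))
  }
  if (any(cohort$blood_fraction < 0 | cohort$blood_fraction > 1)) {
    abort("`blood_fraction` must lie in [0, 1].")
  }
  shifts <- if ("logit_shift" %in% names(cohort)) cohort$logit_shift else
    rep(logit_shift, nrow(cohort))
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(seq_len(nrow(cohort)), function(i) {
    p_blood <- cohort$blood_fraction[i]
    p_serum <- serum_fraction(p_blood, shifts[i])
    purrr::map_dfr(
      list(c("whole_blood", p_blood), c("serum", p_serum)),
      function(sp) {
        p <- as.numeric(sp[2])
        dplyr::bind_cols(
          tibble::tibble(
            subject_id = cohort$subject_id[i],
            sample_id = paste(cohort$subject_id[i], sp[1], sep = "_"),
            specimen = sp[1],
            true_fraction = p
          ),
          sim_pair_draws(config, p = p)
        )
      }
    )
  })
}

#' Serum mutant fraction implied by a log-odds enrichment
#'
#' @param blood_fraction Blood mutant fraction in `[0, 1]`.
#' @param logit_shift Log-odds shift (default 0.25).
#' @return The serum fraction; equal to the blood fraction at 0 and 1.
#' @examples
#' serum_fraction(0.5, 0.3)  # 0.5744
#' @export
serum_fraction <- function(blood_fraction, logit_shift = 0.25) {
  ifelse(
    blood_fraction <= 0 | blood_fraction >= 1,
    blood_fraction,
    stats::plogis(stats::qlogis(blood_fraction) + logit_shift)
  )
}

#' Example paired-specimen cohort layout
#'
#' A fixed cohort emulating a clinical paired blood/serum series: negatives,
#' a low-burden stratum below 20% mutant allele and a higher-burden stratum
#' above it (defaults 60/15/20, the composition of a typical screening
#' cohort of 95 subjects). Fractions are evenly spaced grids, so the layout
#' is deterministic.
#'
#' @param n_negative,n_low,n_high Subjects per stratum.
#' @param low_range,high_range Fraction ranges of the two positive strata.
#' @return A tibble with `subject_id` and `blood_fraction`.
#' @examples
#' example_paired_cohort()
#' @export
example_paired_cohort <- function(n_negative = 60, n_low = 15, n_high = 20,
                                  low_range = c(0.02, 0.19),
                                  high_range = c(0.21, 0.94)) {
  fractions <- c(
    rep(0, n_negative),
    if (n_low > 0) seq(low_range[1], low_range[2], length.out = n_low),
    if (n_high > 0) seq(high_range[1], high_range[2], length.out = n_high)
  )
  tibble::tibble(
    subject_id = sprintf("subj_%03d", seq_along(fractions)),
    blood_fraction = fractions
  )
}

#' Summarise a simulated paired cohort into reference/test percentages
#'
#' Classifies every record of a [simulate_paired_specimens()] table and
#' pivots the cohort into one row per subject with the whole-blood
#' (reference) and serum (test) results side by side, ready for
#' [method_comparison()] and [qualitative_agreement()].
#'
#' @param records Output of [simulate_paired_specimens()].
#' @param policy A [qc_policy()].
#' @param formula Passed to [classify_results()].
#' @return A tibble with `subject_id`, `reference` / `test` percentages
#'   (`NA` when not quantified), and `reference_detected` / `test_detected`
#'   logical calls.
#' @export
summarise_paired_cohort <- function(records, policy = qc_policy(),
                                    formula = "auto") {
  res <- suppressWarnings(classify_results(records, policy, formula))
  res$subject_id <- records$subject_id
  res$detected <- res$status %in% c("detected_below_loq", "quantified")
  wide <- tidyr::pivot_wider(
    dplyr::select(res, "subject_id", "specimen", "percent", "detected"),
    names_from = "specimen", values_from = c("percent", "detected")
  )
  tibble::tibble(
    subject_id = wide$subject_id,
    reference = wide$percent_whole_blood,
    test = wide$percent_serum,
    reference_detected = wide$detected_whole_blood,
    test_detected = wide$detected_serum
  )
}
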