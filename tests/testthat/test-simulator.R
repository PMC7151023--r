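test_that("ideal deterministic settings recover the true fraction exactly", {
  for (p in c(0.001, 0.05, 0.1, 0.5, 0.9, 0.999)) {
    cfg <- sim_config(p, sampling = "deterministic", noise_sd = 0,
                      crosstalk_delta = Inf)
    r <- simulate_reaction_pair(cfg)
    expect_equal(mutant_percent_simple(r$cq_wt, r$cq_mut), 100 * p,
                 tolerance = 1e-9)
    # the RNase P-corrected estimate agrees (both tubes see the same N)
    expect_equal(
      mutant_percent_corrected(r$cq_wt, r$cq_mut, r$cq_rp_wt, r$cq_rp_mut),
      100 * p, tolerance = 1e-9
    )
  }
})

test_that("a symmetric sample yields equal Cqs and 50%", {
  cfg <- sim_config(0.5, sampling = "deterministic", noise_sd = 0,
                    crosstalk_delta = Inf)
  r <- simulate_reaction_pair(cfg)
  expect_equal(r$cq_wt, r$cq_mut)
  expect_equal(mutant_percent_simple(r$cq_wt, r$cq_mut), 50)
})

test_that("crosstalk alone creates the predicted false signal on a negative sample", {
  cfg <- sim_config(0, sampling = "deterministic", noise_sd = 0,
                    crosstalk_delta = 10)
  r <- simulate_reaction_pair(cfg)
  expect_true(is.finite(r$cq_mut))
  expect_equal(mutant_percent_simple(r$cq_wt, r$cq_mut), 100 / (2^10 + 1),
               tolerance = 1e-9)
  expect_equal(mutant_percent_simple(r$cq_wt, r$cq_mut), 0.0976, tolerance = 1e-3)

  # with the default 18-cycle delay the wrong-allele signal is censored
  cfg2 <- sim_config(0, sampling = "deterministic", noise_sd = 0)
  r2 <- simulate_reaction_pair(cfg2)
  expect_true(is.infinite(r2$cq_mut))
  # and perfectly specific primers never amplify the wrong allele
  cfg3 <- sim_config(0, crosstalk_delta = Inf, seed = 1)
  r3 <- simulate_reaction_pair(cfg3, n = 5)
  expect_true(all(is.infinite(r3$cq_mut)))
})

test_that("efficiency mismatch biases the estimate away from truth as theory predicts", {
  est <- function(p, E) {
    cfg <- sim_config(p, sampling = "deterministic", noise_sd = 0,
                      crosstalk_delta = Inf, efficiency_wt = E, efficiency_mut = E)
    r <- simulate_reaction_pair(cfg)
    mutant_percent_simple(r$cq_wt, r$cq_mut)
  }
  # shared E < 1 stretches delta Cq: overestimates above 50%, underestimates below
  for (p in c(0.6, 0.75, 0.9)) {
    expect_gt(est(p, 0.9), 100 * p)
    expect_lt(est(1 - p, 0.9), 100 * (1 - p))
    expect_lt(est(p, 1.1), 100 * p)
  }
  # error grows with |E - 1| at fixed p, and with |logit p| at fixed E
  errs_E <- sapply(c(1, 0.95, 0.9, 0.85), function(E) abs(est(0.75, E) - 75))
  expect_true(all(diff(errs_E) > 0))
  # on the log-odds scale the distortion is linear in logit p, so the
  # recovery error grows with |logit p| at fixed E
  ps <- c(0.55, 0.7, 0.85, 0.95)
  errs_p <- mapply(function(p) abs(qlogis(est(p, 0.9) / 100) - qlogis(p)), ps)
  expect_true(all(diff(errs_p) > 0))
  # at p = 0.5 there is no bias regardless of shared efficiency
  expect_equal(est(0.5, 0.85), 50, tolerance = 1e-9)
})

test_that("crosstalk inflates low fractions but is negligible mid-range", {
  est <- function(p, delta) {
    cfg <- sim_config(p, sampling = "deterministic", noise_sd = 0,
                      crosstalk_delta = delta)
    r <- simulate_reaction_pair(cfg)
    mutant_percent_simple(r$cq_wt, r$cq_mut)
  }
  for (delta in c(8, 10, 12)) {
    expect_gt(est(0.001, delta), 0.1)            # inflated at low p
    rel_err_mid <- abs(est(0.5, delta) - 50) / 50
    expect_lt(rel_err_mid, 2 * 2^(-delta))       # negligible at 50%
  }
  expect_gt(est(0.001, 8), est(0.001, 12))       # worse with shorter delay
})

test_that("identical seeds give bit-identical simulations", {
  cfg <- sim_config(0.2, seed = 123)
  expect_identical(simulate_reaction_pair(cfg, n = 10),
                   simulate_reaction_pair(cfg, n = 10))
  expect_identical(simulate_dilution_series(cfg, c(1, 0.5, 0.25), replicates = 3),
                   simulate_dilution_series(cfg, c(1, 0.5, 0.25), replicates = 3))
  expect_identical(simulate_lod_panel(cfg, 0.0116 * 2^-(0:4), replicates = 5),
                   simulate_lod_panel(cfg, 0.0116 * 2^-(0:4), replicates = 5))
  cohort <- example_paired_cohort(n_negative = 3, n_low = 3, n_high = 3)
  expect_identical(simulate_paired_specimens(cohort, seed = 9),
                   simulate_paired_specimens(cohort, seed = 9))
})

test_that("noiseless dilution series yields the closed-form slope", {
  cfg <- sim_config(0.5, sampling = "deterministic", noise_sd = 0,
                    crosstalk_delta = Inf)
  d <- simulate_dilution_series(cfg, c(1, 0.1, 0.01))
  fit <- fit_standard_curve(d, log10_conc, cq_mut)
  expect_equal(fit$slope, -log(10) / log(2), tolerance = 1e-9)
  expect_equal(fit$efficiency, 1, tolerance = 1e-9)
})

test_that("dilution below one template copy censors rather than errors", {
  cfg <- sim_config(0.5, total_allele_copies = 10, seed = 3)
  d <- simulate_dilution_series(cfg, c(1, 0.01))
  expect_equal(nrow(d), 2)
  expect_true(is.infinite(d$cq_wt[2]) && is.infinite(d$cq_mut[2]))
})

test_that("detection panels are monotone and saturate far above the LOD", {
  cfg <- sim_config(0, seed = 21)
  panel <- simulate_lod_panel(cfg, 0.0116 * 2^-(0:7), replicates = 9)
  expect_s3_class(panel, "detection_table")
  expect_true(all(diff(panel$n_detected) <= 0))
  # far above the LOD every replicate is detected
  high <- simulate_lod_panel(sim_config(0, seed = 22), c(0.5, 0.25), replicates = 6)
  expect_equal(high$n_detected, c(6, 6))
})

test_that("paired-specimen truths follow the logit-shift model", {
  expect_equal(serum_fraction(0.5, 0.3), plogis(0.3), tolerance = 1e-12)
  expect_equal(serum_fraction(0.5, 0.3), 0.5744, tolerance = 1e-4)
  expect_equal(serum_fraction(0, 0.3), 0)
  expect_equal(serum_fraction(1, 0.3), 1)

  cohort <- example_paired_cohort(n_negative = 2, n_low = 2, n_high = 2)
  sims0 <- simulate_paired_specimens(cohort, logit_shift = 0, seed = 4)
  truths <- tidyr::pivot_wider(
    dplyr::distinct(sims0, subject_id, specimen, true_fraction),
    names_from = specimen, values_from = true_fraction
  )
  expect_equal(truths$serum, truths$whole_blood)
})

test_that("an all-negative cohort gives 100% negative agreement", {
  cohort <- tibble::tibble(subject_id = sprintf("n%02d", 1:8), blood_fraction = 0)
  sims <- simulate_paired_specimens(
    cohort, config = sim_config(0, crosstalk_delta = Inf), seed = 5
  )
  paired <- summarise_paired_cohort(sims)
  agr <- qualitative_agreement(paired, reference = reference_detected,
                               test = test_detected)
  expect_equal(agr$negative_agreement, 100)
  expect_equal(agr$counts$tn, 8)
})
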