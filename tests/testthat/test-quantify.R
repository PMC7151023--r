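test_that("simple comparative-Cq formula matches hand-evaluated cases", {
  expect_equal(mutant_percent_simple(30, 30), 50)
  expect_equal(mutant_percent_simple(31, 30), 100 / (2^-1 + 1), tolerance = 1e-12)
  expect_equal(mutant_percent_simple(31, 30), 66.6667, tolerance = 1e-4)
  # a Cq-42 mutant signal against an early wild type: vanishing fraction
  expect_equal(mutant_percent_simple(26, 42), 100 / (2^16 + 1), tolerance = 1e-12)
  expect_equal(mutant_percent_simple(26, 42), 0.001526, tolerance = 1e-3)
})

test_that("simple formula is symmetric, bounded and monotone in delta Cq", {
  set.seed(1)
  a <- runif(200, 15, 45)
  b <- runif(200, 15, 45)
  expect_equal(mutant_percent_simple(a, b) + mutant_percent_simple(b, a),
               rep(100, 200), tolerance = 1e-9)
  p <- mutant_percent_simple(a, b)
  expect_true(all(p > 0 & p < 100))
  ord <- order(a - b)
  expect_true(all(diff(p[ord]) > 0))
})

test_that("corrected formula matches hand cases and reduces to the simple one", {
  expect_equal(mutant_percent_corrected(30, 30, 25, 25), 50)
  expect_equal(mutant_percent_corrected(30, 30, 25, 26), 100 / (2^-1 + 1),
               tolerance = 1e-12)
  set.seed(2)
  for (i in 1:50) {
    cqw <- runif(1, 20, 40); cqm <- runif(1, 20, 40); rp <- runif(1, 20, 30)
    expect_equal(
      mutant_percent_corrected(cqw, cqm, rp, rp),
      mutant_percent_simple(cqw, cqm),
      tolerance = 1e-12
    )
  }
})

test_that("formula recovers the exact allele fraction from ideal copy-count Cqs", {
  # derivation check: with Cq = c0 - log2(copies), the comparative-Cq
  # estimate equals the direct fraction 100 * M / (M + W)
  set.seed(3)
  for (i in 1:50) {
    m <- runif(1, 1, 1e6); w <- runif(1, 1, 1e6)
    expect_equal(
      mutant_percent_simple(ideal_cq(w), ideal_cq(m)),
      100 * m / (m + w),
      tolerance = 1e-9
    )
  }
})

test_that("undetermined Cqs are rejected by the bare formulas", {
  expect_error(mutant_percent_simple(Inf, 30), "undetermined")
  expect_error(mutant_percent_corrected(30, 30, Inf, 25), "undetermined")
})

test_that("classification applies cutoff, LOD and LOQ buckets", {
  cqs <- tibble::tibble(
    sample_id = c("neg_undet", "neg_cutoff", "at_cutoff", "below_loq", "quant", "below_lod"),
    cq_wt = c(27, 26, 26, 30, 30, 30),
    cq_mut = c(Inf, 43, 42, 37.64, 31, 40.5)
  )
  res <- classify_results(cqs, formula = "simple")
  expect_s3_class(res, "tbl_df")
  expect_equal(as.character(res$status),
               c("not_detected", "not_detected", "not_detected",
                 "detected_below_loq", "quantified", "not_detected"))
  # percent present iff detected_below_loq or quantified
  expect_true(all(is.na(res$percent[res$status == "not_detected"])))
  expect_false(anyNA(res$percent[res$status != "not_detected"]))
  expect_equal(res$percent[res$sample_id == "below_loq"], 100 / (2^7.64 + 1),
               tolerance = 1e-6)
})

test_that("a failed wild-type reaction is an invalid sample, not a negative", {
  cqs <- tibble::tibble(sample_id = "x", cq_wt = Inf, cq_mut = 30)
  expect_error(classify_results(cqs), "Invalid sample")
})

test_that("forcing the corrected formula without RNase P flags invalid_no_reference", {
  cqs <- tibble::tibble(sample_id = c("a", "b"),
                        cq_wt = c(30, 30), cq_mut = c(31, 31),
                        cq_rp_wt = c(25, NA), cq_rp_mut = c(25, NA))
  res <- classify_results(cqs, formula = "rnasep_corrected")
  expect_equal(as.character(res$status), c("quantified", "invalid_no_reference"))
  expect_true(is.na(res$percent[2]))
  # auto falls back to the simple formula instead
  res_auto <- classify_results(cqs, formula = "auto")
  expect_equal(res_auto$formula, c("rnasep_corrected", "simple"))
  expect_equal(as.character(res_auto$status), c("quantified", "quantified"))
})

test_that("RNase P imbalance and high reference Cq raise QC warnings", {
  cqs <- tibble::tibble(sample_id = c("imbalanced", "late_rp"),
                        cq_wt = c(30, 30), cq_mut = c(31, 31),
                        cq_rp_wt = c(25, 31), cq_rp_mut = c(26.6, 31.2))
  expect_warning(res <- classify_results(cqs), "QC flag")
  expect_match(res$warnings[1], "rp_delta=1.60")
  expect_match(res$warnings[2], "rp_high_cq")
})

test_that("Cq exactly at the cutoff is treated as unspecific (configurable)", {
  cqs <- tibble::tibble(sample_id = "s", cq_wt = 33, cq_mut = 42)
  expect_equal(as.character(classify_results(cqs)$status), "not_detected")
  lax <- qc_policy(cq_cutoff = 43)
  expect_equal(as.character(classify_results(cqs, lax)$status), "detected_below_loq")
})

test_that("standard-curve inversion recovers copies from Cq", {
  rp <- standard_curve(slope = -3.26, intercept = 29.75)
  expect_equal(copies_from_cq(29.75, rp), 1)
  expect_equal(copies_from_cq(23.23, rp), 100, tolerance = 1e-9)
  expect_equal(copies_from_cq(10.19, rp), 1e6, tolerance = 1e-9)
  # inversion is the identity on copies for any valid curve
  set.seed(4)
  for (i in 1:20) {
    curve <- standard_curve(runif(1, -4, -3), runif(1, 25, 40))
    copies <- 10^runif(1, 0, 7)
    cq <- curve$slope * log10(copies) + curve$intercept
    expect_equal(copies_from_cq(cq, curve), copies, tolerance = 1e-9)
  }
})

test_that("copy counts convert to ng/uL by mass, strandedness and volume", {
  expect_equal(dna_concentration_from_copies(0), 0)
  expect_equal(dna_concentration_from_copies(1000), 0.33)
  expect_equal(dna_concentration_from_copies(7575.8), 2.5, tolerance = 1e-4)
  expect_error(dna_concentration_from_copies(-1), "non-negative")
})

test_that("percent rendering keeps 2 decimals above 1% and 4 significant digits below", {
  expect_equal(format_percent(c(52.4638, 1, 0.5012345, NA)),
               c("52.46", "1.00", "0.5012", NA))
  expect_equal(format_percent(0.0015258), "0.001526")
})
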