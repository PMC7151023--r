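test_that("summary t-test matches direct computation", {
  res <- one_sample_t_from_summary(1.16, 0.25, 9, 1.16)
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)

  res2 <- one_sample_t_from_summary(1.03, 0.25, 9, 1.16)
  expect_equal(res2$t, (1.03 - 1.16) / (0.25 / 3), tolerance = 1e-12)
  expect_equal(res2$t, -1.56, tolerance = 1e-2)
  expect_equal(res2$p_value, 0.157, tolerance = 1e-2)

  res3 <- one_sample_t_from_summary(0.19, 0.06, 9, 0.58)
  expect_lt(res3$p_value, 1e-4)
})

test_that("zero-SD summaries degenerate cleanly", {
  expect_equal(one_sample_t_from_summary(1, 0, 5, 1)$p_value, 1)
  expect_equal(one_sample_t_from_summary(1.2, 0, 5, 1)$p_value, 0)
})

test_that("LOQ from the printed accuracy summaries is the highest level", {
  printed <- tibble::tibble(
    level_percent = c(1.16, 0.58, 0.29, 0.15),
    mean = c(1.03, 0.19, 0.048, 0.0098),
    sd = c(0.25, 0.06, 0.037, 0.0053),
    n = 9,
    n_detected = c(9, 9, 8, 8)
  )
  res <- loq_assessment(printed)
  expect_true(res$defined)
  expect_equal(res$loq, 1.16)
  expect_equal(res$table$pass, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("unbiased levels push the LOQ to the lowest level; none passing leaves it undefined", {
  perfect <- tibble::tibble(
    level_percent = c(1.16, 0.58, 0.29),
    mean = c(1.16, 0.58, 0.29), sd = 0.01, n = 9
  )
  expect_equal(loq_assessment(perfect)$loq, 0.29)

  hopeless <- tibble::tibble(
    level_percent = c(1.16, 0.58),
    mean = c(0.2, 0.05), sd = c(0.05, 0.01), n = 9
  )
  res <- loq_assessment(hopeless)
  expect_false(res$defined)
  expect_true(is.na(res$loq))
})

test_that("replicate-layout input aggregates and applies the detection rule", {
  set.seed(6)
  reps <- tidyr::crossing(level_percent = c(1.16, 0.58), rep = 1:9)
  reps$observed_percent <- reps$level_percent + rnorm(18, 0, 0.02)
  # knock out 3 of 9 replicates at the lower level: fails the >= 8/9 rule
  reps$observed_percent[reps$level_percent == 0.58][1:3] <- NA
  res <- loq_assessment(dplyr::select(reps, level_percent, observed_percent))
  expect_equal(res$table$n_detected, c(9, 6))
  expect_equal(res$table$detection_ok, c(TRUE, FALSE))
  expect_equal(res$loq, 1.16)
})

test_that("precision components match the hand-computed ANOVA example", {
  d <- tibble::tibble(day = rep(1:2, each = 2), replicate = rep(1:2, 2),
                      percent = c(10, 12, 14, 16))
  res <- precision_analysis(d)
  expect_equal(res$mean, 13)
  expect_equal(res$cv_within_run, 100 * sqrt(2) / 13, tolerance = 1e-9)
  expect_equal(res$cv_between_day, 100 * sqrt(7) / 13, tolerance = 1e-9)
  expect_equal(res$cv_total, 100 * sqrt(9) / 13, tolerance = 1e-9)
  expect_equal(res$cv_within_run, 10.88, tolerance = 1e-2)
  expect_equal(res$cv_between_day, 20.35, tolerance = 1e-2)
  expect_equal(res$cv_total, 23.08, tolerance = 1e-2)
})

test_that("identical measurements give zero CVs", {
  d <- tidyr::crossing(day = 1:9, replicate = 1:2)
  d$percent <- 54.1
  res <- precision_analysis(d)
  expect_equal(res$cv_total, 0)
  expect_equal(res$cv_between_day, 0)
  expect_equal(res$cv_within_run, 0)
})

test_that("variance components equal the definitional two-pass oracle on random designs", {
  set.seed(7)
  for (i in 1:20) {
    k <- sample(3:9, 1); r <- sample(2:4, 1)
    d <- tidyr::crossing(day = 1:k, replicate = 1:r)
    day_eff <- rnorm(k, 0, runif(1, 0, 3))
    d$percent <- 50 + day_eff[d$day] + rnorm(k * r, 0, runif(1, 0.2, 2))
    res <- precision_analysis(d)
    oracle <- brute_variance_components(d$day, d$percent)
    expect_equal(res$mean, oracle$mean, tolerance = 1e-9)
    expect_equal(res$cv_within_run, oracle$cv_within, tolerance = 1e-9)
    expect_equal(res$cv_between_day, oracle$cv_between, tolerance = 1e-9)
    expect_equal(res$cv_total, oracle$cv_total, tolerance = 1e-9)
  }
})

test_that("known generating variances are recovered with many days", {
  set.seed(8)
  k <- 200; r <- 3
  sigma_day <- 2; sigma_rep <- 1
  d <- tidyr::crossing(day = 1:k, replicate = 1:r)
  day_eff <- rnorm(k, 0, sigma_day)
  d$percent <- 50 + day_eff[d$day] + rnorm(k * r, 0, sigma_rep)
  res <- precision_analysis(d)
  expect_equal(res$cv_within_run, 100 * sigma_rep / 50, tolerance = 0.1)
  expect_equal(res$cv_between_day, 100 * sigma_day / 50, tolerance = 0.1)
})

test_that("unbalanced or undersized precision designs are rejected", {
  bad <- tibble::tibble(day = c(1, 1, 2), replicate = c(1, 2, 1),
                        percent = c(10, 11, 12))
  expect_error(precision_analysis(bad), "balanced")
  one_day <- tibble::tibble(day = 1, replicate = 1:3, percent = c(1, 2, 3))
  expect_error(precision_analysis(one_day), "2 days")
})
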