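# Independent oracles used to cross-check the implementation. These never
# call the code paths they verify.

# Ideal amplification: a template of `copies` crosses threshold at
# c0 - log2(copies) under perfect doubling.
ideal_cq <- function(copies, c0 = 42) c0 - log2(copies)

# Brute-force probit MLE by iterative grid search over (intercept, slope),
# maximizing the binomial log-likelihood on the linear percent dose scale.
grid_probit_lod <- function(tab, target = 0.95, rounds = 6) {
  loglik <- function(a, b) {
    p <- pnorm(a + b * tab$level_percent)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    sum(tab$n_detected * log(p) + (tab$n_tested - tab$n_detected) * log(1 - p))
  }
  a_rng <- c(-50, 10)
  b_rng <- c(0.01, 400)
  for (r in seq_len(rounds)) {
    a_grid <- seq(a_rng[1], a_rng[2], length.out = 61)
    b_grid <- seq(b_rng[1], b_rng[2], length.out = 61)
    ll <- outer(a_grid, b_grid, Vectorize(loglik))
    idx <- arrayInd(which.max(ll), dim(ll))
    a_best <- a_grid[idx[1]]; b_best <- b_grid[idx[2]]
    a_step <- diff(a_rng) / 60; b_step <- diff(b_rng) / 60
    a_rng <- a_best + c(-2, 2) * a_step
    b_rng <- pmax(b_best + c(-2, 2) * b_step, 1e-4)
  }
  list(a = a_best, b = b_best, lod = (qnorm(target) - a_best) / b_best)
}

# Definitional variance components of a balanced day x replicate design,
# computed from two-pass sums of squares (no ANOVA machinery).
brute_variance_components <- function(day, percent) {
  days <- unique(day)
  k <- length(days)
  r <- length(percent) / k
  grand <- mean(percent)
  day_means <- vapply(days, function(d) mean(percent[day == d]), numeric(1))
  ss_within <- sum((percent - day_means[match(day, days)])^2)
  ms_within <- ss_within / (k * (r - 1))
  ss_between <- r * sum((day_means - grand)^2)
  ms_between <- ss_between / (k - 1)
  var_within <- ms_within
  var_between <- max(0, (ms_between - ms_within) / r)
  list(
    mean = grand,
    cv_within = 100 * sqrt(var_within) / grand,
    cv_between = 100 * sqrt(var_between) / grand,
    cv_total = 100 * sqrt(var_within + var_between) / grand
  )
}

# The printed eight-level detection panel used throughout validation tests.
reference_detection_panel <- function() {
  detection_table(
    c(1.160, 0.580, 0.290, 0.145, 0.073, 0.036, 0.018, 0.009),
    9, c(9, 9, 9, 8, 4, 0, 0, 0)
  )
}
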