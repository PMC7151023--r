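---
title: "Comparative-Cq quantification of mutant allele burden and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative-Cq quantification of mutant allele burden and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asqpcr)
library(dplyr)
```

## The measurement problem

Somatic hotspot mutations such as JAK2 V617F occur in a fraction of a
patient's blood cells, and that fraction — the mutant allele burden —
carries prognostic weight. Allele-specific qPCR (AS-qPCR) interrogates the
locus with two reactions that differ only in the 3′-terminal primer base:
one extends efficiently on the wild-type allele, the other on the mutant.
Classically the two reactions are read against standard curves (absolute
quantification). This package instead treats the two reactions as the two
"conditions" of the comparative Cq (2^-ΔΔCq) framework, which removes the
standard curves altogether.

Both reactions draw aliquots from the same DNA extract, so under equal
amplification efficiencies the Cq difference measures the log2 ratio of the
two allele counts. Writing ΔCq = Cq~wt~ − Cq~mut~,

$$\%\text{mut} = \frac{100}{2^{-\Delta Cq} + 1}.$$

Equal Cqs give exactly 50%; each additional wild-type cycle doubles the
mutant:wild-type odds. Because the two reactions are physically independent
pipetting events, a reference target (RNase P, single-copy) co-amplified in
each tube can absorb small input differences:
ΔΔCq = (Cq~wt~ − Cq~RP,wt~) − (Cq~mut~ − Cq~RP,mut~), used in the same
formula. When the two reference Cqs are equal the corrected estimate reduces
algebraically to the simple one; `classify_results(formula = "auto")` uses
the corrected form whenever both reference Cqs are available.

The method presumes the two allele-specific reactions amplify with similar
efficiencies close to 1 — both formulas silently convert cycles to factors
of 2. The package therefore ships the premise check itself
(`fit_standard_curve()`, `efficiency_from_slope()`, `compare_slopes()`):
dilution-series slopes near −3.32 cycles/decade, and a non-significant
slope-equality test, license the comparative-Cq shortcut.

## Decision policy

`classify_results()` applies the assay's operating rules to a table of Cq
quartets:

* **Undetermined** (no signal within the run's `total_cycles`, default 45)
  is represented as `Inf` — beyond any cycle — and is distinct from `NA`
  (not measured). File sentinels `"Undetermined"`, `"NA"` and `""` map to it
  on read.
* A failed **wild-type** reaction invalidates the sample (no amplifiable
  template or inhibition). This is an error, not a negative call.
* A **mutant** reaction that is undetermined, or at/beyond the Cq cutoff
  (default 42), is `not_detected`. The cutoff exists because allele-specific
  primers do extend on the wrong allele eventually — the mismatch delays
  rather than blocks extension — so very late signals are unspecific. The
  boundary is applied inclusively (a signal exactly at 42 is discarded) and
  is configurable through `qc_policy()`.
* Computed percentages are bucketed against the validated limits: below the
  LOD (default 0.15%) → `not_detected` (the number is suppressed); between
  LOD and LOQ (default 1.16%) → `detected_below_loq` (reportable as
  "detected", not as a quantity); at or above the LOQ → `quantified`.
* RNase P sanity checks (pair imbalance > 1 cycle, or Cq > 30) warn and are
  recorded in a `warnings` column, so QC flags survive file round-trips.

Percentages print with two decimals at ≥ 1% and four significant digits
below (`format_percent()`); computation is always full precision.

## Validation statistics

**Probit LOD.** Replicate detection counts across a dilution panel are
modelled as binomial with P(detect) = Φ(a + b·dose), fitted by maximum
likelihood (`stats::glm`, probit link). The LOD is the dose with 95% fitted
detection probability; its confidence interval comes from the delta method,
by default on the log10(LOD) scale so the interval stays positive.

The **dose metameter** was a genuinely open choice. For this assay's
validation panel the *linear* percent scale is the right one: fitted to the
packaged eight-level panel it reproduces the observed detection profile
across the whole range — including the shallow sub-LOD tail — whereas a
log10 metameter overshoots the LOD and misstates the mid-panel
probabilities. `probit_lod()` therefore defaults to `dose_scale =
"percent"`, with `"log10"` available for assays whose response is closer to
log-linear.

```{r lod}
panel <- detection_table(
  c(1.160, 0.580, 0.290, 0.145, 0.073, 0.036, 0.018, 0.009),
  9, c(9, 9, 9, 8, 4, 0, 0, 0)
)
fit <- probit_lod(panel)
fit
predict(fit, c(0.145, 0.073))
```

**LOQ.** `loq_assessment()` walks a dilution-accuracy experiment: a level
qualifies when detected in at least `ceiling(0.85 · n)` replicates
(generalising "eight of nine") *and* a one-sample t-test finds the observed
replicates compatible with the nominal value (p > 0.05). The LOQ is the
lowest qualifying level below which every tested level fails — the point
where the response stops being unbiased. `one_sample_t_from_summary()`
exposes the underlying test for tabulated mean/SD/n triplets. No
multiple-testing adjustment is applied across levels; the procedure is a
sequential screen, not a family of simultaneous claims.

**Precision.** `precision_analysis()` decomposes a balanced day × replicate
design (CLSI EP05 style, default 9 days × 2 replicates) by one-way
random-effects ANOVA: within-run variance = MS~within~; between-day
variance = max(0, (MS~between~ − MS~within~)/r) — truncated at zero so a
quiet between-day term cannot produce a negative component; total = sum;
CVs divide by the grand mean.

**Agreement.** `method_comparison()` reports Pearson r, OLS of test on
reference, and Bland–Altman statistics with the difference direction
test − reference (serum minus blood; candidate method minus comparator), so
positive bias means the test reads higher. Both the 95% limits of agreement
(bias ± 1.96·SD(d), expected to cover ~95% of individual differences) and
the t-based CI of the bias are returned — the two are easily conflated in
published tables, and they answer different questions. Subgrouping splits
at 20% mutant allele on the *reference* values by default (`subgroup_by =
"test"` is available; splitting on the test specimen is what a
serum-enrichment analysis would naturally do). `qualitative_agreement()`
reduces paired calls to the 2×2 table; an empty reference stratum leaves
that agreement undefined (`NA`) rather than 0 or 100.

## The simulator: what it emulates

`sim_config()` + `simulate_reaction_pair()` generate Cq quartets from a
mechanistic model:

| parameter | default | meaning |
|---|---|---|
| `total_allele_copies` | 7576 | 25 ng input / 0.0033 ng per haploid genome |
| `efficiency_wt`, `efficiency_mut` | 1.0 | per-cycle fold-increase − 1 |
| `single_copy_cq` | 42 | Cq of one template copy |
| `rp_single_copy_cq` | 38 | RNase P single-copy Cq (puts RNase P near Cq 25) |
| `noise_sd` | 0.15 cycles | Gaussian Cq noise, independent per reaction |
| `crosstalk_delta` | 18 cycles | wrong-allele extension delay |
| `total_cycles` | 45 | censoring horizon |

Allele sampling is binomial per extraction and shared between the two
reactions of a pair (both pipette from the same tube). Crosstalk enters as
additive template attenuated by 2^−`crosstalk_delta`: with the default 18
cycles a pure wild-type sample's mutant reaction lands beyond 45 cycles and
is censored, matching the observation that unspecific amplification is
rare; shortening the delay to 10 reproduces a late false signal near
0.1% — the phenomenon that motivates the Cq cutoff. A single integer seed
drives a fixed draw order (dilution levels → replicates → allele count →
the four Cq noises; cohorts iterate subjects, then blood before serum), so
identical seeds give bit-identical tables.

`simulate_dilution_series()` rescales copies at fixed fraction (standard
curves), `simulate_lod_panel()` builds detection tables, and
`simulate_paired_specimens()` emulates a paired blood/serum cohort in which
serum is enriched by a shift δ on the log-odds scale:
p~serum~ = logistic(logit(p) + δ). The logit form makes the enrichment
vanish at 0% and 100% and peak mid-range, which is the qualitative shape a
preferential lysis of the mutant-bearing myeloid compartment would produce.
The default δ = 0.25 was chosen once so that a mid-range cohort (the
`example_paired_cohort()` layout: 15 subjects under 20%, 20 over) shows a
cohort-mean enrichment of roughly 4 percentage points, larger in the
high-burden stratum — a calibration of magnitude, not a mechanistic claim.

Within a LOD panel, a replicate counts as detected when its mutant reaction
amplifies below the Cq cutoff — not when its percentage clears the LOD,
which is the *output* of that experiment and would be circular as an input.

**What the simulator does not emulate.** Real low-level spikes lose
linearity below ~1% (observed means fall well under nominal); the simulator
is unbiased at all levels, so simulated LOQ experiments bind on the
detection rule rather than on trueness. PCR inhibition, per-cycle
stochastic amplification (single-molecule Poisson efficiency), fragment-size
effects in serum DNA and inter-instrument threshold differences are all out
of scope. Passing simulation-based tests therefore demonstrates the
correctness of the estimators and decision logic under the stated model,
not the wet-lab performance of any particular assay.

**A note on noise propagation.** With independent per-Cq noise of SD 0.15
cycles, the ΔCq SD is 0.15·√2 ≈ 0.21 cycles and the percent-scale SD of a
single estimate near 50% burden is ≈ 3.7 points (d%/dΔCq = 100·ln2·p(1−p)),
so the Monte-Carlo SE of an 18-replicate mean is ≈ 0.9 points there. A real
assay does better mid-range because the paired reactions share extraction
and much of their pipetting error, which the independent-noise model
deliberately ignores; treat the default `noise_sd` as conservative for
mid-range burdens and realistic at the extremes.

## Numerical choices and degenerate inputs

* Probit separation (no level with partial detection) raises an explicit
  error rather than returning a divergent estimate; convergence is also
  checked through the glm flag and coefficient standard errors.
* Exact (noiseless) fits are legal everywhere: slope comparisons resolve
  zero-residual cases exactly (identical slopes → p = 1, different → p = 0)
  instead of forming 0/0 F statistics, and perfect-fit warnings from
  `summary.lm` are silenced where exact agreement is an expected input.
* `one_sample_t_from_summary()` with SD = 0 degenerates to p = 1 when the
  mean equals the expectation and p = 0 otherwise.
* Zero-variance inputs to `method_comparison()` leave the correlation block
  `NA` with a `degenerate` flag; bias statistics are still reported.
* Dilutions below one template copy are emitted as censored
  (`undetermined`) records, not errors.

## Problem sizes

The shipped tests run the full validation chain at the scale of the real
experiments they mirror: eight-level × 9-replicate detection panels,
9 × 2 precision designs (plus 200-day designs for parameter recovery),
35-subject paired cohorts, and 2000–4000-pair cohorts for
limits-of-agreement coverage. Everything completes in seconds on one core.

## Limitations

* The comparative-Cq estimate is only as good as the equal-efficiency
  premise; the package tests the premise but cannot repair a violated one
  (the efficiency-mismatch bias is characterised in the simulator tests).
* The LOD confidence interval is a delta-method approximation; profile or
  fiducial intervals from dedicated dose-response software will differ
  slightly in small panels.
* The serum-enrichment model is phenomenological. Its single parameter δ
  captures magnitude and mid-range shape, not biology.
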