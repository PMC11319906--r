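---
title: "Methods behind adipometrics: indices, energy adjustment, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind adipometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adipometrics)
```

## What the package models

`adipometrics` implements the analytic chain of a cross-sectional
nutritional-epidemiology study: per-participant body-composition and
cardiometabolic indices computed from anthropometry and fasting lipids,
energy adjustment of B-vitamin intakes (thiamine B1, riboflavin B2, niacin
B3, pyridoxine B6) from two 24-hour recalls, tertile stratification of the
adjusted intakes, and the inferential surface relating the two: tertile-wise
ANOVA, sex-stratified Pearson correlations, and variance-explained
regression. A seeded synthetic-cohort generator reproduces the statistical
structure these analyses assume, so the whole pipeline is testable without
any participant data.

## The index panel

Ten indices are computed per participant (units: weight kg, height m, waist
and hip circumference cm, TG and HDL mmol/L):

* BMI = weight / height²; WHtR = waist / height.
* Conicity index CI = WC(m) / (0.109 · √(weight/height)) — waist relative
  to a cylinder of the same mass and stature.
* Body adiposity index BAI = hip / height^1.5 − 18.
* Abdominal volume index AVI = (2·WC² + 0.7·(WC − HC)²) / 1000.
* Body roundness index BRI = 364.2 − 365.5 · √(1 − ((WC/2π)² / (0.5·h)²)).
* Weight-adjusted waist index WWI = WC / √weight.
* Lipid accumulation product LAP = (WC − 65)·TG for males,
  (WC − 58)·TG for females.
* Cardiometabolic index CMI = (TG/HDL) · WHtR.
* Atherogenic index of plasma AIP = log₁₀(TG/HDL).

Three conventions are deliberately configurable because published usage
varies, and every pipeline run records which was used:

* **BAI hip unit.** The standard formula takes hip in centimetres (values
  ≈ 25–35 in adults). Some reports are only reproducible with hip expressed
  in metres, which shifts the index to ≈ −17.5; `formula_options(bai_hip_unit
  = "m")` provides that mode as a first-class citizen.
* **BRI constant.** The standard leading constant is 364.2; 365.2 appears in
  some printed formulas and is offered as an alternative. Note that BRI
  values near 1.5–2.5 reported in parts of the literature are *not*
  reproducible from this formula on typical adult anthropometry (which gives
  ≈ 3–6); the package computes the formula as written under either constant
  and leaves that discrepancy documented rather than reverse-engineering an
  unstated variant.
* **Negative LAP.** A very lean participant's waist can fall below the
  sex-specific offset. Values are kept (flagged) rather than truncated at
  zero so tertile means stay unbiased; `allow_negative_lap = FALSE` replaces
  them with `NA`.

AIP uses base-10 logarithm, the index's defining convention; this is not
configurable, to prevent silently incomparable results. All indices are
computed on unrounded inputs; rounding is purely presentational. A useful
algebraic cross-check wired into the tests: CI = WWI·√height / 10.9 exactly,
since both formulas reduce to it.

Units are a classic failure mode here, so the reader stores height in
metres (converting centimetre columns when values exceed 3) and requires
lipid unit conversion from mg/dL (TG ÷ 88.57, HDL ÷ 38.67) to be requested
explicitly. Sex codes are never guessed; a `sex_map` must be supplied when
the source file does not use `"male"`/`"female"`.

## Energy adjustment and tertiles

Usual intake is the arithmetic mean of two recalls (participants with a
single recall are excluded by default; a flag-and-use-single policy exists
for simulated data). The energy adjustment is the residual method: ordinary
least squares of nutrient on total energy (with intercept), adjusted value =
residual + cohort mean nutrient intake. Two invariants characterise it —
the adjusted vector is exactly uncorrelated with energy, and its mean equals
the raw mean — and both are enforced by tests at 1e−10/1e−9 tolerances.
Adjustment is computed once on the whole analysed cohort (not within sex
strata), giving a single set of tertile cutpoints.

Tertiles use the 33rd and 66th percentiles with linear interpolation at
positions (n−1)p + 1 (`quantile type 7`). Labels are T1 strictly below the
33rd percentile, T2 closed on both ends, T3 strictly above the 66th. The
percentile convention is recorded alongside the cuts because group sizes at
the boundaries can depend on it.

## Inference

* Tertile summaries report mean ± SEM (SD/√n) per tertile with a classic
  equal-variance one-way ANOVA p-value (no Welch correction, matching the
  named test); with two groups F equals the squared pooled-variance t.
* Correlations are Pearson r with two-tailed p from the t transform on
  n − 2 df, reported for the pooled sample and per sex stratum.
* Variance explained defaults to the bivariate mode, percent = 100·r²,
  because in the source analysis the printed model R equals the bivariate
  |r|, implying age and sex were not actually partialled in those numbers.
  The nested mode (increment in R² over an age + sex base model, partial-F
  p-value) is always computed and reported alongside.
* No multiple-testing correction is applied (none was applied in the source
  analysis); the pipeline provenance records the number of tests performed
  so readers can judge.
* The finite-population sample size is n = ⌈N·x / ((N−1)E² + x)⌉ with
  x = z²p(1−p), z the exact two-sided normal quantile (1.959964 at 95%),
  then ⌈n(1+inflation)⌉. Ceiling is applied at both steps — a fractional
  participant cannot be enrolled — and the exact-z versus 1.96 choice does
  not change the reference results (385 minimum; 424 with 10% inflation for
  an adult population of 5,621,970).

## The synthetic cohort

`synthetic_config()` defaults define the study conditions: n = 491, 70%
male, age groups 20–34 / 35–44 / 45–65 weighted 198:169:124 (enrolment
starts at 18, so ages 18–19 are drawn inside the lowest group), energy
N(3050.09, 914.90²) kcal truncated above 800, and age-group anthropometry
(BMI, waist, hip means and SDs) matching the observed cohort
characteristics. Joint structure is the generator's own choice, since a
cross-sectional report carries no covariance information beyond means, SDs
and a few correlations:

* Height is sex-specific, N(1.75, 0.07²) m male and N(1.61, 0.06²) m
  female — typical adult values for the region, chosen once since the
  source reports no heights.
* (BMI, waist, hip) come from a Gaussian copula with correlations
  0.80/0.75/0.85 and age-group margins; weight = BMI · height². This yields
  the within-person weight–waist–hip coupling downstream analyses assume.
* TG is lognormal (meanlog log 2.0, sdlog 0.5 on the mmol/L scale) with its
  log correlated 0.30 with the standardised waist driver; HDL is
  N(1.10, 0.25²) truncated above 0.4 with waist correlation −0.20. These
  levels put LAP near 60 and AIP near 0.5, the observed magnitudes.
* Nutrient intake = density · energy/1000 · lognormal(mean 1, CV 0.25)
  plus a waist-linked additive term. Densities default to the observed
  unadjusted intake means divided by mean energy in Mcal
  (B1 0.685, B2 0.587, B3 10.77, B6 0.662 mg per 1000 kcal).

The waist-linked coefficient is calibrated in closed form. Writing the
intake as a·E·L + c·(W − μ_W) with E ⟂ W, E[L] = 1, Var(L) = CV², the
population residual after regressing on energy has variance
V = a²·CV²·(Var E + (E E)²) from the noise term (truncated-normal energy
moments are used), so the post-adjustment correlation with waist is
c·σ_W / √(V + c²σ_W²); solving for c hits the configured
`adiposity_coupling` in expectation. Default coupling is −0.156 for B1
(the reference effect size) and 0 for the other vitamins. Configurations
that cannot be calibrated — |ρ| ≥ 0.99, or any non-zero coupling with zero
density noise — are rejected with the bound named. Heavier intake tails
(the upper tail of B6 in real recall data is far heavier than a CV-0.25
lognormal) can be emulated by raising that nutrient's entry in
`density_cv`; no claim of distributional fidelity is made.

One root seed drives per-variable sub-streams, so adding a variable block
never perturbs earlier draws and cohorts are bit-reproducible. Truncation
(energy > 800 kcal, waist/hip > 50 cm, HDL > 0.4) is rejection-sampled and
the rejection counts logged in `ground_truth()`.

What the generator does *not* emulate: food items and recall coding error,
seasonality, the heavy B6 outlier tail, and any fitting to the archived
participant table. Passing recovery tests therefore demonstrate that the
*pipeline* estimates what was injected — not that real intake data satisfy
the generator's Gaussian-copula assumptions.

```{r recovery, eval = FALSE}
rep <- recovery_experiment(synthetic_config(n = 491, seed = 7),
                           replicates = 200)
rep
```

With 200 replicates of n = 491 at coupling −0.156, the mean estimated r
falls within ±0.02 of the target and the two-tailed rejection rate sits at
the Fisher-z analytic power (`fisher_z_power(0.156, 491)` ≈ 0.935); at
coupling 0 the rejection rate is the nominal 0.05. Problem sizes in the
test suite (200 replicates; convergence checks at n = 50,000; null-coupling
checks at n = 10,000–20,000) were chosen so Monte-Carlo error is comfortably
below the asserted bands while the whole suite runs in seconds.

## Degenerate inputs and numerical choices

* BRI's root argument goes negative when WC/2π exceeds half the height; the
  error names the offending ratio rather than returning NaN.
* `compute_indices()` evaluates per record: one invalid record yields `NA`
  in the affected column, never aborting the cohort; missing lipids blank
  only the lipid indices.
* All-identical adjusted intakes produce a single degenerate tertile (all
  T2) with a warning.
* A tertile with fewer than 2 members suppresses the ANOVA p (with a
  warning) but still reports means.
* Zero-variance strata in correlations are flagged `NA`, not fatal.
* Chi-squared expectations with a zero cell fall back to Fisher's exact
  test, flagged in the table's test record.

## Limitations

Cross-sectional by construction: nothing here supports causal or
longitudinal claims. The reproduction of the archived participant analysis
requires that deposit (one external download); without it the package
demonstrates correctness on synthetic cohorts and algebraic oracles only.
The published BRI group means discussed above remain unexplained by the
printed formula; both constants are provided, and the discrepancy is
reported rather than patched.
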