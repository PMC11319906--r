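# adipometrics

An R package for cross-sectional nutritional-epidemiology analyses that link
B-vitamin intake (thiamine B1, riboflavin B2, niacin B3, pyridoxine B6) to
body-composition and cardiometabolic indices. It implements the full analytic
chain on a per-participant cohort table:

1. **Ingestion and exclusion** — CSV or SPSS `.sav` cohorts, explicit unit
   handling (height m, circumferences cm, lipids mmol/L with an explicit
   mg/dL converter), rule-based exclusions with a structured log.
2. **A ten-index panel** — BMI, waist-to-height ratio, conicity index
   CI = WC(m)/(0.109·√(weight/height)), body adiposity index
   BAI = hip/height^1.5 − 18, abdominal volume index
   AVI = (2·WC² + 0.7·(WC−HC)²)/1000, body roundness index
   BRI = 364.2 − 365.5·√(1 − (WC/2π)²/(0.5·h)²), weight-adjusted waist index
   WWI = WC/√weight, lipid accumulation product
   LAP = (WC − 65|58)·TG (male|female), cardiometabolic index
   CMI = (TG/HDL)·WHtR, and atherogenic index of plasma AIP = log₁₀(TG/HDL).
3. **Residual-method energy adjustment** — nutrient regressed on total
   energy, adjusted intake = residual + cohort mean (exactly
   energy-orthogonal, mean-preserving), then tertiles at the 33rd/66th
   percentiles.
4. **Inference** — tertile-wise mean ± SEM with one-way ANOVA,
   sex-stratified Pearson correlations, variance-explained regression
   (bivariate 100·r² and an age/sex-partialled nested mode), demographic
   tables, and the finite-population sample-size formula
   n = ⌈N·z²p(1−p) / ((N−1)E² + z²p(1−p))⌉.
5. **A synthetic-cohort generator** — seeded, with a calibrated
   post-adjustment nutrient–adiposity coupling, plus a parameter-recovery
   harness, so every stage is exercisable and testable with no external
   data.

## Worked example

```r
library(adipometrics)

rec <- data.frame(weight = 74.04, height = 1.698, waist = 89.69,
                  hip = 102.98, sex = "male", tg = 1.9, hdl = 1.1)
round(compute_indices(rec)[, c("bmi","whtr","ci","bai","avi","bri","wwi","lap","cmi","aip")], 4)
#>       bmi   whtr     ci     bai     avi    bri     wwi    lap    cmi    aip
#> 1 25.6798 0.5282 1.2461 28.5421 16.2122 3.9032 10.4234 46.911 0.9124 0.2374
```

BMI 25.68 kg/m² (overweight threshold), CI 1.246 and AVI 16.2 are typical
young-adult central-adiposity values; LAP 46.9 cm·mmol/L and AIP 0.24
reflect the moderately elevated TG/HDL ratio of 1.73. With
`formula_options(bai_hip_unit = "m")` BAI is computed on metre-scale hip
(−17.53 for this record), the convention some published tables use.

Designing a survey of Jordan's 5,621,970 adults at a 5% margin of error,
95% confidence and 50% response distribution:

```r
sample_size(5621970)                    # 385
sample_size(5621970, inflation = 0.10)  # 424
```

End-to-end on a synthetic cohort, and checking that an injected
post-adjustment B1–waist correlation of −0.156 is recovered:

```r
res <- run_pipeline(pipeline_config(out_dir = "out", seed = 7, n = 491))
recovery_experiment(synthetic_config(n = 491, seed = 7), replicates = 200)
#> Recovery of b1-waist coupling (target -0.156), 200 replicates of n = 491
#>   mean estimated r: -0.1542 (empirical SE 0.0451)
#>   sign recovery:    100.0%
#>   rejection rate:   0.925 (analytic Fisher-z power 0.935)
```

The pipeline writes `table1.csv` (demographics by age group), `table2.csv`
(index means ± SEM by nutrient tertile with ANOVA p), `table3.csv`
(sex-stratified correlations), `table4.csv` (variance explained), a tertile
cuts sidecar, an exclusion log (JSONL), and `provenance.json` naming every
mode and constant used; re-runs with the same config are byte-identical.

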