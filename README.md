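# ctdoserisk

Estimates of cancer incidence attributable to CT scanning are built in two
stages: organ equivalent doses are computed from scan parameters by
dosimetry software, and those doses are multiplied by age- and sex-specific
risk coefficients.  The dosimetry stage depends heavily on the
computational *phantom* inside the software — older programs use a
hermaphrodite mathematical phantom (quadric-surface organs), newer ones use
the sex-specific voxelised ICRP reference phantoms — so two programs fed
identical scans can disagree substantially, and any trend seen when
comparing epidemiological studies across eras may be an artefact of the
software change.  `ctdoserisk` is for radiation epidemiologists and medical
physicists who need to quantify that artefact: it compares paired organ
equivalent doses from a mathematical-phantom program ("ImPACT") and a
voxelised-phantom program ("NCICT") and propagates the disagreement into
lifetime cancer-risk projections.

The package implements:

* **Reference-denominated Bland–Altman agreement.**  Differences scale
  with dose magnitude, so each pair is plotted as a percentage of the
  voxelised (reference) result,
  `d = 100 (x_NCICT − x_ImPACT) / x_NCICT`, with bias `d̄` and limits of
  agreement `d̄ ± 1.96 s_d`.
* **Passing–Bablok regression**, the rank-based method-comparison
  regression: the slope *B* is the shifted median of all pairwise slopes
  `S_ij = (y_j − y_i)/(x_j − x_i)` (offset by the count of slopes below
  −1), the intercept is `A = median(y_i − B x_i)`, and confidence
  intervals come from the Kendall-variance normal approximation
  `w = z_{1−α/2} √(n(n−1)(2n+5)/18)`.  The intercept CI excluding 0 flags
  a *systematic* difference, the slope CI excluding 1 a *proportional*
  difference, and the residual SD interval `±1.96·RSD` summarises
  *random* differences.
* **A CUSUM linearity test** on the residual signs around the fitted
  line, with a Monte-Carlo-calibrated null (the classical Kolmogorov tail
  is badly conservative once the line has been fitted) and an automatic
  log–log refit where linearity fails.
* **Lifetime attributable risk (LAR) projection.**  Median organ doses
  (mSv ≡ mGy for CT photons) are combined with the BEIR VII Table 12D-1
  incidence coefficients (cases per 100,000 persons per 0.1 Gy),
  linearly interpolated over exposure age, to give per-site and total LAR
  for every exposure age 18–80:
  `LAR_site(a) = dose_site / 100 × c_site(a)`.
* **A synthetic study generator** reproducing the source study's sampling
  frame (8 providers × 20 cases × 3 protocols, modal 120 kV) with a known
  per-site linear inter-method model, so the whole pipeline is testable
  without the original scan records.

## Worked example

```r
library(ctdoserisk)

tab <- study_median_doses()         # published median doses, all protocols
dose_difference(tab, "abdomen_pelvis", "male", "prostate")
#> [1] -5.69                        # mSv; voxelised median is 5.69 lower

co <- beir_coefficients()           # vendored BEIR VII incidence table
imp <- lar_curve(tab, co, "male", protocol = "abdomen_pelvis", software = "impact")
nci <- lar_curve(tab, co, "male", protocol = "abdomen_pelvis", software = "ncict")
glance(pct_higher_curve(nci, imp))
#> # A tibble: 1 × 3
#>     min   max  mean
#>   <dbl> <dbl> <dbl>
#> 1  2.97  6.61  4.11
```

So for males scanned with the abdomen/pelvis protocol, the voxelised
program projects between 2.97% and 6.61% more lifetime cancer cases per
100,000 exposed than the mathematical program, depending on exposure age —
the same scans, the same risk model, different phantoms.

On synthetic data the comparison machinery works end to end:

```r
d <- generate_pairs(200, intercept = 0.5, slope = 1.2, residual_sd = 0.1, seed = 1)
fit <- pb_fit(d, x, y)
tidy(fit)
#> # A tibble: 2 × 4
#>   term      estimate conf.low conf.high
#>   <chr>        <dbl>    <dbl>     <dbl>
#> 1 intercept    0.518    0.481     0.566
#> 2 slope        1.20     1.19      1.20
```

The intercept interval excludes 0 and the slope interval excludes 1, so the
fit flags the systematic (+0.5) and proportional (×1.2) differences that
the generator injected.

A file-based pipeline (`run_simulate()`, `run_compare()`, `run_lar()`, and
the wrapper script in `inst/scripts/ctdoserisk.R`) chains the stages:
simulated or real case CSVs → kV filtering → median tables with the
difference column → Bland–Altman and Passing–Bablok JSON → LAR curves and
disparity summaries.

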