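# lymphtrial

Genetic subtype-guided trial analysis for relapsed/refractory diffuse
large B-cell lymphoma (R/R DLBCL).

Salvage immunochemotherapy for R/R DLBCL has historically been applied
uniformly, despite the disease splitting into genetic subtypes with
distinct driver biology. `lymphtrial` implements the computational core of
a genotype-guided phase II salvage trial for biostatisticians and
translational researchers working with targeted mutation panels:

- **Rule-based genetic subtyping.** A 38-gene panel plus BCL2/BCL6/MYC
  FISH assigns each patient one of seven subtypes — MCD-like, BN2-like,
  N1-like, TP53-mutant, EZB-like, ST2-like, or NOS (not otherwise
  specified). *TP53* mutation takes absolute precedence; otherwise the
  rule matching the most defining features wins, ties falling to a fixed
  priority order. Each subtype maps to its targeted-agent arm on an R-ICE
  backbone (zanubrutinib, lenalidomide, decitabine, chidamide,
  tofacitinib).
- **Simon two-stage designs by exact binomial enumeration.** For null and
  alternative response rates p₀ < p₁ the search enumerates every
  `(r₁, n₁, r, n)` boundary, keeping designs with attained one-sided type
  I error ≤ α and power ≥ 1 − β, and returns the *optimal* (minimum
  E[N | p₀]) or *minimax* (minimum n) design. Validated against Simon's
  published design tables.
- **Endpoint statistics from first principles.** Response rates with
  exact Clopper-Pearson intervals, Kaplan-Meier product-limit curves with
  Greenwood standard errors, the two-group log-rank test
  (hypergeometric variance), univariate Cox regression for binary
  biomarkers (Breslow ties, Newton-Raphson), and adverse-event
  tabulation.
- **A calibrated synthetic cohort generator.** Seeded, substreamed
  generation of mutation/FISH/clinical tables matching the marginal
  mutation frequencies, seven-subtype prevalences, per-arm response
  distributions and 2-year PFS/OS anchors of the trial the package
  parallels, so the whole pipeline is testable without patient-level
  data.

## Worked example

```r
library(lymphtrial)

cfg <- cohort_config(n_patients = 76, seed = 20220426)
res <- run_pipeline("demo_out", config = cfg)

res$design
#> Simon two-stage optimal design  (p0=0.36, p1=0.56, alpha=0.05, beta=0.2)
#>   stage 1: n1 = 15, stop for futility if responses <= 6 (continue needs >= 7)
#>   overall: n = 51, reject H0 if responses > 23
#>   attained alpha = 0.0480, power = 0.8013, PET(p0) = 0.7278, E[N|p0] = 24.80
```

The design says: treat 15 evaluable patients; if 6 or fewer reach
complete response, stop for futility (which happens 73% of the time when
the true CR rate is the null 36%); otherwise continue to 51 and declare
the regimen active if more than 23 respond. The attained error rates are
recomputed from the returned boundary, not assumed.

```r
res$frequency
#>    subtype  n proportion
#> 1 TP53_mut  7 0.09210526
#> 2  N1_like  7 0.09210526
#> 3 MCD_like 18 0.23684211
#> 4 BN2_like 22 0.28947368
#> 5 EZB_like  0 0.00000000
#> 6 ST2_like  1 0.01315789
#> 7      NOS 21 0.27631579

response_rates(res$cohort$clinical$response)
#> n = 76  CR 39 (51.3%, clopper_pearson CI 39.6-63.0%)  ORR 61 (80.3%, CI 69.5-88.5%)
#> SD 3  PD 12  not assessed 0
```

At n = 76 the simulated subtype mix and response rates scatter around
their configured values (MCD-like 25%, CR 56.6%); a 10,000-patient cohort
reproduces them to within binomial sampling error. The output directory
holds the three input TSVs, per-patient `subtype_calls.tsv`,
`design.json`, `endpoints.json` (2-year PFS/OS read off the Kaplan-Meier
curves, CD70 hazard ratio) and a `manifest.json` recording the full
configuration and seed.

## Layout

- `R/` — cohort I/O, the subtyping rule engine, the design search,
  endpoint statistics, the synthetic generator, and the pipeline driver.
- `tests/testthat/` — unit, property and end-to-end tests, including
  brute-force oracles for the design search, Kaplan-Meier and Cox
  routines.
- `vignettes/subtype-guided-trial.Rmd` — the methods vignette: models,
  assumptions, parameter choices, and known limitations.
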