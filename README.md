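# domrisk

Quantitative tools for single-gene diseases caused by a **dominant allele**
in the autosomal two-allele model, aimed at population geneticists,
epidemiologists and clinician-researchers who need prevalence arithmetic,
diagnostic-test calibration, and familial-aggregation measures that are
explicit about their assumptions.

Under Hardy–Weinberg equilibrium with dominant-allele frequency *p* and
penetrance ratio *r* = P(D|Cc)/P(D|CC) ∈ (0, 1], disease prevalence is the
closed form

    P(D) = p (2r + (1 − 2r) p) P(D|CC),

bracketed for any *r* by the envelope (p² P(D|CC), p(2 − p) P(D|CC)].
Around this core the package provides:

* **Diagnostics** — 2×2 disease-by-test tables; accuracy, sensitivity,
  specificity, PPV; necessary/sufficient classification; the
  disease-iceberg correction for undiagnosed cases; and an interval
  estimator P(T) − (1 − P(T))α₀/(1 − α₀) ≤ P(D) ≤ P(T) for a test that is
  necessary for the disease with false-positive rate at most α₀.
* **Lifetime risk** — age-of-detection rate curves f(i) on ages 1..100,
  cumulative curves F(i), and the underestimation 1 − F(a) incurred by
  age-truncated studies.
* **Offspring groups** — the six parental-genotype strata F1..F6, their
  frequencies, Mendelian offspring distributions, risks βᵢ(r)·P(D|CC),
  recurrence-risk ratios μᵢ = P(D|Fᵢ)/P(D), the decomposition
  Σ P(Fᵢ)μᵢ = 1, sibling risk and the λs = 1 identity, and
  sibling-prediction utilities.
* **Simulator** — a seeded forward Mendelian family simulator with
  estimators for prevalence, sibling risk, group frequencies/risks, IBD
  allele sharing, and ascertainment-bias experiments (F6 exclusion, proband
  enrolment).

A command-line wrapper is installed at `exec/domrisk` with subcommands
`prevalence`, `diagnose`, `lifetime`, `groups`, `simulate`, `reproduce`.

## Worked example

A disease with p = 0.2, r = 1 and the CC genotype fully penetrant:

```r
library(domrisk)
m <- dominant_model(p = 0.2, r = 1)
m
#> Dominant-allele disease model (Hardy-Weinberg)
#>   allele frequencies: p = P(C) = 0.2, q = P(c) = 0.8
#>   penetrances: P(D|CC) = 1, P(D|Cc) = 1, P(D|cc) = 0  (r = 1)
#>   prevalence P(D) = 0.36  [envelope (0.04, 0.36], concave down in p]
```

36% of the population is affected. A clinical study of 1000 people with a
necessary test (no false negatives) but 30 false positives brackets that
prevalence from the table alone:

```r
estimate_prevalence(diagnostic_table(330, 0, 30, 640))
#> Prevalence interval from a necessary diagnostic test
#>   P(T) = 0.36; alpha_hat = 0.04478; alpha0 (upper 95% bound) = 0.06044
#>   P(D) in [0.3188, 0.36]
```

The six offspring groups show where the disease aggregates — 57% of all
cases come from Cc × cc families, and the all-recessive group F6 (41% of
the population) contributes none:

```r
offspring_groups(m)
#>  group mating_type frequency risk beta    mu proportion
#>     F1     CC x CC    0.0016 1.00 1.00 2.778   0.004444
#>     F2     CC x Cc    0.0256 1.00 1.00 2.778   0.071110
#>     F3     CC x cc    0.0512 1.00 1.00 2.778   0.142200
#>     F4     Cc x Cc    0.1024 0.75 0.75 2.083   0.213300
#>     F5     Cc x cc    0.4096 0.50 0.50 1.389   0.568900
#>     F6     cc x cc    0.4096 0.00 0.00 0.000   0.000000
```

For a person with an affected sibling, the F5-only prediction is
μ₅ × P(D) = 1.39 × 0.36 ≈ 0.50, and the proportion-weighted average over
F1..F5 is 0.66 — both well above the population risk of 0.36:

```r
sibling_prediction(m)
#>   F5-only prediction:      0.5
#>   weighted prediction:     0.662
```

The simulator shows what estimators actually do on Mendelian families.
Because siblings share parents, the naive pair estimator of the sibling
recurrence-risk ratio sits near 1.8 rather than the independence value 1,
and ascertainment inflates it further:

```r
ascertainment_experiment(m, 20000, seed = 1)
#>         mode   K_hat   Ks_used lambda_s_hat frac_families_excluded
#> 1       none 0.36365 0.6614877     1.819023                0.00000
#> 2 exclude_F6 0.36365 1.1162465     3.069563                0.40740
#> 3    proband 0.36365 1.3589886     3.737078                0.51325
```

See the vignette (`vignettes/dominant-disease-framework.Rmd`) for the model,
its assumptions, and a discussion of this gap between the λs = 1 identity
and the behaviour of Mendelian families.

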