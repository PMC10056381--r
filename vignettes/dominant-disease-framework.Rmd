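---
title: "A quantitative framework for diseases caused by dominant alleles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A quantitative framework for diseases caused by dominant alleles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domrisk)
```

## The model

`domrisk` works with single-gene diseases caused by a dominant allele in an
autosomal two-allele model. The dominant allele `C` has population frequency
$p$ and the recessive allele `c` has frequency $q = 1 - p$. Genotype
frequencies follow Hardy–Weinberg equilibrium ($p^2$, $2pq$, $q^2$); the
heterozygote is a single genotype with frequency $2pq$ (phase is never
tracked) and no inbreeding coefficient is modelled. The link from genotype
to phenotype is *penetrance*: the conditional probabilities
$P(D\mid CC)$, $P(D\mid Cc)$, $P(D\mid cc)$ of having the disease $D$ given
each genotype. A dominant disease has $P(D\mid cc) = 0$,
$0 < P(D\mid Cc) \le P(D\mid CC)$, so the *penetrance ratio*

$$r = \frac{P(D\mid Cc)}{P(D\mid CC)} \in (0, 1]$$

together with $p$ and $P(D\mid CC)$ characterises the disease completely.
Prevalence follows from the law of total probability,

$$P(D) = p^2 P(D\mid CC) + 2pq\, P(D\mid Cc) + q^2 P(D\mid cc)
       = p\,(2r + (1 - 2r)p)\,P(D\mid CC),$$

a parabola in $p$ that is concave down for $r > 1/2$, linear at $r = 1/2$
and concave up for $r < 1/2$, and that always lies in the envelope
$(p^2 P(D\mid CC),\; p(2-p) P(D\mid CC)]$. The package rejects $r = 0$
rather than returning the limiting curve: a dominant disease requires a
positive heterozygote penetrance, so the lower envelope bound is an
unattainable infimum, not a member of the family.

```{r}
m <- dominant_model(p = 0.2, r = 1)
prevalence(m)
prevalence_envelope(0.2)
```

All probabilities are fractions internally; percentages appear only in
presentation-layer output with an explicit label.

## Diagnostic tables and the prevalence interval

A diagnostic test `T` partitions a cohort into the familiar 2×2 table
against disease status. `table_rates()` returns accuracy, sensitivity
$P(T\mid D)$, specificity $P(T'\mid D')$, PPV $P(D\mid T)$ and the two error
rates; a rate whose margin is empty is flagged `NA` rather than silently 0.
A test is *necessary* for the disease when false negatives are absent and
*sufficient* when false positives are absent; `classify_test()` uses an
off-diagonal tolerance (default 1% of the cohort) to operationalise
"approximately zero".

Two corrections address systematic underestimation of prevalence:

* **Iceberg correction.** If a fraction $u$ of true cases is undiagnosed,
  the perceived prevalence is $(1-u)P(D)$ and
  `iceberg_true_prevalence(perceived, u)` inverts the relation (erroring if
  the implied prevalence exceeds 1).
* **Interval estimation.** For a test that is necessary for the disease with
  false-positive rate at most $\alpha_0$,
  $$P(T) - (1 - P(T))\frac{\alpha_0}{1-\alpha_0} \;\le\; P(D) \;\le\; P(T).$$
  The lower bound is clamped at 0 (the algebra can go negative for large
  $\alpha_0$). `estimate_prevalence()` wraps the four-step procedure:
  necessity check (the procedure is *rejected outright* if the test is not
  necessary), $\hat P(T)$, a Wald upper confidence bound on the
  false-positive rate, and the interval.

```{r}
estimate_prevalence(diagnostic_table(330, 0, 30, 640))
```

Numerical choices worth stating. The Wald bound is
$\hat\alpha + z\sqrt{\hat\alpha(1-\hat\alpha)/m}$ with
$z = \Phi^{-1}(1-(1-\text{conf})/2)$, so the default 95% level reproduces
the conventional 1.96 multiplier; the confidence level is exposed as a
parameter. The standard-error denominator $m$ defaults to the
disease-negative margin $n_{21}+n_{22}$ — the binomial sample on which
$\hat\alpha$ is defined — with a `denominator = "total"` mode using the
whole cohort size for compatibility with formulations that divide by $n$.
No Wilson or Clopper–Pearson variants are offered: the interval construction
is itself the object of study here, not a general-purpose binomial CI
toolkit.

## Cumulative lifetime risk

For diseases detected later in life, prevalence is a cumulative lifetime
quantity. The package represents the age-of-detection distribution as 100
rates $f(i)$ on integer ages $1..100$ (a fixed maximum lifetime; $F(0)=0$
is implied). A valid curve is nonnegative, sums to 1 — the test accounts for
every lifetime case — and is weakly unimodal (plateaus are allowed; strict
log-concavity is deliberately not required). A sum within $10^{-6}$ of 1 is
renormalised exactly; anything further off is rejected as an
inaccurate-diagnosis flag rather than silently rescaled. The cumulative
curve $F(i)$ is the running sum, and
`truncation_underestimate(F, a) = 1 - F(a)` is the fraction of lifetime
cases a study truncated at age $a$ never sees.

`make_bell_curve(mode_age, spread, skew)` builds synthetic curves for
testing and illustration: a two-piece Gaussian kernel with scale
`spread * exp(-skew)` below the mode and `spread * exp(skew)` above it,
discretised at integer ages and normalised. This construction was chosen
over a skewed beta family because it keeps the mode exactly at the requested
age for any skew and is unimodal by construction; `spread` is approximately
the standard deviation in years in the symmetric case.

```{r}
f <- make_bell_curve(mode_age = 50, spread = 12, skew = 0.4)
truncation_underestimate(cumulative_curve(f), 55)
```

One curve type serves both the age-true-positive and age-positive-predictive
roles; the two rates obey the same constraints and are never combined
numerically, so a second type would add nothing but duplication.

## Offspring groups

Random mating produces exactly six population strata ("offspring groups")
defined by the parental genotype pair, with frequencies
$P(F_1..F_6) = (p^4,\,4p^3q,\,2p^2q^2,\,4p^2q^2,\,4pq^3,\,q^4)$ — ordered
parents and heterozygote phase are absorbed into the multipliers, which is
equivalent to drawing each parent's two alleles independently with
probability $p$ (the simulator uses exactly this construction so the two
agree). Each group has a Mendelian offspring-genotype distribution, a group
risk $P(D\mid F_i) = \beta_i(r)P(D\mid CC)$ with
$\beta = (1, \tfrac{1+r}{2}, r, \tfrac{1+2r}{4}, \tfrac{r}{2}, 0)$, a
recurrence-risk ratio $\mu_i = P(D\mid F_i)/P(D)$ (independent of
$P(D\mid CC)$, which cancels), and a share $P(F_i)\mu_i$ of all diseased
individuals; the six shares sum to 1. When the `CC` genotype is lethal
before birth (Huntington's disease, Marfan syndrome), groups F1–F3 are
absent from the living population and $\mu_4$, $\mu_5$ carry the clinical
weight.

```{r}
offspring_groups(m)
sibling_prediction(m)
```

The clinical use: a person with an affected sibling cannot be in F6, and
either the group-specific risk applies (if the parental genotypes are
known) or the proportions $P(F_i)\mu_i$ serve as weights for an aggregate
prediction. Printed-table comparisons in the tests use the displayed number
of decimals with absolute tolerance 0.005; the weighted prediction is
computed from exact, unrounded proportions and risks.

## The sibling recurrence-risk ratio and its limits

Within the framework, sibling risk is defined through the group
decomposition $K_s = \sum_{i\le 5} P(D\mid F_i)P(F_i)$, and this sum
algebraically equals the closed-form prevalence $K$ for every
$(p, r, P(D\mid CC))$ — the package verifies the identity to $10^{-12}$ on a
dense grid, coding the two sides independently. Hence $\lambda_s = K_s/K =
1$, the single-locus zero-IBD sharing probability is $\varphi_s = 1/4$
(verified by exhaustive enumeration of the 16 transmission patterns), and
the percentage-HLA-contribution formula
$100\log(\lambda_{sHLA})/\log(\lambda_s)$ is undefined at the theoretical
value — `percent_lambda_s_hla()` raises a dedicated error there, while
`lambda_s_hla(0)` returns a tagged `Inf` because clinical tabulations report
that outcome rather than failing.

**A limitation the simulator makes visible.** The identity above rests on
treating the disease states of two siblings as *unconditionally*
independent. The forward simulator implements the framework's own
generative assumptions — Hardy–Weinberg mating, Mendelian transmission,
disease independent across individuals *given genotype* — and under that
process siblings share parents, so their genotypes are positively
correlated. The joint probability both are affected is
$\sum_i P(F_i)P(D\mid F_i)^2$, which exceeds $K^2$, and the standard
conditional pair estimator of $P(D_2\mid D_1)$ converges to

$$\hat\lambda_s \;\to\; \frac{\sum_i P(F_i)\,\beta_i(r)^2}
  {\big[p(2r + (1-2r)p)\big]^2} \;>\; 1$$

(about 1.84 at $p = 0.2$, $r = 1$, full penetrance), not to 1. Likewise the
zero-IBD share among doubly affected pairs is
$\tfrac14 K^2 / \sum_i P(F_i)P(D\mid F_i)^2 < 1/4$: affected pairs share
*more* alleles than random pairs. The package computes all three routes —
closed form, exhaustive enumeration and simulation — and they agree with
each other, not with the independence value. The acceptance suite keeps the
framework's calibration expectation for the unascertained estimator
unaltered, so that check fails by construction and documents the gap; users
should read $\lambda_s = 1$ as a property of the framework's independence
premise, not of Mendelian families.

Ascertainment bias comes on top of this. `ascertainment_experiment()`
contrasts three designs on matched seeds: no ascertainment; excluding the
all-`cc` families (F6) from the study while the prevalence denominator
remains population-wide, which multiplies the estimate by
$1/(1-P(F_6))$ (at $p\le0.2$ more than 40% of families are in F6); and
proband enrolment (families with at least one affected member), which
multiplies it by $1/P(\ge 1\text{ affected})$. The biased modes estimate
the joint sibling probability in the study sample but take the prevalence
from the full cohort held inside the same object — the mix that real
clinical studies produce, and the only construction under which the
exclusion mechanism inflates the ratio (if both pieces came from the study
sample the bias would cancel). `sensitivity_of_lambda_to_K()` exposes the
complementary effect: $\lambda_s = P(D_1\cap D_2)/K^2$ is quadratic in the
prevalence, so halving $K$ quadruples the ratio.

## The simulator and what passing tests show

`simulate_cohort()` consumes randomness in a fixed order (parental slots,
paternal then maternal transmissions, disease, test), so a seed reproduces a
cohort exactly. Defaults follow the framework's study conditions: two
offspring per family (the sibling-pair setting), a perfect test
(sensitivity 1, false-positive rate 0), and no ascertainment; imperfect
tests and the two ascertainment designs are switches. The generator
emulates a static Hardy–Weinberg snapshot only: no overlapping generations,
mutation, selection, assortative mating or age structure. Passing tests
therefore certify the arithmetic of the framework and the behaviour of its
estimators under the framework's own assumptions — they say nothing about
environmental covariance between siblings, multi-locus architecture, or
secular change in real populations.

Problem sizes are package choices balancing Monte-Carlo error against run
time: parameter-recovery checks use $10^5$ families (binomial three-sigma
bands), the replicate study of the ascertainment experiment uses 50 seeds ×
20{,}000 families, and the Monte-Carlo check of $\varphi_s$ uses $10^6$
sibling pairs.

## Degenerate inputs and tie-breaks

* `p = 1` collapses the prevalence envelope to the point $P(D\mid CC)$; the
  strict lower inequality degenerates there.
* `curvature_class()` compares `r` to 1/2 exactly; callers holding a
  floating approximation of 1/2 should round first.
* The mode age of a plateaued rate curve is reported as the first age
  attaining the maximum.
* Equality contracts use absolute tolerance $10^{-9}$ unless a tighter one
  is stated ($10^{-12}$ for the two prevalence-identity grids).
* A supplied `r` and a supplied penetrance pair must agree within
  $10^{-9}$ or construction fails — no silent preference for either source.
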