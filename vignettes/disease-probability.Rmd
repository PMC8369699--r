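---
title: "From PRS summary statistics to disease probability curves"
author: "prsprob"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From PRS summary statistics to disease probability curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsprob)
```

## The problem

A polygenic risk score orders individuals by genetic liability but carries
no absolute meaning: its scale depends on how many SNPs were aggregated,
with what weights, and on which GWAS the weights came from. Two individuals
scored by different studies cannot be compared, and a single individual's
score says nothing about their actual chance of developing disease. For a
disease like Alzheimer's the relevant baseline also moves dramatically with
age (a few percent lifetime, around 10% at 65+, around 30% at 85+) and with
a small number of high-effect variants that a PRS dilutes rather than
captures.

`prsprob` addresses this by converting the PRS to a probability of disease,
using only the prevalence $K$ and the PRS mean and variance in cases
($m_1, \sigma_1^2$) and non-cases ($m_0, \sigma_0^2$). These five numbers
can be published without sharing genotypes, and the resulting probability
is comparable across studies, age strata and genotype groups.

## Score definition and moments

For individual $j$ the score is the average weighted dosage
$$ PRS_j = \frac{1}{N_{snps}} \sum_{i=1}^{N_{snps}} g_{ij}\,\beta_i $$
with $g_{ij} \in \{0,1,2\}$ counting effect alleles and $\beta_i$ the log
odds ratio from an independent GWAS. Two conventions deserve a note because
they differ from common practice:

* the $1/N_{snps}$ divisor makes the score an average rather than a sum.
  This shrinks the scale as the panel grows, which is harmless: every
  downstream formula uses only moments computed on the same scale, and
  summary-parameter workflows accept whatever moments the user supplies.
* `sample_moments()` uses the $1/N_{ind}$ (population) variance divisor,
  not the $1/(N-1)$ of `var()`. At the sample sizes this framework targets
  the difference is far below every tolerance in the package; the divisor
  is kept for internal consistency.

Dosages count the *effect* allele named in the weights table. When
genotypes come from a VCF, the dosage is flipped ($2-g$) whenever the
effect allele is the REF allele; a weight whose allele matches neither REF
nor ALT is an error rather than a silent drop. Missing dosages are never
imputed: an individual missing any weighted genotype is excluded, with a
warning recording the count. Matching is by SNP id only — the method is
site-agnostic, and positions or builds are out of scope.

## From moments to probability

Assuming normal within-group score distributions, Bayesian inversion gives
the raw probability $\hat P(x) = K p_1(x) / (K p_1(x) + (1-K) p_0(x))$.
This is an exact posterior but not yet the logistic probability a
regression on case/control data would produce. The package therefore
projects the raw log-odds
$$ y(x) = \log \frac{K\,p_1(x)}{(1-K)\,p_0(x)} $$
onto an affine function of $x$ by weighted least squares, with the
population mixture density $p_p = K p_1 + (1-K) p_0$ as weight. For normal
components this projection has the closed form implemented in
`closed_form_coefficients()` (see the README or `?closed_form_coefficients`
for the formulas). Two facts anchor its correctness and are enforced by the
test suite:

* with equal group variances the log-odds is exactly affine, and the
  coefficients reduce to the discriminant-analysis values
  $\beta = (m_1-m_0)/\sigma^2$,
  $\alpha = \log(K/(1-K)) - (m_1^2-m_0^2)/(2\sigma^2)$;
* `weighted_logit_fit()`, the explicit finite-grid weighted regression,
  reproduces the closed form to discretisation error for any valid moments
  — with unequal variances the true log-odds is quadratic in $x$ and both
  routes compute the same best linear approximation under the population
  weight. The package deliberately implements this weighted-linear
  treatment rather than an "improved" quadratic model; the quadratic
  posterior is available as the `raw_probability` column of curve tables
  for comparison.

The raw probability also satisfies an exact conservation law,
$\int \hat P(x)\, p_p(x)\, dx = K$: averaging the posterior over the
population returns the prior. `prevalence_integral()` checks it by
adaptive quadrature over an interval reaching 10 component SDs beyond each
component mean — extending the interval per component, rather than in
population SDs, matters when one variance is several times the other,
because the wider component otherwise keeps non-negligible tail mass
outside the integration range.

### Unscreened controls

Biobank-style reference samples are population samples, not screened
non-cases: a fraction $K$ of them are undetected cases. Given case and
population moments, `infer_noncase_moments()` inverts the mixture
identities
$m_p = K m_1 + (1-K) m_0$ and
$\sigma_p^2 = K\sigma_1^2 + (1-K)\sigma_0^2 + K(1-K)(m_1-m_0)^2$.
An implied non-case variance $\le 0$ means the stated inputs cannot arise
from any case/non-case mixture with that prevalence; the package treats
this as a loud error rather than clamping, since it always indicates a
user-side inconsistency (e.g. moments and prevalence from incompatible
populations).

### Standardisation

Curves are reported against the standardised score
$x_{st} = (x - m_p)/\sigma_p$. This axis is study-portable, and every curve
table produced by `probability_curve()` is tabulated on it while the
underlying coefficients stay on the raw scale.

## Rare high-penetrance variants

A rare risk variant is handled at the probability level, not inside the
score. If its allele is rare enough to leave $K$ unchanged, its odds ratio
determines an intrinsic probability $p_{rare} = K(OR-1)/(K(OR-1)+1)$, and
assuming independence from the polygenic background a carrier's probability
is $P = P_{PRS} + p_{rare}(1-P_{PRS})$ — rising from $p_{rare}$ at the low
tail to 1. Two modelling guards are deliberate:

* $OR \le 1$ is rejected, not clamped to $p_{rare}=0$: protective or null
  "rare variants" indicate an input error under this model.
* the rarity assumption is documented rather than enforced; a supplied
  allele frequency above 0.005 triggers a warning, since at that frequency
  the variant starts to move the prevalence it is supposed to leave fixed.

Several independent rare variants combine as a union of independent events,
$p_{rare} = 1 - \prod_j (1 - p_{rare,j})$, though carrying two genuinely
rare variants is itself improbable.

## High-effect common variants (APOE)

A common high-effect allele like APOE-ε4 *does* move the prevalence and
cannot be treated as above. Instead, the prevalence is split by genotype.
Under Hardy–Weinberg equilibrium in the population and in non-cases —
reasonable when $K$ is low, increasingly wrong for high-prevalence
conditions, where the package raises an error if a genotype prevalence
leaves $[0,1]$ — the three genotype prevalences $K_0, K_1, K_2$ follow in
closed form from $(K, f, OR)$ via an auxiliary root $\nu$ of a quadratic
(`solve_nu()`). Numerical choices:

* the $OR = 1$ singularity (division by $1-OR$) is removable; within
  $10^{-8}$ of 1 the analytic limit $\nu = K(1-f)$ is used, and the test
  suite checks continuity across the switch at $10^{-4}$;
* the quadratic's discriminant is provably non-negative on the whole valid
  domain ($K, f \in (0,1)$, $OR > 0$), so the negative-discriminant error
  branch is purely defensive;
* exact identities — the HWE mixture of $K_0, K_1, K_2$ returning $K$, and
  recoverability of the input allelic OR — hold by construction and are
  tested against an independent brute-force solver that finds the non-case
  allele frequency by root-finding.

`stratified_curves()` then builds one probability curve per genotype with
the *same* case/non-case moments of a PRS computed excluding the variant's
region — justified by the approximate independence of that PRS from the
variant genotype — and only the prevalence changed. Age-dependent allele
frequency (APOE-ε4 falls from ~0.18 at 55+ to ~0.05 at 85+) is handled by
calling the function per age stratum with that stratum's $(K, f)$; the
package has no internal age model. The ε2 protective allele and
three-allele APOE genotypes are not modelled: the treatment is biallelic,
and excluding the APOE region from the PRS discards the information of
carrying ε2, which slightly flattens the variant-free curve relative to a
true ε4 non-carrier curve.

## The simulation ladder

`validate()` checks the closed form against three progressively more
abstract regression procedures, each on curves re-anchored to the
population prevalence:

(a) genotypes for $n$ cases and $n$ controls are simulated SNP-by-SNP in
HWE, controls at frequency $f$ and cases at the frequency implied by the
SNP's allelic odds ratio; the resulting scores are fit by ML logistic
regression. (b) scores are drawn directly from the two fitted normal
distributions and fit the same way. (c) the raw log-odds is regressed
linearly on the score with the mixture density as weight, on a grid of
2,001 points spanning $m_p \pm 8\sigma_p$ (odd count so the mean is a grid
point; weight mass beyond 8 SD is negligible). The closed form and (c) are
the same projection, so their discrepancy is pure discretisation;
procedures (a) and (b) add sampling noise and, in (a), whatever
non-normality the genotype architecture produces.

Because simulations draw balanced case/control samples while the curves are
on the population scale, fitted intercepts are re-anchored by
$\log(K/(1-K)) - \log(n_{cases}/n_{controls})$ — the standard case-control
intercept correction. Whether the original analyses re-anchored is not
documented anywhere we could rely on; the correction is therefore an
explicit, documented choice here, and it is exact (not approximate) for
logistic models under outcome-dependent sampling.

### What the generator emulates — and what it does not

`scenario_config()` provides two architectures: an oligogenic score of 39
strong SNPs (OR uniform in 1.1–1.4) and a polygenic score of 10,039 SNPs
(the 39 strong SNPs plus 10,000 weak ones, OR uniform in 1.00–1.05 with
random effect direction), control MAF uniform in 0.05–0.5 throughout, at
10,000 cases + 10,000 controls. The weak-SNP effect range is a deliberate
calibration: simulating each SNP's case frequency from its marginal odds
ratio means per-SNP separations add across independent SNPs, and 10,000
SNPs with ORs of even 1.05–1.3 would yield a score separating cases from
controls by ~10 population SDs — a jointly impossible architecture
(implied heritability far above 1) under which logistic ML does not exist.
With the chosen range the aggregate separation is ~1.7 SDs (AUC ≈ 0.88),
at the optimistic end of real polygenic scores for strongly heritable
disease. The generator draws independent SNPs (no LD), uses a single root
seed for frequencies, effects and genotypes, and streams SNP chunks into
the running score (`simulate_prs()`) so the 10,039-SNP panel never
materialises a full matrix.

Real data differ in ways these simulations do not probe: LD between
scoring SNPs, effect-size estimation noise in the weights, population
stratification, and case/control ascertainment that correlates with
covariates. A passing validation therefore shows that *given* the
two-normal summary description, the closed form reproduces what logistic
regression would estimate — the oligogenic scenario showing the larger
discrepancy illustrates the normality assumption straining at few, strong
SNPs — not that any particular published PRS satisfies that description.

### Problem sizes

The validation and parameter-recovery checks in the test suite run at
10,000 + 10,000 individuals (genotype-level, 10,039 SNPs) and
100,000 + 100,000 (score-level), sizes at which Monte-Carlo error is well
below the tolerances being asserted while a full suite run stays in the
tens of seconds. Property-style identities (mixture inversion,
equal-variance exactness, HWE identities) use 300–1,000 random parameter
draws under fixed seeds.

## Numerical and degenerate-input policy

* All density work is in log space (`dnorm(log = TRUE)`, `plogis`,
  `qlogis`); density ratios are never formed directly, so curves are stable
  beyond $|x_{st}| = 6$ and linear predictors up to several hundred.
* Group variances must be strictly positive at construction
  (`group_moments()`), which converts downstream division-by-zero into an
  immediate, named error; constant score sets are rejected at the moment
  stage.
* Probabilities passed to combination functions are range-checked;
  out-of-range inputs error rather than clamp.
* Perfect or quasi-perfect separation in any ML fit (detected through
  non-convergence or the fitted-probability warning of `glm`) is an error:
  a curve from a separated fit would be meaningless.
* Curve files report probabilities to 6 decimal places and grid values to
  10 significant digits; computation is double precision throughout.

## Known limitations

The framework inherits the assumptions baked into its inputs: normality of
the PRS within groups, independence of rare variants from the polygenic
background, independence of the variant-free PRS from the APOE genotype,
and HWE in non-cases (low-prevalence diseases only). Prevalence enters as
an external number and must come from a population matching the moments —
mixing age strata or ancestries between $K$ and the moments silently
mis-calibrates the curve, which is also why the unscreened-control
inversion refuses inconsistent inputs. Confidence intervals for $\alpha,
\beta$ are out of scope: the closed form propagates no uncertainty from the
summary moments, and the simulation machinery quantifies only Monte-Carlo
disagreement, not parameter uncertainty in the reference study.
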