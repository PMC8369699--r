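# prsprob

Calibrated probability-of-disease curves from polygenic risk score (PRS)
summary statistics.

A raw PRS is not a risk measure: its scale depends on the SNP set and
weighting used to build it, so values are not comparable between studies,
and standardising against the population mean and SD is not enough — how far
cases sit above non-cases matters too. `prsprob` converts five summary
numbers — the disease prevalence *K* and the mean and variance of the PRS in
cases (*m₁*, *σ₁²*) and in non-cases (*m₀*, *σ₀²*) — into an absolute
probability of disease as a function of the PRS, with no individual-level
reference data required. It is aimed at statistical geneticists and
clinical-risk modellers working on diseases such as Alzheimer's, where
prevalence varies strongly with age and a handful of variants (APOE-ε4, rare
*SORL1*/*TREM2*/*APP* mutations) carry effects too large to fold into the
PRS.

## The model

Assuming the PRS is normal within cases and non-cases, Bayesian inversion
gives the raw probability of disease at score *x*:

    P̂(x) = K p₁(x) / (K p₁(x) + (1 − K) p₀(x))

Projecting the corresponding log-odds onto an affine function of *x*,
weighted by the population mixture density p_p = K p₁ + (1 − K) p₀, yields a
logistic model P(x) = 1 / (1 + exp(−(α + βx))) with closed-form
coefficients

    β = (m₁ − m₀)/σ_p² · ( K(1−K)((r₀ + r₁)/2 − 1) + K σ₁²/σ₀² + (1−K) σ₀²/σ₁² )
    α = log( Kσ₀ / ((1−K)σ₁) ) + ½((r₀ − 1)K + (1 − r₁)(1 − K)) − m_p β

where r₀ = (σ₁² + (m₁−m₀)²)/σ₀², r₁ = (σ₀² + (m₁−m₀)²)/σ₁², and m_p, σ_p²
are the population mixture moments. For equal group variances these reduce
exactly to the discriminant-analysis coefficients β = (m₁−m₀)/σ²,
α = log(K/(1−K)) − (m₁²−m₀²)/(2σ²).

On top of the base curve the package provides:

- **Unscreened controls** — when only case and whole-population moments are
  available, non-case moments are recovered by inverting the mixture
  (`infer_noncase_moments()`).
- **Rare high-penetrance variants** — a rare risk allele with odds ratio OR
  adds an intrinsic probability p_rare = K(OR−1)/(K(OR−1)+1), combined
  independently with the PRS curve: P = P_PRS + p_rare(1 − P_PRS)
  (`intrinsic_probability()`, `combined_probability()`).
- **High-effect common variants (APOE-like)** — the overall prevalence is
  split into per-genotype prevalences K₀, K₁, K₂ under Hardy–Weinberg
  equilibrium in the population and in non-cases, giving one probability
  curve per genotype that shares the variant-free PRS moments
  (`genotype_prevalences()`, `stratified_curves()`).
- **A validation ladder** — HWE genotype simulation, normal score sampling
  and density-weighted logit regression, each compared against the closed
  form (`scenario_config()`, `validate()`).

## Worked example

An Alzheimer's-like setting in the 65+ age group: prevalence 10%, cases on
average 0.28 population SDs above non-cases on a standardised PRS scale.

```r
library(prsprob)

cases    <- group_moments(0.28, 1.0, "cases")
noncases <- group_moments(0.00, 1.0, "noncases")
curve    <- closed_form_coefficients(cases, noncases, K = 0.10)
curve
#> Logistic disease-probability curve (K = 0.1)
#>   alpha = -2.23642, beta = 0.28
#>   cases:    mean 0.28, var 1
#>   noncases: mean 0, var 1
#>   population: mean 0.028, var 1.00706

probability_curve(curve, n = 5)
#>   x_st probability raw_probability
#> 1   -4      0.0338          0.0338
#> 2   -2      0.0578          0.0578
#> 3    0      0.0972          0.0972
#> 4    2      0.1589          0.1589
#> 5    4      0.2489          0.2489
```

The probability of disease rises from about 3% four SDs below the
population mean to about 25% four SDs above it (raw and logistic
probabilities coincide here because the group variances are equal). A
carrier of a rare *SORL1*-like variant (OR = 7.2) never drops below its
intrinsic probability:

```r
rv <- rare_variant("SORL1", odds_ratio = 7.2, K = 0.10)
rv
#> Rare variant 'SORL1': OR = 7.2, K = 0.1 -> p_rare = 0.3827

round(combined_probability(probability_curve(curve, n = 5)$probability, rv$p_rare), 4)
#> [1] 0.4036 0.4184 0.4427 0.4808 0.5363
```

Splitting the same prevalence by APOE-ε4 genotype (allele frequency 0.18,
allelic OR 3.2):

```r
genotype_prevalences(K = 0.10, f = 0.18, OR = 3.2)
#> Genotype-stratified prevalence (K = 0.1, f = 0.18, OR = 3.2)
#>   K0 (non-risk homozygote): 0.051649
#>   K1 (heterozygote):        0.187714
#>   K2 (risk homozygote):     0.304258
```

so an ε4 homozygote faces a 30% prevalence against 5% for a non-carrier,
and `stratified_curves()` turns these into three probability curves.

A thin command-line wrapper is installed under `inst/cli/prsprob` with
subcommands `score`, `fit`, `curve`, `prob`, `apoe`, `infer-controls`,
`simulate` and `validate`; see `?prsprob_cli`.

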