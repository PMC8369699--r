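Package: prsprob
Title: Disease Probability Curves from Polygenic Risk Score Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts polygenic risk score (PRS) summary parameters (group
    means and variances in cases and controls, or cases and an unscreened
    population sample) together with disease prevalence into calibrated
    logistic probability-of-disease curves. Provides closed-form logistic
    coefficients derived from a Bayesian inversion of the case and non-case
    score densities, moment inference for unscreened controls,
    genotype-stratified prevalences for high-effect common variants (such as
    APOE epsilon-4 in Alzheimer's disease) under Hardy-Weinberg equilibrium,
    intrinsic-probability handling of rare high-penetrance variants, and a
    simulation suite (Hardy-Weinberg genotype simulation, normal score
    sampling, weighted logit regression) that validates the closed forms
    against maximum-likelihood logistic regression.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite
Config/testthat/edition: 3
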