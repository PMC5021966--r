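Package: vitdmr
Title: One-Sample Mendelian Randomization of Serum Vitamin D and Bone Outcomes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for one-sample Mendelian randomization of serum
    25-hydroxyvitamin D (25OHD) against bone mineral density and bone-metabolism
    markers in a postmenopausal cohort: subject-exclusion cascade, extreme-value
    trimming and log transformation, free and bioavailable 25OHD from the
    binding-equilibrium (Vermeulen-type) model, SNP quality control
    (Hardy-Weinberg, genotyping rate, linkage-disequilibrium proxies),
    covariate-adjusted observational regressions with false-discovery-rate
    control, and allele-score two-stage least squares with weak-instrument
    diagnostics and Hausman endogeneity testing. A synthetic-cohort generator
    with Hardy-Weinberg genotypes, weak genetic effects on log-25OHD, a latent
    confounder and a configurable causal effect makes every stage verifiable
    without access to individual-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
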