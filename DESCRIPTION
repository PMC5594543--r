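Package: evmir
Title: Simulation and Analysis of Short-Term PM10 Effects on Extracellular
    Vesicle miRNAs and Coagulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable analytical chain for panel studies of short-term
    particulate air pollution and plasma extracellular vesicles (EVs):
    daily-lag PM10 exposure assignment from fixed monitors or grid cells with
    an apparent-temperature covariate; OpenArray-style miRNA panel quality
    control (Crt/AmpScore rules), stability-scored normalization (global mean,
    reference assays, geNorm M and NormFinder), and 2^-DeltaCrt expression
    matrices; adjusted linear association models with percent-change (Delta%)
    effect transforms, Benjamini-Hochberg FDR, two-stage screening/validation,
    and BMI-stratified/interaction models; product-of-coefficients mediation
    with bias-corrected bootstrap confidence intervals; and miRNA-target
    disease enrichment with hub-gene and pathway overlays. A synthetic-cohort
    generator plants known exposure effects so every stage can be checked by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
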