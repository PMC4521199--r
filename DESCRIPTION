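Package: agestage
Title: Age-Stage, Two-Sex Life Table Analysis for Insect Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes age-stage, two-sex life tables from per-individual
    daily life-history records of metamorphic insects: age-stage survival
    (sxj), age-specific survival (lx), fecundity (mx) and maternity (lxmx)
    schedules, age-stage life expectancy (exj) and reproductive value (vxj),
    and the demographic parameters r, lambda, R0 and T with bootstrap
    standard errors and pairwise group comparisons (two-sample z and
    Tukey-Kramer with compact letter displays). Includes a stochastic
    cohort generator with analytic expected schedules, calibrated presets
    emulating serially inbred and outbred diamondback moth lines, and a
    small command-line pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics, yaml
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
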