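Package: kinmr
Title: Mendelian Randomisation of Lipoprotein Traits Using Outcomes in
    First-Degree Relatives
Version: 0.1.0
Authors@R: person("kinmr", "maintainers", email = "kinmr@example.org",
    role = c("aut", "cre"))
Description: Two-sample Mendelian randomisation (MR) of genetically
    predicted lipoprotein traits (apolipoprotein B, LDL cholesterol,
    triglycerides) against disease and lifespan outcomes reported in
    first-degree relatives of genotyped index individuals. Provides a
    family-structured synthetic cohort generator with Mendelian
    transmission and liability-threshold outcomes, per-SNP association
    scans with inverse rank-normalisation, LD clumping and instrument
    strength diagnostics (mean and conditional F-statistics), univariable
    and multivariable MR estimators (IVW, MR-Egger, weighted median,
    weighted mode, MVMR, MVMR-Egger), Benjamini-Hochberg FDR screening
    across relative-outcome families, mediation via total and direct
    effects, and a plain-TSV command line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
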