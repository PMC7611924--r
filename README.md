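# kinmr

Mendelian randomisation (MR) of lipoprotein traits — apolipoprotein B
(apoB), LDL cholesterol and triglycerides — against disease and lifespan
outcomes reported in **first-degree relatives** of genotyped index
individuals.

## The problem

Large biobanks ask participants whether their father, mother or siblings
had any of 12 diseases (heart disease, stroke, hypertension, diabetes,
…), whether each parent is still alive and, if not, at what age they
died. Treating these family reports as outcomes of a GWAS performed on
the *participants'* genotypes gives a "GWAS-by-proxy" design: the
genetic instrument is measured in people who share only half their
alleles with the people in whom the outcome occurs, so any causal effect
is expected to be diluted to roughly 50% of its direct magnitude, with
further dilution from self-report error and from siblings being reported
cumulatively rather than individually.

`kinmr` implements the full analysis chain for this design, and — since
the underlying biobank data are access-controlled — a family-structured
synthetic cohort generator with Mendelian transmission and
liability-threshold outcomes, so every stage has ground truth and is
testable end to end.

## What is in the box

| stage | functions |
|---|---|
| synthetic cohort | `sim_config()`, `simulate_trios()`, `lipid_effect_model()`, `simulate_lipids()`, `disease_model()`, `simulate_outcomes()`, `report_model()`, `apply_report_noise()` |
| GWAS & instruments | `inverse_rank_normalise()`, `run_gwas_quantitative()`, `run_gwas_binary()`, `linear_to_logodds()`, `ld_clump()`, `multivariable_clump()`, `mean_f_statistic()`, `conditional_f_statistic()`, `region_exclude()` |
| MR estimators | `harmonise()`, `wald_ratio()`, `ivw()`, `mr_egger()`, `weighted_median()`, `weighted_mode()`, `mvmr_ivw()`, `mvmr_egger()`, `to_odds_ratio()` |
| screening & inference | `outcome_catalog()` (the 38 relative-outcome slots), `bh_fdr()`, `univariable_screen()`, `sensitivity_suite()`, `bidirectional_mr()`, `mediation_proportion()`, `years_to_months()`, `dilution_ratio()`, `sex_stratified_run()` |
| calibration experiments | `proxy_dilution_experiment()`, `sign_reversal_experiment()` |
| IO & CLI | `read_summary_stats()`, `write_summary_stats()`, `read_run_config()`, `write_results()`, `run_pipeline()`, `cli_main()` |

The estimators follow the conventions of the standard two-sample MR
software stack. IVW is the no-intercept weighted regression of
SNP-outcome on SNP-exposure effects with weights 1/se_out²,

    beta_IVW = sum(w * bx * by) / sum(w * bx^2),

with multiplicative random-effects SE scaling `max(1, sqrt(Q/(L-1)))`.
MR-Egger adds an intercept (average directional pleiotropy) after
orienting all SNP-exposure effects positive. Multivariable MR regresses
outcome effects on the L×K exposure-effect matrix, giving each trait's
direct effect; instrument strength is reported as the mean F
(`mean((beta/se)^2)`) and, conditionally on the other exposures, as the
conditional F-statistic, `Q/(L-K+1)` from a weighted regression of
the target trait's effects on the others'. Screening across the 38
relative outcomes uses Benjamini-Hochberg FDR at q = 0.05.

## Worked example

Simulate a 5000-family cohort, derive an apoB instrument and estimate
the effect of genetically predicted apoB on the father's years of life
lost (the proxy-lifespan outcome):

```r
library(kinmr)
co  <- simulate_trios(sim_config(n_families = 5000, n_snps = 60,
                                 maf_range = c(0.1, 0.5), seed = 42))
mod <- lipid_effect_model(co$snp_meta$maf, var_explained = c(0.3, 0.3, 0.3),
                          seed = 42)
lip <- simulate_lipids(co, mod, "offspring", seed = 42)
out <- apply_report_noise(simulate_outcomes(co, mod, disease_model(),
                                            seed = 42),
                          report_model(), seed = 42)
gw  <- lapply(c("apoB", "LDL", "TG"), function(k)
  run_gwas_quantitative(co$offspring, inverse_rank_normalise(lip[, k]),
                        co$snp_meta, trait_label = k))
names(gw) <- c("apoB", "LDL", "TG")
instr <- ld_clump(gw$apoB, cohort_panel(co), p_thresh = 1e-6)
instr
#> instrument_set: 17 SNPs x 1 trait(s) [apoB]
#>   mean F: apoB=80.4

fat  <- out[out$role == "father", ]; dead <- fat$alive == 0
yll  <- run_gwas_quantitative(co$offspring[fat$family[dead], ],
                              -fat$death_age[dead], co$snp_meta,
                              trait_label = "father.age_at_death")
attr(yll, "scale") <- "years"
est <- ivw(harmonise(gw$apoB, yll, snp_subset = instr))
est[, c("method", "nsnp", "beta", "se", "lo95", "hi95", "pval")]
#>   method nsnp      beta        se       lo95     hi95    pval
#> 1    ivw   16 0.6803883 0.4267166 -0.1559763 1.516753 0.11083
years_to_months(est$beta)
#> [1] 8.2
```

Interpretation: each SD of genetically predicted apoB in the index
person is estimated to cost the father 0.68 years (8.2 months) of life;
the generative model planted a direct apoB effect of 2.0 years with an
opposing LDL effect of −1.5, and the proxy design halves what the
offspring's genotype can see, so attenuated univariable estimates like
this are exactly the expected behaviour. The multivariable model
separates the traits:

```r
mv <- multivariable_clump(gw, cohort_panel(co), p_thresh = 1e-6)
mvmr_ivw(harmonise(gw, yll, snp_subset = mv))[, c("exposure", "beta", "se")]
#>      exposure        beta        se
#> apoB     apoB  0.88317436 0.4917556
#> LDL       LDL -0.14936424 0.5072063
#> TG         TG -0.03223181 0.4163837
```

The whole chain is also available from the command line
(`inst/cli/kinmr`): `simulate`, `gwas`, `clump`, `mr` and `pipeline`
subcommands; `pipeline --config inst/extdata/toy_config.txt --out
results/` runs simulate → GWAS → clump → screen → sensitivity →
mediation end to end and writes `screen.tsv`, `sensitivity.tsv`,
`mediation.tsv`, `forest_data.tsv` and `run.log`.

## Scope notes

The association engine is OLS (the synthetic cohort has no relatedness
among index individuals, so a mixed model would add cost without
benefit); binary family outcomes are analysed on the linear-probability
scale and converted to log-odds with the μ(1−μ) factor. Population
stratification, assortative mating, imputation, genotype QC and
sex-chromosome transmission are out of scope. See
`vignettes/kinmr-methods.Rmd` for the model, parameter choices and
limitations.
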