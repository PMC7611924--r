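---
title: "kinmr: models and methods for family-proxy Mendelian randomisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kinmr: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## 1. The design being modelled

`kinmr` analyses a GWAS-by-proxy design: lipoprotein exposures (apoB,
LDL cholesterol, triglycerides) are measured on genotyped index
individuals, while the outcomes — 12 self-reported diseases, parental
vital status and parental age at death — occur in the index person's
first-degree relatives. Because a parent or full sibling shares half of
the index person's alleles, the per-allele association between an index
genotype and a relative's outcome is, in expectation, half the
association that would be seen if the outcome occurred in the genotyped
person; any MR estimate built on such associations is attenuated by the
same factor. Self-report misclassification and the cumulative (rather
than per-person) reporting of sibling disease dilute effects further.
The package's synthetic cohort makes all three dilution mechanisms
explicit and testable.

## 2. The synthetic cohort

**Genotypes.** Parents are drawn under Hardy-Weinberg equilibrium from
haplotypes generated per LD block by autoregressive allele copying: the
first SNP of a block is Bernoulli(MAF); each subsequent SNP copies its
left neighbour with probability `ld_rho`, otherwise draws fresh. This
gives tunable adjacent-SNP correlation without shipping a reference
panel. Blocks are placed on 10-Mb shelves so inter-block SNPs are
farther apart than the 1-Mb clumping window. Children receive one
complete haplotype from each parent (no recombination), so Mendelian
consistency holds exactly at every SNP and the parent-offspring dosage
correlation is 0.5 in expectation. Sibling counts are drawn per family
from a distribution over 0–3 (default 0.15/0.35/0.30/0.20, a
plausible spread for a mid-century European birth cohort; chosen once
and not tuned).

A limitation worth stating: when MAFs differ along a block, the AR
copying slightly distorts realised allele frequencies relative to the
nominal MAF of downstream SNPs. With the default `ld_block_size = 1`
this never arises; with LD enabled, effect-size scaling that uses the
nominal MAF is approximate.

**Lipid traits.** Trait = centred-dosage × β + correlated Gaussian
residual, scaled so each trait has unit variance, then empirically
standardised. A fraction `shared_fraction` (default 0.6) of causal SNPs
affects all three traits with correlated effect sizes (apoB–LDL effect
correlation 0.9, apoB–TG 0.4), reproducing the strong genetic
correlation between apoB and LDL cholesterol that drives the
multivariable analyses; residual correlations default to 0.90/0.40/0.30
(apoB–LDL/apoB–TG/LDL–TG). Default SNP-explained variance is 0.10 per
trait, matching the order of magnitude a genome-wide lipid instrument
explains in practice. One SD of apoB is labelled 0.24 g/L.

**Outcomes.** Each relative's disease arises from *that relative's own
genotype*: liability = weighted sum of the relative's latent lipid
values plus N(0, `env_sd`) environment, standardised by its theoretical
SD; disease iff liability exceeds `qnorm(1 - prevalence)`. Default
prevalences are taken from the bundled questionnaire counts (fathers'
column; mothers' for the female-only cancers), so the simulated world
matches the descriptive table it stands in for. Default liability
weights encode the lipid biology the tests exercise — apoB raises heart
disease, stroke and hypertension risk, and diabetes has a positive
direct apoB weight with a stronger negative LDL weight, so its
univariable apoB association inverts in sign, the pattern the
multivariable analysis is designed to resolve. Parental death age =
sex-specific baseline (70.9 father / 75.7 mother, the questionnaire
means) − years-of-life-lost weights (default apoB +2.0, LDL −1.5, TG
+0.6, the magnitudes and signs of the multivariable lifespan estimates)
× lipid values + N(0, 13) noise; vital status is death age >
`censor_age` (default 60, a typical parental age at study entry — the
questionnaire gives no generative model for parental ages, so this is a
single fixed constant, not a fitted quantity).

**Report noise.** Each true status flips independently with the
per-disease sensitivity/specificity; `sensitivity = specificity = 1`
(the default) reproduces truth exactly. Misreporting correlated with the
index person's own status — a plausible real-world mechanism — is *not*
modelled; the flag is independent by design and documented as such.
Sibling rows are collapsed to one any-affected indicator per family.

**What a green test does not establish.** The generator has no
population stratification, assortative mating, dynastic effects,
genotyping error or missing data. Tests that pass on this cohort verify
the statistical machinery under the design's stated assumptions; they
say nothing about robustness to the confounding structures the real
cohort may contain.

## 3. Association scans and instruments

Inverse rank-normalisation uses the Blom offset,
Φ⁻¹((rank − 3/8)/(n + 1/4)), with average ranks for ties. The
association engine is per-SNP OLS with covariate residualisation
(Frisch–Waugh), replacing the mixed model used on biobank data: the
synthetic index individuals are unrelated, so a mixed model would add
cost without changing the estimates. Monomorphic SNPs are excluded with
a logged count. Binary family outcomes are analysed on the
linear-probability scale and converted to log-odds by dividing beta and
SE by μ(1−μ) at the observed case fraction — the first-order
equivalence between the two scales; the conversion is isolated in
`linear_to_logodds()` so any alternative can be swapped in.

Clumping is greedy: candidates sorted by ascending p (ties broken by
chromosome, then position), each accepted iff no previously accepted
SNP on the same chromosome within ±1 Mb has panel r² ≥ 0.001. The
defaults (p < 5e-8, r² < 0.001, 1 Mb) encode the conventional
genome-wide instrument rule; "a distance of 1 megabase" is interpreted
as a ±1 Mb flank around the index SNP. Multivariable instruments pool
all traits' results, take the per-SNP minimum p, clump once, and carry
every trait's beta/SE for each retained SNP.

Instrument strength: mean F = mean((β/se)²); the conditional F for one
exposure regresses its SNP effects on the other exposures' effects
(weights 1/se², no intercept) and scales the weighted residual sum of
squares as Q/(L−K+1). Cross-trait sampling covariance of SNP effects is
assumed zero — stated here rather than silently assumed; with all
traits estimated in one synthetic cohort this is an approximation, as
it is in the two-sample software this mirrors.

## 4. Estimators and numerical choices

All estimators operate on a harmonised set aligned to the first
exposure's effect allele. Strand flips are resolved by allele
complementation; palindromic (A/T, C/G) SNPs are kept only when both
allele frequencies lie outside [0.42, 0.58] (orientation then decided
by frequency-side agreement) and dropped otherwise — including when an
eaf is missing. The 0.42 limit is a documented package default, not an
inference about any particular dataset; in a same-cohort design
palindromes are unambiguous anyway.

* **IVW**: weighted no-intercept regression; multiplicative
  random-effects SE scaling `max(1, sqrt(Q/(L−1)))`, never deflating
  below the fixed-effect SE. L = 1 reduces exactly to the Wald ratio
  with first-order SE se_out/|β_exp|.
* **MR-Egger**: SNPs oriented so exposure effects are positive;
  weighted regression with intercept; scaling `max(1, sqrt(Q/(L−2)))`.
* **Weighted median**: ratios ordered, inverse-variance weights
  accumulated, estimate interpolated at cumulative weight 0.5; SE from
  a seeded parametric bootstrap (default 1000 draws) resampling both
  beta vectors. The point estimate is deterministic; only the SE is
  resampled.
* **Weighted mode**: Gaussian-kernel weighted density over ratios,
  bandwidth = factor × 0.9·min(sd, mad)·L^(−1/5) of the ratio SEs
  (falling back to the same scale of the ratios themselves if the SEs
  are degenerate); estimate = argmax over a 1024-point grid spanning
  the ratio range ±3 bandwidths. All-identical ratios short-circuit to
  that value.
* **MVMR / MVMR-Egger**: weighted multiple regression without/with an
  intercept; MVMR-Egger sign-orients rows by a chosen trait. SE scaling
  uses L−K (and L−K−1) degrees of freedom. An aliased exposure column
  (e.g. identically zero) yields an NA estimate with a warning rather
  than an error — the contract's "rank-deficient" error is reserved for
  a design with no estimable column at all, because the degenerate
  zero-column case must still reduce to the univariable estimate for
  the remaining exposure.

P-values are normal-theory throughout (Wald-type CIs); a t-reference
for Egger would be a config switch, default off. Odds ratios are
exp(β) with CI exp(β ± 1.96 se), only on the log-odds scale.

Under the summary-level valid-instrument simulation used by the
acceptance suite (L = 50, n = 20 000, instruments explaining 10% of the
exposure), IVW CI coverage sits near the lower half of the 93–97% band:
with mean F ≈ 40 the noisy exposure betas attenuate the slope slightly
(the NOME approximation), a known small-sample property of IVW rather
than an implementation artefact.

## 5. Screening, mediation and reporting

The FDR family is the 38 applicable relative-outcome slots (13 father,
13 mother, 12 sibling after the sex-applicability mask), adjusted by an
own-implementation Benjamini-Hochberg step-up (tested against
`stats::p.adjust` as an independent oracle); repeating the screen for
LDL cholesterol or triglycerides adjusts within that trait's own
38-test family. Age at death is analysed as a continuous trait among
deceased parents (negated, so positive = years of life lost); vital
status as binary among all parents — the cross-sectional reading of
parental survival data.

Mediation reports 1 − direct/total, with the total from univariable IVW
and the direct from MVMR including the mediators. The CI comes from
independent normal resampling of the two estimates (10 000 seeded
draws); no closed-form CI is claimed for a ratio of correlated
estimates, and the estimates here are treated as independent — a
simplification flagged in the output when the total's CI spans zero.
Mediators can be entered jointly (the default pipeline does) or singly;
both are legitimate readings of a "proportion mediated" range, and the
function does not privilege either.

`years_to_months()` multiplies by 12 and rounds to one decimal for
display, keeping the unrounded value as an attribute, so reporting
matches the convention of quoting months while computing in years.

## 6. The calibration experiments

`proxy_dilution_experiment()` is the package's core acceptance
property: a continuous outcome generated from the *father's* genetic
score, with SNP-outcome effects estimated against *offspring* dosage,
gives an IVW estimate that should be 50% of the direct-design estimate.
Design constants (2000 families, 50 SNPs, MAF 0.3) follow the stated
experiment; the free effect sizes were fixed a priori from power
arithmetic so that Monte-Carlo error stays inside the ±5-percentage-
point band: the 50 SNPs carry h² = 0.5 of the exposure and the outcome
noise SD is 0.5. These are deliberately strong — this is a calibration
experiment isolating the transmission factor, not a claim about lipid
genetics. The same environmental noise realisation is used in both
designs (common random numbers), which cancels a shared noise term from
the ratio without changing either design's marginal model.

`sign_reversal_experiment()` reproduces the correlated-exposure
phenomenon that motivates the multivariable analysis: two exposures
with SNP-effect correlation ≈ 0.9 and direct liability weights +0.3 and
−0.6 on a disease of prevalence 0.097. The univariable estimate of
exposure 1 takes the sign of the combined effect (negative), while MVMR
recovers the planted positive direct effect. The weights are chosen so
the combined effect θ₁ + 0.9·θ₂ is clearly negative while θ₁ is
clearly positive; prevalence is the diabetes prevalence of the bundled
counts.

## 7. Reproducibility and limitations

All randomness flows from one master seed through named sub-streams
(`simulate`, `lipids`, `outcomes`, `report`, `bootstrap`, `mediation`,
`replicate`), so stages re-run in isolation reproduce exactly; the
pipeline writes byte-identical outputs for identical seed and config.
Config files are flat `key = value` text with unknown keys rejected —
deliberately minimal, since the whole configuration is a couple of
dozen scalars.

Known limitations: no missing data (the questionnaire's "do not know"
coding is left as a config hook), no correlated misreporting, no
recombination within transmitted haplotypes, nominal-MAF scaling under
LD, independence approximation in the mediation CI, and OLS in place of
a mixed model — appropriate here only because the simulated index
individuals are unrelated.
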