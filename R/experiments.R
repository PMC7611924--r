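# Self-contained calibration experiments built from the package's own
# pipeline pieces. These exist as first-class functions because the two
# phenomena they demonstrate - proxy-design dilution by Mendelian
# transmission, and the univariable/multivariable sign reversal under
# correlated exposures - are the scientific core the synthetic cohort is
# meant to make testable.

#' Family-proxy dilution experiment
#'
#' Quantifies the attenuation a proxy design imposes: a continuous
#' outcome is generated from the father's genetic score (theta times the
#' score plus noise), SNP-outcome effects are estimated by regressing
#' that outcome on the offspring's dosages, and IVW MR is run against
#' SNP-exposure effects estimated in the offspring. The same outcome
#' model applied directly to the offspring's own score gives the direct
#' design. First-degree relatives share half their alleles, so the
#' proxy/direct slope ratio is expected to be 0.5.
#'
#' Effect sizes are fixed a priori so Monte-Carlo error stays well below
#' the 5-percentage-point acceptance band at the default design size:
#' the exposure's 50 SNPs carry half its variance (a deliberately strong
#' polygenic signal; this is a calibration experiment, not a biology
#' claim) and the outcome noise SD is 0.5.
#'
#' @param n_families trio count (default 2000).
#' @param n_snps independent SNPs (default 50).
#' @param maf common allele frequency (default 0.3).
#' @param h2 exposure variance explained by the SNPs.
#' @param theta outcome effect per unit genetic score.
#' @param noise_sd outcome noise SD.
#' @param seed integer seed.
#' @return list with `ratio_pct` (100 x proxy/direct), `proxy` and
#'   `direct` IVW `mr_estimate` rows, and `dilution` (the
#'   [dilution_ratio()] result).
#' @export
proxy_dilution_experiment <- function(n_families = 2000, n_snps = 50,
                                      maf = 0.3, h2 = 0.5, theta = 1,
                                      noise_sd = 0.5, seed = 1L) {
  cfg <- sim_config(n_families = n_families, n_snps = n_snps,
                    maf_range = c(maf, maf + 1e-9),
                    ld_block_size = 1, ld_rho = 0,
                    n_siblings_dist = c(1, 0, 0, 0), seed = seed)
  co <- simulate_trios(cfg)
  n <- n_families
  set.seed(stream_seed(seed, "replicate"))
  vdos <- 2 * maf * (1 - maf)
  beta <- stats::rnorm(n_snps)
  beta <- beta * sqrt(h2 / sum(vdos * beta^2))
  ctr <- 2 * co$snp_meta$maf
  g_off <- as.numeric(sweep(co$offspring, 2, ctr) %*% beta)
  g_fat <- as.numeric(sweep(co$father, 2, ctr) %*% beta)
  exposure <- g_off + stats::rnorm(n, sd = sqrt(1 - h2))
  # common random numbers: the same environmental noise realisation in
  # both designs, so it cancels from the proxy/direct ratio instead of
  # inflating its Monte-Carlo error; each design's marginal model is
  # unchanged
  e <- stats::rnorm(n, sd = noise_sd)
  y_direct <- theta * g_off + e
  y_proxy <- theta * g_fat + e

  bx <- run_gwas_quantitative(co$offspring, exposure, co$snp_meta,
                              trait_label = "exposure")
  by_d <- run_gwas_quantitative(co$offspring, y_direct, co$snp_meta,
                                trait_label = "direct")
  by_p <- run_gwas_quantitative(co$offspring, y_proxy, co$snp_meta,
                                trait_label = "proxy")
  est_d <- ivw(harmonise(bx, by_d))
  est_p <- ivw(harmonise(bx, by_p))
  dil <- dilution_ratio(est_p, est_d)
  list(ratio_pct = 100 * dil$ratio, proxy = est_p, direct = est_d,
       dilution = dil)
}

#' Univariable/multivariable sign-reversal experiment
#'
#' Reproduces the signature of two highly correlated exposures with
#' opposing direct effects on a liability-threshold disease (the
#' apoB/LDL-cholesterol versus type 2 diabetes pattern): exposure 1 has a
#' positive direct liability weight and exposure 2 a stronger negative
#' one, with SNP-effect correlation about 0.9 between the exposures, so
#' the univariable estimate of exposure 1 takes the sign of the combined
#' effect (negative) while MVMR recovers the planted positive direct
#' effect. Disease prevalence defaults to 0.097 and the binary GWAS runs
#' on the index individuals' own status.
#'
#' @param n_families index individuals (trios are simulated; only
#'   offspring are used here).
#' @param n_snps causal SNPs shared by both exposures.
#' @param w1,w2 direct liability weights of the two exposures.
#' @param prevalence disease prevalence.
#' @param seed integer seed.
#' @return list with `uni` (univariable IVW row for exposure 1) and
#'   `mvmr` (MVMR rows).
#' @export
sign_reversal_experiment <- function(n_families = 10000, n_snps = 60,
                                     w1 = 0.3, w2 = -0.6,
                                     prevalence = 0.097, seed = 1L) {
  cfg <- sim_config(n_families = n_families, n_snps = n_snps,
                    maf_range = c(0.1, 0.5), ld_block_size = 1, ld_rho = 0,
                    n_siblings_dist = c(1, 0, 0, 0), seed = seed)
  co <- simulate_trios(cfg)
  lmod <- lipid_effect_model(co$snp_meta$maf,
                             var_explained = c(0.2, 0.2, 0.2),
                             shared_fraction = 1, seed = seed)
  tr <- simulate_lipids(co, lmod, "offspring", seed = seed,
                        standardise = FALSE)
  w <- matrix(c(w1, w2, 0), 1, 3,
              dimnames = list("diabetes", c("apoB", "LDL", "TG")))
  dmod <- disease_model(weights = w,
                        prevalence = c(diabetes = prevalence))
  set.seed(stream_seed(seed, "outcomes"))
  status <- kinmr_liability(tr, dmod)
  gx1 <- run_gwas_quantitative(co$offspring, tr[, "apoB"], co$snp_meta,
                               trait_label = "exposure1")
  gx2 <- run_gwas_quantitative(co$offspring, tr[, "LDL"], co$snp_meta,
                               trait_label = "exposure2")
  gy <- linear_to_logodds(run_gwas_binary(co$offspring, status, co$snp_meta,
                                          trait_label = "disease"))
  uni <- ivw(harmonise(gx1, gy))
  mv <- mvmr_ivw(harmonise(list(gx1, gx2), gy))
  list(uni = uni, mvmr = mv)
}

# liability-threshold assignment shared with simulate_outcomes()
kinmr_liability <- function(tr, dmod) {
  liability_disease(tr, dmod$weights["diabetes", ],
                    dmod$threshold[["diabetes"]], dmod$env_sd)
}
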