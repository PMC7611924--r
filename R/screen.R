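# The inference layer: the 38-outcome FDR screen, sensitivity suites,
# bidirectional MR, mediation, sex stratification and reporting
# conversions.

#' The 38-slot catalogue of first-degree-relative outcomes
#'
#' Fathers and mothers each contribute the 12 diseases minus the
#' sex-inapplicable cancer (no breast cancer in fathers, no prostate
#' cancer in mothers) plus vital status and age at death; siblings
#' contribute the 12 diseases only (no vital status is recorded for
#' siblings). 13 + 13 + 12 = 38 applicable outcome slots.
#'
#' @return data.frame with columns relative, outcome, type
#'   (`"binary"`/`"continuous"`).
#' @export
outcome_catalog <- function() {
  dis <- disease_names()
  rows <- rbind(
    data.frame(relative = "father", outcome = setdiff(dis, "breast_cancer"),
               type = "binary", stringsAsFactors = FALSE),
    data.frame(relative = "father", outcome = c("alive", "age_at_death"),
               type = c("binary", "continuous"), stringsAsFactors = FALSE),
    data.frame(relative = "mother", outcome = setdiff(dis, "prostate_cancer"),
               type = "binary", stringsAsFactors = FALSE),
    data.frame(relative = "mother", outcome = c("alive", "age_at_death"),
               type = c("binary", "continuous"), stringsAsFactors = FALSE),
    data.frame(relative = "sibling", outcome = dis, type = "binary",
               stringsAsFactors = FALSE)
  )
  rows$slot <- paste(rows$relative, rows$outcome, sep = ".")
  rownames(rows) <- NULL
  rows
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values: sort ascending, multiply p_(i) by n/i, then
#' enforce monotonicity by a running minimum from the largest rank down,
#' capping at 1. Adjusted values are always >= the raw values.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return adjusted p-values in the original order.
#' @export
bh_fdr <- function(pvals) {
  n <- length(pvals)
  if (n == 0) stop("empty p-value vector")
  if (any(!is.finite(pvals)) || any(pvals <= 0 | pvals > 1)) {
    stop("p-values must be in (0, 1]")
  }
  o <- order(pvals)
  adj <- pvals[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

#' Univariable MR screen across a catalogue of relative outcomes
#'
#' Runs IVW of one exposure instrument against every available outcome
#' and adjusts the IVW p-values by Benjamini-Hochberg across the family
#' of available slots. Slots whose outcome statistics are missing are
#' marked unavailable and excluded from the FDR family with a message.
#'
#' @param exposure_stats a `summary_stats` for the exposure.
#' @param instrument the exposure's `instrument_set`.
#' @param outcome_stats named list of `summary_stats`, names matching
#'   catalogue slots (`relative.outcome`).
#' @param catalog outcome catalogue (default [outcome_catalog()]).
#' @param q FDR level (default 0.05).
#' @return object of class `screen_result`: data.frame of per-slot IVW
#'   estimates with raw and FDR-adjusted p and a pass flag.
#' @export
univariable_screen <- function(exposure_stats, instrument, outcome_stats,
                               catalog = outcome_catalog(), q = 0.05) {
  avail <- catalog$slot %in% names(outcome_stats)
  if (any(!avail)) {
    message(sum(!avail), " outcome slot(s) unavailable; excluded from the FDR family")
  }
  rows <- lapply(catalog$slot[avail], function(slot) {
    h <- harmonise(exposure_stats, outcome_stats[[slot]],
                   snp_subset = instrument)
    est <- ivw(h)
    est$slot <- slot
    est
  })
  res <- do.call(rbind, rows)
  res$p_adjusted <- bh_fdr(res$pval)
  res$pass <- res$p_adjusted < q
  res <- merge(catalog, as.data.frame(res), by = "slot", sort = FALSE)
  attr(res, "q") <- q
  class(res) <- c("screen_result", "data.frame")
  res
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("screen_result: %d outcome slots, %d pass at q=%g\n",
              nrow(x), sum(x$pass), attr(x, "q")))
  invisible(x)
}

#' Sensitivity estimator suite for one screened outcome
#'
#' Runs MR-Egger, weighted median and weighted mode alongside IVW on the
#' univariable harmonised set and, when a multivariable set is supplied,
#' MVMR-IVW and MVMR-Egger. Flags a directional disagreement between the
#' IVW and MR-Egger slopes (a hallmark of unbalanced horizontal
#' pleiotropy). Estimators whose minimum SNP count is not met are skipped
#' with a message.
#'
#' @param h univariable `harmonised_set` (K = 1).
#' @param h_mv optional multivariable `harmonised_set` (K >= 2).
#' @param n_boot,seed bootstrap controls for median/mode.
#' @return data.frame of `mr_estimate` rows with attribute
#'   `sign_disagreement` (logical).
#' @export
sensitivity_suite <- function(h, h_mv = NULL, n_boot = 1000, seed = 1L) {
  out <- list(ivw(h))
  L <- length(h$beta_out)
  if (L >= 3) {
    out <- c(out, list(mr_egger(h),
                       weighted_median(h, n_boot, seed),
                       weighted_mode(h, n_boot = n_boot, seed = seed)))
  } else {
    message("fewer than 3 SNPs: Egger/median/mode skipped")
  }
  if (!is.null(h_mv)) {
    K <- ncol(h_mv$beta_exp)
    if (length(h_mv$beta_out) > K) out <- c(out, list(mvmr_ivw(h_mv)))
    if (length(h_mv$beta_out) > K + 1) out <- c(out, list(mvmr_egger(h_mv)))
  }
  res <- do.call(rbind, out)
  slope_ivw <- res$beta[res$method == "ivw"]
  slope_egger <- res$beta[res$method == "mr_egger"]
  flag <- length(slope_egger) == 1 && sign(slope_ivw) != sign(slope_egger)
  attr(res, "sign_disagreement") <- flag
  res
}

#' Bidirectional MR: disease liability to lipid trait
#'
#' The reverse direction of the screen: instruments for disease liability
#' against a lipid outcome, reported with the three univariable
#' estimators (IVW, MR-Egger, weighted median).
#'
#' @param h `harmonised_set` with the disease-liability exposure and the
#'   lipid outcome.
#' @param n_boot,seed bootstrap controls.
#' @return data.frame of `mr_estimate` rows (3 methods).
#' @export
bidirectional_mr <- function(h, n_boot = 1000, seed = 1L) {
  rbind(ivw(h),
        mr_egger(h)[1, ],
        weighted_median(h, n_boot, seed))
}

#' Proportion of an exposure effect mediated by intermediate traits
#'
#' total = univariable IVW of exposure on outcome; direct = the
#' exposure's MVMR estimate with the mediators included; proportion
#' mediated = 1 - direct/total. The CI comes from independent normal
#' resampling of the two estimates (seeded, default 10000 draws) - the
#' two-sample difference method's standard approximation. When the total
#' effect's CI spans zero the proportion is flagged unstable.
#'
#' @param total an `mr_estimate` row for the total effect (or a
#'   univariable `harmonised_set`, in which case IVW is run).
#' @param direct an `mr_estimate` row for the direct effect (or a
#'   multivariable `harmonised_set` plus `exposure` name).
#' @param exposure exposure name used to pick the MVMR row.
#' @param n_draws resampling draws.
#' @param seed integer seed.
#' @return list with `proportion`, `lo95`, `hi95`, `total`, `direct`,
#'   `unstable`.
#' @export
mediation_proportion <- function(total, direct, exposure = NULL,
                                 n_draws = 10000, seed = 1L) {
  if (inherits(total, "harmonised_set")) total <- ivw(total)
  if (inherits(direct, "harmonised_set")) {
    direct <- mvmr_ivw(direct)
  }
  if (!is.null(exposure)) direct <- direct[direct$exposure == exposure, ]
  if (nrow(direct) > 1) direct <- direct[1, ]
  if (total$beta == 0) stop("total effect is zero; proportion undefined")
  unstable <- total$lo95 < 0 && total$hi95 > 0
  prop <- 1 - direct$beta / total$beta
  set.seed(stream_seed(seed, "mediation"))
  td <- stats::rnorm(n_draws, total$beta, total$se)
  dd <- stats::rnorm(n_draws, direct$beta, direct$se)
  draws <- 1 - dd / td
  list(proportion = prop,
       lo95 = unname(stats::quantile(draws, 0.025)),
       hi95 = unname(stats::quantile(draws, 0.975)),
       total = total$beta, direct = direct$beta,
       unstable = unstable)
}

#' Convert a years-of-life estimate to months for reporting
#'
#' Multiplies by 12 and rounds to one decimal for display; the unrounded
#' value is kept in the `"unrounded"` attribute.
#'
#' @param years estimate in years (scale `"years"`).
#' @return months, rounded to 1 decimal.
#' @export
years_to_months <- function(years) {
  m <- years * 12
  structure(round(m, 1), unrounded = m)
}

#' Ratio of a family-proxy estimate to the direct estimate
#'
#' proxy/direct with a delta-method SE. First-degree relatives share half
#' their alleles, so a proxy-design estimate is expected to be about half
#' the direct estimate; sibling any-affected aggregation dilutes further.
#' Flagged when the direct estimate's CI spans zero.
#'
#' @param proxy,direct `mr_estimate` rows (proxy design and direct
#'   design).
#' @return list with `ratio`, `se`, `flagged`.
#' @export
dilution_ratio <- function(proxy, direct) {
  if (direct$beta == 0) stop("direct estimate is zero; ratio undefined")
  r <- proxy$beta / direct$beta
  se <- sqrt(proxy$se^2 / direct$beta^2 +
               proxy$beta^2 * direct$se^2 / direct$beta^4)
  list(ratio = r, se = se,
       flagged = direct$lo95 < 0 && direct$hi95 > 0)
}

#' Sex-stratified instrument derivation and MR
#'
#' Re-runs the exposure GWAS within one sex stratum of the index
#' individuals, re-derives the instrument by clumping, and estimates IVW
#' against the supplied outcome statistics; returned side by side with
#' the sex-agnostic result for comparison. Intended for sex-limited
#' outcomes (breast cancer in mothers/sisters, prostate cancer in
#' fathers/brothers).
#'
#' @param cohort a `trio_cohort` (index sex in `cohort$sex`).
#' @param trait index-person exposure vector (pre-normalisation values
#'   are re-normalised within stratum).
#' @param outcome_stats `summary_stats` for the (sex-limited) outcome.
#' @param sex stratum to use: 0 = female, 1 = male.
#' @param panel reference panel (defaults to the cohort's index panel).
#' @param p_thresh,r2_thresh,window_kb clumping parameters.
#' @param trait_label exposure label.
#' @return list with `stratified` and `pooled` `mr_estimate` rows and the
#'   two instrument sets.
#' @export
sex_stratified_run <- function(cohort, trait, outcome_stats, sex,
                               panel = cohort_panel(cohort),
                               p_thresh = 5e-8, r2_thresh = 0.001,
                               window_kb = 1000, trait_label = "trait") {
  stopifnot(sex %in% c(0L, 1L))
  idx <- cohort$sex == sex
  if (sum(idx) < 50) stop("stratum too small for GWAS")
  run_one <- function(rows) {
    gw <- run_gwas_quantitative(cohort$offspring[rows, , drop = FALSE],
                                inverse_rank_normalise(trait[rows]),
                                cohort$snp_meta, trait_label = trait_label)
    instr <- ld_clump(gw, panel, p_thresh, r2_thresh, window_kb)
    if (nrow(instr$beta) == 0) return(list(gwas = gw, instrument = instr, est = NULL))
    h <- harmonise(gw, outcome_stats, snp_subset = instr)
    list(gwas = gw, instrument = instr, est = ivw(h))
  }
  strat <- run_one(which(idx))
  pooled <- run_one(seq_along(trait))
  list(stratified = strat$est, pooled = pooled$est,
       stratified_instrument = strat$instrument,
       pooled_instrument = pooled$instrument)
}

# ---- bundled descriptive counts ----------------------------------------

#' Descriptive counts of self-reported outcomes in first-degree relatives
#'
#' The bundled reference table of raw numerators and denominators from
#' the UK Biobank family-history questionnaire (cases and respondents per
#' relative and outcome, plus parents-alive counts and mean age at
#' death). Prevalences are recomputed from the counts, never stored.
#'
#' @return data.frame with columns relative, outcome, cases, total.
#' @export
relative_outcome_counts <- function() {
  path <- system.file("extdata", "relative_outcome_counts.tsv",
                      package = "kinmr")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Prevalence (in percent) from the bundled descriptive counts
#'
#' @param relative `"father"`, `"mother"` or `"sibling"`.
#' @param outcome outcome name, e.g. `"heart_disease"`, `"alive"`.
#' @param counts counts table (default the bundled one).
#' @return percentage, cases/total * 100.
#' @export
relative_prevalence <- function(relative, outcome,
                                counts = relative_outcome_counts()) {
  row <- counts[counts$relative == relative & counts$outcome == outcome, ]
  if (nrow(row) != 1) stop("no unique count row for ", relative, "/", outcome)
  100 * row$cases / row$total
}
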