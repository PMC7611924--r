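# Harmonisation and the MR estimator suite.
#
# Conventions follow the widely used two-sample MR software stack:
# multiplicative random-effects scaling of IVW / Egger standard errors
# (never deflated below 1), Wald-type normal CIs and p-values, and
# first-order standard errors for per-SNP ratios.

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) COMPLEMENT[a1] == a2

# ---- harmonisation ------------------------------------------------------

#' Align exposure and outcome summary statistics to one effect allele
#'
#' All datasets are aligned to the first exposure's effect allele. For
#' each SNP, a dataset whose alleles are swapped has its beta sign
#' flipped and eaf complemented; alleles that only match after strand
#' complementation are complemented first. Palindromic SNPs (A/T or C/G)
#' are ambiguous under strand flips: they are kept when both allele
#' frequencies fall outside `[palindrome_eaf_limit, 1 - palindrome_eaf_limit]`
#' (frequency agreement then resolves the orientation: discordant sides
#' imply a flip), and dropped otherwise, including when either eaf is
#' missing. Irreconcilable allele sets are dropped with a logged reason.
#'
#' @param exposures a `summary_stats`, an `instrument_set` plus exposure
#'   stats, or a list of `summary_stats` (one per exposure). When an
#'   `instrument_set` is given as `snp_subset`, only its SNPs are used.
#' @param outcome a `summary_stats` for the outcome.
#' @param snp_subset optional `instrument_set` restricting the SNP list.
#' @param palindrome_eaf_limit ambiguity half-window (default 0.42, i.e.
#'   drop when either eaf is in [0.42, 0.58]).
#' @return an object of class `harmonised_set`: `snps`, `beta_exp`/`se_exp`
#'   (L x K), `beta_out`/`se_out`, `log` (per-SNP action and reason),
#'   `outcome_scale`, `exposures`, `outcome`.
#' @export
harmonise <- function(exposures, outcome, snp_subset = NULL,
                      palindrome_eaf_limit = 0.42) {
  if (inherits(exposures, "summary_stats")) exposures <- list(exposures)
  stopifnot(length(exposures) >= 1, inherits(outcome, "summary_stats"))
  lim <- palindrome_eaf_limit

  ref <- as.data.frame(exposures[[1]])
  shared <- Reduce(intersect, c(lapply(exposures, `[[`, "SNP"),
                                list(outcome$SNP)))
  if (!is.null(snp_subset)) shared <- intersect(shared, snp_subset$snps$SNP)
  if (length(shared) == 0) stop("no shared SNPs between exposures and outcome")
  ref <- ref[match(shared, ref$SNP), , drop = FALSE]

  # align one dataset to the reference orientation; returns aligned rows
  # plus a status vector
  align_one <- function(d) {
    d <- as.data.frame(d)[match(shared, d$SNP), , drop = FALSE]
    status <- rep("kept", length(shared))
    for (i in seq_along(shared)) {
      ea <- d$effect_allele[i]; oa <- d$other_allele[i]
      rea <- ref$effect_allele[i]; roa <- ref$other_allele[i]
      pal <- is_palindromic(rea, roa)
      same <- ea == rea && oa == roa
      swap <- ea == roa && oa == rea
      if (!same && !swap) {
        # try strand complement
        ea2 <- unname(COMPLEMENT[ea]); oa2 <- unname(COMPLEMENT[oa])
        if (identical(ea2, rea) && identical(oa2, roa)) { same <- TRUE
        } else if (identical(ea2, roa) && identical(oa2, rea)) { swap <- TRUE
        } else { status[i] <- "dropped:alleles"; next }
      }
      if (pal) {
        f1 <- ref$eaf[i]; f2 <- d$eaf[i]
        if (is.na(f1) || is.na(f2) ||
            (f1 >= lim && f1 <= 1 - lim) || (f2 >= lim && f2 <= 1 - lim)) {
          status[i] <- "dropped:palindromic"
          next
        }
        # orientation decided by frequency agreement, not allele letters
        flip <- (f1 < 0.5) != (f2 < 0.5)
        if (flip) {
          d$beta[i] <- -d$beta[i]
          d$eaf[i] <- 1 - d$eaf[i]
          status[i] <- "palindromic_flipped"
        } else if (status[i] == "kept") status[i] <- "kept"
        next
      }
      if (swap) {
        d$beta[i] <- -d$beta[i]
        d$eaf[i] <- 1 - d$eaf[i]
        status[i] <- "flipped"
      }
    }
    list(d = d, status = status)
  }

  aligned <- lapply(exposures[-1], align_one)
  out_al <- align_one(outcome)
  drop <- grepl("^dropped", out_al$status)
  for (a in aligned) drop <- drop | grepl("^dropped", a$status)

  log <- data.frame(SNP = shared, action = out_al$status,
                    stringsAsFactors = FALSE)
  for (a in aligned) {
    log$action[grepl("^dropped", a$status)] <-
      a$status[grepl("^dropped", a$status)]
  }
  keep <- !drop
  if (!any(keep)) stop("all SNPs dropped during harmonisation")

  K <- length(exposures)
  traits <- vapply(exposures, attr, character(1), "trait")
  beta_exp <- matrix(NA_real_, sum(keep), K, dimnames = list(NULL, traits))
  se_exp <- beta_exp
  beta_exp[, 1] <- ref$beta[keep]; se_exp[, 1] <- ref$se[keep]
  if (K > 1) {
    for (k in 2:K) {
      beta_exp[, k] <- aligned[[k - 1]]$d$beta[keep]
      se_exp[, k] <- aligned[[k - 1]]$d$se[keep]
    }
  }
  structure(list(snps = ref$SNP[keep],
                 beta_exp = beta_exp, se_exp = se_exp,
                 beta_out = out_al$d$beta[keep],
                 se_out = out_al$d$se[keep],
                 log = log,
                 outcome_scale = attr(outcome, "scale"),
                 exposures = traits,
                 outcome = attr(outcome, "trait")),
            class = "harmonised_set")
}

#' Construct a harmonised set directly from numeric effects
#'
#' Convenience constructor for already-aligned effects (simulation and
#' testing); no allele bookkeeping is performed.
#'
#' @param beta_exp L x K matrix (or vector) of SNP-exposure effects.
#' @param se_exp matching SEs.
#' @param beta_out,se_out SNP-outcome effects and SEs.
#' @param outcome_scale `"sd-units"`, `"log-odds"`, `"years"` or
#'   `"linear-probability"`.
#' @param exposures,outcome labels.
#' @return a `harmonised_set`.
#' @export
harmonised_set <- function(beta_exp, se_exp, beta_out, se_out,
                           outcome_scale = "sd-units",
                           exposures = NULL, outcome = "outcome") {
  beta_exp <- as.matrix(beta_exp); se_exp <- as.matrix(se_exp)
  if (is.null(exposures)) {
    exposures <- colnames(beta_exp)
    if (is.null(exposures)) exposures <- paste0("exposure", seq_len(ncol(beta_exp)))
  }
  colnames(beta_exp) <- colnames(se_exp) <- exposures
  stopifnot(nrow(beta_exp) == length(beta_out),
            length(beta_out) == length(se_out))
  structure(list(snps = paste0("snp", seq_along(beta_out)),
                 beta_exp = beta_exp, se_exp = se_exp,
                 beta_out = as.numeric(beta_out),
                 se_out = as.numeric(se_out),
                 log = NULL, outcome_scale = outcome_scale,
                 exposures = exposures, outcome = outcome),
            class = "harmonised_set")
}

#' @export
print.harmonised_set <- function(x, ...) {
  cat(sprintf("harmonised_set: %d SNPs, exposures [%s] -> %s (%s)\n",
              length(x$snps), paste(x$exposures, collapse = ", "),
              x$outcome, x$outcome_scale))
  invisible(x)
}

# ---- estimate container -------------------------------------------------

# one result row; OR columns filled only on the log-odds scale
mr_estimate <- function(method, exposure, outcome, nsnp, beta, se, scale,
                        Q = NA_real_, Q_df = NA_integer_) {
  lo <- beta - 1.96 * se
  hi <- beta + 1.96 * se
  p <- 2 * stats::pnorm(-abs(beta / se))
  d <- data.frame(outcome = outcome, exposure = exposure, method = method,
                  nsnp = nsnp, beta = beta, se = se, lo95 = lo, hi95 = hi,
                  pval = p, scale = scale, Q = Q, Q_df = Q_df,
                  or = NA_real_, or_lo = NA_real_, or_hi = NA_real_,
                  stringsAsFactors = FALSE)
  if (identical(scale, "log-odds")) {
    d$or <- exp(beta); d$or_lo <- exp(lo); d$or_hi <- exp(hi)
  }
  class(d) <- c("mr_estimate", "data.frame")
  d
}

#' Express a log-odds MR estimate as an odds ratio
#'
#' OR = exp(beta) with CI exp(beta +/- 1.96 se). Errors if the estimate is
#' not on the log-odds scale.
#'
#' @param est an `mr_estimate` row (or data.frame of rows).
#' @return the same rows with or/or_lo/or_hi filled.
#' @export
to_odds_ratio <- function(est) {
  if (!all(est$scale == "log-odds")) stop("estimate is not on the log-odds scale")
  est$or <- exp(est$beta)
  est$or_lo <- exp(est$lo95)
  est$or_hi <- exp(est$hi95)
  est
}

# ---- estimators ---------------------------------------------------------

#' Wald ratio for a single SNP
#'
#' ratio = beta_out / beta_exp with the first-order standard error
#' se_out / |beta_exp|.
#'
#' @param beta_exp,se_exp SNP-exposure effect and SE (beta_exp != 0).
#' @param beta_out,se_out SNP-outcome effect and SE.
#' @param scale outcome scale label.
#' @return an `mr_estimate` row.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out,
                       scale = "sd-units") {
  if (beta_exp == 0) stop("beta_exp must be non-zero")
  mr_estimate("wald_ratio", "exposure", "outcome", 1L,
              beta_out / beta_exp, se_out / abs(beta_exp), scale)
}

#' Inverse-variance-weighted MR estimate
#'
#' The slope of the no-intercept regression of SNP-outcome effects on
#' SNP-exposure effects with weights 1/se_out^2; equivalently the
#' inverse-variance meta-analysis of per-SNP Wald ratios. Standard errors
#' use multiplicative random-effects scaling max(1, sqrt(Q/(L-1))) for
#' L >= 2 (never deflated below the fixed-effect SE). With a single SNP
#' the estimate reduces exactly to the Wald ratio.
#'
#' @param h a `harmonised_set` with one exposure.
#' @return an `mr_estimate` row.
#' @export
ivw <- function(h) {
  stopifnot(inherits(h, "harmonised_set"), ncol(h$beta_exp) == 1)
  L <- length(h$beta_out)
  if (L == 0) stop("no SNPs to estimate from")
  bx <- h$beta_exp[, 1]; by <- h$beta_out
  w <- 1 / h$se_out^2
  bhat <- sum(w * bx * by) / sum(w * bx^2)
  se_fixed <- sqrt(1 / sum(w * bx^2))
  Q <- sum(w * (by - bhat * bx)^2)
  scal <- if (L >= 2) max(1, sqrt(Q / (L - 1))) else 1
  mr_estimate("ivw", h$exposures[1], h$outcome, L, bhat, se_fixed * scal,
              h$outcome_scale, Q, L - 1L)
}

#' MR-Egger regression
#'
#' SNPs are oriented so all exposure effects are positive, then the
#' outcome effects are regressed on the exposure effects with an
#' intercept, weights 1/se_out^2. The slope is the causal estimate; the
#' intercept estimates average directional pleiotropy. SEs use
#' multiplicative random-effects scaling max(1, sqrt(Q/(L-2))).
#'
#' @param h a `harmonised_set` with one exposure and L >= 3 SNPs.
#' @return two `mr_estimate` rows: method `"mr_egger"` (slope) and
#'   `"mr_egger_intercept"`.
#' @export
mr_egger <- function(h) {
  stopifnot(inherits(h, "harmonised_set"), ncol(h$beta_exp) == 1)
  L <- length(h$beta_out)
  if (L < 3) stop("MR-Egger needs at least 3 SNPs")
  flip <- sign(h$beta_exp[, 1]); flip[flip == 0] <- 1
  bx <- h$beta_exp[, 1] * flip
  by <- h$beta_out * flip
  w <- 1 / h$se_out^2
  fit <- stats::lm(by ~ bx, weights = w)
  cf <- stats::coef(summary(fit))
  Q <- sum(w * stats::residuals(fit)^2)
  scal <- max(1, sqrt(Q / (L - 2)))
  rbind(
    mr_estimate("mr_egger", h$exposures[1], h$outcome, L,
                cf["bx", "Estimate"], cf["bx", "Std. Error"] * scal,
                h$outcome_scale, Q, L - 2L),
    mr_estimate("mr_egger_intercept", h$exposures[1], h$outcome, L,
                cf["(Intercept)", "Estimate"],
                cf["(Intercept)", "Std. Error"] * scal,
                h$outcome_scale, Q, L - 2L)
  )
}

# per-SNP ratios and their first-order SEs
snp_ratios <- function(h) {
  bx <- h$beta_exp[, 1]
  list(r = h$beta_out / bx, se = h$se_out / abs(bx))
}

weighted_median_point <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

# parametric bootstrap SE shared by median and mode estimators
ratio_bootstrap_se <- function(h, point_fun, n_boot, seed) {
  set.seed(stream_seed(seed, "bootstrap"))
  L <- length(h$beta_out)
  est <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    bx <- stats::rnorm(L, h$beta_exp[, 1], h$se_exp[, 1])
    by <- stats::rnorm(L, h$beta_out, h$se_out)
    bx[bx == 0] <- 1e-12
    est[b] <- point_fun(by / bx, h$se_out / abs(bx))
  }
  stats::sd(est)
}

#' Weighted median MR estimate
#'
#' The weighted median of per-SNP Wald ratios: ratios are ordered, weights
#' (inverse ratio variance, normalised) accumulated, and the estimate is
#' the linear interpolation of the ratio at cumulative weight 0.5. It is
#' consistent when SNPs carrying at least half the weight are valid
#' instruments. The SE comes from a seeded parametric bootstrap
#' (resampling beta_exp and beta_out from their sampling distributions).
#'
#' @param h a `harmonised_set` with one exposure and L >= 3 SNPs.
#' @param n_boot bootstrap draws (default 1000).
#' @param seed integer seed for the bootstrap.
#' @return an `mr_estimate` row.
#' @export
weighted_median <- function(h, n_boot = 1000, seed = 1L) {
  stopifnot(inherits(h, "harmonised_set"), ncol(h$beta_exp) == 1)
  L <- length(h$beta_out)
  if (L < 3) stop("weighted median needs at least 3 SNPs")
  rr <- snp_ratios(h)
  w <- 1 / rr$se^2
  point <- weighted_median_point(rr$r, w)
  se <- ratio_bootstrap_se(h, function(r, rse) weighted_median_point(r, 1 / rse^2),
                           n_boot, seed)
  mr_estimate("weighted_median", h$exposures[1], h$outcome, L, point, se,
              h$outcome_scale)
}

weighted_mode_point <- function(r, rse, w, bandwidth_factor) {
  if (length(unique(r)) == 1) return(r[1])
  s <- 0.9 * min(stats::sd(rse), stats::mad(rse)) * length(r)^(-1 / 5)
  if (!is.finite(s) || s <= 0) {
    s <- 0.9 * min(stats::sd(r), stats::mad(r)) * length(r)^(-1 / 5)
  }
  if (!is.finite(s) || s <= 0) s <- stats::sd(r) * length(r)^(-1 / 5)
  hband <- bandwidth_factor * s
  grid <- seq(min(r) - 3 * hband, max(r) + 3 * hband, length.out = 1024)
  dens <- vapply(grid, function(g)
    sum(w * stats::dnorm((g - r) / hband)), numeric(1))
  grid[which.max(dens)]
}

#' Weighted mode MR estimate
#'
#' The mode of a Gaussian-kernel-smoothed weighted density over per-SNP
#' Wald ratios (bandwidth = `bandwidth_factor` times a modified-Silverman
#' scale of the ratio SEs). Consistent when the largest homogeneous
#' cluster of SNPs is valid. Bootstrap SE as for [weighted_median()].
#'
#' @inheritParams weighted_median
#' @param bandwidth_factor multiplier on the Silverman bandwidth.
#' @return an `mr_estimate` row.
#' @export
weighted_mode <- function(h, bandwidth_factor = 1, n_boot = 1000, seed = 1L) {
  stopifnot(inherits(h, "harmonised_set"), ncol(h$beta_exp) == 1)
  L <- length(h$beta_out)
  if (L < 3) stop("weighted mode needs at least 3 SNPs")
  rr <- snp_ratios(h)
  w <- (1 / rr$se^2) / sum(1 / rr$se^2)
  point <- weighted_mode_point(rr$r, rr$se, w, bandwidth_factor)
  se <- ratio_bootstrap_se(h, function(r, rse) {
    wi <- (1 / rse^2) / sum(1 / rse^2)
    weighted_mode_point(r, rse, wi, bandwidth_factor)
  }, n_boot, seed)
  mr_estimate("weighted_mode", h$exposures[1], h$outcome, L, point, se,
              h$outcome_scale)
}

#' Multivariable IVW
#'
#' No-intercept weighted multiple regression of SNP-outcome effects on
#' the L x K matrix of SNP-exposure effects (weights 1/se_out^2),
#' returning each exposure's direct effect holding the others constant.
#' An exposure whose effect column is aliased (e.g. identically zero)
#' gets an NA estimate with a warning; SEs use the same multiplicative
#' random-effects scaling as univariable IVW with L - K degrees of
#' freedom.
#'
#' @param h a `harmonised_set` with K >= 2 exposures and L > K SNPs.
#' @return `mr_estimate` rows, one per (estimable) exposure.
#' @export
mvmr_ivw <- function(h) {
  stopifnot(inherits(h, "harmonised_set"))
  K <- ncol(h$beta_exp)
  L <- length(h$beta_out)
  if (K < 2) stop("mvmr_ivw needs at least 2 exposures; use ivw()")
  if (L <= K) stop("need more SNPs than exposures")
  X <- h$beta_exp
  w <- 1 / h$se_out^2
  fit <- stats::lm(h$beta_out ~ 0 + X, weights = w)
  cf <- stats::coef(fit)
  if (anyNA(cf)) warning("rank-deficient exposure matrix; aliased exposures set to NA")
  sm <- stats::coef(summary(fit))
  df_used <- sum(!is.na(cf))
  Q <- sum(w * stats::residuals(fit)^2)
  scal <- max(1, sqrt(Q / (L - df_used)))
  rows <- lapply(seq_len(K), function(k) {
    nm <- paste0("X", colnames(X)[k])
    if (is.na(cf[k])) {
      mr_estimate("mvmr_ivw", h$exposures[k], h$outcome, L, NA_real_,
                  NA_real_, h$outcome_scale, Q, L - df_used)
    } else {
      mr_estimate("mvmr_ivw", h$exposures[k], h$outcome, L,
                  sm[nm, "Estimate"], sm[nm, "Std. Error"] * scal,
                  h$outcome_scale, Q, L - df_used)
    }
  })
  do.call(rbind, rows)
}

#' Multivariable MR-Egger
#'
#' Rows are sign-flipped so the orienting trait's effects are all
#' positive, then the outcome effects are regressed on all exposures'
#' effects with an intercept (weights 1/se_out^2). The intercept captures
#' average directional pleiotropy under that orientation.
#'
#' @param h a `harmonised_set` with K >= 2 exposures and L > K + 1 SNPs.
#' @param orient_trait exposure name or index used for orientation.
#' @return `mr_estimate` rows per exposure plus an
#'   `"mvmr_egger_intercept"` row.
#' @export
mvmr_egger <- function(h, orient_trait = 1) {
  stopifnot(inherits(h, "harmonised_set"))
  K <- ncol(h$beta_exp)
  L <- length(h$beta_out)
  if (K < 2) stop("mvmr_egger needs at least 2 exposures")
  if (L <= K + 1) stop("need more SNPs than exposures + 1")
  if (is.character(orient_trait)) {
    orient_trait <- match(orient_trait, h$exposures)
    if (is.na(orient_trait)) stop("orient_trait not among the exposures")
  }
  flip <- sign(h$beta_exp[, orient_trait]); flip[flip == 0] <- 1
  X <- h$beta_exp * flip
  by <- h$beta_out * flip
  w <- 1 / h$se_out^2
  fit <- stats::lm(by ~ X, weights = w)
  sm <- stats::coef(summary(fit))
  Q <- sum(w * stats::residuals(fit)^2)
  scal <- max(1, sqrt(Q / (L - K - 1)))
  rows <- lapply(seq_len(K), function(k) {
    mr_estimate("mvmr_egger", h$exposures[k], h$outcome, L,
                sm[paste0("X", colnames(h$beta_exp)[k]), "Estimate"],
                sm[paste0("X", colnames(h$beta_exp)[k]), "Std. Error"] * scal,
                h$outcome_scale, Q, L - K - 1L)
  })
  rows <- do.call(rbind, rows)
  rbind(rows,
        mr_estimate("mvmr_egger_intercept", h$exposures[orient_trait],
                    h$outcome, L, sm["(Intercept)", "Estimate"],
                    sm["(Intercept)", "Std. Error"] * scal,
                    h$outcome_scale, Q, L - K - 1L))
}
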