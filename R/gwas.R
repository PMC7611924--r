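# Per-SNP association scans and instrument construction.
#
# The association engine is ordinary least squares. The synthetic cohort
# has no relatedness among index individuals, so the mixed-model machinery
# used on biobank-scale data is unnecessary here; OLS with covariate
# residualisation (Frisch-Waugh) gives identical per-SNP estimates at a
# fraction of the cost.

#' Inverse rank-normalise a trait
#'
#' Blom transform: Phi^-1((rank - 3/8) / (n + 1/4)) with average ranks for
#' ties, computed over finite values (NAs are preserved in place). The
#' result has mean ~0, SD ~1 and is invariant to monotone transforms of
#' the input.
#'
#' @param x numeric vector with at least 2 finite values.
#' @return numeric vector of the same length.
#' @export
inverse_rank_normalise <- function(x) {
  ok <- is.finite(x)
  if (sum(ok) < 2) stop("need at least 2 finite values")
  v <- x[ok]
  if (length(unique(v)) == 1) stop("all values identical; rank transform undefined")
  r <- rank(v, ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[ok] <- stats::qnorm((r - 3 / 8) / (length(v) + 1 / 4))
  out
}

# internal: vectorised per-SNP OLS after residualising on covariates.
# Returns beta, se, pval (t-reference), df. Covariates always include an
# intercept; duplicate/collinear covariate columns are an error.
snp_ols <- function(dosages, y, covariates = NULL) {
  n <- length(y)
  C <- cbind(`(Intercept)` = rep(1, n), covariates)
  if (qr(C)$rank < ncol(C)) stop("covariate matrix is rank deficient")
  # Frisch-Waugh: residualise trait and every dosage column on C
  Cq <- qr.Q(qr(C))
  yr <- y - Cq %*% crossprod(Cq, y)
  Xr <- dosages - Cq %*% crossprod(Cq, dosages)
  sxx <- colSums(Xr^2)
  beta <- as.numeric(crossprod(Xr, yr)) / sxx
  df <- n - ncol(C) - 1L
  rss <- sum(yr^2) - beta^2 * sxx   # per-SNP residual SS
  sigma2 <- pmax(rss, 0) / df
  se <- sqrt(sigma2 / sxx)
  tval <- beta / se
  pval <- 2 * stats::pt(-abs(tval), df)
  list(beta = beta, se = se, pval = pval, df = df)
}

# internal: build a summary_stats data.frame
make_summary_stats <- function(snp_meta, eaf, beta, se, pval, n,
                               trait, scale) {
  out <- data.frame(SNP = snp_meta$SNP, chr = snp_meta$chr,
                    pos = snp_meta$pos,
                    effect_allele = snp_meta$A1, other_allele = snp_meta$A2,
                    eaf = eaf, beta = beta, se = se, pval = pval, n = n,
                    stringsAsFactors = FALSE)
  structure(out, trait = trait, scale = scale,
            class = c("summary_stats", "data.frame"))
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("summary_stats: trait=%s scale=%s, %d SNPs\n",
              attr(x, "trait"), attr(x, "scale"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x)))
  invisible(x)
}

#' GWAS of a quantitative trait by per-SNP least squares
#'
#' Regresses the (already normalised) trait on each SNP dosage plus the
#' covariates, one SNP at a time. Monomorphic SNPs are excluded with a
#' message. P-values use the t reference with the OLS degrees of freedom.
#'
#' @param dosages n x m dosage matrix (0/1/2 effect-allele counts).
#' @param trait numeric trait vector of length n.
#' @param snp_meta data.frame with SNP, chr, pos, A1, A2 matching columns
#'   of `dosages`.
#' @param covariates optional numeric covariate matrix (full rank).
#' @param trait_label label carried on the result.
#' @return a `summary_stats` object (scale `"sd-units"`).
#' @export
run_gwas_quantitative <- function(dosages, trait, snp_meta,
                                  covariates = NULL,
                                  trait_label = "trait") {
  stopifnot(nrow(dosages) == length(trait), ncol(dosages) == nrow(snp_meta))
  mono <- apply(dosages, 2, function(d) length(unique(d)) < 2)
  if (any(mono)) {
    message(sum(mono), " monomorphic SNP(s) excluded")
    dosages <- dosages[, !mono, drop = FALSE]
    snp_meta <- snp_meta[!mono, , drop = FALSE]
  }
  fit <- snp_ols(dosages, trait, covariates)
  make_summary_stats(snp_meta, eaf = colMeans(dosages) / 2,
                     beta = fit$beta, se = fit$se, pval = fit$pval,
                     n = length(trait), trait = trait_label,
                     scale = "sd-units")
}

#' GWAS of a binary outcome on the linear-probability scale
#'
#' Same least-squares engine as [run_gwas_quantitative()]; the estimand is
#' the change in outcome probability per effect allele
#' (scale `"linear-probability"`), convertible to log-odds with
#' [linear_to_logodds()].
#'
#' @inheritParams run_gwas_quantitative
#' @param status 0/1 outcome vector; needs at least 10 cases and 10
#'   controls.
#' @return a `summary_stats` object.
#' @export
run_gwas_binary <- function(dosages, status, snp_meta, covariates = NULL,
                            trait_label = "outcome") {
  if (!all(status %in% c(0L, 1L))) stop("status must be 0/1")
  if (sum(status == 1) < 10 || sum(status == 0) < 10) {
    stop("fewer than 10 cases or controls")
  }
  out <- run_gwas_quantitative(dosages, as.numeric(status), snp_meta,
                               covariates, trait_label)
  attr(out, "scale") <- "linear-probability"
  attr(out, "case_fraction") <- mean(status)
  out
}

#' Convert linear-probability effects to the log-odds scale
#'
#' Divides beta and SE by mu(1-mu), the binomial variance at the case
#' fraction mu: the first-order equivalence between a linear-probability
#' slope and a logistic slope at prevalence mu. Z-scores and p-values are
#' unchanged.
#'
#' @param stats a `summary_stats` with scale `"linear-probability"`.
#' @param case_fraction observed case fraction, strictly inside (0,1);
#'   defaults to the value recorded by [run_gwas_binary()].
#' @return a `summary_stats` with scale `"log-odds"`.
#' @export
linear_to_logodds <- function(stats, case_fraction = attr(stats, "case_fraction")) {
  if (!identical(attr(stats, "scale"), "linear-probability")) {
    stop("input scale must be linear-probability")
  }
  if (is.null(case_fraction) || case_fraction <= 0 || case_fraction >= 1) {
    stop("case_fraction must be in (0, 1)")
  }
  f <- case_fraction * (1 - case_fraction)
  stats$beta <- stats$beta / f
  stats$se <- stats$se / f
  attr(stats, "scale") <- "log-odds"
  stats
}

# ---- reference panel and clumping --------------------------------------

#' Reference panel for LD r-squared computation
#'
#' @param dosage n x m dosage matrix with columns named or ordered as
#'   `snp_meta$SNP`.
#' @param snp_meta data.frame with at least SNP, chr, pos.
#' @return object of class `reference_panel`.
#' @export
reference_panel <- function(dosage, snp_meta) {
  colnames(dosage) <- snp_meta$SNP
  structure(list(dosage = dosage, snp_meta = snp_meta),
            class = "reference_panel")
}

#' Reference panel from a simulated cohort's index individuals
#' @param cohort a `trio_cohort`.
#' @return a [reference_panel()].
#' @export
cohort_panel <- function(cohort) {
  reference_panel(cohort$offspring, cohort$snp_meta)
}

panel_r2 <- function(panel, snp_a, snp_b) {
  stats::cor(panel$dosage[, snp_a], panel$dosage[, snp_b])^2
}

# internal greedy clump over a prepared candidate table (sorted by p with
# the chr/pos tie-break). Accept a SNP iff no previously accepted SNP on
# the same chromosome within +/- window has panel r2 >= r2_thresh.
greedy_clump <- function(cand, panel, r2_thresh, window_bp) {
  keep <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in keep) {
      if (cand$chr[j] == cand$chr[i] &&
          abs(cand$pos[j] - cand$pos[i]) <= window_bp &&
          panel_r2(panel, cand$SNP[j], cand$SNP[i]) >= r2_thresh) {
        ok <- FALSE
        break
      }
    }
    if (ok) keep <- c(keep, i)
  }
  cand[keep, , drop = FALSE]
}

order_candidates <- function(d) d[order(d$pval, d$chr, d$pos), , drop = FALSE]

# internal constructor; beta/se are L x K matrices with trait columns
new_instrument_set <- function(snps, beta, se, traits, p_thresh,
                               r2_thresh, window_kb) {
  mean_f <- apply(beta / se, 2, function(z) mean(z^2))
  obj <- structure(list(snps = snps, beta = beta, se = se, traits = traits,
                        p_thresh = p_thresh, r2_thresh = r2_thresh,
                        window_kb = window_kb, mean_f = mean_f,
                        conditional_f = NULL),
                   class = "instrument_set")
  if (length(traits) >= 2 && nrow(beta) > length(traits)) {
    obj$conditional_f <- vapply(seq_along(traits), function(k)
      conditional_f_statistic(obj, k), numeric(1))
    names(obj$conditional_f) <- traits
  }
  obj
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("instrument_set: %d SNPs x %d trait(s) [%s]\n",
              nrow(x$beta), length(x$traits), paste(x$traits, collapse = ", ")))
  cat("  mean F:", paste(sprintf("%s=%.1f", x$traits, x$mean_f), collapse = " "), "\n")
  if (!is.null(x$conditional_f)) {
    cat("  conditional F:",
        paste(sprintf("%s=%.1f", x$traits, x$conditional_f), collapse = " "), "\n")
  }
  invisible(x)
}

#' Greedy LD clumping of one trait's GWAS results
#'
#' SNPs passing the p-value threshold are sorted by ascending p (ties
#' broken by chromosome then position) and accepted greedily: a SNP is
#' kept iff no previously accepted SNP on the same chromosome lies within
#' the window with panel r-squared at or above `r2_thresh`. Defaults
#' encode the conventional genome-wide instrument rule:
#' p < 5e-8, r2 < 0.001, 1 Mb window.
#'
#' @param stats a `summary_stats`.
#' @param panel a [reference_panel()] covering the candidate SNPs.
#' @param p_thresh selection p-value threshold.
#' @param r2_thresh r-squared exclusion threshold.
#' @param window_kb flank distance in kb around an accepted SNP.
#' @return an `instrument_set` with a single trait column.
#' @export
ld_clump <- function(stats, panel, p_thresh = 5e-8, r2_thresh = 0.001,
                     window_kb = 1000) {
  cand <- as.data.frame(stats)[stats$pval < p_thresh, , drop = FALSE]
  if (nrow(cand) == 0) {
    warning("no SNP passes the p-value threshold; empty instrument set")
    empty <- matrix(numeric(0), 0, 1, dimnames = list(NULL, attr(stats, "trait")))
    return(new_instrument_set(cand[, c("SNP", "chr", "pos")], empty, empty,
                              attr(stats, "trait"), p_thresh, r2_thresh,
                              window_kb))
  }
  missing <- setdiff(cand$SNP, panel$snp_meta$SNP)
  if (length(missing) > 0) stop("panel does not cover: ", paste(missing, collapse = ","))
  kept <- greedy_clump(order_candidates(cand), panel, r2_thresh, window_kb * 1000)
  tr <- attr(stats, "trait")
  new_instrument_set(kept[, c("SNP", "chr", "pos")],
                     matrix(kept$beta, ncol = 1, dimnames = list(NULL, tr)),
                     matrix(kept$se, ncol = 1, dimnames = list(NULL, tr)),
                     tr, p_thresh, r2_thresh, window_kb)
}

#' Pooled clumping across several correlated traits
#'
#' For multivariable MR the GWAS results of all exposures are combined
#' before clumping so that one mutually independent SNP list instruments
#' every trait: per SNP the minimum p across traits decides selection and
#' ordering, and the retained SNPs carry each trait's beta/SE in the
#' effect matrix (a SNP selected by one trait still instruments all
#' columns).
#'
#' @param stats_list list of `summary_stats`, one per trait, sharing a
#'   SNP universe.
#' @inheritParams ld_clump
#' @return an `instrument_set` with K trait columns and conditional
#'   F-statistics.
#' @export
multivariable_clump <- function(stats_list, panel, p_thresh = 5e-8,
                                r2_thresh = 0.001, window_kb = 1000) {
  stopifnot(length(stats_list) >= 1)
  if (length(stats_list) == 1) return(ld_clump(stats_list[[1]], panel,
                                               p_thresh, r2_thresh, window_kb))
  traits <- vapply(stats_list, attr, character(1), "trait")
  shared <- Reduce(intersect, lapply(stats_list, `[[`, "SNP"))
  if (length(shared) == 0) stop("traits have disjoint SNP universes")
  aligned <- lapply(stats_list, function(s) {
    s <- as.data.frame(s)
    s[match(shared, s$SNP), , drop = FALSE]
  })
  minp <- do.call(pmin, lapply(aligned, `[[`, "pval"))
  cand <- aligned[[1]][, c("SNP", "chr", "pos")]
  cand$pval <- minp
  cand <- cand[cand$pval < p_thresh, , drop = FALSE]
  if (nrow(cand) == 0) warning("no SNP passes the p-value threshold; empty instrument set")
  kept <- greedy_clump(order_candidates(cand), panel, r2_thresh, window_kb * 1000)
  idx <- match(kept$SNP, shared)
  beta <- vapply(aligned, function(a) a$beta[idx], numeric(nrow(kept)))
  se <- vapply(aligned, function(a) a$se[idx], numeric(nrow(kept)))
  beta <- matrix(beta, nrow = nrow(kept), dimnames = list(NULL, traits))
  se <- matrix(se, nrow = nrow(kept), dimnames = list(NULL, traits))
  new_instrument_set(kept[, c("SNP", "chr", "pos")], beta, se, traits,
                     p_thresh, r2_thresh, window_kb)
}

# ---- instrument strength -----------------------------------------------

#' Mean F-statistic of an instrument set
#'
#' The squared-z approximation: F = mean((beta/se)^2) over the L
#' instrument SNPs for the trait.
#'
#' @param instrument an `instrument_set`.
#' @param trait trait name or column index (default first).
#' @return scalar F.
#' @export
mean_f_statistic <- function(instrument, trait = 1) {
  z <- instrument$beta[, trait] / instrument$se[, trait]
  mean(z^2)
}

#' Conditional F-statistic for one exposure in a multivariable set
#'
#' Instrument strength of the target exposure conditional on the others:
#' the target trait's SNP effects are regressed on the other traits'
#' SNP effects by weighted least squares (no intercept, weights
#' 1/se_target^2); the weighted residual sum of squares Q is scaled as
#' F = Q / (L - K + 1). A target collinear with the other exposures gives
#' F near 0 rather than an error. Cross-trait sampling covariance of the
#' SNP effects is assumed zero (effects estimated in non-overlapping or
#' effectively independent samples); this assumption is stated, not
#' corrected for.
#'
#' @param instrument an `instrument_set` with K >= 2 traits and L > K.
#' @param target trait name or column index.
#' @return scalar conditional F.
#' @export
conditional_f_statistic <- function(instrument, target) {
  K <- length(instrument$traits)
  L <- nrow(instrument$beta)
  if (K < 2) stop("conditional F needs at least 2 traits")
  if (L <= K) stop("conditional F needs more SNPs than traits")
  if (is.character(target)) target <- match(target, instrument$traits)
  y <- instrument$beta[, target]
  X <- instrument$beta[, -target, drop = FALSE]
  w <- 1 / instrument$se[, target]^2
  XtWX <- crossprod(X * sqrt(w))
  coef <- tryCatch(solve(XtWX, crossprod(X, w * y)),
                   error = function(e) NULL)
  if (is.null(coef)) return(0)
  resid <- y - X %*% coef
  Q <- sum(w * resid^2)
  Q / (L - K + 1)
}

# ---- region exclusion ---------------------------------------------------

#' Exclude SNPs in a genomic region
#'
#' Removes all SNPs with 1-based position inside `[start_bp, end_bp]` on
#' `chrom` (used e.g. to drop a pleiotropic gene region such as the APOE
#' locus before re-estimation).
#'
#' @param x a `summary_stats` or `instrument_set`.
#' @param chrom chromosome.
#' @param start_bp,end_bp inclusive 1-based interval bounds.
#' @return object of the same class with the region removed.
#' @export
region_exclude <- function(x, chrom, start_bp, end_bp) {
  if (start_bp > end_bp) stop("inverted interval")
  UseMethod("region_exclude")
}

#' @export
region_exclude.summary_stats <- function(x, chrom, start_bp, end_bp) {
  if (start_bp > end_bp) stop("inverted interval")
  inside <- x$chr == chrom & x$pos >= start_bp & x$pos <= end_bp
  out <- x[!inside, , drop = FALSE]
  if (nrow(out) == 0) warning("all SNPs removed by region exclusion")
  out
}

#' @export
region_exclude.instrument_set <- function(x, chrom, start_bp, end_bp) {
  if (start_bp > end_bp) stop("inverted interval")
  inside <- x$snps$chr == chrom & x$snps$pos >= start_bp & x$snps$pos <= end_bp
  if (all(inside)) warning("all SNPs removed by region exclusion")
  x$snps <- x$snps[!inside, , drop = FALSE]
  x$beta <- x$beta[!inside, , drop = FALSE]
  x$se <- x$se[!inside, , drop = FALSE]
  x$mean_f <- apply(x$beta / x$se, 2, function(z) mean(z^2))
  if (!is.null(x$conditional_f) && nrow(x$beta) > length(x$traits)) {
    x$conditional_f <- vapply(seq_along(x$traits), function(k)
      conditional_f_statistic(x, k), numeric(1))
    names(x$conditional_f) <- x$traits
  }
  x
}
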