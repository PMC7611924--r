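# Independent reference implementations and fixture builders used as
# oracles. These deliberately take the dumbest correct route (dense
# loops, explicit matrix algebra, base-R fits) so they share no code
# with the package paths they check.

# greedy clumping on a precomputed dense r2 matrix: sort by p (chr, pos
# tie-break), accept iff compatible with everything already accepted
oracle_clump <- function(p, chr, pos, r2mat, p_thresh, r2_thresh, window_bp) {
  idx <- which(p < p_thresh)
  idx <- idx[order(p[idx], chr[idx], pos[idx])]
  kept <- integer(0)
  for (i in idx) {
    bad <- FALSE
    for (j in kept) {
      if (chr[i] == chr[j] && abs(pos[i] - pos[j]) <= window_bp &&
          r2mat[i, j] >= r2_thresh) bad <- TRUE
    }
    if (!bad) kept <- c(kept, i)
  }
  sort(kept)
}

# explicit weighted-least-squares estimate via the normal equations
oracle_wls <- function(X, y, w, intercept = FALSE) {
  X <- as.matrix(X)
  if (intercept) X <- cbind(1, X)
  W <- diag(w, nrow = length(w))
  solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
}

# build a summary_stats object from explicit columns
toy_stats <- function(SNP, beta, se, eaf = 0.3, chr = 1,
                      pos = seq_along(SNP) * 2e6,
                      ea = "A", oa = "G", pval = NULL, n = 10000,
                      trait = "trait", scale = "sd-units") {
  k <- length(SNP)
  d <- data.frame(SNP = SNP, chr = rep_len(chr, k), pos = rep_len(pos, k),
                  effect_allele = rep_len(ea, k),
                  other_allele = rep_len(oa, k),
                  eaf = rep_len(eaf, k), beta = beta, se = se,
                  pval = if (is.null(pval)) 2 * pnorm(-abs(beta / se)) else pval,
                  n = rep_len(n, k), stringsAsFactors = FALSE)
  structure(d, trait = trait, scale = scale,
            class = c("summary_stats", "data.frame"))
}

# small deterministic cohort shared by several tests
small_cohort <- function(n = 500, m = 20, seed = 42, ...) {
  simulate_trios(sim_config(n_families = n, n_snps = m, seed = seed, ...))
}

# summary-level two-sample MR simulation with valid instruments:
# true SNP-exposure effects beta_x, causal effect theta, sampling noise
# from n_exp / n_out individuals at MAF 0.3
sim_summary_mr <- function(L = 50, n_exp = 20000, n_out = 20000,
                           theta = 0.3, h2 = 0.1, pleiotropy = 0) {
  vdos <- 2 * 0.3 * 0.7
  bsd <- sqrt(h2 / (L * vdos))
  bx_true <- rnorm(L, 0, bsd)
  se_x <- rep(sqrt(1 / (n_exp * vdos)), L)
  se_y <- rep(sqrt(1 / (n_out * vdos)), L)
  bx <- bx_true + rnorm(L, 0, se_x)
  by <- theta * bx_true + pleiotropy + rnorm(L, 0, se_y)
  harmonised_set(bx, se_x, by, se_y, exposures = "exposure")
}
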