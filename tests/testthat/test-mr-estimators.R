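# harmonisation and the estimator suite, against closed-form oracles

test_that("harmonisation rule table: identity, swap, strand, palindromes", {
  exp <- toy_stats(c("s1", "s2", "s3", "s4", "s5"),
                   beta = c(0.1, 0.2, 0.3, 0.4, 0.5),
                   se = rep(0.01, 5),
                   eaf = c(0.3, 0.3, 0.3, 0.10, 0.50))
  exp$effect_allele <- c("A", "A", "A", "A", "A")
  exp$other_allele <- c("G", "G", "G", "T", "T")  # s4, s5 palindromic
  out <- exp
  attr(out, "trait") <- "outcome"
  out$beta <- c(0.05, -0.05, 0.07, 0.08, 0.09)
  # s1 identical coding; s2 swapped alleles; s3 strand-complemented;
  # s4 palindromic with eaf on the other side; s5 palindromic ambiguous
  out$effect_allele <- c("A", "G", "T", "A", "A")
  out$other_allele <- c("G", "A", "C", "T", "T")
  out$eaf <- c(0.3, 0.7, 0.3, 0.88, 0.50)

  h <- harmonise(exp, out)
  expect_setequal(h$snps, c("s1", "s2", "s3", "s4"))  # s5 dropped
  i <- match(c("s1", "s2", "s3", "s4"), h$snps)
  expect_equal(h$beta_out[i], c(0.05, +0.05, 0.07, -0.08))
  log <- h$log
  expect_identical(log$action[log$SNP == "s2"], "flipped")
  expect_identical(log$action[log$SNP == "s4"], "palindromic_flipped")
  expect_identical(log$action[log$SNP == "s5"], "dropped:palindromic")

  # palindromic with missing eaf is dropped; irreconcilable alleles dropped
  out2 <- out
  out2$eaf[4] <- NA
  # A/C against the exposure's A/G cannot be resolved even by strand flips
  out2$effect_allele[1] <- "A"; out2$other_allele[1] <- "C"
  h2 <- harmonise(exp, out2)
  expect_setequal(h2$snps, c("s2", "s3"))
  expect_true("dropped:alleles" %in% h2$log$action)
})

test_that("identical coding harmonises to the identity", {
  exp <- toy_stats(paste0("s", 1:4), beta = c(0.1, -0.2, 0.3, 0.15),
                   se = rep(0.02, 4))
  out <- toy_stats(paste0("s", 1:4), beta = c(0.01, 0.02, -0.01, 0.04),
                   se = rep(0.01, 4), trait = "outcome")
  h <- harmonise(exp, out)
  expect_equal(h$beta_exp[, 1], exp$beta)
  expect_equal(h$beta_out, out$beta)
})

test_that("wald ratio arithmetic and invariances", {
  wr <- wald_ratio(0.2, 0.01, 0.1, 0.02)
  expect_equal(wr$beta, 0.5)
  expect_equal(wr$se, 0.1)
  expect_equal(wald_ratio(0.2, 0.01, 0, 0.02)$beta, 0)
  flip <- wald_ratio(-0.2, 0.01, -0.1, 0.02)
  expect_equal(flip$beta, 0.5)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.02), "non-zero")
})

test_that("IVW matches the closed-form oracle, reduces to Wald at L=1, exact fit has Q=0", {
  bx <- c(0.12, -0.08, 0.20, 0.15)
  sx <- rep(0.01, 4)
  by <- c(0.030, -0.028, 0.055, 0.050)
  sy <- c(0.01, 0.02, 0.015, 0.012)
  h <- harmonised_set(bx, sx, by, sy)
  est <- ivw(h)
  w <- 1 / sy^2
  expect_equal(est$beta, sum(w * bx * by) / sum(w * bx^2), tolerance = 1e-12)
  # L = 1 reduction
  h1 <- harmonised_set(bx[1], sx[1], by[1], sy[1])
  expect_equal(ivw(h1)$beta, by[1] / bx[1])
  expect_equal(ivw(h1)$se, sy[1] / abs(bx[1]))
  # exact proportionality: slope recovered, Q = 0, se not inflated
  h0 <- harmonised_set(bx, sx, 0.3 * bx, sy)
  e0 <- ivw(h0)
  expect_equal(e0$beta, 0.3, tolerance = 1e-12)
  expect_equal(e0$Q, 0, tolerance = 1e-20)
  expect_equal(e0$se, sqrt(1 / sum(w * bx^2)), tolerance = 1e-12)
})

test_that("IVW/Egger standard errors use multiplicative random effects, never below fixed", {
  set.seed(31)
  h <- sim_summary_mr(L = 30, theta = 0.3)
  # heterogeneous outcome noise
  h$beta_out <- h$beta_out + rnorm(30, 0, 0.05)
  est <- ivw(h)
  w <- 1 / h$se_out^2
  se_fixed <- sqrt(1 / sum(w * h$beta_exp[, 1]^2))
  expect_gte(est$se, se_fixed)
  expect_equal(est$se / se_fixed, max(1, sqrt(est$Q / 29)), tolerance = 1e-10)
})

test_that("MR-Egger recovers slope and pleiotropy intercept", {
  set.seed(33)
  h <- sim_summary_mr(L = 2000, n_exp = 1e6, n_out = 1e6, theta = 0.3)
  e <- mr_egger(h)
  slope <- e[e$method == "mr_egger", ]
  icept <- e[e$method == "mr_egger_intercept", ]
  expect_equal(slope$beta, 0.3, tolerance = 0.05)
  expect_lt(abs(icept$beta), 3 * icept$se + 1e-4)
  # constant directional pleiotropy appears in the intercept, slope unchanged
  h2 <- h
  flip <- sign(h$beta_exp[, 1])
  h2$beta_out <- h$beta_out + 0.02 * flip  # +c in the oriented frame
  e2 <- mr_egger(h2)
  expect_equal(e2$beta[e2$method == "mr_egger_intercept"], 0.02,
               tolerance = 0.003)
  expect_equal(e2$beta[e2$method == "mr_egger"],
               e$beta[e$method == "mr_egger"], tolerance = 1e-8)
  expect_error(mr_egger(harmonised_set(1:2 / 10, c(0.01, 0.01),
                                       1:2 / 100, c(0.01, 0.01))), "3 SNPs")
})

test_that("estimators are invariant to row order and joint sign flips", {
  set.seed(35)
  h <- sim_summary_mr(L = 25, theta = 0.25)
  perm <- sample(25)
  flip <- sample(c(-1, 1), 25, replace = TRUE)
  h2 <- harmonised_set((h$beta_exp[, 1] * flip)[perm], h$se_exp[perm, 1],
                       (h$beta_out * flip)[perm], h$se_out[perm])
  for (f in list(ivw,
                 function(x) mr_egger(x)[1, ],
                 function(x) weighted_median(x, n_boot = 50, seed = 2),
                 function(x) weighted_mode(x, n_boot = 50, seed = 2))) {
    expect_equal(f(h)$beta, f(h2)$beta, tolerance = 1e-10)
  }
})

test_that("weighted median: interpolated median, breakdown robustness, degenerate SE", {
  # equal weights, ratios {1,2,9} -> 2
  h <- harmonised_set(c(1, 1, 1), rep(0.01, 3), c(1, 2, 9), rep(0.5, 3))
  expect_equal(weighted_median(h, n_boot = 50, seed = 1)$beta, 2)
  # 50% contamination by weight stays near the valid value 0.3
  set.seed(37)
  L <- 40
  bx <- rnorm(L, 0.15, 0.02)
  sy <- rep(0.004, L)
  by <- 0.3 * bx
  bad <- 1:18  # 45% of SNPs wildly invalid
  by[bad] <- by[bad] + runif(18, 0.05, 0.2)
  hb <- harmonised_set(bx, rep(0.001, L), by, sy)
  expect_equal(weighted_median(hb, n_boot = 100, seed = 3)$beta, 0.3,
               tolerance = 0.05)
  # all ratios equal c -> estimate c; bootstrap se shrinks with se_out
  hc <- harmonised_set(c(0.1, 0.2, 0.3), rep(1e-6, 3),
                       0.7 * c(0.1, 0.2, 0.3), rep(1e-6, 3))
  wm <- weighted_median(hc, n_boot = 100, seed = 4)
  expect_equal(wm$beta, 0.7, tolerance = 1e-10)
  expect_lt(wm$se, 1e-4)
})

test_that("weighted mode finds the dominant cluster and is bandwidth-stable", {
  bx <- rep(1, 7)
  sx <- rep(0.01, 7)
  by <- c(0.41, 0.40, 0.39, 0.40, 0.405, 1.5, -0.8)
  sy <- c(rep(0.02, 5), 0.021, 0.019)
  h <- harmonised_set(bx, sx, by, sy)
  m1 <- weighted_mode(h, n_boot = 50, seed = 5)
  expect_equal(m1$beta, 0.4, tolerance = 0.02)
  m2 <- weighted_mode(h, bandwidth_factor = 0.5, n_boot = 50, seed = 5)
  expect_equal(m2$beta, m1$beta, tolerance = 0.02)
  # degenerate: all ratios identical
  hd <- harmonised_set(c(1, 1, 1), rep(0.01, 3), c(0.2, 0.2, 0.2), rep(0.01, 3))
  expect_equal(weighted_mode(hd, n_boot = 20, seed = 6)$beta, 0.2)
})

test_that("MVMR matches the normal-equations oracle; zero column reduces to univariable", {
  set.seed(41)
  L <- 6
  X <- cbind(e1 = rnorm(L, 0, 0.1), e2 = rnorm(L, 0, 0.1))
  sy <- runif(L, 0.005, 0.02)
  by <- 2 * X[, 1] - 1 * X[, 2] + rnorm(L, 0, 0.001)
  h <- harmonised_set(X, matrix(0.01, L, 2), by, sy)
  est <- mvmr_ivw(h)
  oracle <- oracle_wls(X, by, 1 / sy^2)
  expect_equal(est$beta, as.numeric(oracle), tolerance = 1e-12)
  # exact linear outcome: estimates (2, -1), residual ~ 0
  h0 <- harmonised_set(X, matrix(0.01, L, 2), 2 * X[, 1] - X[, 2], sy)
  e0 <- mvmr_ivw(h0)
  expect_equal(e0$beta, c(2, -1), tolerance = 1e-10)
  expect_lt(e0$Q[1], 1e-18)
  # aliased second exposure: exposure-1 estimate equals univariable IVW
  hz <- harmonised_set(cbind(e1 = X[, 1], e2 = rep(0, L)),
                       matrix(0.01, L, 2), by, sy)
  expect_warning(ez <- mvmr_ivw(hz), "rank-deficient")
  h1 <- harmonised_set(X[, 1], rep(0.01, L), by, sy, exposures = "e1")
  expect_equal(ez$beta[1], ivw(h1)$beta, tolerance = 1e-12)
  expect_true(is.na(ez$beta[2]))
})

test_that("MVMR-Egger: orientation, pleiotropy capture, estimable contract", {
  set.seed(43)
  L <- 200
  X <- cbind(e1 = rnorm(L, 0, 0.1), e2 = rnorm(L, 0, 0.1))
  sy <- rep(0.003, L)
  flip <- sign(X[, 1])
  by <- 0.5 * X[, 1] - 0.2 * X[, 2] + 0.01 * flip + rnorm(L, 0, sy)
  h <- harmonised_set(X, matrix(0.01, L, 2), by, sy)
  e <- mvmr_egger(h, orient_trait = "e1")
  expect_lt(abs(e$beta[e$method == "mvmr_egger_intercept"] - 0.01), 0.002)
  slopes <- e$beta[e$method == "mvmr_egger"]
  expect_equal(slopes, c(0.5, -0.2), tolerance = 0.02)
  # MVMR-IVW absorbs the directional pleiotropy into bias; Egger is closer
  ivw_slopes <- mvmr_ivw(h)$beta
  expect_lt(abs(slopes[1] - 0.5), abs(ivw_slopes[1] - 0.5))
  # changing orientation changes the intercept but stays well-defined
  e2 <- mvmr_egger(h, orient_trait = "e2")
  expect_true(all(is.finite(e2$beta)))
  expect_error(mvmr_egger(h, orient_trait = "nope"), "orient_trait")
})

test_that("odds-ratio conversion inverts the printed CI", {
  est <- kinmr:::mr_estimate("ivw", "apoB", "lifespan90", 100,
                             -0.9676, 0.274, "log-odds")
  o <- to_odds_ratio(est)
  expect_equal(o$or, 0.38, tolerance = 0.005)
  expect_equal(o$or_lo, 0.22, tolerance = 0.01)
  expect_equal(o$or_hi, 0.65, tolerance = 0.01)
  expect_equal(to_odds_ratio(kinmr:::mr_estimate("ivw", "x", "y", 5, 0,
                                                 0.1, "log-odds"))$or, 1)
  expect_equal(to_odds_ratio(kinmr:::mr_estimate("ivw", "x", "y", 5, log(2),
                                                 0.1, "log-odds"))$or, 2)
  expect_error(to_odds_ratio(kinmr:::mr_estimate("ivw", "x", "y", 5, 1,
                                                 0.1, "sd-units")), "log-odds")
})

test_that("valid-instrument recovery: all estimators hit the planted effect", {
  set.seed(47)
  h <- sim_summary_mr(L = 50, n_exp = 20000, n_out = 20000, theta = 0.3,
                      h2 = 0.1)
  ests <- rbind(ivw(h), mr_egger(h)[1, ],
                weighted_median(h, n_boot = 300, seed = 8),
                weighted_mode(h, n_boot = 300, seed = 8))
  for (i in seq_len(nrow(ests))) {
    expect_lt(abs(ests$beta[i] - 0.3), 3 * ests$se[i] + 0.02)
  }
})
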