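# inverse rank-normalisation, per-SNP scans, clumping, instrument strength

test_that("inverse rank-normalise matches the Blom formula and its invariances", {
  # oracle: evaluate Phi^-1((r - 3/8)/(n + 1/4)) directly
  x <- c(1, 2, 3)
  expected <- qnorm((rank(x) - 3 / 8) / (3 + 1 / 4))
  expect_equal(inverse_rank_normalise(x), expected, tolerance = 1e-12)
  expect_equal(expected, c(-0.8694, 0, 0.8694), tolerance = 1e-4)

  y <- rnorm(101)
  expect_equal(inverse_rank_normalise(y), inverse_rank_normalise(exp(y)))
  # symmetric odd-length input: middle element maps to 0
  s <- c(-5, -1, 0, 1, 5)
  expect_equal(inverse_rank_normalise(s)[3], 0)
  expect_error(inverse_rank_normalise(rep(1, 5)), "identical")
  expect_error(inverse_rank_normalise(c(1, NA, NA)), "finite")
  # ties get average ranks
  expect_equal(inverse_rank_normalise(c(1, 1, 2))[1],
               inverse_rank_normalise(c(1, 1, 2))[2])
})

test_that("normalised traits pass a KS normality check at n=10000", {
  set.seed(5)
  x <- rexp(10000)  # heavily skewed input
  z <- inverse_rank_normalise(x)
  expect_gt(suppressWarnings(ks.test(z, "pnorm")$p.value), 0.05)
  expect_equal(mean(z), 0, tolerance = 1e-3)
  expect_equal(sd(z), 1, tolerance = 0.01)
})

test_that("quantitative scan equals per-SNP lm() and recovers a planted effect", {
  co <- small_cohort(800, 10, seed = 3)
  covar <- cbind(age = rnorm(800), sex = rbinom(800, 1, 0.5))
  y <- 0.2 * co$offspring[, 4] + 0.1 * covar[, "age"] + rnorm(800)
  gw <- run_gwas_quantitative(co$offspring, y, co$snp_meta, covariates = covar)
  # oracle: full lm per SNP
  for (j in c(1, 4, 9)) {
    fit <- summary(lm(y ~ co$offspring[, j] + covar))$coefficients
    expect_equal(gw$beta[j], fit[2, 1], tolerance = 1e-10)
    expect_equal(gw$se[j], fit[2, 2], tolerance = 1e-10)
    expect_equal(gw$pval[j], fit[2, 4], tolerance = 1e-10)
  }
  # consistency: planted effect recovered at larger n
  co2 <- small_cohort(20000, 10, seed = 4)
  y2 <- 0.2 * co2$offspring[, 4] + rnorm(20000)
  gw2 <- run_gwas_quantitative(co2$offspring, y2, co2$snp_meta)
  expect_equal(gw2$beta[4], 0.2, tolerance = 3 * gw2$se[4])
  expect_error(run_gwas_quantitative(co$offspring, y, co$snp_meta,
                                     covariates = cbind(covar, covar[, 1])),
               "rank deficient")
})

test_that("null scan p-values are uniform; monomorphic SNPs excluded", {
  co <- small_cohort(2000, 50, seed = 6)
  set.seed(8)
  y <- rnorm(2000)
  gw <- run_gwas_quantitative(co$offspring, y, co$snp_meta)
  expect_gt(suppressWarnings(ks.test(gw$pval, "punif")$p.value), 0.01)

  dos <- co$offspring
  dos[, 3] <- 1L
  expect_message(gw2 <- run_gwas_quantitative(dos, y, co$snp_meta),
                 "monomorphic")
  expect_equal(nrow(gw2), 49)
  expect_false("rs00003" %in% gw2$SNP)
})

test_that("binary scan agrees with logistic regression after scale conversion", {
  co <- small_cohort(20000, 10, seed = 7)
  set.seed(9)
  liab <- 0.3 * scale(co$offspring[, 5]) + rnorm(20000)
  status <- as.integer(liab > quantile(liab, 0.8))  # prevalence 0.2
  gw <- run_gwas_binary(co$offspring, status, co$snp_meta)
  expect_identical(attr(gw, "scale"), "linear-probability")
  lo <- linear_to_logodds(gw)
  orc <- coef(summary(glm(status ~ co$offspring[, 5], family = binomial)))[2, 1]
  expect_equal(lo$beta[5], orc, tolerance = 0.1 * abs(orc))
  expect_error(run_gwas_binary(co$offspring, rep(0L, 20000), co$snp_meta),
               "10 cases")
})

test_that("linear-probability to log-odds conversion is the mu(1-mu) factor", {
  s <- toy_stats(c("a", "b", "c"), beta = c(0.01, 0.009, 0), se = c(0.1, 0.1, 0.1))
  attr(s, "scale") <- "linear-probability"
  expect_equal(linear_to_logodds(s, 0.5)$beta, c(0.04, 0.036, 0))
  expect_equal(linear_to_logodds(s, 0.1)$beta[2], 0.1)
  expect_equal(linear_to_logodds(s, 0.1)$se, rep(0.1 / 0.09, 3))
  expect_error(linear_to_logodds(s, 0), "case_fraction")
  attr(s, "scale") <- "sd-units"
  expect_error(linear_to_logodds(s, 0.5), "linear-probability")
})

test_that("greedy clumping matches the exhaustive oracle on random panels of size <= 8", {
  for (rep in 1:20) {
    set.seed(100 + rep)
    m <- sample(3:8, 1)
    n <- 400
    # random LD: pairs of duplicated columns induce r2 = 1 blocks
    base <- matrix(rbinom(n * m, 2, 0.3), n, m)
    dup <- sample(m, size = min(2, m - 1))
    base[, dup[1]] <- base[, max(dup)]
    chr <- sample(1:2, m, replace = TRUE)
    pos <- sample(1:3, m, replace = TRUE) * 4e5
    meta <- data.frame(SNP = paste0("s", 1:m), chr = chr, pos = pos,
                       A1 = "A", A2 = "G")
    panel <- reference_panel(base, meta)
    p <- runif(m, 1e-12, 1e-4)
    stats <- toy_stats(meta$SNP, beta = rnorm(m), se = rep(0.02, m),
                       chr = chr, pos = pos, pval = p)
    got <- ld_clump(stats, panel, p_thresh = 1e-3, r2_thresh = 0.2,
                    window_kb = 1000)
    r2mat <- suppressWarnings(cor(base)^2)
    want <- oracle_clump(p, chr, pos, r2mat, 1e-3, 0.2, 1e6)
    expect_setequal(got$snps$SNP, meta$SNP[want])
  }
})

test_that("clumping keeps the lower-p duplicate and everything on distinct chromosomes", {
  n <- 300
  set.seed(12)
  g <- matrix(rbinom(n * 5, 2, 0.4), n, 5)
  g[, 2] <- g[, 1]  # r2 = 1 pair
  meta <- data.frame(SNP = paste0("s", 1:5), chr = c(1, 1, 2, 3, 4),
                     pos = c(1e5, 2e5, 1e5, 1e5, 1e5), A1 = "A", A2 = "G")
  stats <- toy_stats(meta$SNP, beta = rep(0.1, 5), se = rep(0.01, 5),
                     chr = meta$chr, pos = meta$pos,
                     pval = c(1e-10, 1e-12, 1e-9, 1e-9, 1e-9))
  got <- ld_clump(stats, reference_panel(g, meta), p_thresh = 1e-8,
                  r2_thresh = 0.001)
  expect_true("s2" %in% got$snps$SNP)   # lower p of the duplicate pair
  expect_false("s1" %in% got$snps$SNP)
  expect_setequal(got$snps$SNP, c("s2", "s3", "s4", "s5"))
  # no passing SNP -> empty set with warning
  expect_warning(e <- ld_clump(stats, reference_panel(g, meta),
                               p_thresh = 1e-20), "no SNP")
  expect_equal(nrow(e$beta), 0)
})

test_that("pooled multivariable clumping reduces to univariable and fills all columns", {
  co <- small_cohort(3000, 30, seed = 17)
  mod <- lipid_effect_model(co$snp_meta$maf, var_explained = c(0.3, 0.3, 0.3),
                            seed = 17)
  tr <- simulate_lipids(co, mod, seed = 17)
  gw <- lapply(colnames(tr), function(k)
    run_gwas_quantitative(co$offspring, tr[, k], co$snp_meta, trait_label = k))
  names(gw) <- colnames(tr)
  panel <- cohort_panel(co)

  uni <- ld_clump(gw$apoB, panel, p_thresh = 1e-4)
  red <- multivariable_clump(gw["apoB"], panel, p_thresh = 1e-4)
  expect_identical(red$snps$SNP, uni$snps$SNP)

  mv <- multivariable_clump(gw, panel, p_thresh = 1e-4)
  expect_equal(ncol(mv$beta), 3)
  expect_false(anyNA(mv$beta))
  # SNP selected by any trait instruments all three columns
  uni_counts <- vapply(gw, function(s)
    nrow(ld_clump(s, panel, p_thresh = 1e-4)$beta), numeric(1))
  expect_lte(nrow(mv$beta), sum(uni_counts))
  # every trait's betas in mv equal that trait's own GWAS betas
  idx <- match(mv$snps$SNP, gw$TG$SNP)
  expect_equal(unname(mv$beta[, "TG"]), gw$TG$beta[idx])
})

test_that("mean F-statistic is the mean squared z-score", {
  ins <- ld_clump(toy_stats(c("a", "b"), beta = c(0.10, 0.12),
                            se = c(0.01, 0.01), chr = c(1, 2)),
                  reference_panel(matrix(rbinom(400, 2, 0.3), 100, 4)[, 1:2],
                                  data.frame(SNP = c("a", "b"), chr = c(1, 2),
                                             pos = c(1, 1))),
                  p_thresh = 1)
  expect_equal(unname(ins$mean_f), (100 + 144) / 2)
  expect_equal(mean_f_statistic(ins), 122)
  # all z = 1 -> F = 1
  expect_equal(mean((c(1, 1, 1))^2), 1)
  # F scales with n in simulation
  co <- small_cohort(4000, 10, seed = 19)
  mod <- lipid_effect_model(co$snp_meta$maf, var_explained = c(0.3, 0, 0),
                            shared_fraction = 0, seed = 19)
  tr <- simulate_lipids(co, mod, seed = 19)
  f_of_n <- function(rows) {
    gw <- run_gwas_quantitative(co$offspring[rows, ], tr[rows, "apoB"],
                                co$snp_meta)
    mean((gw$beta / gw$se)^2)
  }
  f_full <- f_of_n(1:4000)
  f_half <- f_of_n(1:2000)
  expect_equal(f_full / f_half, 2, tolerance = 0.35)
})

test_that("conditional F matches the explicit WLS oracle and its reductions", {
  set.seed(23)
  L <- 12
  beta <- cbind(t1 = rnorm(L, 0, 0.1), t2 = rnorm(L, 0, 0.1),
                t3 = rnorm(L, 0, 0.1))
  se <- matrix(runif(L * 3, 0.005, 0.02), L, 3,
               dimnames = list(NULL, colnames(beta)))
  ins <- structure(list(snps = data.frame(SNP = paste0("s", 1:L)),
                        beta = beta, se = se, traits = colnames(beta)),
                   class = "instrument_set")
  w <- 1 / se[, 1]^2
  coefs <- oracle_wls(beta[, 2:3], beta[, 1], w)
  Q <- sum(w * (beta[, 1] - beta[, 2:3] %*% coefs)^2)
  expect_equal(conditional_f_statistic(ins, 1), Q / (L - 3 + 1),
               tolerance = 1e-10)
  # target an exact linear combination of the others -> F ~ 0
  ins2 <- ins
  ins2$beta[, 1] <- 2 * beta[, 2] - beta[, 3]
  expect_lt(conditional_f_statistic(ins2, 1), 1e-20)
  # conditional strength <= unconditional-style strength when traits share signal
  ins3 <- ins
  ins3$beta[, 2] <- beta[, 1] * 0.9 + rnorm(L, 0, 0.01)
  uncond <- sum(w * beta[, 1]^2) / (L - 3 + 1)
  expect_lt(conditional_f_statistic(ins3, 1), uncond)
})

test_that("region exclusion removes exactly the in-window SNPs", {
  s <- toy_stats(paste0("s", 1:10), beta = rnorm(10), se = rep(0.01, 10),
                 chr = c(rep(19, 5), rep(2, 5)),
                 pos = c(1e6, 2e6, 3e6, 9e6, 9.5e6, 1e6, 2e6, 3e6, 4e6, 5e6))
  out <- region_exclude(s, 19, 1.5e6, 3.5e6)
  expect_equal(nrow(out), 8)
  expect_false(any(out$chr == 19 & out$pos >= 1.5e6 & out$pos <= 3.5e6))
  expect_equal(nrow(region_exclude(s, 21, 1, 2)), 10)   # empty overlap
  expect_warning(region_exclude(s[s$chr == 19, ], 19, 1, 1e9), "all SNPs")
  expect_error(region_exclude(s, 19, 10, 1), "inverted")
})

test_that("clumped sets satisfy the pairwise constraint post hoc", {
  co <- small_cohort(2000, 40, seed = 29,
                     ld_block_size = 4, ld_rho = 0.8)
  mod <- lipid_effect_model(co$snp_meta$maf, var_explained = c(0.4, 0, 0),
                            shared_fraction = 0, seed = 29)
  tr <- simulate_lipids(co, mod, seed = 29)
  gw <- run_gwas_quantitative(co$offspring, tr[, "apoB"], co$snp_meta)
  panel <- cohort_panel(co)
  ins <- ld_clump(gw, panel, p_thresh = 1e-3, r2_thresh = 0.1)
  snps <- ins$snps
  expect_gte(nrow(snps), 2)  # strong planted effects guarantee instruments
  if (nrow(snps) >= 2) {
    for (i in 1:(nrow(snps) - 1)) {
      for (j in (i + 1):nrow(snps)) {
        same_win <- snps$chr[i] == snps$chr[j] &&
          abs(snps$pos[i] - snps$pos[j]) <= 1e9 * 0 + 1e6
        if (same_win) {
          r2 <- cor(panel$dosage[, snps$SNP[i]], panel$dosage[, snps$SNP[j]])^2
          expect_lt(r2, 0.1)
        }
      }
    }
  }
})
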