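# ---- seed plumbing -----------------------------------------------------

#' Derive a reproducible sub-stream seed from a master seed
#'
#' All randomness in the package flows from one master seed. Each pipeline
#' stage draws from a named sub-stream so that stages can be re-run in
#' isolation and still be bit-reproducible. The derived seed is kept below
#' 2^31 so it is always a valid R integer.
#'
#' @param seed master integer seed.
#' @param stream one of `"simulate"`, `"lipids"`, `"outcomes"`, `"report"`,
#'   `"gwas"`, `"bootstrap"`, `"mediation"`, `"replicate"`.
#' @return an integer seed.
#' @export
stream_seed <- function(seed, stream) {
  offsets <- c(simulate = 101L, lipids = 211L, outcomes = 307L,
               report = 401L, gwas = 433L, bootstrap = 503L,
               mediation = 601L, replicate = 809L)
  if (!stream %in% names(offsets)) {
    stop("unknown random stream: ", stream)
  }
  (abs(as.integer(seed)) %% 2000003L) * 1000L + offsets[[stream]]
}

# ---- SimConfig ---------------------------------------------------------

#' Configuration for the synthetic family cohort
#'
#' Describes a nuclear-family cohort: `n_families` father/mother/offspring
#' trios, genotyped at `n_snps` biallelic SNPs. SNPs are laid out in LD
#' blocks of `ld_block_size` adjacent markers; within a block adjacent
#' haplotype alleles correlate at roughly `ld_rho` (autoregressive copying),
#' and blocks are placed more than the clumping window apart so they are
#' independent. Sibling counts are drawn per family from
#' `n_siblings_dist`, a probability vector over 0..3 siblings.
#'
#' @param n_families number of families.
#' @param n_snps number of SNPs.
#' @param maf_range minor allele frequency range, inside (0.01, 0.5].
#' @param ld_block_size SNPs per LD block (1 = full independence).
#' @param ld_rho adjacent-SNP copying probability within a block, in [0,1).
#' @param n_siblings_dist probabilities for 0,1,2,3 siblings per family.
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_families = 2000L, n_snps = 100L,
                       maf_range = c(0.05, 0.5),
                       ld_block_size = 1L, ld_rho = 0,
                       n_siblings_dist = c(0.15, 0.35, 0.30, 0.20),
                       seed = 1L) {
  if (n_families < 1 || n_snps < 1) stop("n_families and n_snps must be positive")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2]) {
    stop("maf_range must be an increasing pair")
  }
  if (maf_range[1] <= 0.01 || maf_range[2] > 0.5) {
    stop("maf_range must lie within (0.01, 0.5]")
  }
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  if (ld_block_size < 1) stop("ld_block_size must be >= 1")
  if (length(n_siblings_dist) != 4 || any(n_siblings_dist < 0) ||
      abs(sum(n_siblings_dist) - 1) > 1e-8) {
    stop("n_siblings_dist must be 4 probabilities over 0..3 siblings summing to 1")
  }
  structure(list(n_families = as.integer(n_families),
                 n_snps = as.integer(n_snps),
                 maf_range = as.numeric(maf_range),
                 ld_block_size = as.integer(ld_block_size),
                 ld_rho = as.numeric(ld_rho),
                 n_siblings_dist = as.numeric(n_siblings_dist),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Haplotypes under HWE with within-block AR(1) allele copying:
# the first SNP of a block is Bernoulli(maf); each subsequent SNP copies
# the previous allele with probability ld_rho, else draws fresh.
sim_haplotypes <- function(n_hap, maf, block, rho) {
  n_snps <- length(maf)
  h <- matrix(0L, n_hap, n_snps)
  h[, 1] <- as.integer(stats::runif(n_hap) < maf[1])
  if (n_snps > 1) {
    for (j in 2:n_snps) {
      fresh <- as.integer(stats::runif(n_hap) < maf[j])
      if (block[j] == block[j - 1] && rho > 0) {
        copy <- stats::runif(n_hap) < rho
        h[, j] <- ifelse(copy, h[, j - 1], fresh)
      } else {
        h[, j] <- fresh
      }
    }
  }
  h
}

#' Simulate a trio cohort with Mendelian transmission
#'
#' Parents are drawn under Hardy-Weinberg equilibrium from block-LD
#' haplotypes; every offspring and sibling receives one complete haplotype
#' from each parent (no recombination), so Mendelian consistency holds at
#' every SNP and the expected parent-offspring dosage correlation is 0.5
#' under random mating. Index individuals (offspring) are assigned a sex.
#'
#' @param config a [sim_config()].
#' @return an object of class `trio_cohort` with dosage matrices
#'   (`father`, `mother`, `offspring`, `siblings`), `sibling_family`
#'   indices, `sex` of index individuals (0 = female, 1 = male), and
#'   `snp_meta` (id, chrom, pos, A1 = effect/alt allele, A2, maf).
#' @export
simulate_trios <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, "simulate"))
  n <- config$n_families
  m <- config$n_snps

  maf <- stats::runif(m, config$maf_range[1], config$maf_range[2])
  block <- (seq_len(m) - 1L) %/% config$ld_block_size
  # each block on its own 10 Mb shelf => inter-block distance > 1 Mb window
  chrom <- (block %% 22L) + 1L
  pos <- (block %/% 22L) * 10000000L + ((seq_len(m) - 1L) %% config$ld_block_size) * 5000L + 1L
  bases <- c("A", "C", "G", "T")
  a1 <- sample(bases, m, replace = TRUE)
  a2 <- vapply(a1, function(b) sample(setdiff(bases, b), 1L), character(1))
  snp_meta <- data.frame(SNP = sprintf("rs%05d", seq_len(m)),
                         chr = chrom, pos = pos,
                         A1 = a1, A2 = a2, maf = maf,
                         stringsAsFactors = FALSE)

  fh1 <- sim_haplotypes(n, maf, block, config$ld_rho)
  fh2 <- sim_haplotypes(n, maf, block, config$ld_rho)
  mh1 <- sim_haplotypes(n, maf, block, config$ld_rho)
  mh2 <- sim_haplotypes(n, maf, block, config$ld_rho)

  transmit <- function(h1, h2) {
    pick <- stats::runif(n) < 0.5
    out <- h1
    out[!pick, ] <- h2[!pick, ]
    out
  }
  offspring <- transmit(fh1, fh2) + transmit(mh1, mh2)

  n_sib <- sample(0:3, n, replace = TRUE, prob = config$n_siblings_dist)
  sib_fam <- rep(seq_len(n), n_sib)
  siblings <- matrix(0L, length(sib_fam), m)
  if (length(sib_fam) > 0) {
    pick_f <- stats::runif(length(sib_fam)) < 0.5
    pick_m <- stats::runif(length(sib_fam)) < 0.5
    siblings <- ifelse(pick_f, 1, 0) * fh1[sib_fam, , drop = FALSE] +
      ifelse(pick_f, 0, 1) * fh2[sib_fam, , drop = FALSE] +
      ifelse(pick_m, 1, 0) * mh1[sib_fam, , drop = FALSE] +
      ifelse(pick_m, 0, 1) * mh2[sib_fam, , drop = FALSE]
  }

  structure(list(father = fh1 + fh2,
                 mother = mh1 + mh2,
                 offspring = offspring,
                 siblings = siblings,
                 sibling_family = sib_fam,
                 sex = as.integer(stats::runif(n) < 0.5),
                 snp_meta = snp_meta,
                 config = config),
            class = "trio_cohort")
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf("trio_cohort: %d families, %d SNPs, %d siblings\n",
              nrow(x$offspring), ncol(x$offspring), nrow(x$siblings)))
  invisible(x)
}

# dosage matrix for a family role
role_dosage <- function(cohort, role = c("offspring", "father", "mother", "siblings")) {
  role <- match.arg(role)
  cohort[[role]]
}

# ---- lipid trait model -------------------------------------------------

#' Per-SNP genetic effect model for the three lipoprotein traits
#'
#' Effect vectors (SD units per effect allele) for apoB, LDL cholesterol
#' and triglycerides. A fraction `shared_fraction` of causal SNPs affects
#' all three traits with correlated effect sizes (apoB-LDL effect
#' correlation 0.9, apoB-TG 0.4), which induces the strong genetic
#' correlation between apoB and LDL cholesterol seen in practice; the
#' remaining causal SNPs are trait-specific. Effects are scaled so each
#' trait's SNPs explain `var_explained` of its (unit) variance.
#'
#' @param maf per-SNP effect-allele frequencies (sets dosage variance
#'   2p(1-p) used in the scaling).
#' @param var_explained named or ordered length-3 vector of genetic
#'   variance per trait (default 0.10 each).
#' @param shared_fraction fraction of causal SNPs shared by all traits.
#' @param causal_fraction fraction of SNPs that are causal at all.
#' @param resid_corr 3x3 residual (environmental) correlation matrix.
#' @param trait_sd_gL physical SD labels; apoB 1 SD = 0.24 g/L.
#' @param seed integer seed for the effect draws.
#' @return object of class `lipid_model` with `beta` (n_snps x 3),
#'   `var_explained`, `resid_corr`, `maf`, `traits`.
#' @export
lipid_effect_model <- function(maf,
                               var_explained = c(apoB = 0.10, LDL = 0.10, TG = 0.10),
                               shared_fraction = 0.6,
                               causal_fraction = 1.0,
                               resid_corr = default_resid_corr(),
                               trait_sd_gL = c(apoB = 0.24, LDL = NA, TG = NA),
                               seed = 1L) {
  m <- length(maf)
  stopifnot(length(var_explained) == 3)
  ev <- eigen(resid_corr, symmetric = TRUE, only.values = TRUE)$values
  if (!isSymmetric(unname(resid_corr)) || any(ev <= 0) ||
      any(abs(diag(resid_corr) - 1) > 1e-8)) {
    stop("resid_corr must be symmetric positive-definite with unit diagonal")
  }
  if (any(var_explained < 0) || any(var_explained >= 1)) {
    stop("var_explained must be in [0, 1)")
  }
  set.seed(stream_seed(seed, "lipids"))
  causal <- which(stats::runif(m) < causal_fraction)
  shared <- causal[stats::runif(length(causal)) < shared_fraction]
  specific <- setdiff(causal, shared)

  beta <- matrix(0, m, 3, dimnames = list(NULL, c("apoB", "LDL", "TG")))
  u <- stats::rnorm(m)
  beta[shared, "apoB"] <- u[shared]
  beta[shared, "LDL"] <- 0.9 * u[shared] + sqrt(1 - 0.81) * stats::rnorm(length(shared))
  beta[shared, "TG"] <- 0.4 * u[shared] + sqrt(1 - 0.16) * stats::rnorm(length(shared))
  # trait-specific loci split evenly across the three traits
  if (length(specific) > 0) {
    which_tr <- sample(1:3, length(specific), replace = TRUE)
    beta[cbind(specific, which_tr)] <- stats::rnorm(length(specific))
  }
  vdos <- 2 * maf * (1 - maf)
  for (k in 1:3) {
    vg <- sum(vdos * beta[, k]^2)
    if (vg > 0) beta[, k] <- beta[, k] * sqrt(var_explained[k] / vg)
  }
  structure(list(beta = beta, var_explained = var_explained,
                 resid_corr = resid_corr, maf = maf,
                 trait_sd_gL = trait_sd_gL,
                 traits = colnames(beta)),
            class = "lipid_model")
}

#' Default residual correlation among apoB, LDL cholesterol, triglycerides
#'
#' apoB and LDL cholesterol are near-collinear at the phenotypic level;
#' triglycerides correlate moderately with both.
#' @return 3x3 correlation matrix.
#' @export
default_resid_corr <- function() {
  r <- matrix(c(1, 0.90, 0.40,
                0.90, 1, 0.30,
                0.40, 0.30, 1), 3, 3,
              dimnames = list(c("apoB", "LDL", "TG"), c("apoB", "LDL", "TG")))
  r
}

#' Simulate standardised lipid traits for one family role
#'
#' trait = dosage %*% beta + correlated Gaussian residual, where the
#' residual covariance is `resid_corr` scaled so each trait has total
#' variance about 1; the result is then empirically standardised to
#' mean 0, SD 1. The same model applies to any role: offspring get the
#' measured exposures, parents get their own latent lipid values that
#' drive their outcomes.
#'
#' @param cohort a `trio_cohort`.
#' @param model a [lipid_effect_model()].
#' @param role `"offspring"`, `"father"`, `"mother"` or `"siblings"`.
#' @param seed integer seed (role is mixed in so roles differ).
#' @param standardise empirically standardise columns (default TRUE).
#' @return n x 3 matrix of trait values.
#' @export
simulate_lipids <- function(cohort, model, role = "offspring", seed = 1L,
                            standardise = TRUE) {
  stopifnot(inherits(cohort, "trio_cohort"), inherits(model, "lipid_model"))
  X <- role_dosage(cohort, role)
  if (ncol(X) != nrow(model$beta)) stop("effect vectors do not match n_snps")
  role_off <- match(role, c("offspring", "father", "mother", "siblings"))
  set.seed(stream_seed(seed, "lipids") + role_off * 7L)
  # centred dosages: trait mean stays at 0 whatever the allele frequencies
  g <- sweep(X, 2, 2 * model$maf) %*% model$beta
  vdos <- 2 * model$maf * (1 - model$maf)
  vg <- colSums(vdos * model$beta^2)
  resid_sd <- sqrt(pmax(1 - vg, 1e-8))
  z <- matrix(stats::rnorm(nrow(X) * 3), ncol = 3) %*% chol(model$resid_corr)
  traits <- g + sweep(z, 2, resid_sd, `*`)
  if (standardise && nrow(traits) > 1) traits <- scale(traits)
  colnames(traits) <- model$traits
  traits[, , drop = FALSE]
}

# ---- disease / lifespan model ------------------------------------------

#' The 12-disease catalogue with default liability weights and prevalences
#'
#' Diseases asked about for first-degree relatives: heart disease, stroke,
#' high blood pressure, chronic bronchitis or emphysema, Alzheimer's
#' disease or dementia, diabetes, Parkinson's disease, severe depression,
#' lung cancer, bowel cancer, prostate cancer, breast cancer. Default
#' prevalences follow the fathers' column of the bundled descriptive
#' counts (mothers' values for the two female-only cancers). Default
#' liability weights encode the lipid biology exercised by the tests:
#' apoB raises heart disease, stroke and hypertension risk; diabetes has
#' a positive direct apoB weight but a negative LDL weight, so its
#' univariable apoB association is inverted by the apoB-LDL correlation.
#'
#' @param weights optional 12x3 matrix of liability weights
#'   (rows = diseases, cols = apoB, LDL, TG) to override the defaults.
#' @param prevalence optional named vector of prevalences.
#' @param env_sd environmental liability SD (default 1).
#' @param lifespan_yll years of life lost per SD of each lipid trait in
#'   the carrier of the genotype; defaults apoB +2.0, LDL -1.5, TG +0.6
#'   (direct effects: higher apoB shortens life, cholesterol content per
#'   particle is protective once particle number is held).
#' @param lifespan_baseline mean death age for father and mother.
#' @param lifespan_sd residual death-age SD in years.
#' @param censor_age parental age at study entry used for vital status;
#'   a parent is "alive" iff simulated death age exceeds it.
#' @return object of class `disease_model`.
#' @export
disease_model <- function(weights = NULL, prevalence = NULL, env_sd = 1,
                          lifespan_yll = c(apoB = 2.0, LDL = -1.5, TG = 0.6),
                          lifespan_baseline = c(father = 70.9, mother = 75.7),
                          lifespan_sd = 13,
                          censor_age = 60) {
  dis <- disease_names()
  w <- matrix(0, length(dis), 3, dimnames = list(dis, c("apoB", "LDL", "TG")))
  w["heart_disease", ] <- c(0.20, 0.05, 0.05)
  w["stroke", ] <- c(0.08, 0.02, 0.02)
  w["high_blood_pressure", ] <- c(0.06, 0.00, 0.06)
  w["diabetes", ] <- c(0.25, -0.35, 0.15)
  if (!is.null(weights)) w[rownames(weights), colnames(weights)] <- weights
  prev <- c(heart_disease = 0.327, stroke = 0.156, high_blood_pressure = 0.226,
            bronchitis_emphysema = 0.115, alzheimers_dementia = 0.048,
            diabetes = 0.097, parkinsons = 0.025, severe_depression = 0.039,
            lung_cancer = 0.093, bowel_cancer = 0.060,
            prostate_cancer = 0.077, breast_cancer = 0.083)
  if (!is.null(prevalence)) prev[names(prevalence)] <- prevalence
  if (any(!is.finite(stats::qnorm(1 - prev)))) stop("liability threshold non-finite")
  structure(list(weights = w, prevalence = prev[dis],
                 threshold = stats::qnorm(1 - prev[dis]),
                 env_sd = env_sd,
                 lifespan_yll = lifespan_yll,
                 lifespan_baseline = lifespan_baseline,
                 lifespan_sd = lifespan_sd,
                 censor_age = censor_age),
            class = "disease_model")
}

#' Names of the 12 family-history diseases
#' @return character vector of length 12.
#' @export
disease_names <- function() {
  c("heart_disease", "stroke", "high_blood_pressure",
    "bronchitis_emphysema", "alzheimers_dementia", "diabetes",
    "parkinsons", "severe_depression", "lung_cancer", "bowel_cancer",
    "prostate_cancer", "breast_cancer")
}

# liability-threshold draw for one person-set given their lipid values
liability_disease <- function(lipids, w, threshold, env_sd) {
  sys <- as.numeric(lipids %*% w)
  liab <- sys + stats::rnorm(nrow(lipids), sd = env_sd)
  v <- stats::var(sys) + env_sd^2
  as.integer(liab / sqrt(v) > threshold)
}

#' Simulate relative outcomes from their own genotypes
#'
#' Each relative's disease status arises from that relative's own genotype
#' through the liability-threshold model: latent liability = weighted sum
#' of the relative's (latent) lipid traits plus Gaussian environment,
#' standardised; disease iff liability exceeds the prevalence threshold.
#' Parental death age = sex-specific baseline minus the years-of-life-lost
#' weighted lipid sum plus noise; vital status is death age > censor age.
#' Outcomes are also generated for the index person ("offspring") so that
#' direct-versus-proxy designs and bidirectional analyses have ground
#' truth.
#'
#' @param cohort a `trio_cohort`.
#' @param lipid_model a [lipid_effect_model()].
#' @param dmodel a [disease_model()].
#' @param seed integer seed.
#' @return data.frame with columns family, role, one 0/1 column per
#'   disease, death_age, alive (parents only; NA otherwise).
#' @export
simulate_outcomes <- function(cohort, lipid_model, dmodel, seed = 1L) {
  stopifnot(inherits(dmodel, "disease_model"))
  set.seed(stream_seed(seed, "outcomes"))
  roles <- list(father = seq_len(nrow(cohort$father)),
                mother = seq_len(nrow(cohort$mother)),
                offspring = seq_len(nrow(cohort$offspring)))
  out <- list()
  for (role in c("father", "mother", "offspring", "siblings")) {
    if (role == "siblings" && nrow(cohort$siblings) == 0) next
    lip <- simulate_lipids(cohort, lipid_model, role = role,
                           seed = seed, standardise = FALSE)
    n <- nrow(lip)
    fam <- if (role == "siblings") cohort$sibling_family else seq_len(n)
    df <- data.frame(family = fam, role = role, stringsAsFactors = FALSE)
    for (d in rownames(dmodel$weights)) {
      df[[d]] <- liability_disease(lip, dmodel$weights[d, ],
                                   dmodel$threshold[[d]], dmodel$env_sd)
    }
    if (role %in% c("father", "mother")) {
      base <- dmodel$lifespan_baseline[[role]]
      death <- base - as.numeric(lip %*% dmodel$lifespan_yll) +
        stats::rnorm(n, sd = dmodel$lifespan_sd)
      df$death_age <- death
      df$alive <- as.integer(death > dmodel$censor_age)
    } else {
      df$death_age <- NA_real_
      df$alive <- NA_integer_
    }
    out[[role]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---- self-report noise --------------------------------------------------

#' Misclassification model for self-reported family outcomes
#'
#' @param sensitivity,specificity per-disease probabilities (scalars are
#'   recycled). sensitivity = specificity = 1 reproduces the truth.
#' @return object of class `report_model`.
#' @export
report_model <- function(sensitivity = 1, specificity = 1) {
  dis <- disease_names()
  sens <- rep_len(sensitivity, length(dis)); names(sens) <- dis
  spec <- rep_len(specificity, length(dis)); names(spec) <- dis
  if (any(sens < 0 | sens > 1 | spec < 0 | spec > 1)) {
    stop("sensitivity and specificity must be in [0, 1]")
  }
  structure(list(sensitivity = sens, specificity = spec),
            class = "report_model")
}

#' Apply self-report misclassification and sibling aggregation
#'
#' True disease statuses are reported with the model's per-disease
#' sensitivity/specificity (independently of the index person's own
#' status). Sibling rows are then collapsed to one any-affected indicator
#' per family, mirroring questionnaires that ask about siblings
#' cumulatively rather than individually; families without siblings get
#' no sibling row. Death age and vital status are carried unchanged.
#'
#' @param outcomes output of [simulate_outcomes()].
#' @param rmodel a [report_model()].
#' @param seed integer seed.
#' @return data.frame shaped like `outcomes` with at most one `siblings`
#'   row per family.
#' @export
apply_report_noise <- function(outcomes, rmodel, seed = 1L) {
  stopifnot(inherits(rmodel, "report_model"))
  set.seed(stream_seed(seed, "report"))
  rep_out <- outcomes
  for (d in disease_names()) {
    truth <- outcomes[[d]]
    keep_pos <- stats::runif(length(truth)) < rmodel$sensitivity[[d]]
    false_pos <- stats::runif(length(truth)) >= rmodel$specificity[[d]]
    rep_out[[d]] <- ifelse(truth == 1L, as.integer(keep_pos),
                           as.integer(false_pos))
  }
  sib <- rep_out[rep_out$role == "siblings", , drop = FALSE]
  rest <- rep_out[rep_out$role != "siblings", , drop = FALSE]
  if (nrow(sib) > 0) {
    agg <- stats::aggregate(sib[disease_names()],
                            by = list(family = sib$family),
                            FUN = function(x) as.integer(any(x == 1L)))
    agg$role <- "siblings"
    agg$death_age <- NA_real_
    agg$alive <- NA_integer_
    rest <- rbind(rest, agg[, names(rest)])
  }
  rownames(rest) <- NULL
  rest
}

# ---- cohort text formats ------------------------------------------------

#' Write a cohort in the plain-text exchange format
#'
#' Three files: `<prefix>_dosage.txt` (transposed dosages, rows = SNPs,
#' cols = individuals, space-separated, one header row of individual ids),
#' `<prefix>_snps.tsv` (SNP metadata: id, chrom, pos, A1, A2) and
#' `<prefix>_pheno.tsv` (family id, role, trait values, outcome
#' indicators, death age, vital status).
#'
#' @param cohort a `trio_cohort`.
#' @param traits index-person trait matrix from [simulate_lipids()].
#' @param outcomes reported outcome table.
#' @param prefix output path prefix.
#' @return invisibly, the three file paths.
#' @export
write_cohort <- function(cohort, traits, outcomes, prefix) {
  ids <- c(sprintf("F%04d", seq_len(nrow(cohort$father))),
           sprintf("M%04d", seq_len(nrow(cohort$mother))),
           sprintf("O%04d", seq_len(nrow(cohort$offspring))))
  dos <- t(rbind(cohort$father, cohort$mother, cohort$offspring))
  colnames(dos) <- ids
  dosage_path <- paste0(prefix, "_dosage.txt")
  utils::write.table(dos, dosage_path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  snp_path <- paste0(prefix, "_snps.tsv")
  utils::write.table(cohort$snp_meta[, c("SNP", "chr", "pos", "A1", "A2")],
                     snp_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ph <- data.frame(family = seq_len(nrow(cohort$offspring)),
                   role = "offspring", sex = cohort$sex,
                   round(traits, 6), stringsAsFactors = FALSE)
  pheno_path <- paste0(prefix, "_pheno.tsv")
  utils::write.table(merge(ph, outcomes, by = c("family", "role"), all = TRUE),
                     pheno_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(dosage_path, snp_path, pheno_path))
}
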