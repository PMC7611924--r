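# End-to-end pipeline: simulate -> GWAS -> clump -> screen -> sensitivity,
# plus the command-line surface.

# per-slot outcome GWAS over the catalogue; returns a named list of
# summary_stats keyed by "relative.outcome"
outcome_gwas_all <- function(cohort, outcomes, catalog = outcome_catalog()) {
  res <- list()
  for (i in seq_len(nrow(catalog))) {
    rel <- catalog$relative[i]
    out <- catalog$outcome[i]
    role <- if (rel == "sibling") "siblings" else rel
    rows <- outcomes[outcomes$role == role, , drop = FALSE]
    if (nrow(rows) == 0) next
    fam <- rows$family
    X <- cohort$offspring[fam, , drop = FALSE]
    label <- catalog$slot[i]
    stats <- tryCatch({
      if (out == "age_at_death") {
        dead <- rows$alive == 0L
        run_gwas_quantitative(X[dead, , drop = FALSE],
                              -rows$death_age[dead],  # years of life lost
                              cohort$snp_meta, trait_label = label)
      } else {
        y <- if (out == "alive") rows$alive else rows[[out]]
        s <- run_gwas_binary(X, y, cohort$snp_meta, trait_label = label)
        linear_to_logodds(s)
      }
    }, error = function(e) NULL)
    if (!is.null(stats)) {
      if (out == "age_at_death") attr(stats, "scale") <- "years"
      res[[label]] <- stats
    }
  }
  res
}

#' Run the full family-proxy MR pipeline
#'
#' simulate trios -> lipid exposures on index individuals (inverse
#' rank-normalised) -> relative outcomes with self-report noise -> per-SNP
#' GWAS of exposures and of every catalogue outcome slot -> univariable
#' and pooled multivariable clumping -> 38-outcome FDR screen for apoB ->
#' sensitivity suite (Egger, median, mode, MVMR, MVMR-Egger) for passing
#' slots -> mediation of the apoB-lifespan effect through the index
#' person's own heart disease and diabetes liability. Results are written
#' as `screen.tsv`, `sensitivity.tsv`, `mediation.tsv`, `forest_data.tsv`
#' and `run.log` (seed and config echo).
#'
#' @param cfg configuration list from [read_run_config()].
#' @param outdir results directory.
#' @return invisibly, a list with the main intermediate objects.
#' @export
run_pipeline <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  cohort <- simulate_trios(config_to_sim(cfg))
  lmodel <- lipid_effect_model(cohort$snp_meta$maf,
                               var_explained = rep(cfg$var_explained, 3),
                               shared_fraction = cfg$shared_fraction,
                               seed = seed)
  dmodel <- disease_model()
  exposures <- simulate_lipids(cohort, lmodel, "offspring", seed = seed)
  outcomes_true <- simulate_outcomes(cohort, lmodel, dmodel, seed = seed)
  rmodel <- report_model(cfg$report_sensitivity, cfg$report_specificity)
  outcomes <- apply_report_noise(outcomes_true, rmodel, seed = seed)

  covar <- cbind(sex = cohort$sex)
  exp_stats <- lapply(colnames(exposures), function(tr) {
    run_gwas_quantitative(cohort$offspring,
                          inverse_rank_normalise(exposures[, tr]),
                          cohort$snp_meta, covariates = covar,
                          trait_label = tr)
  })
  names(exp_stats) <- colnames(exposures)

  panel <- cohort_panel(cohort)
  instr <- lapply(exp_stats, ld_clump, panel = panel, p_thresh = cfg$p_thresh,
                  r2_thresh = cfg$r2_thresh, window_kb = cfg$window_kb)
  instr_mv <- multivariable_clump(exp_stats, panel, cfg$p_thresh,
                                  cfg$r2_thresh, cfg$window_kb)

  out_stats <- outcome_gwas_all(cohort, outcomes)
  screen <- univariable_screen(exp_stats$apoB, instr$apoB, out_stats,
                               q = cfg$fdr_q)

  sens <- list()
  for (slot in screen$slot[screen$pass]) {
    h <- harmonise(exp_stats$apoB, out_stats[[slot]], snp_subset = instr$apoB,
                   palindrome_eaf_limit = cfg$palindrome_eaf_limit)
    h_mv <- tryCatch(
      harmonise(exp_stats, out_stats[[slot]], snp_subset = instr_mv,
                palindrome_eaf_limit = cfg$palindrome_eaf_limit),
      error = function(e) NULL)
    tab <- sensitivity_suite(h, h_mv, n_boot = cfg$n_boot, seed = seed)
    tab$slot <- slot
    sens[[slot]] <- tab
  }
  sens_tab <- if (length(sens) > 0) do.call(rbind, sens) else
    mr_estimate(character(0), character(0), character(0), integer(0),
                numeric(0), numeric(0), character(0))[0, ]

  mediation <- pipeline_mediation(cohort, exposures, outcomes_true,
                                  exp_stats, instr, panel, cfg, seed)

  forest <- rbind(
    data.frame(stage = "screen", slot = screen$slot,
               as.data.frame(screen)[, c("exposure", "method", "nsnp",
                                         "beta", "lo95", "hi95", "or",
                                         "or_lo", "or_hi")],
               stringsAsFactors = FALSE),
    if (nrow(sens_tab) > 0)
      data.frame(stage = "sensitivity", slot = sens_tab$slot,
                 sens_tab[, c("exposure", "method", "nsnp", "beta",
                              "lo95", "hi95", "or", "or_lo", "or_hi")],
                 stringsAsFactors = FALSE)
  )

  write_results(list(screen = as.data.frame(screen),
                     sensitivity = as.data.frame(sens_tab),
                     mediation = mediation,
                     forest_data = forest), outdir)
  cfg_echo <- paste(names(cfg), unlist(cfg), sep = "=", collapse = " ")
  writeLines(c(sprintf("kinmr %s", as.character(utils::packageVersion("kinmr"))),
               sprintf("seed %d", as.integer(seed)),
               sprintf("config %s", cfg_echo),
               sprintf("config_hash %d", sum(utf8ToInt(cfg_echo)))),
             file.path(outdir, "run.log"))
  invisible(list(cohort = cohort, exposures = exposures,
                 exposure_stats = exp_stats, instruments = instr,
                 instrument_mv = instr_mv, outcome_stats = out_stats,
                 screen = screen, sensitivity = sens_tab,
                 mediation = mediation))
}

# mediation of apoB -> father's years of life lost through the index
# person's own heart-disease and diabetes liability
pipeline_mediation <- function(cohort, exposures, outcomes_true, exp_stats,
                               instr, panel, cfg, seed) {
  empty <- data.frame(exposure = character(0), outcome = character(0),
                      mediators = character(0), proportion = numeric(0),
                      lo95 = numeric(0), hi95 = numeric(0),
                      unstable = logical(0))
  off <- outcomes_true[outcomes_true$role == "offspring", , drop = FALSE]
  fat <- outcomes_true[outcomes_true$role == "father", , drop = FALSE]
  if (nrow(off) == 0 || nrow(instr$apoB$beta) < 5) return(empty)
  med_stats <- tryCatch(lapply(c("heart_disease", "diabetes"), function(d) {
    s <- run_gwas_binary(cohort$offspring, off[[d]], cohort$snp_meta,
                         trait_label = d)
    linear_to_logodds(s)
  }), error = function(e) NULL)
  if (is.null(med_stats)) return(empty)
  dead <- fat$alive == 0L
  if (sum(dead) < 50) return(empty)
  yll_stats <- run_gwas_quantitative(cohort$offspring[fat$family[dead], , drop = FALSE],
                                     -fat$death_age[dead], cohort$snp_meta,
                                     trait_label = "father.age_at_death")
  attr(yll_stats, "scale") <- "years"
  h_total <- harmonise(exp_stats$apoB, yll_stats, snp_subset = instr$apoB)
  h_direct <- harmonise(c(list(exp_stats$apoB), med_stats), yll_stats,
                        snp_subset = instr$apoB)
  med <- tryCatch(
    mediation_proportion(h_total, h_direct, exposure = "apoB", seed = seed),
    error = function(e) NULL)
  if (is.null(med)) return(empty)
  data.frame(exposure = "apoB", outcome = "father.age_at_death",
             mediators = "heart_disease+diabetes",
             proportion = med$proportion, lo95 = med$lo95, hi95 = med$hi95,
             unstable = med$unstable, stringsAsFactors = FALSE)
}

# ---- command-line interface ---------------------------------------------

parse_argv <- function(argv) {
  out <- list()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a)
    key <- substring(a, 3)
    if (i == length(argv) || startsWith(argv[i + 1], "--")) {
      stop("flag --", key, " needs a value")
    }
    out[[key]] <- c(out[[key]], argv[i + 1])
    i <- i + 2
  }
  out
}

cli_usage <- function() {
  paste(
    "usage: kinmr <subcommand> [flags]",
    "  simulate --seed <int> [--config <file>] --out <prefix>",
    "  gwas     --dosage <txt> --snps <tsv> --pheno <tsv> --trait <name> --out <tsv>",
    "  clump    --stats <tsv> [--stats <tsv> ...] --panel-dosage <txt> --panel-snps <tsv>",
    "           [--p <num>] [--r2 <num>] [--window-kb <num>] --out <tsv>",
    "  mr       --exposure <tsv> [--exposure <tsv> ...] --outcome <tsv>",
    "           [--methods ivw,egger,wmedian,wmode] [--seed <int>] --out <tsv>",
    "  pipeline --config <file> [--seed <int>] --out <dir>",
    sep = "\n")
}

read_dosage_txt <- function(path) {
  d <- utils::read.table(path, header = TRUE, check.names = FALSE)
  t(as.matrix(d))  # stored rows=SNPs, cols=individuals
}

cli_simulate <- function(args) {
  if (is.null(args$seed)) stop("--seed is mandatory for simulate")
  cfg <- read_run_config(args$config,
                         overrides = list(seed = as.integer(args$seed)))
  cohort <- simulate_trios(config_to_sim(cfg))
  lmodel <- lipid_effect_model(cohort$snp_meta$maf,
                               var_explained = rep(cfg$var_explained, 3),
                               shared_fraction = cfg$shared_fraction,
                               seed = cfg$seed)
  traits <- simulate_lipids(cohort, lmodel, "offspring", seed = cfg$seed)
  outc <- simulate_outcomes(cohort, lmodel, disease_model(), seed = cfg$seed)
  outc <- apply_report_noise(outc, report_model(cfg$report_sensitivity,
                                                cfg$report_specificity),
                             seed = cfg$seed)
  write_cohort(cohort, traits, outc, args$out)
  0L
}

cli_gwas <- function(args) {
  dos <- read_dosage_txt(args$dosage)
  snps <- utils::read.delim(args$snps, stringsAsFactors = FALSE)
  ph <- utils::read.delim(args$pheno, stringsAsFactors = FALSE)
  ph <- ph[ph$role == "offspring", , drop = FALSE]
  rows <- grep("^O", rownames(dos))
  if (!args$trait %in% names(ph)) stop("trait not in phenotype file: ", args$trait)
  gw <- run_gwas_quantitative(dos[rows, , drop = FALSE],
                              inverse_rank_normalise(ph[[args$trait]]),
                              snps, trait_label = args$trait)
  write_summary_stats(gw, args$out)
  0L
}

cli_clump <- function(args) {
  stats <- lapply(args$stats, read_summary_stats)
  dos <- read_dosage_txt(args[["panel-dosage"]])
  snps <- utils::read.delim(args[["panel-snps"]], stringsAsFactors = FALSE)
  panel <- reference_panel(dos, snps)
  p <- if (is.null(args$p)) 5e-8 else as.numeric(args$p)
  r2 <- if (is.null(args$r2)) 0.001 else as.numeric(args$r2)
  win <- if (is.null(args[["window-kb"]])) 1000 else as.numeric(args[["window-kb"]])
  instr <- if (length(stats) == 1) ld_clump(stats[[1]], panel, p, r2, win)
           else multivariable_clump(stats, panel, p, r2, win)
  long <- do.call(rbind, lapply(seq_along(instr$traits), function(k)
    data.frame(instr$snps, trait = instr$traits[k],
               beta = instr$beta[, k], se = instr$se[, k],
               mean_f = instr$mean_f[k],
               conditional_f = if (is.null(instr$conditional_f)) NA_real_
                               else instr$conditional_f[k],
               stringsAsFactors = FALSE)))
  utils::write.table(long, args$out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  0L
}

cli_mr <- function(args) {
  exposures <- lapply(args$exposure, read_summary_stats)
  outcome <- read_summary_stats(args$outcome)
  seed <- if (is.null(args$seed)) 1L else as.integer(args$seed)
  methods <- if (is.null(args$methods)) c("ivw", "egger", "wmedian", "wmode")
             else strsplit(args$methods, ",")[[1]]
  h <- harmonise(exposures, outcome)
  L <- length(h$beta_out)
  rows <- list()
  if (length(exposures) >= 2) {
    rows <- c(rows, list(mvmr_ivw(h), mvmr_egger(h)))
  } else if (L == 1) {
    warning("single SNP: Wald ratio only")
    wr <- wald_ratio(h$beta_exp[1, 1], h$se_exp[1, 1], h$beta_out[1],
                     h$se_out[1], scale = h$outcome_scale)
    wr$exposure <- h$exposures[1]; wr$outcome <- h$outcome
    rows <- list(wr)
  } else {
    if ("ivw" %in% methods) rows <- c(rows, list(ivw(h)))
    if ("egger" %in% methods && L >= 3) rows <- c(rows, list(mr_egger(h)))
    if ("wmedian" %in% methods && L >= 3)
      rows <- c(rows, list(weighted_median(h, seed = seed)))
    if ("wmode" %in% methods && L >= 3)
      rows <- c(rows, list(weighted_mode(h, seed = seed)))
  }
  res <- do.call(rbind, rows)
  out <- res[, c("outcome", "exposure", "method", "nsnp", "beta", "se",
                 "lo95", "hi95", "pval", "or", "or_lo", "or_hi")]
  for (col in names(out)) if (is.numeric(out[[col]])) out[[col]] <- signif(out[[col]], 6)
  utils::write.table(out, args$out, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = ".")
  0L
}

cli_pipeline <- function(args) {
  overrides <- list()
  if (!is.null(args$seed)) overrides$seed <- as.integer(args$seed)
  cfg <- read_run_config(args$config, overrides)
  run_pipeline(cfg, args$out)
  0L
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `gwas`, `clump`, `mr`, `pipeline` (see the
#' usage text). Returns 0 on success, 2 on usage or configuration errors,
#' 1 on runtime failures, with a one-line diagnostic on stderr. Intended
#' to be called from the `inst/cli/kinmr` wrapper script as
#' `Rscript kinmr <subcommand> ...`.
#'
#' @param argv character vector of arguments (defaults to the process
#'   command line).
#' @return exit code, invisibly.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (length(argv) == 0) {
    message(cli_usage())
    return(invisible(2L))
  }
  sub <- argv[1]
  handler <- switch(sub,
                    simulate = cli_simulate, gwas = cli_gwas,
                    clump = cli_clump, mr = cli_mr,
                    pipeline = cli_pipeline, NULL)
  if (is.null(handler)) {
    message("unknown subcommand: ", sub, "\n", cli_usage())
    return(invisible(2L))
  }
  args <- tryCatch(parse_argv(argv[-1]), error = function(e) e)
  if (inherits(args, "error")) {
    message(conditionMessage(args), "\n", cli_usage())
    return(invisible(2L))
  }
  code <- tryCatch(handler(args), error = function(e) {
    message("kinmr ", sub, ": ", conditionMessage(e))
    if (grepl("unknown config key|mandatory|missing column", conditionMessage(e))) 2L else 1L
  })
  invisible(code)
}
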