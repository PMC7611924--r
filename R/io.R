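# Plain-TSV formats, run configuration and results writing. Everything is
# text: the data volumes are desk-scale and diffable outputs make the
# pipeline testable byte-for-byte.

SUMMARY_COLS <- c("SNP", "chr", "pos", "effect_allele", "other_allele",
                  "eaf", "beta", "se", "pval", "n", "trait", "scale")

#' Read GWAS summary statistics from TSV
#'
#' Schema (tab-delimited, header required, `.` for missing):
#' `SNP chr pos effect_allele other_allele eaf beta se pval n trait scale`.
#' Rows are validated: beta/se numeric, se > 0, p in (0,1], no duplicate
#' SNP ids. A missing eaf is parsed as NA; such a SNP is dropped during
#' harmonisation if palindromic.
#'
#' @param path file path.
#' @return a `summary_stats` object.
#' @export
read_summary_stats <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", "."),
                         colClasses = "character")
  missing <- setdiff(SUMMARY_COLS, names(d))
  if (length(missing) > 0) stop("missing column(s): ", paste(missing, collapse = ", "))
  num <- function(col) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(!is.na(d[[col]]) & is.na(v))
    if (length(bad) > 0) stop("non-numeric ", col, " at line ", bad[1] + 1)
    v
  }
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) d[[col]] <- num(col)
  if (anyNA(d$beta) || anyNA(d$se)) stop("beta and se must be present for every SNP")
  if (any(d$se <= 0)) stop("se <= 0 at line ", which(d$se <= 0)[1] + 1)
  if (any(!is.na(d$pval) & (d$pval <= 0 | d$pval > 1))) {
    stop("pval outside (0,1] at line ", which(d$pval <= 0 | d$pval > 1)[1] + 1)
  }
  if (anyDuplicated(d$SNP)) stop("duplicate SNP id: ", d$SNP[anyDuplicated(d$SNP)])
  trait <- unique(d$trait); scale <- unique(d$scale)
  if (length(trait) != 1 || length(scale) != 1) {
    stop("trait and scale must be constant within one file")
  }
  out <- d[, setdiff(SUMMARY_COLS, c("trait", "scale"))]
  structure(out, trait = trait, scale = scale,
            class = c("summary_stats", "data.frame"))
}

#' Write summary statistics to TSV (round-trips with [read_summary_stats()])
#' @param stats a `summary_stats`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_summary_stats <- function(stats, path) {
  d <- as.data.frame(stats)
  d$trait <- attr(stats, "trait")
  d$scale <- attr(stats, "scale")
  d <- d[, SUMMARY_COLS]
  for (col in c("eaf", "beta", "se", "pval")) d[[col]] <- signif(d[[col]], 6)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".")
  invisible(path)
}

# ---- run configuration --------------------------------------------------

run_config_defaults <- function() {
  list(
    n_families = 2000, n_snps = 100, maf_min = 0.05, maf_max = 0.5,
    ld_block_size = 1, ld_rho = 0,
    sib_p0 = 0.15, sib_p1 = 0.35, sib_p2 = 0.30, sib_p3 = 0.20,
    var_explained = 0.10, shared_fraction = 0.6,
    report_sensitivity = 1, report_specificity = 1,
    p_thresh = 5e-8, r2_thresh = 0.001, window_kb = 1000,
    fdr_q = 0.05, n_boot = 1000, palindrome_eaf_limit = 0.42,
    seed = 1
  )
}

#' Read a flat key-value run configuration
#'
#' Format: one `key = value` per line, `#` comments, blank lines ignored.
#' Unknown keys are rejected. Defaults exactly encode the canonical
#' instrument rule: p_thresh 5e-8, r2_thresh 0.001, window_kb 1000,
#' fdr_q 0.05.
#'
#' @param path config file path, or NULL for pure defaults.
#' @param overrides named list of values overriding the file (CLI flags).
#' @return named list of configuration values.
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- run_config_defaults()
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2) stop("malformed config line: ", ln)
      key <- trimws(kv[1]); val <- trimws(kv[2])
      if (!key %in% names(cfg)) stop("unknown config key: ", key)
      cfg[[key]] <- as.numeric(val)
    }
  }
  for (key in names(overrides)) {
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    cfg[[key]] <- overrides[[key]]
  }
  cfg
}

config_to_sim <- function(cfg) {
  sim_config(n_families = cfg$n_families, n_snps = cfg$n_snps,
             maf_range = c(cfg$maf_min, cfg$maf_max),
             ld_block_size = cfg$ld_block_size, ld_rho = cfg$ld_rho,
             n_siblings_dist = c(cfg$sib_p0, cfg$sib_p1, cfg$sib_p2, cfg$sib_p3),
             seed = cfg$seed)
}

# ---- results writing ----------------------------------------------------

#' Write result tables as deterministic TSV files
#'
#' Each named table becomes `<outdir>/<name>.tsv` with a fixed column
#' order (as given), rows sorted lexicographically over all columns and
#' numeric values formatted to 6 significant digits, so identical runs
#' produce byte-identical files. Empty tables yield a header-only file.
#'
#' @param tables named list of data.frames.
#' @param outdir output directory (created if needed).
#' @return invisibly, the file paths.
#' @export
write_results <- function(tables, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    d <- as.data.frame(tables[[nm]])
    if (nrow(d) > 0) {
      keys <- unname(lapply(d, function(c) if (is.numeric(c)) c else as.character(c)))
      d <- d[do.call(order, keys), , drop = FALSE]
      for (col in names(d)) {
        if (is.numeric(d[[col]])) d[[col]] <- signif(d[[col]], 6)
      }
    }
    p <- file.path(outdir, paste0(nm, ".tsv"))
    utils::write.table(d, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = ".")
    paths <- c(paths, p)
  }
  invisible(paths)
}
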