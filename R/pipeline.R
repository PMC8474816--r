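#' Read a genotype dosage matrix
#'
#' Parses either the PLINK `.raw` dialect (whitespace-separated, header
#' `FID IID PAT MAT SEX PHENOTYPE` followed by one column per SNP,
#' dosages 0/1/2, `NA` for missing) or a plain CSV (first column = animal
#' ID, remaining columns = SNP dosages). Dosages outside {0, 1, 2,
#' missing} and duplicate animal IDs are hard errors.
#'
#' @param path File path.
#' @param dialect `"auto"` (by extension), `"plink-raw"` or `"csv"`.
#' @return A `genotype_matrix` object (no pedigree).
#' @export
read_genotypes <- function(path, dialect = c("auto", "plink-raw", "csv")) {
  dialect <- match.arg(dialect)
  .assert(file.exists(path), sprintf("file not found: %s", path))
  if (dialect == "auto")
    dialect <- if (grepl("\\.raw$", path)) "plink-raw" else "csv"
  if (dialect == "plink-raw") {
    df <- read.table(path, header = TRUE, check.names = FALSE,
                     stringsAsFactors = FALSE)
    .assert(ncol(df) > 6 && identical(names(df)[1:2], c("FID", "IID")),
            "not a PLINK .raw file (expected FID IID PAT MAT SEX PHENOTYPE ...)")
    ids <- as.character(df$IID)
    M <- as.matrix(df[, -(1:6), drop = FALSE])
  } else {
    df <- read.csv(path, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
    ids <- as.character(df[[1]])
    M <- as.matrix(df[, -1, drop = FALSE])
  }
  .assert(!anyDuplicated(ids), "duplicate animal IDs in genotype file")
  storage.mode(M) <- "double"
  bad <- which(!(is.na(M) | M == 0 | M == 1 | M == 2), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf(
      "invalid dosage %s at animal '%s', SNP '%s'",
      format(M[bad[1, 1], bad[1, 2]]), ids[bad[1, 1]],
      colnames(M)[bad[1, 2]]), call. = FALSE)
  rownames(M) <- ids
  p <- colMeans(M, na.rm = TRUE) / 2
  structure(list(dosage = M, freqs = p, pedigree = NULL),
            class = "genotype_matrix")
}

#' Write a genotype dosage matrix
#'
#' Writes PLINK `.raw` dialect (FID/IID = animal ID, PAT = sire where
#' known, SEX 0, PHENOTYPE -9) or plain CSV.
#'
#' @param genotypes A `genotype_matrix`.
#' @param path Output file path.
#' @param dialect `"auto"` (by extension), `"plink-raw"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(genotypes, path,
                            dialect = c("auto", "plink-raw", "csv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.raw$", path)) "plink-raw" else "csv"
  M <- genotypes$dosage
  ids <- rownames(M)
  if (dialect == "plink-raw") {
    pat <- if (!is.null(genotypes$pedigree))
      genotypes$pedigree$sire[match(ids, genotypes$pedigree$animal)]
    else rep("0", length(ids))
    df <- data.frame(FID = ids, IID = ids, PAT = pat, MAT = "0",
                     SEX = 0L, PHENOTYPE = -9L,
                     stringsAsFactors = FALSE, check.names = FALSE)
    df <- cbind(df, as.data.frame(M, check.names = FALSE))
    write.table(df, path, quote = FALSE, sep = " ", row.names = FALSE)
  } else {
    df <- data.frame(animal = ids, as.data.frame(M, check.names = FALSE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Run the full quality-assessment study end-to-end
#'
#' Simulates a dataset from `config`, builds the GRM, fits the whole-data
#' (multi-trait) model, runs the cohort-based partial/whole
#' cross-validation, computes the Q1Q4 regressions on both accuracy
#' metrics and the metric ANOVA, and writes the study tables as CSV files
#' plus a machine-readable manifest to `out_dir`. The whole run is
#' deterministic given `config$seed`.
#'
#' Outputs: `phenotypes.csv`, `true_breeding_values.csv`,
#' `descriptive_stats.csv` (per-trait n/mean/SD/min/max),
#' `h2_correlations.csv` (heritabilities on the diagonal, genetic
#' correlations above, residual below), `metrics_cells.csv` (one row per
#' cohort x trait cell), `metric_summaries.csv`, `anova_metrics.csv`,
#' `q1q4_cells.csv`, `q1q4_regression.csv`, `relationship_summary.csv`,
#' `manifest.json`.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @param masking,h2_source,sd_ref_scope Passed to [run_crossval()].
#' @param write_genotype_files Also write `genotypes.raw` (can be large).
#' @param verbose Print stage boundaries.
#' @return Invisibly, a list with all in-memory results (`data`,
#'   `whole_fit`, `metrics`, `summary`, `anova`, `q1q4_regressions`,
#'   `linkage`, `manifest`).
#' @export
run_full_study <- function(config, out_dir,
                           masking = "single", h2_source = "whole",
                           sd_ref_scope = "all",
                           write_genotype_files = FALSE,
                           verbose = TRUE) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[gebvqc] ", sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  files <- character(0)
  emit <- function(df, name, row.names = FALSE) {
    fp <- file.path(out_dir, name)
    write.csv(df, fp, row.names = row.names)
    files <<- c(files, name)
    fp
  }

  say("simulate: %d animals, %d SNPs, %d trait(s)",
      config$n_animals, config$n_snps, config$n_traits)
  dat <- stage("simulate", simulate_dataset(config))
  traits <- config$traits

  emit(dat$pheno, "phenotypes.csv")
  emit(data.frame(animal = rownames(dat$truth$true_bv),
                  dat$truth$true_bv, check.names = FALSE),
       "true_breeding_values.csv")
  if (write_genotype_files) {
    write_genotypes(dat$genotypes, file.path(out_dir, "genotypes.raw"))
    files <- c(files, "genotypes.raw")
  }

  desc <- do.call(rbind, lapply(c(traits, "fage", "cage"), function(cl) {
    v <- dat$pheno[[cl]]
    v <- v[!is.na(v)]
    data.frame(variable = cl, n = length(v), mean = mean(v), sd = sd(v),
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  }))
  emit(desc, "descriptive_stats.csv")

  say("grm + relationship summary")
  rel <- stage("grm", relationship_summary(dat$grm))
  emit(data.frame(F_bar = rel$F_bar, two_f_bar = rel$two_f_bar,
                  sd_diag = rel$sd_diag, sd_offdiag = rel$sd_offdiag,
                  n = rel$n, n_snps_used = dat$grm$n_snps_used,
                  n_snps_dropped = dat$grm$n_snps_dropped),
       "relationship_summary.csv")

  say("whole-data fit (%d traits) + crossval (%d cells)",
      length(traits), config$n_cohorts * length(traits))
  metrics <- stage("crossval",
                   run_crossval(dat$pheno, dat$grm, traits = traits,
                                masking = masking, h2_source = h2_source,
                                sd_ref_scope = sd_ref_scope,
                                truth = dat$truth, verbose = verbose))
  whole_fit <- attr(metrics, "whole_fit")

  # heritabilities on the diagonal, genetic above, residual below
  t <- length(traits)
  h2corr <- matrix(NA_real_, t, t, dimnames = list(traits, traits))
  diag(h2corr) <- whole_fit$h2
  if (t > 1) {
    h2corr[upper.tri(h2corr)] <- whole_fit$gen_corr[upper.tri(h2corr)]
    h2corr[lower.tri(h2corr)] <- whole_fit$res_corr[lower.tri(h2corr)]
  }
  emit(data.frame(trait = traits, h2corr, check.names = FALSE),
       "h2_correlations.csv")

  emit(as.data.frame(metrics), "metrics_cells.csv")
  summ <- summarize_metrics(metrics)
  emit(summ$per_trait, "metric_summaries.csv")

  say("meta-analysis + Q1Q4")
  anova_res <- lapply(c("acc_t", "acc_lr", "bias_lr", "disp_lr"),
                      function(me) tryCatch(anova_metrics(metrics, me),
                                            error = function(e) NULL))
  names(anova_res) <- c("acc_t", "acc_lr", "bias_lr", "disp_lr")
  an_tab <- do.call(rbind, lapply(names(anova_res), function(me) {
    a <- anova_res[[me]]
    if (is.null(a))
      return(data.frame(metric = me, term = NA, p_value = NA, r2 = NA))
    data.frame(metric = me, term = names(a$p_values),
               p_value = unname(a$p_values), r2 = a$r2,
               stringsAsFactors = FALSE)
  }))
  emit(an_tab, "anova_metrics.csv")

  qq_tab <- metrics[, c("trait", "cohort", "n_validation", "q1q4_raw",
                        "q1q4_se", "q1q4_sd", "n_q1")]
  emit(as.data.frame(qq_tab), "q1q4_cells.csv")
  regs <- lapply(c("acc_lr", "acc_t"), function(ac)
    tryCatch(regress_q1q4(metrics, ac), error = function(e) NULL))
  names(regs) <- c("acc_lr", "acc_t")
  reg_tab <- do.call(rbind, lapply(names(regs), function(ac) {
    r <- regs[[ac]]
    if (is.null(r))
      return(data.frame(acc_column = ac, slope_per_0.1 = NA,
                        intercept = NA, intercept_p = NA, r2 = NA, n = NA))
    data.frame(acc_column = ac, slope_per_0.1 = r$slope_per_0.1_acc,
               intercept = r$intercept$estimate,
               intercept_p = r$intercept$p, r2 = r$r2, n = r$n,
               stringsAsFactors = FALSE)
  }))
  emit(reg_tab, "q1q4_regression.csv")

  linkage <- linkage_report(dat$pheno)
  emit(as.data.frame.matrix(linkage$shared_sires), "sire_linkage.csv",
       row.names = TRUE)

  manifest <- list(
    seed = config$seed,
    n_animals = config$n_animals,
    n_snps = config$n_snps,
    traits = traits,
    n_cells = nrow(metrics),
    n_cells_converged = sum(metrics$converged),
    whole_fit_converged = whole_fit$converged,
    files = files
  )
  fp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, fp, auto_unbox = TRUE, pretty = TRUE)
  files <- c(files, "manifest.json")
  say("done: %d files in %s", length(files), out_dir)

  invisible(list(data = dat, whole_fit = whole_fit, metrics = metrics,
                 summary = summ, anova = anova_res,
                 q1q4_regressions = regs, linkage = linkage,
                 manifest = manifest))
}
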