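#' ANOVA of a GEBV quality metric on its determinants
#'
#' Fits `metric ~ h2 + cohort + trait` by ordinary least squares over the
#' cross-validation cells, where `h2` is the per-cell partial-run
#' heritability estimate (the whole-data estimate is constant within
#' trait and would be perfectly aliased with the trait factor), and
#' reports a marginal (type-III-style) F-test P-value per term and the
#' overall coefficient of determination as a percentage.
#'
#' @param metrics A `metrics_table` from [run_crossval()].
#' @param metric One of `"acc_t"`, `"acc_lr"`, `"bias_lr"`, `"disp_lr"`.
#' @return List of class `anova_metrics`: `metric`, `p_values` (named:
#'   h2, cohort, trait), `r2` (percent), `n`, `fit`.
#' @export
anova_metrics <- function(metrics,
                          metric = c("acc_t", "acc_lr", "bias_lr",
                                     "disp_lr")) {
  metric <- if (is.character(metric)) metric[1] else metric
  .assert(metric %in% names(metrics),
          sprintf("no column '%s' in metrics", metric))
  df <- data.frame(y = metrics[[metric]],
                   h2 = metrics$h2_partial,
                   cohort = factor(metrics$cohort),
                   trait = factor(metrics$trait))
  df <- df[complete.cases(df), , drop = FALSE]
  within_var <- tapply(df$h2, df$trait, function(v) var(v))
  if (all(within_var < 1e-12, na.rm = TRUE))
    stop("h2 is constant within every trait (aliased with the trait ",
         "factor); use per-cell partial-run heritability estimates",
         call. = FALSE)
  terms_use <- c("h2",
                 if (nlevels(droplevels(df$cohort)) > 1) "cohort",
                 if (nlevels(droplevels(df$trait)) > 1) "trait")
  npar <- 1 + 1 + (nlevels(droplevels(df$cohort)) - 1) +
    (nlevels(droplevels(df$trait)) - 1)
  .assert(nrow(df) >= npar + 1, "too few cells for the ANOVA")
  fit <- lm(as.formula(paste("y ~", paste(terms_use, collapse = "+"))),
            data = df)
  sm <- summary(fit)
  d1 <- drop1(fit, test = "F")
  pv <- setNames(d1[["Pr(>F)"]][-1], rownames(d1)[-1])
  structure(list(metric = metric, p_values = pv,
                 r2 = 100 * sm$r.squared, n = nrow(df), fit = fit),
            class = "anova_metrics")
}

#' @export
print.anova_metrics <- function(x, ...) {
  cat(sprintf("ANOVA of %s (n = %d cells): R2 = %.1f%%\n",
              x$metric, x$n, x$r2))
  for (tm in names(x$p_values))
    cat(sprintf("  %s: P = %.4g\n", tm, x$p_values[[tm]]))
  invisible(x)
}

#' Variability and correlation summaries of the accuracy metrics
#'
#' Per trait, the across-cohort SD and coefficient of variation (100 x
#' SD/mean, undefined when the mean is not positive) of the traditional
#' and LR accuracies; across all cells, the Pearson correlation (with
#' P-value) between the two accuracies, and the correlations of the
#' partial heritability with the LR accuracy and with the LR dispersion,
#' each with the large-sample SE `sqrt((1 - r^2) / (n - 2))`.
#'
#' @param metrics A `metrics_table` from [run_crossval()].
#' @return List with `per_trait` (data frame: trait, n, sd_acc_t,
#'   cv_acc_t, sd_acc_lr, cv_acc_lr) and `correlations` (list of
#'   acc_t_acc_lr, h2_acc_lr, h2_disp_lr with r, se, p, n).
#' @export
accuracy_dispersion_summary <- function(metrics) {
  per <- do.call(rbind, lapply(unique(metrics$trait), function(tr) {
    sub <- metrics[metrics$trait == tr, , drop = FALSE]
    .assert(nrow(sub) >= 2,
            sprintf("need >= 2 cohorts per trait (trait %s)", tr))
    cv <- function(v) {
      v <- v[!is.na(v)]
      if (mean(v) <= 0) return(NA_real_)
      100 * sd(v) / mean(v)
    }
    data.frame(trait = tr, n = nrow(sub),
               sd_acc_t = sd(sub$acc_t, na.rm = TRUE),
               cv_acc_t = cv(sub$acc_t),
               sd_acc_lr = sd(sub$acc_lr, na.rm = TRUE),
               cv_acc_lr = cv(sub$acc_lr),
               stringsAsFactors = FALSE)
  }))
  corr <- function(x, y) {
    keep <- !is.na(x) & !is.na(y)
    if (sum(keep) < 3)
      return(list(r = NA_real_, se = NA_real_, p = NA_real_,
                  n = sum(keep)))
    h <- cor.test(x[keep], y[keep])
    r <- unname(h$estimate)
    n <- sum(keep)
    list(r = r, se = sqrt((1 - r^2) / (n - 2)), p = h$p.value, n = n)
  }
  list(per_trait = per,
       correlations = list(
         acc_t_acc_lr = corr(metrics$acc_t, metrics$acc_lr),
         h2_acc_lr = corr(metrics$h2_partial, metrics$acc_lr),
         h2_disp_lr = corr(metrics$h2_partial, metrics$disp_lr)))
}

#' Sire and herd linkage report
#'
#' Incidence of sires and herds across year-of-birth cohorts: in the
#' intended design each sire's progeny fall in a single cohort, so the
#' off-diagonal shared-sire counts are (near) zero and each cohort forms
#' an independent validation set.
#'
#' @param pheno Phenotype table with `sire`, `herd`, `cohort` columns.
#' @return List with `sire_by_cohort` and `herd_by_cohort` incidence
#'   tables, `shared_sires` (cohort x cohort counts of sires with progeny
#'   in both), `progeny_per_sire` (mean, min, max), `sires_per_cohort`.
#' @export
linkage_report <- function(pheno) {
  .assert(all(c("sire", "cohort") %in% names(pheno)),
          "pheno needs 'sire' and 'cohort' columns")
  sire <- as.character(pheno$sire)
  sire[is.na(sire) | sire == ""] <- "unknown"
  cohort <- factor(pheno$cohort)
  sbc <- table(sire = sire, cohort = cohort)
  inc <- sbc > 0
  shared <- t(inc) %*% inc  # [c1, c2] = sires present in both cohorts
  diag_known <- rownames(sbc) != "unknown"
  pps <- rowSums(sbc[diag_known, , drop = FALSE])
  out <- list(
    sire_by_cohort = sbc,
    shared_sires = shared,
    progeny_per_sire = c(mean = mean(pps), min = min(pps), max = max(pps)),
    sires_per_cohort = colSums(inc[diag_known, , drop = FALSE])
  )
  if ("herd" %in% names(pheno))
    out$herd_by_cohort <- table(herd = factor(pheno$herd), cohort = cohort)
  out
}
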