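#' Cross-validation plan over validation cohorts and traits
#'
#' Enumerates all cohort x trait cells of the partial/whole validation
#' design (one univariate partial fit per cell). Seven traits by seven
#' year-of-birth cohorts give the 49-cell design.
#'
#' @param cohorts Ordered cohort labels.
#' @param traits Ordered trait names.
#' @return Object of class `crossval_plan`: data frame `cells` with
#'   columns `cohort`, `trait`, plus the cohort/trait vectors.
#' @export
crossval_plan <- function(cohorts, traits) {
  .assert(length(cohorts) >= 1 && length(traits) >= 1,
          "need at least one cohort and one trait")
  cells <- expand.grid(cohort = cohorts, trait = traits,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  structure(list(cohorts = cohorts, traits = traits, cells = cells),
            class = "crossval_plan")
}

#' Mask one trait for one validation cohort
#'
#' Returns a copy of the phenotype table in which the focal trait is set
#' missing for every animal of the focal cohort; all other records are
#' untouched. The number of newly masked records is attached as the
#' `masked_n` attribute.
#'
#' @param pheno Phenotype table with a `cohort` column.
#' @param cohort Focal cohort label.
#' @param trait Focal trait column.
#' @param forward If `TRUE`, also mask all later cohorts (forward
#'   truncation variant for sensitivity analysis); default masks the
#'   focal cohort only.
#' @return The masked phenotype table.
#' @export
mask_cell <- function(pheno, cohort, trait, forward = FALSE) {
  .assert(trait %in% names(pheno), sprintf("unknown trait '%s'", trait))
  .assert(cohort %in% as.character(pheno$cohort),
          sprintf("unknown cohort '%s'", cohort))
  lev <- if (forward) {
    all_lev <- levels(factor(pheno$cohort))
    all_lev[seq(match(cohort, all_lev), length(all_lev))]
  } else cohort
  sel <- as.character(pheno$cohort) %in% lev
  masked_n <- sum(sel & !is.na(pheno[[trait]]))
  out <- pheno
  out[[trait]][sel] <- NA_real_
  .assert(any(!is.na(out[[trait]])),
          "masking left no training records for the trait")
  attr(out, "masked_n") <- masked_n
  out
}

#' Traditional accuracy of GEBV
#'
#' Pearson correlation between partial-data GEBV and adjusted phenotypes
#' of the validation animals, divided by the square root of the
#' heritability. Pairs with missing adjusted phenotype are excluded.
#'
#' @param u_p Partial-data GEBV of the validation animals.
#' @param y_star Adjusted phenotypes of the same animals (same order).
#' @param h2 Heritability in (0, 1].
#' @return The traditional accuracy (NA with a warning if either vector
#'   has zero variance).
#' @export
acc_traditional <- function(u_p, y_star, h2) {
  .assert(length(u_p) == length(y_star), "length mismatch")
  .assert(is.finite(h2) && h2 > 0 && h2 <= 1, "h2 must lie in (0, 1]")
  keep <- !is.na(u_p) & !is.na(y_star)
  .assert(sum(keep) >= 3, "need at least 3 validation pairs")
  u <- u_p[keep]; y <- y_star[keep]
  if (var(u) == 0 || var(y) == 0) {
    warning("zero variance: traditional accuracy undefined")
    return(NA_real_)
  }
  cor(u, y) / sqrt(h2)
}

#' LR-method bias
#'
#' Difference between the mean partial-data GEBV and the mean whole-data
#' GEBV of the validation animals, in trait units. Zero in expectation
#' for unbiased predictions.
#'
#' @param u_p,u_w Partial- and whole-data GEBV (same animals, same order).
#' @return `mean(u_p) - mean(u_w)`.
#' @export
bias_lr <- function(u_p, u_w) {
  .assert(length(u_p) == length(u_w) && length(u_p) >= 1,
          "u_p and u_w must be non-empty and of equal length")
  mean(u_p) - mean(u_w)
}

#' LR-method dispersion
#'
#' Slope of the regression of whole-data GEBV on partial-data GEBV over
#' the validation animals, `cov(u_w, u_p) / var(u_p)`; 1 in expectation
#' for correctly dispersed predictions (< 1 indicates over-dispersion of
#' the partial GEBV).
#'
#' @param u_w,u_p Whole- and partial-data GEBV (same animals, same order).
#' @return The regression slope (NA with a warning if `var(u_p)` is 0).
#' @export
dispersion_lr <- function(u_w, u_p) {
  .assert(length(u_p) == length(u_w) && length(u_p) >= 3,
          "need at least 3 animals")
  if (var(u_p) == 0) {
    warning("zero variance in u_p: dispersion undefined")
    return(NA_real_)
  }
  cov(u_w, u_p) / var(u_p)
}

#' LR-method accuracy
#'
#' `sqrt(cov(u_w, u_p) / ((1 + F_bar - 2f_bar) * sigma2_g))`, where
#' `F_bar` and `2f_bar` are the average inbreeding and average pairwise
#' relationship of the validation animals and `sigma2_g` is the additive
#' genetic variance (estimated from the partial dataset, assuming the
#' validation animals are not under selection).
#'
#' @param u_w,u_p Whole- and partial-data GEBV of the validation animals.
#' @param rel A [relationship_summary()] over the validation animals.
#' @param sigma_g Additive genetic variance (> 0).
#' @return The LR accuracy; NA (flagged with a warning, never silently
#'   clamped) when the radicand is negative.
#' @export
acc_lr <- function(u_w, u_p, rel, sigma_g) {
  .assert(length(u_p) == length(u_w) && length(u_p) >= 3,
          "need at least 3 animals")
  .assert(is.finite(sigma_g) && sigma_g > 0, "sigma_g must be positive")
  denom_f <- 1 + rel$F_bar - rel$two_f_bar
  .assert(denom_f > 0,
          sprintf("non-positive denominator: F_bar = %.4f, 2f_bar = %.4f",
                  rel$F_bar, rel$two_f_bar))
  rad <- cov(u_w, u_p) / (denom_f * sigma_g)
  if (rad < 0) {
    warning("negative radicand: LR accuracy undefined for this cell")
    return(NA_real_)
  }
  sqrt(rad)
}

#' Run the cohort-based partial/whole cross-validation
#'
#' One whole-data (multi-trait if several traits) fit provides the
#' calibration GEBV `u_w` and the fixed-effect estimates used to adjust
#' phenotypes; then, for every cohort x trait cell of the plan, the focal
#' trait is masked for the focal cohort, a univariate partial fit is run,
#' and the four GEBV quality metrics plus the Q1Q4 quartile difference
#' are computed on the validation animals (cohort animals with an
#' observed phenotype for the trait).
#'
#' @param pheno Phenotype table.
#' @param grm [compute_grm()] result covering all animals.
#' @param traits Traits to analyse (default: all).
#' @param spec [model_spec()] (default: [default_model_spec()]).
#' @param plan [crossval_plan()] (default: all cohorts x traits).
#' @param masking `"single"` (default) masks the focal cohort only;
#'   `"forward"` also masks all later cohorts.
#' @param h2_source Heritability used by the traditional accuracy:
#'   `"whole"` (default) the whole-data estimate, `"partial"` the
#'   cell's partial estimate.
#' @param sd_ref_scope SD used to express Q1Q4 in SD units: adjusted
#'   phenotypes of `"all"` animals (default) or of the `"validation"`
#'   cohort only.
#' @param truth Optional truth list from [simulate_phenotypes()]; adds a
#'   `true_acc` column (correlation of `u_p` with true breeding values).
#' @param whole_fit Optional precomputed whole-data fit to reuse.
#' @param verbose Print progress.
#' @return A `metrics_table` data frame with one row per cell: `trait`,
#'   `cohort`, `n_validation`, `acc_t`, `bias_lr`, `disp_lr`, `acc_lr`,
#'   `h2_partial`, `sigma_g_partial`, `F_bar`, `two_f_bar`, `q1q4_raw`,
#'   `q1q4_se`, `q1q4_sd`, `n_q1`, `converged` (and `true_acc` when truth
#'   is given). The whole fit and adjusted phenotypes are attached as
#'   attributes `whole_fit` and `adjusted`.
#' @export
run_crossval <- function(pheno, grm, traits = NULL, spec = NULL,
                         plan = NULL, masking = c("single", "forward"),
                         h2_source = c("whole", "partial"),
                         sd_ref_scope = c("all", "validation"),
                         truth = NULL, whole_fit = NULL, verbose = FALSE) {
  masking <- match.arg(masking)
  h2_source <- match.arg(h2_source)
  sd_ref_scope <- match.arg(sd_ref_scope)
  if (is.null(traits)) traits <- attr(pheno, "traits")
  if (is.null(spec)) spec <- default_model_spec(pheno, traits)
  if (is.null(plan))
    plan <- crossval_plan(levels(factor(pheno$cohort)), traits)

  if (is.null(whole_fit)) {
    if (verbose) message("whole-data fit (", length(traits), " traits)")
    whole_fit <- fit_reml(pheno, grm, traits = traits, spec = spec)
  }
  .assert(whole_fit$converged,
          "whole-data fit did not converge; cannot calibrate")
  adjusted <- adjust_phenotypes(pheno, whole_fit)

  cells <- plan$cells
  res <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    co <- cells$cohort[i]; tr <- cells$trait[i]
    if (verbose) message(sprintf("cell %d/%d: %s x %s",
                                 i, nrow(cells), tr, co))
    row <- data.frame(trait = tr, cohort = co, n_validation = NA_integer_,
                      acc_t = NA_real_, bias_lr = NA_real_,
                      disp_lr = NA_real_, acc_lr = NA_real_,
                      h2_partial = NA_real_, sigma_g_partial = NA_real_,
                      F_bar = NA_real_, two_f_bar = NA_real_,
                      q1q4_raw = NA_real_, q1q4_se = NA_real_,
                      q1q4_sd = NA_real_, n_q1 = NA_integer_,
                      converged = FALSE, stringsAsFactors = FALSE)
    if (!is.null(truth)) row$true_acc <- NA_real_
    out <- tryCatch({
      masked <- mask_cell(pheno, co, tr, forward = masking == "forward")
      pfit <- fit_reml(masked, grm, traits = tr, spec = spec)
      val <- pheno$animal[as.character(pheno$cohort) == co &
                            !is.na(pheno[[tr]])]
      .assert(length(val) >= 3, "fewer than 3 validation animals")
      u_p <- pfit$gebv[val, tr]
      u_w <- whole_fit$gebv[val, tr]
      ystar_all <- setNames(adjusted$y_star[[tr]],
                            adjusted$y_star$animal)
      y_val <- ystar_all[val]
      rel <- relationship_summary(grm, val)
      h2_use <- if (h2_source == "whole") whole_fit$h2[[tr]]
                else pfit$h2[[tr]]
      sd_ref <- if (sd_ref_scope == "all") adjusted$sd_per_trait[[tr]]
                else sd(y_val, na.rm = TRUE)

      row$n_validation <- length(val)
      row$acc_t <- acc_traditional(u_p, y_val, h2_use)
      row$bias_lr <- bias_lr(u_p, u_w)
      row$disp_lr <- dispersion_lr(u_w, u_p)
      row$acc_lr <- suppressWarnings(
        acc_lr(u_w, u_p, rel, pfit$V_G[1, 1]))
      row$h2_partial <- pfit$h2[[tr]]
      row$sigma_g_partial <- pfit$V_G[1, 1]
      row$F_bar <- rel$F_bar
      row$two_f_bar <- rel$two_f_bar
      qq <- tryCatch(q1q4_difference(u_p, y_val, sd_ref),
                     error = function(e) NULL)
      if (!is.null(qq)) {
        row$q1q4_raw <- qq$q1q4_raw
        row$q1q4_se <- qq$se
        row$q1q4_sd <- qq$q1q4_sd
        row$n_q1 <- qq$n_q1
      }
      row$converged <- pfit$converged
      if (!is.null(truth))
        row$true_acc <- cor(u_p, truth$true_bv[val, tr])
      row
    }, error = function(e) {
      warning(sprintf("cell %s x %s failed: %s", tr, co,
                      conditionMessage(e)))
      row
    })
    res[[i]] <- out
  }
  mt <- do.call(rbind, res)
  class(mt) <- c("metrics_table", "data.frame")
  attr(mt, "whole_fit") <- whole_fit
  attr(mt, "adjusted") <- adjusted
  attr(mt, "h2_whole") <- whole_fit$h2
  mt
}

#' Summarize a cross-validation metrics table
#'
#' Per-trait mean, SD, min and max of each GEBV quality metric over the
#' validation cohorts (cells flagged as non-converged are excluded, with
#' a count), plus the across-cell Pearson correlation between the
#' traditional and LR accuracies.
#'
#' @param metrics A `metrics_table` from [run_crossval()].
#' @return List with `per_trait` (long data frame: trait, metric, mean,
#'   sd, min, max), `cor_acc` (correlation, P-value, n), `n_excluded`.
#' @export
summarize_metrics <- function(metrics) {
  ok <- metrics$converged & !is.na(metrics$disp_lr)
  m <- metrics[ok, , drop = FALSE]
  mets <- c("acc_t", "acc_lr", "bias_lr", "disp_lr")
  out <- do.call(rbind, lapply(unique(m$trait), function(tr) {
    sub <- m[m$trait == tr, , drop = FALSE]
    do.call(rbind, lapply(mets, function(me) {
      v <- sub[[me]][!is.na(sub[[me]])]
      data.frame(trait = tr, metric = me, mean = mean(v), sd = sd(v),
                 min = min(v), max = max(v), stringsAsFactors = FALSE)
    }))
  }))
  ct <- if (sum(!is.na(m$acc_t) & !is.na(m$acc_lr)) >= 3) {
    h <- cor.test(m$acc_t, m$acc_lr)
    list(r = unname(h$estimate), p_value = h$p.value,
         n = sum(complete.cases(m[, c("acc_t", "acc_lr")])))
  } else list(r = NA_real_, p_value = NA_real_, n = 0L)
  list(per_trait = out, cor_acc = ct, n_excluded = sum(!ok))
}
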