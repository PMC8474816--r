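#' Q1Q4 quartile difference of adjusted phenotypes
#'
#' Ranks validation animals by GEBV (descending, ties broken stably by
#' animal ID), takes the top (`Q1`) and bottom (`Q4`) `floor(n/4)`
#' animals, and returns the difference between their mean adjusted
#' phenotypes: a direct phenotypic-scale readout of how well the GEBV
#' ranking discriminates extremes. The SD-unit version divides by a
#' reference SD of adjusted phenotypes, making it comparable across
#' traits.
#'
#' @param u_rank GEBV used for ranking (validation animals).
#' @param y_star Adjusted phenotypes of the same animals (same order).
#' @param sd_ref Reference SD of adjusted phenotypes (> 0); by
#'   convention the SD over all animals for the trait.
#' @param ids Optional animal IDs for stable tie-breaking (default:
#'   names of `u_rank`, else positional).
#' @return List of class `q1q4`: `q1q4_raw` (trait units), `se`
#'   (`sqrt(s1^2/n1 + s4^2/n4)`), `q1q4_sd` (`q1q4_raw / sd_ref`),
#'   `n_q1`, `n_q4`, `mean_q1`, `mean_q4`.
#' @examples
#' set.seed(1)
#' y <- rnorm(100)
#' q1q4_difference(y, y, sd_ref = sd(y))  # perfect ranking
#' @export
q1q4_difference <- function(u_rank, y_star, sd_ref, ids = NULL) {
  .assert(length(u_rank) == length(y_star), "length mismatch")
  .assert(is.finite(sd_ref) && sd_ref > 0, "sd_ref must be positive")
  if (is.null(ids)) ids <- names(u_rank)
  if (is.null(ids)) ids <- as.character(seq_along(u_rank))
  keep <- !is.na(u_rank) & !is.na(y_star)
  u <- u_rank[keep]; y <- y_star[keep]; id <- ids[keep]
  n <- length(u)
  .assert(n >= 8, "need at least 8 validation animals with observed y*")
  k <- floor(n / 4)
  .assert(k >= 1, "quartile size is zero")
  if (length(unique(u)) == 1)
    warning("all GEBV tied: quartile membership is arbitrary")
  ord <- order(-u, id)
  q1 <- ord[seq_len(k)]
  q4 <- ord[seq(n - k + 1, n)]
  diff <- mean(y[q1]) - mean(y[q4])
  se <- sqrt(var(y[q1]) / k + var(y[q4]) / k)
  structure(list(q1q4_raw = diff, se = se, q1q4_sd = diff / sd_ref,
                 n_q1 = k, n_q4 = k,
                 mean_q1 = mean(y[q1]), mean_q4 = mean(y[q4])),
            class = "q1q4")
}

#' Regression of Q1Q4 on an accuracy metric
#'
#' Ordinary least squares of the SD-unit Q1Q4 difference on trait
#' (categorical), validation cohort (categorical) and a chosen accuracy
#' column (continuous), quantifying how phenotypic discrimination between
#' extreme GEBV quartiles grows with prediction accuracy. Reports the
#' slope per unit and per 0.1 of accuracy, the intercept t-test (an
#' intercept near zero means zero accuracy implies no quartile
#' difference), and marginal (type-III-style) F-tests per term.
#'
#' @param metrics A `metrics_table` from [run_crossval()] (or any data
#'   frame with `q1q4_sd`, `trait`, `cohort` and the accuracy column).
#' @param acc_column `"acc_lr"` or `"acc_t"` (or another numeric column).
#' @return Object of class `q1q4_regression`: `slope_per_unit_acc`,
#'   `slope_per_0.1_acc`, `intercept` (estimate, se, t, p), `p_values`
#'   (per term), `r2`, `n`, and the underlying `fit`.
#' @export
regress_q1q4 <- function(metrics, acc_column = c("acc_lr", "acc_t")) {
  acc_column <- if (is.character(acc_column)) acc_column[1] else acc_column
  .assert(acc_column %in% names(metrics),
          sprintf("no column '%s' in metrics", acc_column))
  df <- data.frame(q1q4_sd = metrics$q1q4_sd,
                   trait = factor(metrics$trait),
                   cohort = factor(metrics$cohort),
                   acc = metrics[[acc_column]])
  df <- df[complete.cases(df), , drop = FALSE]
  npar <- 1 + (nlevels(droplevels(df$trait)) - 1) +
    (nlevels(droplevels(df$cohort)) - 1) + 1
  .assert(nrow(df) >= npar + 1, "too few cells for the Q1Q4 regression")
  terms_use <- c(if (nlevels(droplevels(df$trait)) > 1) "trait",
                 if (nlevels(droplevels(df$cohort)) > 1) "cohort",
                 "acc")
  fit <- lm(as.formula(paste("q1q4_sd ~", paste(terms_use, collapse = "+"))),
            data = df)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; aliased terms: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  d1 <- drop1(fit, test = "F")
  pv <- setNames(d1[["Pr(>F)"]][-1], rownames(d1)[-1])
  slope <- unname(coef(fit)["acc"])
  ic <- sm$coefficients["(Intercept)", ]
  structure(list(
    acc_column = acc_column,
    slope_per_unit_acc = slope,
    slope_per_0.1_acc = slope / 10,
    intercept = list(estimate = unname(ic[1]), se = unname(ic[2]),
                     t = unname(ic[3]), p = unname(ic[4])),
    p_values = pv,
    r2 = sm$r.squared,
    n = nrow(df),
    fit = fit
  ), class = "q1q4_regression")
}

#' @export
print.q1q4_regression <- function(x, ...) {
  cat(sprintf("Q1Q4 ~ trait + cohort + %s  (n = %d cells, R2 = %.3f)\n",
              x$acc_column, x$n, x$r2))
  cat(sprintf("  slope: %.3f SD units per 0.1 accuracy\n",
              x$slope_per_0.1_acc))
  cat(sprintf("  intercept: %.3f (p = %.3g)\n",
              x$intercept$estimate, x$intercept$p))
  for (tm in names(x$p_values))
    cat(sprintf("  %s: P = %.4g\n", tm, x$p_values[[tm]]))
  invisible(x)
}
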