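test_that("the cohort-by-trait plan enumerates every cell", {
  traits7 <- c("ADG", "DMI", "CWT", "EMA", "MBL", "OSS", "RIB")
  plan <- crossval_plan(paste0("C", 1:7), traits7)
  expect_equal(nrow(plan$cells), 49L)
  expect_equal(nrow(unique(plan$cells)), 49L)
  plan2 <- crossval_plan(c("C1", "C2"), "x")
  expect_equal(nrow(plan2$cells), 2L)
})

test_that("cell masking is isolated, counted and non-destructive", {
  d <- quick_uni_dataset(n_sires = 10, cohort_n = 30, n_cohorts = 2,
                         n_snps = 200, missing_rate = 0.1, seed = 6)
  tr <- d$config$traits
  ph <- d$pheno
  masked <- mask_cell(ph, "C1", tr)
  in_c1 <- ph$cohort == "C1"
  expect_true(all(is.na(masked[[tr]][in_c1])))
  expect_identical(masked[[tr]][!in_c1], ph[[tr]][!in_c1])
  expect_equal(attr(masked, "masked_n"),
               sum(in_c1 & !is.na(ph[[tr]])))
  # non-trait columns and the original table are untouched
  expect_identical(masked$animal, ph$animal)
  expect_identical(ph, d$pheno)
  # restoring the masked records reproduces the original values
  restored <- masked
  restored[[tr]][in_c1] <- ph[[tr]][in_c1]
  expect_identical(restored[[tr]], ph[[tr]])
  expect_error(mask_cell(ph, "C9", tr), "cohort")
  expect_error(mask_cell(ph, "C1", "nope"), "trait")
})

test_that("forward masking removes the focal and all later cohorts", {
  d <- quick_uni_dataset(n_sires = 12, cohort_n = 20, n_cohorts = 3,
                         n_snps = 200, seed = 8)
  tr <- d$config$traits
  m <- mask_cell(d$pheno, "C2", tr, forward = TRUE)
  expect_true(all(is.na(m[[tr]][d$pheno$cohort %in% c("C2", "C3")])))
  expect_true(all(!is.na(m[[tr]][d$pheno$cohort == "C1"])))
})

test_that("metric formulas match their closed forms", {
  set.seed(2)
  u <- rnorm(50)
  y <- rnorm(50)
  expect_equal(acc_traditional(u, u, 1), 1)
  expect_equal(acc_traditional(u, y, 0.25), cor(u, y) / 0.5)
  expect_error(acc_traditional(u, y, 0), "h2")
  expect_error(acc_traditional(u, y[1:10], 0.5), "mismatch")

  expect_equal(bias_lr(u, u), 0)
  expect_equal(bias_lr(u + 0.27, u), 0.27)
  v <- rnorm(5)
  w <- rnorm(5)
  expect_equal(bias_lr(v, w), sum(v) / 5 - sum(w) / 5, tolerance = 1e-14)

  expect_equal(dispersion_lr(2 * u, u), 2)
  expect_equal(dispersion_lr(u, u), 1)
  x6 <- rnorm(6); y6 <- rnorm(6)
  ls <- solve(crossprod(cbind(1, x6)), crossprod(cbind(1, x6), y6))
  expect_equal(dispersion_lr(y6, x6), ls[2], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_warning(dispersion_lr(u, rep(1, 50)), "zero variance")
})

test_that("LR accuracy follows its formula and flags bad inputs", {
  u_p <- c(-1, 0, 1)  # var = 1
  rel0 <- list(F_bar = 0, two_f_bar = 0)
  expect_equal(acc_lr(u_p, u_p, rel0, sigma_g = 1), 1)
  # cov = 0.25, F = 0.05, 2f = 0, sigma_g = 0.25
  rel <- list(F_bar = 0.05, two_f_bar = 0)
  expect_equal(acc_lr(0.25 * u_p, u_p, rel, sigma_g = 0.25),
               sqrt(0.25 / (1.05 * 0.25)), tolerance = 1e-12)
  expect_warning(val <- acc_lr(-u_p, u_p, rel0, sigma_g = 1), "radicand")
  expect_true(is.na(val))
  expect_error(acc_lr(u_p, u_p, list(F_bar = -0.5, two_f_bar = 0.6), 1),
               "F_bar")
  expect_error(acc_lr(u_p, u_p, rel0, sigma_g = 0), "sigma_g")
})

test_that("metric invariances hold across random cases", {
  set.seed(33)
  for (r in 1:10) {
    up <- rnorm(30); uw <- rnorm(30); c0 <- runif(1, -5, 5)
    a <- runif(1, 0.2, 3)
    expect_equal(bias_lr(up + c0, uw + c0), bias_lr(up, uw),
                 tolerance = 1e-12)
    expect_equal(dispersion_lr(a * uw, up), a * dispersion_lr(uw, up),
                 tolerance = 1e-10)
    # traditional accuracy invariant to positive affine transforms of y*
    ys <- rnorm(30)
    expect_equal(acc_traditional(up, a * ys + c0, 0.4),
                 acc_traditional(up, ys, 0.4), tolerance = 1e-12)
  }
})

test_that("a toy two-cohort design runs end-to-end with finite metrics", {
  d <- quick_uni_dataset(h2 = 0.5, n_sires = 12, cohort_n = 30,
                         n_cohorts = 2, n_snps = 200, seed = 10)
  mt <- suppressWarnings(
    run_crossval(d$pheno, d$grm, truth = d$truth))
  expect_s3_class(mt, "metrics_table")
  expect_equal(nrow(mt), 2L)
  expect_true(all(mt$converged))
  expect_true(all(is.finite(mt$bias_lr)))
  expect_true(all(is.finite(mt$disp_lr)))
  expect_true(all(mt$n_validation == 30))
  summ <- summarize_metrics(mt)
  expect_equal(nrow(summ$per_trait), 4L)  # 1 trait x 4 metrics
})
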