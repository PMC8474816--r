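# dense mixed-model-equations oracle: solves
# [X'X/s2e  X'Z/s2e          ] [b]   [X'y/s2e]
# [Z'X/s2e  Z'Z/s2e + Kinv/s2g] [u] = [Z'y/s2e]
mme_oracle <- function(y, X, Z, K, s2g, s2e) {
  Kinv <- solve(K)
  C <- rbind(cbind(crossprod(X) / s2e, crossprod(X, Z) / s2e),
             cbind(crossprod(Z, X) / s2e,
                   crossprod(Z) / s2e + Kinv / s2g))
  rhs <- c(crossprod(X, y) / s2e, crossprod(Z, y) / s2e)
  sol <- solve(C, rhs)
  list(beta = sol[seq_len(ncol(X))], u = sol[-seq_len(ncol(X))])
}

test_that("GBLUP solutions equal the dense mixed-model-equations solve", {
  set.seed(1)
  n <- 5
  y <- rnorm(n)
  X <- cbind(1, rnorm(n))
  # identity and non-trivial PD relationship matrices
  for (K in list(diag(n), crossprod(matrix(rnorm(n * n), n)) / n + diag(n))) {
    s <- gblup_solutions(y, X, K, sigma2_g = 0.7, sigma2_e = 0.4)
    o <- mme_oracle(y, X, diag(n), K, 0.7, 0.4)
    expect_lt(max(abs(s$beta - o$beta)), 1e-10)
    expect_lt(max(abs(s$u - o$u)), 1e-10)
  }
})

test_that("GEBV of phenotype-masked animals match the dense oracle", {
  d <- quick_uni_dataset(n_sires = 8, cohort_n = 20, n_cohorts = 2,
                         n_snps = 400, seed = 3)
  tr <- d$config$traits
  ph <- d$pheno
  ph[[tr]][1:8] <- NA  # mask some animals entirely
  spec <- model_spec(tr)  # intercept-only, so the oracle design is exact
  fit <- fit_reml(ph, d$grm, traits = tr, spec = spec)
  obs <- which(!is.na(ph[[tr]]))
  n_all <- nrow(ph)
  Z <- diag(n_all)[obs, , drop = FALSE]
  # MME at the estimated variances, breeding values for ALL animals
  o <- mme_oracle(ph[[tr]][obs], X = matrix(1, length(obs), 1), Z = Z,
                  K = d$grm$values + diag(1e-8, n_all),
                  s2g = fit$V_G[1, 1], s2e = fit$V_R[1, 1])
  expect_lt(max(abs(fit$gebv[ph$animal, tr] - o$u)), 1e-5)
})

test_that("REML is scale equivariant and the log-likelihood is monotone", {
  d <- quick_uni_dataset(n_sires = 15, cohort_n = 75, n_snps = 600,
                         seed = 9)
  tr <- d$config$traits
  f1 <- fit_reml(d$pheno, d$grm)
  ph2 <- d$pheno
  ph2[[tr]] <- 10 * ph2[[tr]]
  f2 <- fit_reml(ph2, d$grm)
  expect_lt(abs(f2$V_G[1, 1] / f1$V_G[1, 1] - 100) / 100, 1e-6)
  expect_lt(abs(f2$V_R[1, 1] / f1$V_R[1, 1] - 100) / 100, 1e-6)
  expect_lt(abs(f2$h2 - f1$h2), 1e-6)
  expect_true(all(diff(f1$logl_trace) > -1e-8))
  expect_true(f1$converged)
})

test_that("a pure-genetic phenotype drives h2 to the flagged boundary", {
  d <- quick_uni_dataset(n_sires = 10, cohort_n = 40, n_cohorts = 1,
                         n_snps = 400, seed = 4)
  tr <- d$config$traits
  ph <- d$pheno
  ph[[tr]] <- d$truth$true_bv[, 1]  # phenotype = breeding value exactly
  spec <- model_spec(tr)            # intercept-only model
  fit <- fit_reml(ph, d$grm, traits = tr, spec = spec)
  expect_gt(fit$h2, 0.99)
  expect_true(fit$boundary)
  expect_true(all(diff(fit$logl_trace) > -1e-8))
})

test_that("multivariate REML recovers diagonal covariance structure", {
  # diagonal truth: genetic correlation estimates centred on zero
  rg <- vapply(1:5, function(r) {
    cfg <- sim_config(n_sires = 20, cohort_sizes = c(100, 100),
                      n_herds = 3, n_snps = 800,
                      traits = c("a", "b"), trait_groups = c(1, 2),
                      V_G = diag(c(0.4, 0.5)), V_R = diag(c(0.6, 0.5)),
                      seed = 40 + r)
    d <- simulate_dataset(cfg)
    fit <- fit_reml(d$pheno, d$grm)
    fit$gen_corr[1, 2]
  }, numeric(1))
  expect_lt(abs(mean(rg)), 3 * mc_se(rg) + 0.05)
})

test_that("multivariate and univariate fits agree on heritability", {
  cfg <- sim_config(n_sires = 25, cohort_sizes = c(120, 120), n_herds = 3,
                    n_snps = 800, traits = c("a", "b"),
                    trait_groups = c(1, 2),
                    V_G = matrix(c(0.4, 0.1, 0.1, 0.5), 2),
                    V_R = matrix(c(0.6, 0.1, 0.1, 0.5), 2),
                    missing_rate = 0.02, seed = 77)
  d <- simulate_dataset(cfg)
  fm <- fit_reml(d$pheno, d$grm)
  fa <- fit_reml(d$pheno, d$grm, traits = "a")
  expect_true(fm$converged)
  expect_lt(abs(fm$h2[["a"]] - fa$h2[["a"]]), 0.1)
  # GEBV from the two routes rank animals the same way
  expect_gt(cor(fm$gebv[, "a"], fa$gebv[, "a"]), 0.9)
})

test_that("phenotype adjustment uses whole-data fixed effects only", {
  d <- quick_uni_dataset(n_sires = 10, cohort_n = 25, n_cohorts = 2,
                         n_snps = 300, seed = 12)
  tr <- d$config$traits
  fit <- fit_reml(d$pheno, d$grm)
  adj <- adjust_phenotypes(d$pheno, fit)
  ys <- adj$y_star[[tr]]
  # missingness pattern preserved; centred by construction
  expect_identical(is.na(ys), is.na(d$pheno[[tr]]))
  expect_lt(abs(mean(ys, na.rm = TRUE)), 0.2)

  # adding a constant to one contemporary group is absorbed exactly
  ph2 <- d$pheno
  lev <- levels(ph2$cg_feedlot)[1]
  sel <- ph2$cg_feedlot == lev
  ph2[[tr]][sel] <- ph2[[tr]][sel] + 5
  # tight optimizer tolerances so both runs reach the same optimum
  fit1 <- fit_reml(d$pheno, d$grm, tol_logl = 1e-10, tol_par = 1e-8)
  fit2 <- fit_reml(ph2, d$grm, tol_logl = 1e-10, tol_par = 1e-8)
  adj2 <- adjust_phenotypes(ph2, fit2)
  adj1 <- adjust_phenotypes(d$pheno, fit1)
  expect_lt(max(abs(adj2$y_star[[tr]] - adj1$y_star[[tr]]), na.rm = TRUE),
            1e-4)
  # variance components are translation invariant
  expect_lt(abs(fit2$V_G[1, 1] - fit1$V_G[1, 1]), 1e-5)
})
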