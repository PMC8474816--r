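test_that("genotype simulation is deterministic given the seed", {
  cfg <- sim_config(n_sires = 8, cohort_sizes = c(20, 20), n_herds = 2,
                    n_snps = 60, V_G = 0.4, V_R = 0.6, seed = 5)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$dosage, g2$dosage)
  expect_identical(g1$pedigree, g2$pedigree)
  cfg2 <- sim_config(n_sires = 8, cohort_sizes = c(20, 20), n_herds = 2,
                     n_snps = 60, V_G = 0.4, V_R = 0.6, seed = 6)
  expect_false(identical(simulate_genotypes(cfg2)$dosage, g1$dosage))

  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$pheno, d2$pheno)
  expect_identical(d1$truth$true_bv, d2$truth$true_bv)
})

test_that("cohort sizes are met exactly and dosages have mean 2p", {
  cfg <- sim_config(n_sires = 40, cohort_sizes = c(150, 250, 200),
                    n_herds = 4, n_snps = 500, V_G = 0.4, V_R = 0.6,
                    maf_range = c(0.5, 0.5), seed = 2)
  g <- simulate_genotypes(cfg)
  expect_equal(unname(table(g$pedigree$cohort)), c(150L, 250L, 200L),
               ignore_attr = TRUE)
  # p = 0.5 everywhere: mean dosage ~ 1 (tolerance covers the half-sib
  # clustering of paternal gametes)
  expect_lt(abs(mean(g$dosage) - 1), 0.02)
  # empirical per-SNP frequencies track the drawn frequencies (many sires,
  # so founder-allele clustering is small)
  cfg2 <- sim_config(n_sires = 100, cohort_sizes = c(500, 500),
                     n_herds = 3, n_snps = 400, V_G = 0.4, V_R = 0.6,
                     seed = 3)
  g2 <- simulate_genotypes(cfg2)
  emp <- colMeans(g2$dosage) / 2
  expect_gt(cor(emp, g2$freqs), 0.98)
  expect_lt(mean(abs(emp - g2$freqs)), 0.02)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_sires = 0, cohort_sizes = c(10), V_G = 1,
                          V_R = 1), "positive")
  expect_error(sim_config(cohort_sizes = c(10, -5), V_G = 1, V_R = 1),
               "positive")
  expect_error(sim_config(cohort_sizes = c(10), maf_range = c(0, 0.5),
                          V_G = 1, V_R = 1), "maf_range")
  expect_error(sim_config(cohort_sizes = c(10), maf_range = c(0.1, 0.7),
                          V_G = 1, V_R = 1), "maf_range")
  expect_error(sim_config(cohort_sizes = c(10),
                          V_G = matrix(c(1, 2, 0, 1), 2),
                          V_R = diag(2)), "symmetric")
  expect_error(sim_config(cohort_sizes = c(10), V_G = 1, V_R = -1),
               "positive definite")
})

test_that("paternal half-sibs show the expected 0.25 genomic relationship", {
  cfg <- sim_config(n_sires = 200, cohort_sizes = 2000, n_herds = 2,
                    n_snps = 5000, V_G = 0.4, V_R = 0.6, seed = 11)
  g <- simulate_genotypes(cfg)
  grm <- compute_grm(g)
  sire <- g$pedigree$sire
  same <- outer(sire, sire, `==`)
  ut <- upper.tri(grm$values)
  hs <- grm$values[ut & same]
  un <- grm$values[ut & !same]
  expect_gt(length(hs), 1000)
  expect_lt(abs(mean(hs) - 0.25), 0.02)   # half-sib additive relationship
  expect_lt(abs(mean(un)), 0.01)          # unrelated pairs near zero
  expect_lt(abs(mean(diag(grm$values)) - 1), 0.02)
})

test_that("phenotype model degenerates correctly at V_G = 0 and V_R -> 0", {
  # no genetic signal: residual variance of (y - fixed part) matches V_R
  cfg0 <- sim_config(n_sires = 30, cohort_sizes = c(400, 400), n_herds = 3,
                     n_snps = 400, V_G = 1e-12, V_R = 2.5,
                     missing_rate = 0, seed = 4)
  d0 <- simulate_dataset(cfg0)
  resid <- d0$pheno[[cfg0$traits]] - d0$truth$fixed_part[, 1]
  expect_lt(abs(var(resid) - 2.5), 3 * 2.5 * sqrt(2 / length(resid)))
  expect_lt(max(abs(d0$truth$true_bv)), 1e-4)

  # vanishing residual and no fixed effects: phenotype equals breeding value
  cfg1 <- sim_config(n_sires = 10, cohort_sizes = c(60), n_herds = 2,
                     n_snps = 300, V_G = 1, V_R = 1e-12, cg_sd = 0,
                     age_slope = 0, aod_effects = matrix(0, 11, 1),
                     missing_rate = 0, seed = 5)
  d1 <- simulate_dataset(cfg1)
  expect_lt(max(abs(d1$pheno[[cfg1$traits]] - d1$truth$true_bv[, 1])),
            1e-4)
})

test_that("phenotypes regress on true breeding values with slope 1", {
  cfg <- sim_config(n_sires = 50, cohort_sizes = c(1000, 1000),
                    n_herds = 4, n_snps = 1000, V_G = 0.53, V_R = 0.47,
                    seed = 6)
  d <- simulate_dataset(cfg)
  y <- d$pheno[[cfg$traits]] - d$truth$fixed_part[, 1]
  fit <- lm(y ~ d$truth$true_bv[, 1])
  sl <- summary(fit)$coefficients[2, ]
  expect_lt(abs(sl[1] - 1), 3 * sl[2])
})

test_that("missingness is applied at the configured rate", {
  cfg <- sim_config(n_sires = 30, cohort_sizes = c(500, 500), n_herds = 3,
                    n_snps = 200, V_G = 0.4, V_R = 0.6,
                    missing_rate = 0.1, seed = 7)
  d <- simulate_dataset(cfg)
  fr <- mean(is.na(d$pheno[[cfg$traits]]))
  expect_lt(abs(fr - 0.1), 3 * sqrt(0.1 * 0.9 / 1000))
})

test_that("breeding-value covariance follows G x V_G", {
  Vg <- matrix(c(0.5, 0.3, 0.3, 0.4), 2)
  cfg <- sim_config(n_sires = 40, cohort_sizes = c(600, 600), n_herds = 3,
                    n_snps = 800, traits = c("a", "b"),
                    trait_groups = c(1, 2), V_G = Vg, V_R = diag(2),
                    seed = 8)
  d <- simulate_dataset(cfg)
  scale <- mean(diag(d$grm$values))
  emp <- cov(d$truth$true_bv) / scale
  expect_lt(max(abs(emp - Vg)), 0.1)
})
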