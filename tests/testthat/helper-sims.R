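# shared simulation helpers; heavyweight replicate studies are cached so
# several test files can reuse the same runs

.sim_cache <- new.env(parent = emptyenv())

# univariate study design used for calibration testing: 800 animals from
# 80 sires in 4 cohorts, 4000 SNPs, contemporary-group and age effects on
lr_study_config <- function(h2, seed, n_sires = 80, cohort_n = 200,
                            n_cohorts = 4, n_snps = 4000, n_herds = 8) {
  sim_config(n_sires = n_sires, cohort_sizes = rep(cohort_n, n_cohorts),
             n_herds = n_herds, n_snps = n_snps,
             V_G = h2, V_R = 1 - h2, seed = seed)
}

# 20 replicates of the calibration design with the full 4-cohort
# cross-validation and simulation truth attached
lr_replicates <- function() {
  if (!is.null(.sim_cache$lr)) return(.sim_cache$lr)
  res <- lapply(1:20, function(r) {
    dat <- simulate_dataset(lr_study_config(0.4, 1000 + r))
    suppressWarnings(
      as.data.frame(run_crossval(dat$pheno, dat$grm, truth = dat$truth)))
  })
  .sim_cache$lr <- res
  res
}

# replicate-mean REML heritability estimates at a given truth
h2_recovery_estimates <- function(h2, seeds) {
  key <- paste0("h2_", h2)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  est <- vapply(seeds, function(s) {
    dat <- simulate_dataset(lr_study_config(h2, s))
    unname(fit_reml(dat$pheno, dat$grm)$h2)
  }, numeric(1))
  .sim_cache[[key]] <- est
  est
}

# small convenience dataset for unit tests
quick_uni_dataset <- function(h2 = 0.4, n_sires = 30, cohort_n = 100,
                              n_cohorts = 2, n_snps = 800, seed = 1,
                              missing_rate = 0, ...) {
  simulate_dataset(sim_config(
    n_sires = n_sires, cohort_sizes = rep(cohort_n, n_cohorts),
    n_herds = 3, n_snps = n_snps, V_G = h2, V_R = 1 - h2,
    missing_rate = missing_rate, seed = seed, ...))
}

# wrap a plain matrix as a grm object (for constructed-G unit tests)
fake_grm <- function(G, ids = NULL) {
  if (is.null(ids)) ids <- rownames(G)
  if (is.null(ids)) ids <- paste0("A", seq_len(nrow(G)))
  dimnames(G) <- list(ids, ids)
  structure(list(values = G, denom = NA_real_, freqs = numeric(0),
                 ids = ids, n_snps_used = 0L, n_snps_dropped = 0L,
                 ridge_applied = 0),
            class = "grm")
}

mc_se <- function(x) sd(x) / sqrt(length(x))
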