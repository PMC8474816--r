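test_that("two-animal single-SNP GRM matches the hand evaluation", {
  M <- rbind(a1 = 0, a2 = 2)
  colnames(M) <- "s1"
  g <- compute_grm(M)
  # p = 0.5, Z = (-1, +1), denom = 0.5
  expect_equal(g$denom, 0.5)
  expect_equal(unname(g$values), rbind(c(2, -2), c(-2, 2)),
               tolerance = 1e-12)
})

test_that("GRM equals a brute-force per-pair accumulation", {
  set.seed(42)
  M <- matrix(rbinom(5 * 20, 2, 0.3), 5, 20,
              dimnames = list(paste0("a", 1:5), paste0("s", 1:20)))
  g <- compute_grm(M)
  p <- colMeans(M) / 2
  keep <- p > 0 & p < 1
  Mk <- M[, keep]; pk <- p[keep]
  denom <- 2 * sum(pk * (1 - pk))
  Gbf <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5)
    Gbf[i, j] <- sum((Mk[i, ] - 2 * pk) * (Mk[j, ] - 2 * pk)) / denom
  expect_lt(max(abs(g$values - Gbf)), 1e-12)
})

test_that("duplicated animals give identical GRM rows", {
  set.seed(7)
  M <- matrix(rbinom(4 * 50, 2, 0.4), 4, 50)
  M <- rbind(M, M[2, ])
  rownames(M) <- paste0("a", 1:5)
  g <- compute_grm(M)
  expect_equal(g$values[2, ], g$values[5, ], ignore_attr = TRUE)
  expect_equal(g$values[2, 2], g$values[5, 5])
})

test_that("unrelated HWE genotypes give diagonal ~1 and off-diagonal ~0", {
  set.seed(13)
  n <- 500; m <- 5000
  p <- runif(m, 0.05, 0.5)
  M <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  rownames(M) <- paste0("a", seq_len(n))
  g <- compute_grm(M)
  expect_lt(abs(mean(diag(g$values)) - 1), 0.02)
  expect_lt(abs(mean(g$values[upper.tri(g$values)])), 0.005)
  # similar spread of within- and between-animal relationship values
  expect_equal(trace <- sum(diag(g$values)) / n,
               1 + relationship_summary(g)$F_bar, tolerance = 1e-12)
})

test_that("GRM is invariant to reference-allele relabelling", {
  set.seed(21)
  M <- matrix(rbinom(20 * 100, 2, 0.3), 20, 100)
  rownames(M) <- paste0("a", 1:20)
  flip <- sample(100, 40)
  M2 <- M
  M2[, flip] <- 2 - M2[, flip]
  expect_lt(max(abs(compute_grm(M)$values - compute_grm(M2)$values)),
            1e-10)
})

test_that("monomorphic SNPs are dropped and all-monomorphic errors", {
  M <- cbind(rep(2, 4), c(0, 1, 2, 1))
  rownames(M) <- paste0("a", 1:4)
  g <- compute_grm(M)
  expect_equal(g$n_snps_dropped, 1L)
  expect_equal(g$n_snps_used, 1L)
  expect_error(compute_grm(matrix(2, 3, 2,
                                  dimnames = list(paste0("a", 1:3), NULL))),
               "monomorphic")
  expect_error(compute_grm(matrix(c(0, 1), 1, 2)), "2 animals")
})

# reference evaluation at externally supplied frequencies
compute_grm_ref <- function(M, p) {
  keep <- p > 0 & p < 1
  Z <- sweep(M[, keep, drop = FALSE], 2, 2 * p[keep])
  tcrossprod(Z) / (2 * sum(p[keep] * (1 - p[keep])))
}

test_that("missing dosages contribute zero after 2p imputation", {
  set.seed(3)
  M <- matrix(rbinom(10 * 40, 2, 0.4), 10, 40)
  rownames(M) <- paste0("a", 1:10)
  Mna <- M
  Mna[1, 5] <- NA
  g <- compute_grm(Mna)
  p <- colMeans(Mna, na.rm = TRUE) / 2
  Mimp <- Mna
  Mimp[1, 5] <- 2 * p[5]
  # frequencies are computed from observed data, imputation = mean fill
  expect_lt(max(abs(g$values - compute_grm_ref(Mimp, p))), 1e-12)
})

test_that("relationship summaries are correct on constructed matrices", {
  gI <- fake_grm(diag(4))
  rs <- relationship_summary(gI)
  expect_equal(rs$F_bar, 0)
  expect_equal(rs$two_f_bar, 0)

  g2 <- fake_grm(rbind(c(2, -2), c(-2, 2)))
  rs2 <- relationship_summary(g2)
  expect_equal(rs2$F_bar, 1)
  expect_equal(rs2$two_f_bar, -2)

  expect_error(relationship_summary(gI, "A1"), "singleton")
  expect_error(relationship_summary(gI, c("A1", "nope")), "absent")
  # subsetting works on simulated data
  d <- quick_uni_dataset(n_sires = 10, cohort_n = 30, n_snps = 200)
  co <- d$pheno$animal[d$pheno$cohort == "C1"]
  rs3 <- relationship_summary(d$grm, co)
  expect_true(is.finite(rs3$F_bar) && is.finite(rs3$two_f_bar))
  expect_equal(rs3$n, length(co))
})

test_that("ridge repair acts only when needed and shifts eigenvalues", {
  # positive-definite input is returned untouched
  set.seed(1)
  Gpd <- crossprod(matrix(rnorm(100), 10)) / 10 + diag(10)
  expect_identical(ridge_repair(fake_grm(Gpd), 1e-6)$ridge_applied, 0)

  # a GRM at observed frequencies is singular (centred columns), and
  # duplicated animals keep it so
  d <- quick_uni_dataset(n_sires = 10, cohort_n = 25, n_cohorts = 2,
                         n_snps = 300)
  M <- d$genotypes$dosage[1:10, ]
  M <- rbind(M, dup = M[1, ])
  rownames(M) <- paste0("a", 1:11)
  gs <- compute_grm(M)
  expect_error(chol(gs$values))
  gr <- ridge_repair(gs, 1e-4)
  expect_gt(gr$ridge_applied, 0)
  expect_silent(chol(gr$values))
  ev0 <- eigen(gs$values, symmetric = TRUE, only.values = TRUE)$values
  ev1 <- eigen(gr$values, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(max(abs(ev1 - (ev0 + gr$ridge_applied))), 1e-8)
})
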