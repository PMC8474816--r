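#' Simulate genotypes for a paternal half-sib cohort design
#'
#' Draws per-SNP allele frequencies uniformly from `config$maf_range`,
#' samples sire genotypes in Hardy-Weinberg proportions, and builds each
#' progeny's dosage as one Mendelian gamete from its sire plus one gamete
#' drawn from population frequencies (dams are not tracked individually;
#' see the package vignette). Sires are assigned to a single year-of-birth
#' cohort each, so sire linkage across cohorts is negligible by
#' construction, and progeny are assigned to herds active in their cohort.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `genotype_matrix`: a list with `dosage`
#'   (animals x SNPs matrix of 0/1/2, rownames = animal IDs), `freqs`
#'   (the drawn allele frequencies), and `pedigree` (data frame with
#'   animal, sire, cohort, herd).
#' @examples
#' g <- simulate_genotypes(sim_config(n_sires = 6, cohort_sizes = c(12, 12),
#'                                    n_herds = 2, n_snps = 20,
#'                                    V_G = 0.4, V_R = 0.6, seed = 7))
#' dim(g$dosage)
#' @export
simulate_genotypes <- function(config) {
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  set.seed(config$seed)
  m <- config$n_snps
  ns <- config$n_sires
  nc <- config$n_cohorts
  sizes <- config$cohort_sizes
  n <- sum(sizes)

  p <- runif(m, config$maf_range[1], config$maf_range[2])
  snp_ids <- sprintf("SNP%05d", seq_len(m))
  sire_ids <- sprintf("S%04d", seq_len(ns))
  animal_ids <- sprintf("A%05d", seq_len(n))

  # sire genotypes: Binomial(2, p_j) per SNP
  S <- matrix(rbinom(ns * m, 2L, rep(p, each = ns)), ns, m,
              dimnames = list(sire_ids, snp_ids))

  # sires split across cohorts proportionally to cohort size (disjoint sets)
  alloc <- pmax(1L, floor(ns * sizes / n))
  while (sum(alloc) < ns) {
    k <- which.max(sizes / alloc)
    alloc[k] <- alloc[k] + 1L
  }
  while (sum(alloc) > ns) {
    k <- which.max(alloc)
    alloc[k] <- alloc[k] - 1L
  }
  sire_cohort <- rep(seq_len(nc), alloc)

  # progeny-to-sire assignment within cohort (uniform with replacement)
  sire_of <- unlist(lapply(seq_len(nc), function(co) {
    cands <- which(sire_cohort == co)
    cands[sample.int(length(cands), sizes[co], replace = TRUE)]
  }))
  cohort_of <- rep(seq_len(nc), sizes)

  # paternal gamete: Mendelian sampling from the sire's two alleles
  Sg <- S[sire_of, , drop = FALSE]
  het <- Sg == 1L
  pat <- (Sg == 2L) * 1L
  pat[het] <- rbinom(sum(het), 1L, 0.5)
  # maternal gamete from population allele frequencies
  mat <- matrix(rbinom(n * m, 1L, rep(p, each = n)), n, m)
  M <- pat + mat
  dimnames(M) <- list(animal_ids, snp_ids)

  # herds span a few consecutive cohorts each; every cohort keeps >=2 herds
  nh <- config$n_herds
  span <- min(config$herd_span, nc)
  herd_start <- sort(sample.int(max(nc - span + 1L, 1L), nh, replace = TRUE))
  herd_sets <- lapply(herd_start, function(s) s:(min(s + span - 1L, nc)))
  herd_of <- integer(n)
  for (co in seq_len(nc)) {
    active <- which(vapply(herd_sets, function(hs) co %in% hs, logical(1)))
    if (length(active) == 0) active <- sample.int(nh, 1L)
    idx <- which(cohort_of == co)
    herd_of[idx] <- active[sample.int(length(active), length(idx),
                                      replace = TRUE)]
  }

  ped <- data.frame(
    animal = animal_ids,
    sire = sire_ids[sire_of],
    cohort = factor(paste0("C", cohort_of),
                    levels = paste0("C", seq_len(nc))),
    herd = factor(paste0("H", herd_of), levels = paste0("H", seq_len(nh))),
    stringsAsFactors = FALSE
  )

  structure(list(dosage = M, freqs = setNames(p, snp_ids), pedigree = ped),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d animals x %d SNPs\n",
              nrow(x$dosage), ncol(x$dosage)))
  if (!is.null(x$pedigree))
    cat(sprintf("  %d sires, %d cohorts, %d herds\n",
                length(unique(x$pedigree$sire)),
                nlevels(x$pedigree$cohort), nlevels(x$pedigree$herd)))
  invisible(x)
}

#' Simulate phenotypes with known breeding values and fixed effects
#'
#' Draws true breeding values from `N(0, G (x) V_G)` using a factorization
#' of the genomic relationship matrix (ridge-repaired if needed) and of
#' `V_G`, adds independent residuals `N(0, V_R)` per animal, and builds
#' phenotypes as contemporary-group effect + age-of-dam effect + age
#' regression + breeding value + residual + trait mean. Contemporary
#' groups are herd x cohort x a 2-level measurement batch, built
#' separately for feedlot and carcase traits. Records are then masked
#' missing uniformly at random at `config$missing_rate`.
#'
#' @param genotypes A `genotype_matrix` from [simulate_genotypes()].
#' @param config The same [sim_config()] used for the genotypes.
#' @param grm Optional precomputed [compute_grm()] result for the same
#'   animals (computed internally if omitted).
#' @return A list with `pheno` (data frame: animal, sire, cohort, herd,
#'   contemporary groups, aod, fage, cage, one column per trait with NAs
#'   for missing records) and `truth` (list with `true_bv`, `true_h2`,
#'   `fixed_truth`, `fixed_part`).
#' @export
simulate_phenotypes <- function(genotypes, config, grm = NULL) {
  .assert(inherits(genotypes, "genotype_matrix"),
          "genotypes must come from simulate_genotypes()")
  .assert(inherits(config, "sim_config"), "config must be a sim_config")
  if (is.null(grm)) grm <- compute_grm(genotypes)
  set.seed(.derive_seed(config$seed, 101L))

  ped <- genotypes$pedigree
  n <- nrow(ped)
  t <- config$n_traits
  traits <- config$traits

  # breeding values: rows ~ G, columns ~ V_G
  Gr <- ridge_repair(grm, 1e-6)
  Lg <- chol(Gr$values + diag(1e-10, n))  # upper: t(Lg) %*% Lg = G
  Z <- matrix(rnorm(n * t), n, t)
  true_bv <- crossprod(Lg, Z) %*% .sym_sqrt(config$V_G)
  dimnames(true_bv) <- list(ped$animal, traits)

  E <- matrix(rnorm(n * t), n, t) %*% chol(config$V_R)

  # ages and age of dam
  ap <- config$age_pars
  fage <- round(rnorm(n, ap["fage_mean"], ap["fage_sd"]))
  cage <- round(rnorm(n, ap["cage_mean"], ap["cage_sd"]))
  aod_p <- dnorm(config$aod_classes, 5, 2)
  aod <- sample(config$aod_classes, n, replace = TRUE, prob = aod_p)

  # contemporary groups: herd x cohort x measurement batch, one factor per
  # trait group (feedlot and carcase measurement dates differ)
  batch1 <- sample(1:2, n, replace = TRUE)
  batch2 <- sample(1:2, n, replace = TRUE)
  cg_feedlot <- factor(paste(ped$herd, ped$cohort, paste0("B", batch1),
                             sep = "."))
  cg_carcase <- factor(paste(ped$herd, ped$cohort, paste0("B", batch2),
                             sep = "."))

  cg_truth <- list(
    feedlot = matrix(rnorm(nlevels(cg_feedlot) * t), nlevels(cg_feedlot), t,
                     dimnames = list(levels(cg_feedlot), traits)),
    carcase = matrix(rnorm(nlevels(cg_carcase) * t), nlevels(cg_carcase), t,
                     dimnames = list(levels(cg_carcase), traits))
  )
  cg_truth$feedlot <- sweep(cg_truth$feedlot, 2, config$cg_sd, `*`)
  cg_truth$carcase <- sweep(cg_truth$carcase, 2, config$cg_sd, `*`)

  fixed_part <- matrix(0, n, t, dimnames = list(ped$animal, traits))
  for (j in seq_len(t)) {
    grp <- config$trait_groups[j]
    cg <- if (grp == 1L) cg_feedlot else cg_carcase
    cg_eff <- if (grp == 1L) cg_truth$feedlot[, j] else cg_truth$carcase[, j]
    age <- if (grp == 1L) fage else cage
    age_mu <- if (grp == 1L) ap["fage_mean"] else ap["cage_mean"]
    aod_eff <- config$aod_effects[as.character(aod), j]
    fixed_part[, j] <- config$trait_means[j] + cg_eff[as.integer(cg)] +
      aod_eff + config$age_slope[j] * (age - age_mu)
  }

  Y <- fixed_part + true_bv + E
  if (config$missing_rate > 0) {
    miss <- matrix(runif(n * t) < config$missing_rate, n, t)
    Y[miss] <- NA_real_
  }

  pheno <- data.frame(
    animal = ped$animal, sire = ped$sire, cohort = ped$cohort,
    herd = ped$herd, cg_feedlot = cg_feedlot, cg_carcase = cg_carcase,
    aod = factor(aod, levels = config$aod_classes),
    fage = fage, cage = cage,
    stringsAsFactors = FALSE
  )
  for (j in seq_len(t)) pheno[[traits[j]]] <- Y[, j]
  attr(pheno, "traits") <- traits
  attr(pheno, "trait_groups") <- config$trait_groups

  truth <- list(
    true_bv = true_bv,
    true_h2 = setNames(diag(config$V_G) / (diag(config$V_G) +
                                             diag(config$V_R)), traits),
    fixed_truth = list(cg = cg_truth, aod = config$aod_effects,
                       age_slope = config$age_slope),
    fixed_part = fixed_part
  )
  list(pheno = pheno, truth = truth)
}

#' Simulate a complete dataset (genotypes, GRM, phenotypes, truth)
#'
#' Convenience wrapper chaining [simulate_genotypes()], [compute_grm()]
#' and [simulate_phenotypes()].
#'
#' @param config A [sim_config()] object.
#' @return List with `genotypes`, `grm`, `pheno`, `truth`, `config`.
#' @export
simulate_dataset <- function(config) {
  genotypes <- simulate_genotypes(config)
  grm <- compute_grm(genotypes)
  ph <- simulate_phenotypes(genotypes, config, grm = grm)
  list(genotypes = genotypes, grm = grm, pheno = ph$pheno,
       truth = ph$truth, config = config)
}
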