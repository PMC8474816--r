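#' Trait parameters for the default Angus steer simulation
#'
#' Returns the seven feedlot/carcase traits used by the default simulation
#' configuration, with their phenotypic means and standard deviations,
#' genomic heritabilities, and genetic and residual correlation matrices.
#' From these the genetic covariance matrix `V_G` and residual covariance
#' matrix `V_R` are assembled as `D %*% R %*% D` with
#' `D = diag(sqrt(h2) * sd)` (genetic) and `D = diag(sqrt(1 - h2) * sd)`
#' (residual).
#'
#' Traits: average daily gain (ADG, kg/d), daily dry matter intake
#' (DMI, kg/d), carcase weight (CWT, kg), eye muscle area (EMA, cm2),
#' marbling score (MBL), ossification score (OSS) and rib fat depth
#' (RIB, mm). ADG and DMI are feedlot traits (group 1, age covariate =
#' age at feedlot entry); the rest are carcase traits (group 2, age
#' covariate = age at carcase assessment).
#'
#' @return A list with elements `traits`, `groups`, `mean`, `sd`, `h2`,
#'   `gen_corr`, `res_corr`, `V_G`, `V_R`.
#' @export
angus_trait_defaults <- function() {
  traits <- c("ADG", "DMI", "CWT", "EMA", "MBL", "OSS", "RIB")
  groups <- c(1L, 1L, 2L, 2L, 2L, 2L, 2L)
  mu <- c(1.59, 14.52, 432.99, 90.06, 494.66, 148.25, 17.37)
  sdp <- c(0.33, 2.06, 65.60, 10.86, 122.54, 18.64, 6.04)
  h2 <- c(0.30, 0.38, 0.53, 0.45, 0.42, 0.33, 0.31)
  t <- length(traits)

  Rg <- diag(t)
  Rg[1, 2:7] <- c(0.59, 0.65, 0.15, 0.05, 0.08, 0.11)
  Rg[2, 3:7] <- c(0.63, 0.12, 0.10, 0.10, 0.16)
  Rg[3, 4:7] <- c(0.37, 0.04, 0.13, 0.18)
  Rg[4, 5:7] <- c(0.14, 0.03, -0.17)
  Rg[5, 6:7] <- c(-0.01, -0.09)
  Rg[6, 7] <- 0.00
  Rg[lower.tri(Rg)] <- t(Rg)[lower.tri(Rg)]

  Rr <- diag(t)
  Rr[2, 1] <- 0.31
  Rr[3, 1:2] <- c(0.25, 0.38)
  Rr[4, 1:3] <- c(0.13, 0.15, 0.48)
  Rr[5, 1:4] <- c(0.01, 0.04, 0.08, 0.18)
  Rr[6, 1:5] <- c(-0.04, 0.01, 0.05, 0.05, 0.02)
  Rr[7, 1:6] <- c(0.02, 0.06, 0.19, -0.01, -0.03, 0.07)
  Rr[upper.tri(Rr)] <- t(Rr)[upper.tri(Rr)]

  dimnames(Rg) <- dimnames(Rr) <- list(traits, traits)
  Dg <- diag(sqrt(h2) * sdp)
  Dr <- diag(sqrt(1 - h2) * sdp)
  V_G <- Dg %*% Rg %*% Dg
  V_R <- Dr %*% Rr %*% Dr
  dimnames(V_G) <- dimnames(V_R) <- list(traits, traits)

  list(traits = traits, groups = setNames(groups, traits),
       mean = setNames(mu, traits), sd = setNames(sdp, traits),
       h2 = setNames(h2, traits), gen_corr = Rg, res_corr = Rr,
       V_G = V_G, V_R = V_R)
}

#' Simulation configuration for the synthetic half-sib study design
#'
#' Defines the population structure (sires, year-of-birth cohorts, herds),
#' the SNP panel, and the trait model (genetic covariance `V_G`, residual
#' covariance `V_R`, contemporary-group, age and age-of-dam fixed effects,
#' record missingness) used by [simulate_genotypes()] and
#' [simulate_phenotypes()].
#'
#' The defaults reproduce the multi-herd Angus steer design: 294 sires,
#' seven cohorts of sizes 361, 514, 579, 274, 569, 575 and 536 steers
#' (mean 11.6 progeny per sire), 12 herds, 45,152 SNPs and the seven
#' feedlot/carcase traits of [angus_trait_defaults()]. Smaller designs for
#' testing are obtained by overriding `n_sires`, `cohort_sizes`, `n_snps`
#' and the trait block.
#'
#' @param n_sires Number of sires. Each sire's progeny are placed in a
#'   single cohort so that sire linkage across cohorts is negligible.
#' @param cohort_sizes Integer vector of progeny per year-of-birth cohort.
#' @param n_herds Number of herds (breeding properties).
#' @param n_snps Number of biallelic SNPs.
#' @param maf_range Range (low, high] in (0, 0.5] from which per-SNP
#'   allele frequencies are drawn uniformly.
#' @param traits Character vector of trait names. Defaults to the seven
#'   Angus traits when `V_G` is not supplied.
#' @param trait_groups Integer vector (1 = feedlot, 2 = carcase) per
#'   trait, controlling which contemporary-group factor and age covariate
#'   apply.
#' @param trait_means Phenotypic means added to each trait.
#' @param V_G Genetic trait covariance matrix (positive semi-definite).
#'   A scalar is taken as a 1x1 matrix.
#' @param V_R Residual trait covariance matrix (positive definite).
#' @param cg_sd Standard deviation of contemporary-group effects per
#'   trait. Default 0.5 of the phenotypic SD.
#' @param age_slope Regression of each trait on age at measurement
#'   (trait units per day). Default 0.2 phenotypic SD per 70 days.
#' @param aod_classes Age-of-dam classes in whole years.
#' @param aod_effects Matrix (classes x traits) of age-of-dam offsets.
#'   Default is a young-dam penalty of 0.25 phenotypic SD decaying
#'   geometrically with dam age.
#' @param missing_rate Fraction of trait records set missing uniformly at
#'   random.
#' @param herd_span Number of cohorts each herd contributes to.
#' @param seed Integer seed; all draws of the generator flow from it.
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(n_sires = 10, cohort_sizes = c(30, 30), n_herds = 2,
#'                   n_snps = 50, V_G = 0.4, V_R = 0.6, seed = 1)
#' cfg
#' @export
sim_config <- function(n_sires = 294,
                       cohort_sizes = c(361, 514, 579, 274, 569, 575, 536),
                       n_herds = 12,
                       n_snps = 45152,
                       maf_range = c(0.05, 0.5),
                       traits = NULL,
                       trait_groups = NULL,
                       trait_means = NULL,
                       V_G = NULL,
                       V_R = NULL,
                       cg_sd = NULL,
                       age_slope = NULL,
                       aod_classes = 2:12,
                       aod_effects = NULL,
                       missing_rate = 0.02,
                       herd_span = 3,
                       seed = 1L) {
  if (is.null(V_G) && is.null(traits)) {
    ang <- angus_trait_defaults()
    traits <- ang$traits
    trait_groups <- ang$groups
    trait_means <- ang$mean
    V_G <- ang$V_G
    V_R <- ang$V_R
  }
  if (is.null(V_G) || is.null(V_R))
    stop("V_G and V_R must both be supplied for custom traits", call. = FALSE)
  if (!is.matrix(V_G)) V_G <- matrix(V_G, 1, 1)
  if (!is.matrix(V_R)) V_R <- matrix(V_R, 1, 1)
  t <- nrow(V_G)
  if (is.null(traits)) traits <- if (t == 1) "trait" else paste0("T", seq_len(t))
  if (is.null(trait_groups)) trait_groups <- rep(1L, t)
  if (is.null(trait_means)) trait_means <- rep(0, t)
  trait_groups <- as.integer(trait_groups)
  dimnames(V_G) <- dimnames(V_R) <- list(traits, traits)

  .assert(length(traits) == t && length(trait_groups) == t &&
            length(trait_means) == t,
          "trait metadata lengths must match dim(V_G)")
  .assert(all(cohort_sizes > 0) && length(cohort_sizes) >= 1,
          "cohort_sizes must all be positive")
  .assert(n_sires >= 1 && n_herds >= 1 && n_snps >= 1,
          "counts must be positive")
  .assert(n_sires >= length(cohort_sizes),
          "need at least one sire per cohort")
  .assert(length(maf_range) == 2 && maf_range[1] > 0 &&
            maf_range[2] <= 0.5 && maf_range[1] <= maf_range[2],
          "maf_range must lie within (0, 0.5]")
  .assert(.is_symmetric(V_G, 1e-8), "V_G must be symmetric")
  .assert(.is_symmetric(V_R, 1e-8), "V_R must be symmetric")
  .assert(min(eigen(V_G, symmetric = TRUE, only.values = TRUE)$values) >
            -1e-8 * max(1, max(abs(V_G))),
          "V_G must be positive semi-definite")
  .assert(min(eigen(V_R, symmetric = TRUE, only.values = TRUE)$values) > 0,
          "V_R must be positive definite")
  .assert(missing_rate >= 0 && missing_rate < 1,
          "missing_rate must be in [0, 1)")

  sigma_p <- sqrt(diag(V_G) + diag(V_R))
  if (is.null(cg_sd)) cg_sd <- 0.5 * sigma_p
  if (is.null(age_slope)) age_slope <- 0.2 * sigma_p / 70
  cg_sd <- rep_len(cg_sd, t)
  age_slope <- rep_len(age_slope, t)
  if (is.null(aod_effects)) {
    # young-dam penalty decaying with dam age; zero by age ~6
    dec <- -0.25 * exp(-(aod_classes - min(aod_classes)) / 1.5)
    aod_effects <- outer(dec, sigma_p)
  }
  aod_effects <- as.matrix(aod_effects)
  .assert(nrow(aod_effects) == length(aod_classes) &&
            ncol(aod_effects) == t,
          "aod_effects must be a classes x traits matrix")
  dimnames(aod_effects) <- list(as.character(aod_classes), traits)

  cfg <- list(
    n_sires = as.integer(n_sires),
    cohort_sizes = as.integer(cohort_sizes),
    n_cohorts = length(cohort_sizes),
    n_animals = sum(as.integer(cohort_sizes)),
    n_herds = as.integer(n_herds),
    n_snps = as.integer(n_snps),
    maf_range = as.numeric(maf_range),
    traits = traits,
    n_traits = t,
    trait_groups = setNames(trait_groups, traits),
    trait_means = setNames(as.numeric(trait_means), traits),
    V_G = V_G,
    V_R = V_R,
    cg_sd = setNames(cg_sd, traits),
    age_slope = setNames(age_slope, traits),
    aod_classes = as.integer(aod_classes),
    aod_effects = aod_effects,
    missing_rate = missing_rate,
    herd_span = as.integer(herd_span),
    # age-at-measurement distributions (days): feedlot entry and carcase
    age_pars = c(fage_mean = 512, fage_sd = 69, cage_mean = 735, cage_sd = 99),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  %d animals: %d sires, %d cohorts (%s), %d herds\n",
              x$n_animals, x$n_sires, x$n_cohorts,
              paste(x$cohort_sizes, collapse = ", "), x$n_herds))
  cat(sprintf("  mean progeny per sire: %.1f\n", x$n_animals / x$n_sires))
  cat(sprintf("  %d SNPs, MAF in (%.2f, %.2f]\n",
              x$n_snps, x$maf_range[1], x$maf_range[2]))
  h2 <- diag(x$V_G) / (diag(x$V_G) + diag(x$V_R))
  cat(sprintf("  %d trait(s): %s\n", x$n_traits,
              paste(sprintf("%s (h2=%.2f)", x$traits, h2), collapse = ", ")))
  cat(sprintf("  missing rate %.3f, seed %d\n", x$missing_rate, x$seed))
  invisible(x)
}
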