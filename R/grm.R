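#' Genomic relationship matrix (VanRaden method 1)
#'
#' Computes `G = Z Z' / (2 * sum(p_j (1 - p_j)))` where `Z` is the dosage
#' matrix column-centred at twice the observed allele frequency `p_j`.
#' Allele frequencies are taken from the observed mean dosage, missing
#' dosages are imputed to `2 p_j` (a neutral, zero contribution after
#' centring) and monomorphic SNPs are excluded from both the numerator
#' and the denominator.
#'
#' @param genotypes A `genotype_matrix` from [simulate_genotypes()] /
#'   [read_genotypes()], or a plain animals x SNPs matrix of 0/1/2
#'   dosages (NA for missing) with animal IDs as rownames.
#' @return An object of class `grm`: list with `values` (n x n symmetric
#'   matrix), `denom` (`2 * sum(p q)`), `freqs` (frequencies of the SNPs
#'   used), `ids`, `n_snps_used`, `n_snps_dropped` and `ridge_applied`
#'   (0 until [ridge_repair()] acts).
#' @examples
#' M <- rbind(a1 = c(0, 1, 2), a2 = c(2, 1, 0))
#' compute_grm(M)$values
#' @export
compute_grm <- function(genotypes) {
  M <- if (inherits(genotypes, "genotype_matrix")) genotypes$dosage
       else as.matrix(genotypes)
  .assert(nrow(M) >= 2, "need at least 2 animals to build a GRM")
  vals <- M[!is.na(M)]
  .assert(all(vals >= 0 & vals <= 2),
          "dosages must lie in [0, 2] (0/1/2 coding)")
  if (is.null(rownames(M))) rownames(M) <- paste0("A", seq_len(nrow(M)))
  ids <- rownames(M)
  .assert(!anyDuplicated(ids), "duplicate animal IDs in genotypes")

  p <- colMeans(M, na.rm = TRUE) / 2
  keep <- is.finite(p) & p > 0 & p < 1
  .assert(any(keep),
          "all SNPs are monomorphic: GRM denominator would be zero")
  n_dropped <- sum(!keep)
  M <- M[, keep, drop = FALSE]
  p <- p[keep]

  Z <- sweep(M, 2, 2 * p, `-`)
  Z[is.na(Z)] <- 0
  denom <- 2 * sum(p * (1 - p))
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(ids, ids)

  structure(list(values = G, denom = denom, freqs = p, ids = ids,
                 n_snps_used = ncol(M), n_snps_dropped = n_dropped,
                 ridge_applied = 0),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  d <- diag(x$values)
  o <- x$values[upper.tri(x$values)]
  cat(sprintf("grm: %d animals, %d SNPs used (%d monomorphic dropped)\n",
              length(x$ids), x$n_snps_used, x$n_snps_dropped))
  cat(sprintf("  mean diagonal %.4f, mean off-diagonal %.4f, denom %.2f\n",
              mean(d), mean(o), x$denom))
  if (x$ridge_applied > 0)
    cat(sprintf("  ridge of %g applied to the diagonal\n", x$ridge_applied))
  invisible(x)
}

#' Relationship summaries from a GRM subset
#'
#' Computes the average inbreeding coefficient `F_bar = mean(G_ii) - 1`
#' and the average pairwise relationship `2f_bar = mean(G_ij, i != j)`
#' over a stated subset of animals (typically the validation cohort of a
#' partial run, as used in the denominator of the LR-method accuracy),
#' together with the SDs of the two sets of values.
#'
#' @param grm A [compute_grm()] result.
#' @param subset Character vector of animal IDs (default: all animals).
#' @return List with `F_bar`, `two_f_bar`, `sd_diag`, `sd_offdiag`, `n`.
#' @export
relationship_summary <- function(grm, subset = NULL) {
  .assert(inherits(grm, "grm"), "grm must come from compute_grm()")
  if (is.null(subset)) subset <- grm$ids
  .assert(length(subset) > 0, "subset must be non-empty")
  .assert(all(subset %in% grm$ids),
          "subset contains IDs absent from the GRM")
  .assert(length(subset) >= 2,
          "two_f_bar is undefined for a singleton subset")
  Gs <- grm$values[subset, subset, drop = FALSE]
  d <- diag(Gs)
  o <- Gs[upper.tri(Gs)]
  list(F_bar = mean(d) - 1, two_f_bar = mean(o),
       sd_diag = sd(d), sd_offdiag = sd(o), n = length(subset))
}

#' Repair a non-factorizable GRM by a diagonal ridge
#'
#' Attempts a Cholesky factorization; only if it fails is `epsilon` added
#' to every diagonal entry (and the attempt repeated with growing ridge,
#' up to `max_tries` times). The total ridge applied is recorded in the
#' returned object.
#'
#' @param grm A [compute_grm()] result.
#' @param epsilon Non-negative ridge increment.
#' @param max_tries Maximum number of ridge escalations.
#' @return The (possibly repaired) `grm` object with `ridge_applied` set.
#' @export
ridge_repair <- function(grm, epsilon = 1e-6, max_tries = 6) {
  .assert(inherits(grm, "grm"), "grm must come from compute_grm()")
  .assert(epsilon >= 0, "epsilon must be non-negative")
  ok <- function(G) !inherits(tryCatch(chol(G), error = identity),
                              "error")
  if (ok(grm$values)) return(grm)
  ridge <- epsilon
  for (i in seq_len(max_tries)) {
    G2 <- grm$values + diag(ridge, nrow(grm$values))
    if (ok(G2)) {
      grm$values <- G2
      grm$ridge_applied <- grm$ridge_applied + ridge
      return(grm)
    }
    ridge <- ridge * 10
  }
  stop("GRM still not factorizable after ridge repair", call. = FALSE)
}
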