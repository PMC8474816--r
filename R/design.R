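#' Fixed-effect model specification
#'
#' Names, for each trait, the contemporary-group factor column, the age
#' covariate column and the (shared) age-of-dam class column of the
#' phenotype table. Any of the three components may be `NULL` to omit
#' that term; an intercept is always fitted.
#'
#' @param traits Character vector of trait names.
#' @param cg Named character vector mapping trait -> contemporary-group
#'   column, or a single column name recycled, or `NULL`.
#' @param age Named character vector mapping trait -> age covariate
#'   column, a single name recycled, or `NULL`.
#' @param aod Column name of the age-of-dam class factor, or `NULL`.
#' @return An object of class `model_spec`.
#' @seealso [default_model_spec()]
#' @export
model_spec <- function(traits, cg = NULL, age = NULL, aod = NULL) {
  .assert(length(traits) >= 1, "at least one trait required")
  expand <- function(x) {
    if (is.null(x)) return(NULL)
    if (length(x) == 1 && is.null(names(x))) x <- rep(x, length(traits))
    if (is.null(names(x))) names(x) <- traits
    .assert(all(traits %in% names(x)), "per-trait mapping incomplete")
    x[traits]
  }
  structure(list(traits = traits, cg = expand(cg), age = expand(age),
                 aod = aod),
            class = "model_spec")
}

#' Default model specification for simulated phenotype tables
#'
#' Uses the `trait_groups` attribute written by [simulate_phenotypes()]:
#' feedlot traits (group 1) get the `cg_feedlot` factor and `fage`
#' covariate, carcase traits (group 2) get `cg_carcase` and `cage`; both
#' share the `aod` class factor.
#'
#' @param pheno A phenotype table from [simulate_phenotypes()].
#' @param traits Traits to include (default: all traits of the table).
#' @return A [model_spec()].
#' @export
default_model_spec <- function(pheno, traits = NULL) {
  all_traits <- attr(pheno, "traits")
  .assert(!is.null(all_traits),
          "pheno lacks a 'traits' attribute; supply model_spec() directly")
  if (is.null(traits)) traits <- all_traits
  groups <- attr(pheno, "trait_groups")[traits]
  cg <- ifelse(groups == 1L, "cg_feedlot", "cg_carcase")
  age <- ifelse(groups == 1L, "fage", "cage")
  model_spec(traits, cg = setNames(cg, traits),
             age = setNames(age, traits), aod = "aod")
}

# Build the fixed-effect design matrix for one trait on a data subset.
# Factors are releveled on the subset; terms that collapse to a single
# level (e.g. after cohort masking) are dropped; aliased columns are
# removed by pivoted QR so the design is full rank.
.build_design <- function(df, trait, spec) {
  n <- nrow(df)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  add_factor <- function(X, col, prefix) {
    f <- droplevels(factor(df[[col]]))
    if (nlevels(f) >= 2) {
      Xf <- model.matrix(~f)[, -1, drop = FALSE]
      colnames(Xf) <- paste0(prefix, levels(f)[-1])
      X <- cbind(X, Xf)
    }
    X
  }
  if (!is.null(spec$cg)) {
    .assert(spec$cg[[trait]] %in% names(df),
            sprintf("contemporary-group column '%s' missing",
                    spec$cg[[trait]]))
    X <- add_factor(X, spec$cg[[trait]], "cg:")
  }
  if (!is.null(spec$aod) && spec$aod %in% names(df))
    X <- add_factor(X, spec$aod, "aod:")
  if (!is.null(spec$age)) {
    a <- as.numeric(df[[spec$age[[trait]]]])
    if (length(unique(a)) > 1) X <- cbind(X, age = a)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    X <- X[, sort(keep), drop = FALSE]
  }
  X
}
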