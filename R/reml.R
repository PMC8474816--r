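#' REML estimation of variance components and GEBV under GBLUP
#'
#' Fits the linear mixed model `y = X b + u + e` with `u ~ N(0, G (x) V_G)`
#' and `e ~ N(0, I (x) V_R)`, where `G` is a genomic relationship matrix,
#' by average-information (AI) REML with expectation-maximization fallback
#' steps whenever an AI update would leave the parameter space or decrease
#' the restricted log-likelihood. A single trait is fitted through an
#' eigendecomposition of the observed-animal submatrix of `G` (fast,
#' scales to thousands of animals); several traits are fitted jointly
#' through the dense phenotypic covariance matrix with record-wise
#' missingness (the residual covariance of an animal is the `V_R`
#' submatrix of its observed traits).
#'
#' Convergence is declared when the log-likelihood change is below
#' `tol_logl` and the largest relative parameter change is below
#' `tol_par`. Variance components are floored at `1e-8` times the
#' phenotypic variance; heritabilities estimated at the boundary are
#' flagged. GEBV are returned for every animal in the GRM, including
#' animals without phenotype records (predicted through genomic
#' relationships).
#'
#' @param pheno Phenotype data frame with an `animal` column and one
#'   column per trait (NA = missing record).
#' @param grm A [compute_grm()] result covering all phenotyped animals.
#' @param traits Trait column(s) to fit (default: the table's `traits`
#'   attribute).
#' @param spec A [model_spec()] (default: [default_model_spec()]).
#' @param max_iter Maximum REML iterations (default 200).
#' @param tol_logl Absolute log-likelihood convergence tolerance.
#' @param tol_par Relative parameter-change convergence tolerance.
#' @param start Optional list with `V_G` and `V_R` start matrices.
#' @param verbose Print the iteration trace.
#' @return An object of class `gp_fit`: `V_G`, `V_R`, `h2`, `gen_corr`,
#'   `res_corr`, `beta`, `gebv` (animals x traits, rownames = GRM ids),
#'   `logl`, `logl_trace`, `converged`, `n_iter`, `boundary`,
#'   `fitted_fixed` (per trait, named by animal), `n_records`.
#' @export
fit_reml <- function(pheno, grm, traits = NULL, spec = NULL,
                     max_iter = 200, tol_logl = 1e-6, tol_par = 1e-5,
                     start = NULL, verbose = FALSE) {
  .assert(inherits(grm, "grm"), "grm must come from compute_grm()")
  .assert("animal" %in% names(pheno), "pheno needs an 'animal' column")
  if (is.null(traits)) traits <- attr(pheno, "traits")
  .assert(!is.null(traits) && all(traits %in% names(pheno)),
          "traits must name columns of pheno")
  if (is.null(spec)) spec <- default_model_spec(pheno, traits)
  .assert(all(pheno$animal %in% grm$ids),
          "all phenotyped animals must be present in the GRM")
  .assert(!anyDuplicated(pheno$animal), "duplicate animal IDs in pheno")

  gidx <- match(pheno$animal, grm$ids)
  G <- grm$values

  if (length(traits) == 1) {
    fit <- .fit_one_trait(pheno, G, gidx, traits, spec,
                          max_iter, tol_logl, tol_par, start, verbose)
  } else {
    fit <- .fit_multi_trait(pheno, G, gidx, traits, spec,
                            max_iter, tol_logl, tol_par, start, verbose)
  }
  rownames(fit$gebv) <- grm$ids
  fit$traits <- traits
  fit$spec <- spec
  class(fit) <- "gp_fit"
  fit
}

#' @export
print.gp_fit <- function(x, ...) {
  cat(sprintf("gp_fit: %d trait(s), %s after %d iterations (logL %.4f)\n",
              length(x$traits),
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$logl))
  cat("  h2:", paste(sprintf("%s=%.3f", x$traits, x$h2), collapse = ", "),
      "\n")
  if (any(x$boundary))
    cat("  boundary estimate flagged for:",
        paste(x$traits[x$boundary], collapse = ", "), "\n")
  invisible(x)
}

# ---- univariate path -------------------------------------------------------

.fit_one_trait <- function(pheno, G, gidx, trait, spec,
                           max_iter, tol_logl, tol_par, start, verbose) {
  y_all <- pheno[[trait]]
  obs <- which(!is.na(y_all))
  .assert(length(obs) >= 5, sprintf("too few records for trait %s", trait))
  y <- y_all[obs]
  X <- .build_design(pheno[obs, , drop = FALSE], trait, spec)
  K <- G[gidx[obs], gidx[obs], drop = FALSE]

  st0 <- if (!is.null(start)) c(start$V_G[1, 1], start$V_R[1, 1]) else NULL
  r <- .reml_uni(y, X, K, max_iter, tol_logl, tol_par, st0, verbose)

  gebv <- matrix(r$th[1] * (G[, gidx[obs], drop = FALSE] %*% r$q_orig),
                 ncol = 1, dimnames = list(NULL, trait))
  V_G <- matrix(r$th[1], 1, 1, dimnames = list(trait, trait))
  V_R <- matrix(r$th[2], 1, 1, dimnames = list(trait, trait))
  h2 <- r$th[1] / sum(r$th)
  fitted_fixed <- setNames(drop(X %*% r$beta), pheno$animal[obs])

  list(V_G = V_G, V_R = V_R,
       h2 = setNames(h2, trait),
       gen_corr = matrix(1, 1, 1, dimnames = list(trait, trait)),
       res_corr = matrix(1, 1, 1, dimnames = list(trait, trait)),
       beta = setNames(list(setNames(r$beta, colnames(X))), trait),
       gebv = gebv, logl = r$ll, logl_trace = r$trace,
       converged = r$converged, n_iter = r$n_iter,
       boundary = setNames(h2 > 0.999 | h2 < 1e-6, trait),
       fitted_fixed = setNames(list(fitted_fixed), trait),
       n_records = setNames(length(obs), trait))
}

# AI-REML for one trait on the eigenbasis of K: V = s2g*K + s2e*I becomes
# diagonal, so each iteration is O(n p^2).
.reml_uni <- function(y, X, K, max_iter = 200, tol_logl = 1e-6,
                      tol_par = 1e-5, start = NULL, verbose = FALSE) {
  n <- length(y)
  eg <- eigen(K, symmetric = TRUE)
  D <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- drop(crossprod(U, y))
  Xt <- crossprod(U, X)
  vy <- var(y)
  .assert(vy > 0, "phenotype has zero variance")
  floor_v <- 1e-8 * vy

  eval_at <- function(th) {
    d <- th[1] * D + th[2]
    if (any(d <= 0) || any(!is.finite(d))) return(NULL)
    W <- 1 / d
    XtW <- Xt * W
    A <- crossprod(Xt, XtW)
    cA <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(cA)) return(NULL)
    Ainv <- chol2inv(cA)
    beta <- drop(Ainv %*% crossprod(XtW, yt))
    r <- yt - drop(Xt %*% beta)
    q <- W * r
    ll <- -0.5 * (sum(log(d)) + 2 * sum(log(diag(cA))) + sum(r * q))
    if (!is.finite(ll)) return(NULL)
    list(th = th, W = W, Ainv = Ainv, beta = beta, q = q, ll = ll)
  }

  score_ai <- function(st) {
    W <- st$W; q <- st$q; Ainv <- st$Ainv
    W2 <- W * W
    trPG <- sum(D * W) - sum(Ainv * crossprod(Xt, (D * W2) * Xt))
    trPE <- sum(W) - sum(Ainv * crossprod(Xt, W2 * Xt))
    yPGPy <- sum(q * (D * q))
    yPEPy <- sum(q * q)
    Pv <- function(w) {
      Ww <- W * w
      Ww - W * drop(Xt %*% (Ainv %*% crossprod(Xt, Ww)))
    }
    wg <- D * q
    Pwg <- Pv(wg); Pwe <- Pv(q)
    AI <- 0.5 * matrix(c(sum(wg * Pwg), sum(wg * Pwe),
                         sum(wg * Pwe), sum(q * Pwe)), 2, 2)
    list(sc = -0.5 * c(trPG - yPGPy, trPE - yPEPy), AI = AI,
         em = st$th + st$th^2 * c(yPGPy - trPG, yPEPy - trPE) / n)
  }

  if (is.null(start))
    start <- c(0.5 * vy / max(mean(diag(K)), 1e-6), 0.5 * vy)
  cur <- eval_at(pmax(start, floor_v))
  .assert(!is.null(cur), "REML start values are not evaluable")
  trace <- cur$ll
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    sa <- score_ai(cur)
    prop <- NULL
    step <- tryCatch(drop(solve(sa$AI, sa$sc)), error = function(e) NULL)
    if (!is.null(step) && all(is.finite(step))) {
      h <- 1
      for (k in 1:12) {
        st <- eval_at(pmax(cur$th + h * step, floor_v))
        if (!is.null(st) && st$ll >= cur$ll - 1e-10) { prop <- st; break }
        h <- h / 2
      }
    }
    if (is.null(prop)) {  # EM fallback step
      st <- eval_at(pmax(sa$em, floor_v))
      if (!is.null(st)) prop <- st
    }
    if (is.null(prop)) break
    dll <- prop$ll - cur$ll
    dpar <- max(abs(prop$th - cur$th) / pmax(abs(cur$th), floor_v))
    cur <- prop
    trace <- c(trace, cur$ll)
    if (verbose)
      message(sprintf("it %3d logL %.6f s2g %.6g s2e %.6g",
                      it, cur$ll, cur$th[1], cur$th[2]))
    if (abs(dll) < tol_logl && dpar < tol_par) { converged <- TRUE; break }
  }
  list(th = cur$th, beta = cur$beta, ll = cur$ll, trace = trace,
       converged = converged, n_iter = it,
       q_orig = drop(U %*% cur$q))
}

# ---- multivariate path -----------------------------------------------------

.fit_multi_trait <- function(pheno, G, gidx, traits, spec,
                             max_iter, tol_logl, tol_par, start, verbose) {
  t <- length(traits)
  Y <- as.matrix(pheno[, traits, drop = FALSE])
  obs <- lapply(seq_len(t), function(j) which(!is.na(Y[, j])))
  .assert(all(lengths(obs) >= 5), "too few records for some trait")
  Xlist <- lapply(seq_len(t), function(j)
    .build_design(pheno[obs[[j]], , drop = FALSE], traits[j], spec))

  r <- .reml_multi(Y, Xlist, obs, G, gidx, max_iter, tol_logl, tol_par,
                   start, verbose)

  Vg <- r$Vg; Vr <- r$Vr
  dimnames(Vg) <- dimnames(Vr) <- list(traits, traits)
  h2 <- diag(Vg) / (diag(Vg) + diag(Vr))
  beta <- fitted_fixed <- vector("list", t)
  for (j in seq_len(t)) {
    beta[[j]] <- setNames(r$beta[[j]], colnames(Xlist[[j]]))
    fitted_fixed[[j]] <- setNames(drop(Xlist[[j]] %*% r$beta[[j]]),
                                  pheno$animal[obs[[j]]])
  }
  colnames(r$gebv) <- traits

  list(V_G = Vg, V_R = Vr, h2 = setNames(h2, traits),
       gen_corr = .cov2cor_safe(Vg), res_corr = .cov2cor_safe(Vr),
       beta = setNames(beta, traits), gebv = r$gebv,
       logl = r$ll, logl_trace = r$trace,
       converged = r$converged, n_iter = r$n_iter,
       boundary = setNames(h2 > 0.999 | h2 < 1e-6, traits),
       fitted_fixed = setNames(fitted_fixed, traits),
       n_records = setNames(lengths(obs), traits))
}

# Dense multivariate AI-REML. V is built explicitly from trait-pair blocks
# G[anim_s, anim_t] * V_G[s,t] + 1(same animal) * V_R[s,t]; feasible for a
# few thousand records, which covers the whole (calibration) fits this
# package runs on simulated data.
.reml_multi <- function(Y, Xlist, obs, G, gidx, max_iter = 200,
                        tol_logl = 1e-6, tol_par = 1e-5, start = NULL,
                        verbose = FALSE) {
  t <- ncol(Y)
  nG <- nrow(G)
  nrec <- lengths(obs)
  N <- sum(nrec)
  off <- cumsum(c(0L, nrec))
  rows <- lapply(seq_len(t), function(j) (off[j] + 1L):off[j + 1L])
  anim <- lapply(obs, function(o) gidx[o])
  yvec <- unlist(lapply(seq_len(t), function(j) Y[obs[[j]], j]))

  pdims <- vapply(Xlist, ncol, integer(1))
  poff <- cumsum(c(0L, pdims))
  X <- matrix(0, N, sum(pdims))
  for (j in seq_len(t))
    X[rows[[j]], (poff[j] + 1L):poff[j + 1L]] <- Xlist[[j]]

  Gblk <- Mblk <- vector("list", t)
  for (s in seq_len(t)) {
    Gblk[[s]] <- Mblk[[s]] <- vector("list", t)
    for (u in s:t) {
      Gblk[[s]][[u]] <- G[anim[[s]], anim[[u]], drop = FALSE]
      Mblk[[s]][[u]] <- outer(anim[[s]], anim[[u]], `==`) * 1
    }
  }

  # parameter order matches vech (upper triangle, column-major)
  pars <- list()
  for (mat in c("G", "R"))
    for (b in seq_len(t)) for (a in seq_len(b))
      pars[[length(pars) + 1L]] <- list(mat = mat, a = a, b = b)
  K <- length(pars)
  vech <- function(M) M[upper.tri(M, diag = TRUE)]
  unvech <- function(v) {
    M <- matrix(0, t, t)
    M[upper.tri(M, diag = TRUE)] <- v
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    M
  }

  buildV <- function(Vg, Vr) {
    V <- matrix(0, N, N)
    for (s in seq_len(t)) for (u in s:t) {
      B <- Vg[s, u] * Gblk[[s]][[u]] + Vr[s, u] * Mblk[[s]][[u]]
      V[rows[[s]], rows[[u]]] <- B
      if (u > s) V[rows[[u]], rows[[s]]] <- t(B)
    }
    V
  }

  vdiag <- apply(Y, 2, var, na.rm = TRUE)
  floor_v <- 1e-8 * mean(vdiag)

  eval_at <- function(Vg, Vr) {
    V <- buildV(Vg, Vr)
    cV <- tryCatch(chol(V), error = function(e) NULL)
    if (is.null(cV)) return(NULL)
    Vi <- chol2inv(cV)
    ViX <- Vi %*% X
    A <- crossprod(X, ViX)
    cA <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(cA)) return(NULL)
    Ainv <- chol2inv(cA)
    beta <- drop(Ainv %*% crossprod(ViX, yvec))
    P <- Vi - ViX %*% tcrossprod(Ainv, ViX)
    q <- drop(P %*% yvec)
    ll <- -0.5 * (2 * sum(log(diag(cV))) + 2 * sum(log(diag(cA))) +
                    sum(yvec * q))
    if (!is.finite(ll)) return(NULL)
    list(Vg = Vg, Vr = Vr, P = P, q = q, beta = beta, ll = ll)
  }

  score_ai <- function(st) {
    P <- st$P; q <- st$q
    Wm <- matrix(0, N, K)
    trs <- ypp <- numeric(K)
    for (k in seq_len(K)) {
      pk <- pars[[k]]
      a <- pk$a; b <- pk$b
      B <- if (pk$mat == "G") Gblk[[a]][[b]] else Mblk[[a]][[b]]
      w <- numeric(N)
      w[rows[[a]]] <- w[rows[[a]]] + drop(B %*% q[rows[[b]]])
      if (b != a)
        w[rows[[b]]] <- w[rows[[b]]] + drop(crossprod(B, q[rows[[a]]]))
      mult <- if (a == b) 1 else 2
      trs[k] <- sum(P[rows[[a]], rows[[b]], drop = FALSE] * B) * mult
      ypp[k] <- sum(q * w)
      Wm[, k] <- w
    }
    AI <- 0.5 * crossprod(Wm, P %*% Wm)
    # matrix-form EM-like fallback update: V -> V + V S V / n
    mults <- vapply(pars, function(p) if (p$a == p$b) 1 else 2, numeric(1))
    sel_G <- vapply(pars, function(p) p$mat == "G", logical(1))
    Sg <- unvech(((ypp - trs) / mults)[sel_G])
    Sr <- unvech(((ypp - trs) / mults)[!sel_G])
    em_Vg <- st$Vg + st$Vg %*% Sg %*% st$Vg / nG
    em_Vr <- st$Vr + st$Vr %*% Sr %*% st$Vr / N
    list(sc = -0.5 * (trs - ypp), AI = AI,
         em_Vg = .make_psd(em_Vg, 0), em_Vr = .make_psd(em_Vr, floor_v))
  }

  if (!is.null(start)) {
    Vg0 <- start$V_G; Vr0 <- start$V_R
  } else {
    # start from residual covariance of per-trait fixed-effect fits
    Yadj <- Y
    for (j in seq_len(t)) {
      fitj <- stats::lm.fit(Xlist[[j]], Y[obs[[j]], j])
      Yadj[obs[[j]], j] <- fitj$residuals
    }
    Vp <- .make_psd(cov(Yadj, use = "pairwise.complete.obs"),
                    1e-4 * mean(vdiag))
    Vg0 <- 0.5 * Vp
    Vr0 <- 0.5 * Vp
  }
  cur <- eval_at(Vg0, Vr0)
  .assert(!is.null(cur), "multivariate REML start values are not evaluable")
  trace <- cur$ll
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    sa <- score_ai(cur)
    prop <- NULL
    step <- tryCatch(drop(solve(sa$AI, sa$sc)), error = function(e) NULL)
    if (!is.null(step) && all(is.finite(step))) {
      th <- c(vech(cur$Vg), vech(cur$Vr))
      h <- 1
      for (k in 1:12) {
        thn <- th + h * step
        Vg <- unvech(thn[seq_len(K / 2)])
        Vr <- unvech(thn[K / 2 + seq_len(K / 2)])
        if (min(diag(Vr)) > 0 && min(diag(Vg)) >= 0) {
          Vg <- .make_psd(Vg, 0)
          Vr <- .make_psd(Vr, floor_v)
          st <- eval_at(Vg, Vr)
          if (!is.null(st) && st$ll >= cur$ll - 1e-10) { prop <- st; break }
        }
        h <- h / 2
      }
    }
    if (is.null(prop)) {  # EM-like fallback
      st <- eval_at(sa$em_Vg, sa$em_Vr)
      if (!is.null(st)) prop <- st
    }
    if (is.null(prop)) break
    dll <- prop$ll - cur$ll
    dpar <- max(abs(c(vech(prop$Vg) - vech(cur$Vg),
                      vech(prop$Vr) - vech(cur$Vr))) /
                  max(abs(c(vech(cur$Vg), vech(cur$Vr))), floor_v))
    cur <- prop
    trace <- c(trace, cur$ll)
    if (verbose)
      message(sprintf("it %3d logL %.6f", it, cur$ll))
    if (abs(dll) < tol_logl && dpar < tol_par) { converged <- TRUE; break }
  }

  # GEBV for all animals in G: u_hat = C_uy P y
  Qmat <- matrix(0, nG, t)
  for (j in seq_len(t)) Qmat[anim[[j]], j] <- cur$q[rows[[j]]]
  gebv <- G %*% Qmat %*% cur$Vg

  beta_split <- lapply(seq_len(t), function(j)
    cur$beta[(poff[j] + 1L):poff[j + 1L]])

  list(Vg = cur$Vg, Vr = cur$Vr, beta = beta_split, gebv = gebv,
       ll = cur$ll, trace = trace, converged = converged, n_iter = it)
}

# ---- fixed-variance GBLUP and phenotype adjustment -------------------------

#' GBLUP solutions at fixed variance components
#'
#' Solves the single-trait mixed model `y = X b + u + e`,
#' `u ~ N(0, sigma2_g K)`, `e ~ N(0, sigma2_e I)` for BLUE fixed effects
#' and BLUP breeding values at known variances, via the phenotypic
#' covariance `V = sigma2_g K + sigma2_e I`. Equivalent to solving the
#' mixed-model equations directly.
#'
#' @param y Numeric response vector.
#' @param X Fixed-effect design matrix (full rank).
#' @param K Relationship matrix among the `length(y)` animals.
#' @param sigma2_g,sigma2_e Additive and residual variances (> 0).
#' @return List with `beta` and `u`.
#' @export
gblup_solutions <- function(y, X, K, sigma2_g, sigma2_e) {
  .assert(sigma2_g > 0 && sigma2_e > 0, "variances must be positive")
  V <- sigma2_g * K + diag(sigma2_e, length(y))
  Vi <- chol2inv(chol(V))
  A <- crossprod(X, Vi %*% X)
  beta <- drop(solve(A, crossprod(X, Vi %*% y)))
  q <- drop(Vi %*% (y - X %*% beta))
  list(beta = beta, u = drop(sigma2_g * (K %*% q)))
}

#' Adjust phenotypes by whole-data fixed-effect estimates
#'
#' Subtracts the fixed-effect part estimated by a whole-data fit from
#' each observed record, giving the adjusted phenotypes `y*` used by the
#' traditional accuracy and the Q1Q4 statistic. Fixed effects are always
#' taken from the supplied (whole-data) fit and never re-estimated.
#'
#' @param pheno Phenotype table (same records as used in `whole_fit`).
#' @param whole_fit A converged [fit_reml()] result on the complete data.
#' @return List of class `adjusted_phenotypes` with `y_star` (data frame
#'   `animal` + one column per trait, NA exactly where the raw phenotype
#'   is missing) and `sd_per_trait`.
#' @export
adjust_phenotypes <- function(pheno, whole_fit) {
  .assert(inherits(whole_fit, "gp_fit"), "whole_fit must be a gp_fit")
  traits <- whole_fit$traits
  ys <- data.frame(animal = pheno$animal, stringsAsFactors = FALSE)
  for (tr in traits) {
    fitted <- whole_fit$fitted_fixed[[tr]]
    v <- rep(NA_real_, nrow(pheno))
    obs <- which(!is.na(pheno[[tr]]))
    .assert(all(pheno$animal[obs] %in% names(fitted)),
            sprintf("records for %s absent from the whole-data fit", tr))
    v[obs] <- pheno[[tr]][obs] - fitted[pheno$animal[obs]]
    ys[[tr]] <- v
  }
  structure(list(y_star = ys,
                 sd_per_trait = vapply(ys[traits], sd,
                                       numeric(1), na.rm = TRUE)),
            class = "adjusted_phenotypes")
}
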