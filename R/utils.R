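# internal helpers shared across modules

.assert <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# symmetrize and clip eigenvalues at `floor` (nearest-PSD projection)
.make_psd <- function(A, floor = 0) {
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  if (min(e$values) >= floor) return(A)
  v <- pmax(e$values, floor)
  B <- e$vectors %*% (v * t(e$vectors))
  (B + t(B)) / 2
}

# symmetric matrix square root via eigendecomposition (handles PSD input)
.sym_sqrt <- function(A) {
  A <- (A + t(A)) / 2
  e <- eigen(A, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

.is_symmetric <- function(A, tol = 1e-8) {
  is.matrix(A) && nrow(A) == ncol(A) &&
    max(abs(A - t(A))) <= tol * max(1, max(abs(A)))
}

# deterministic derived seed (kept within 32-bit integer range)
.derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1e6) * 2003 + 48271 * (k %% 1000) + 17)
}

.cov2cor_safe <- function(V) {
  d <- diag(V)
  if (any(d <= 0)) {
    R <- matrix(NA_real_, nrow(V), ncol(V), dimnames = dimnames(V))
    diag(R) <- 1
    return(R)
  }
  stats::cov2cor(V)
}
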