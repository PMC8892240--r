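# shared fixtures and independent oracles used across test files

# benchmark fit configuration for the separable synthetic preset:
# subspace dimension matching the preset, dictionary capacity slightly
# above the generator's latent rank (and below p, as residual
# classification requires)
bench_config <- function(...) {
  mbcc_config(p = 10L, atoms_per_class = 5L, ...)
}

random_psd <- function(n, rank = n) {
  m <- matrix(rnorm(n * rank), n, rank)
  tcrossprod(m)
}

random_orthonormal <- function(d, p) {
  qr.Q(qr(matrix(rnorm(d * p), d, p)))
}

# independent gradient-descent minimizer of
# ||Zp - Dp A||_F^2 + lambda ||A||_F^2 (oracle for ridge_code)
ridge_gd_oracle <- function(Zp, Dp, lambda, iters = 20000L) {
  G <- crossprod(Dp)
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values) + lambda
  A <- matrix(0, ncol(Dp), ncol(Zp))
  DtZ <- crossprod(Dp, Zp)
  for (i in seq_len(iters)) {
    grad <- G %*% A - DtZ + lambda * A
    A <- A - grad / L
    if (max(abs(grad)) < 1e-12) break
  }
  A
}

# scalar bisection root-finder on F(rho) (oracle for solve_projection)
bisect_rho <- function(Anum, H, p, lo = -1e4, hi = 1e4, tol = 1e-10) {
  flo <- f_rho(lo, Anum, H, p)$value
  fhi <- f_rho(hi, Anum, H, p)$value
  stopifnot(flo > 0, fhi < 0)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f_rho(mid, Anum, H, p)$value > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# random consistent model state for dictionary-gradient tests
random_dict_state <- function(d = 6L, atoms = 3L, C = 2L, M = 2L, n = 8L,
                              p = 4L) {
  dict <- dictionary_model(matrix(rnorm(d * atoms * C), d, atoms * C),
                           atoms, C)
  labels <- rep(seq_len(C), length.out = n)
  masks <- class_support_masks(labels, dict)
  Z <- replicate(M, matrix(rnorm(d * n), d, n), simplify = FALSE)
  A_list <- replicate(M, matrix(rnorm(atoms * C * n), atoms * C, n),
                      simplify = FALSE)
  Gband <- replicate(M, random_orthonormal(d, p), simplify = FALSE)
  list(dict = dict, labels = labels, masks = masks, Z = Z, A_list = A_list,
       Gband = Gband)
}

# numeric value of the projected Fisher ratio for a given dictionary
# matrix (used by finite-difference oracles)
fisher_ratio_value <- function(Dmat, st) {
  N <- 0; B <- 0
  for (m in seq_along(st$Z)) {
    Rw <- st$Z[[m]] - Dmat %*% (st$A_list[[m]] * st$masks$delta)
    Rb <- st$Z[[m]] - Dmat %*% (st$A_list[[m]] * st$masks$xi)
    N <- N + sum(crossprod(st$Gband[[m]], Rw)^2)
    B <- B + sum(crossprod(st$Gband[[m]], Rb)^2)
  }
  N / B
}
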