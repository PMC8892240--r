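test_that("F(rho) matches hand values and a randomized brute-force oracle", {
  # H = 0: constant in rho, equal to the sum of the p smallest eigenvalues
  A3 <- diag(c(1, 2, 3))
  z3 <- matrix(0, 3, 3)
  expect_equal(f_rho(0, A3, z3, 2)$value, 3)
  expect_equal(f_rho(17, A3, z3, 2)$value, 3)
  # Anum = diag(1,2,3), H = I, p = 1, rho = 0.5 -> 1 - 0.5 = 0.5
  expect_equal(f_rho(0.5, A3, diag(3), 1)$value, 0.5)
  expect_error(f_rho(0, matrix(rnorm(9), 3, 3), z3, 1), "symmetric")
  expect_error(f_rho(0, A3, z3, 4), "exceeds")

  set.seed(20)
  S <- matrix(rnorm(36), 6, 6); S <- (S + t(S)) / 2
  H <- random_psd(6)
  fr <- f_rho(0.7, S, H, 2)
  M <- S - 0.7 * H
  sampled <- replicate(2000, {
    G <- random_orthonormal(6, 2)
    sum(G * (M %*% G))
  })
  expect_lte(fr$value, min(sampled) + 1e-6)
  expect_equal(crossprod(fr$G), diag(2), tolerance = 1e-10)
})

test_that("F(rho) is non-increasing in rho on random PSD instances", {
  set.seed(21)
  for (i in 1:100) {
    Anum <- random_psd(8)
    H <- random_psd(8)
    r <- sort(rnorm(2, sd = 10))
    expect_gte(f_rho(r[1], Anum, H, 3)$value,
               f_rho(r[2], Anum, H, 3)$value - 1e-10)
  }
})

test_that("solve_projection finds the trace-ratio root", {
  set.seed(22)
  H <- random_psd(8) + diag(8)          # full rank
  # proportional case: Anum = c H  ->  rho* = c
  sol <- solve_projection(3.5 * H, matrix(0, 8, 8), H, alpha = 0, p = 3)
  expect_equal(sol$rho_star, 3.5, tolerance = 1e-6)
  expect_lt(abs(sol$F_value), 1e-6)

  # random instance vs bisection oracle on the same scalar function
  Lambda <- random_psd(20)
  H20 <- random_psd(20) + 0.5 * diag(20)
  sol2 <- solve_projection(Lambda, matrix(0, 20, 20), H20, alpha = 0, p = 5)
  expect_equal(sol2$rho_star, bisect_rho(Lambda, H20, 5), tolerance = 1e-6)
  expect_equal(crossprod(sol2$G), diag(5), tolerance = 1e-8)
  scale <- 1 + abs(sum(sol2$G * (Lambda %*% sol2$G)))
  expect_lte(abs(sol2$F_value), 1e-8 * scale)

  # degenerate denominators are rejected or restricted away
  expect_error(solve_projection(Lambda, matrix(0, 20, 20), matrix(0, 20, 20),
                                alpha = 0, p = 2), "degenerate")
  Hlow <- random_psd(20, rank = 3)      # rank 3 < p = 5
  expect_error(solve_projection(Lambda, matrix(0, 20, 20), Hlow, alpha = 0,
                                p = 5, null_policy = "restrict"),
               "range of H")
})

test_that("dictionary gradient matches central finite differences", {
  set.seed(23)
  st <- random_dict_state(d = 6, atoms = 3, C = 2, M = 2)
  dg <- dictionary_gradient(st$dict, st$Z, st$A_list, st$Gband, st$masks)
  h <- 1e-6
  num <- st$dict$D * 0
  for (i in seq_len(nrow(num))) {
    for (k in seq_len(ncol(num))) {
      Dp <- st$dict$D; Dp[i, k] <- Dp[i, k] + h
      Dm <- st$dict$D; Dm[i, k] <- Dm[i, k] - h
      num[i, k] <- (fisher_ratio_value(Dp, st) - fisher_ratio_value(Dm, st)) /
        (2 * h)
    }
  }
  expect_lt(max(abs(dg$grad - num)) / max(abs(num)), 1e-4)
  # per-class blocks tile the full gradient
  expect_equal(do.call(cbind, dg$grad_by_class), dg$grad)
})

test_that("gradient degenerates and scales as the quotient rule predicts", {
  set.seed(24)
  st <- random_dict_state()
  # exact own-class reconstruction: N = 0 and both quotient terms vanish
  st0 <- st
  st0$Z <- lapply(st$A_list, function(A) st$dict$D %*% (A * st$masks$delta))
  dg0 <- dictionary_gradient(st0$dict, st0$Z, st0$A_list, st0$Gband, st0$masks)
  expect_equal(dg0$within, 0, tolerance = 1e-20)
  expect_lt(max(abs(dg0$grad)), 1e-10)

  # scaling Z and A together leaves the ratio, hence the gradient, unchanged
  dg <- dictionary_gradient(st$dict, st$Z, st$A_list, st$Gband, st$masks)
  stc <- st
  stc$Z <- lapply(st$Z, `*`, 3)
  stc$A_list <- lapply(st$A_list, `*`, 3)
  dgc <- dictionary_gradient(stc$dict, stc$Z, stc$A_list, stc$Gband, stc$masks)
  expect_equal(dgc$grad, dg$grad, tolerance = 1e-10)
})

test_that("dictionary step backtracks to a non-increasing objective", {
  set.seed(25)
  st <- random_dict_state()
  objective <- function(Dmat) fisher_ratio_value(Dmat, st)
  dg <- dictionary_gradient(st$dict, st$Z, st$A_list, st$Gband, st$masks)

  up <- dictionary_step(st$dict, dg$grad, eta = 0.05, objective)
  expect_lte(objective(up$dict$D), objective(st$dict$D) + 1e-12)
  expect_equal(sqrt(colSums(up$dict$D^2)), rep(1, st$dict$K), tolerance = 1e-10)

  same <- dictionary_step(st$dict, 0 * dg$grad, eta = 0.05, objective)
  expect_equal(same$dict$D, st$dict$D, tolerance = 1e-12)
  expect_equal(same$eta_used, 0.05)
  expect_error(dictionary_step(st$dict, dg$grad, eta = 0, objective), "eta")
})

test_that("fit loops honour iteration contracts and are deterministic", {
  syn <- make_synthetic(synth_config(d = 12, n_per_class = 12, seed = 30))
  cfg1 <- mbcc_config(p = 8, atoms_per_class = 3, max_iter = 1)
  fit1 <- fit_mbcc(syn$train, cfg1)
  expect_equal(nrow(fit1$history), 1L)

  cfg <- mbcc_config(p = 8, atoms_per_class = 3, max_iter = 4)
  fa <- fit_mbcc(syn$train, cfg)
  fb <- fit_mbcc(syn$train, cfg)
  expect_identical(fa$projections$stacked, fb$projections$stacked)
  expect_identical(fa$dictionary$D, fb$dictionary$D)
  expect_lte(nrow(fa$history), 4L)
  expect_true(all(fa$history$ortho_dev <= 1e-8))
  expect_true(all(fa$history$objective <=
                    fa$history$objective_before_dict + 1e-12))

  fo <- fit_opfddl(syn$train, cfg)
  expect_true(all(fo$history$rho > 0))          # adaptive weight
  expect_true(all(fo$history$ortho_dev <= 1e-8))
  expect_true(all(fo$history$objective <=
                    fo$history$objective_before_dict + 1e-12))
  # stacked projection orthonormal, per-band blocks recombine it
  G <- fo$projections$stacked
  expect_equal(crossprod(G), diag(ncol(G)), tolerance = 1e-10)

  expect_error(fit_mbcc(syn$train, mbcc_config(p = 50, atoms_per_class = 3)),
               "exceeds feature dimension")
})

test_that("sigma = 0 collapses every band to the shared projection", {
  syn <- make_synthetic(synth_config(d = 12, n_per_class = 12, seed = 31))
  fit <- fit_mbcc(syn$train, mbcc_config(p = 8, atoms_per_class = 3,
                                         sigma = 0, max_iter = 3))
  for (m in 2:syn$train$M)
    expect_equal(fit$projections$Gband[[m]], fit$projections$Gband[[1]],
                 tolerance = 1e-12)
  expect_equal(fit$projections$Gband[[1]], fit$projections$G0,
               tolerance = 1e-12)
})

test_that("shared projection recovers the data subspace when mixing is shared", {
  # subspace dimension set to the generator's full latent rank
  # (C * k_true = 12), so the recovery target is well defined
  angles <- vapply(1:5, function(s) {
    syn <- make_synthetic(separable_preset(sigma_true = 0, noise_sd = 0.01,
                                           seed = s))
    fit <- fit_mbcc(syn$train, mbcc_config(p = 12, atoms_per_class = 5))
    Q1 <- qr.Q(qr(fit$projections$G0))
    X <- do.call(cbind, syn$train$Z)
    Q2 <- svd(X, nu = 12, nv = 0)$u
    sv <- svd(crossprod(Q1, Q2))$d
    acos(min(pmin(sv, 1))) * 180 / pi     # largest principal angle, degrees
  }, numeric(1))
  expect_lte(median(angles), 30)
})
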