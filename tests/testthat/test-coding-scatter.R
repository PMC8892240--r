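test_that("dictionary atoms are unit-norm and class blocks partition 1..K", {
  set.seed(10)
  dict <- dictionary_model(matrix(rnorm(4 * 6), 4, 6), atoms_per_class = 3, C = 2)
  expect_equal(sqrt(colSums(dict$D^2)), rep(1, 6), tolerance = 1e-12)
  expect_equal(dict$atom_class, rep(1:2, each = 3))
  expect_error(dictionary_model(matrix(rnorm(8), 4, 2), 3, 2),
               "atoms_per_class")
  expect_error(dictionary_model(cbind(c(0, 0), c(1, 1)), 1, 2), "nonzero")
})

test_that("class support masks enumerate by definition", {
  dict2 <- dictionary_model(matrix(rnorm(3 * 4), 3, 4), 2, 2)
  masks <- class_support_masks(c(1, 2), dict2)
  expect_equal(masks$delta,
               matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 4, 2))
  expect_true(all(masks$delta + masks$xi == 1))

  dict1 <- dictionary_model(matrix(rnorm(3 * 2), 3, 2), 2, 1)
  m1 <- class_support_masks(rep(1, 5), dict1)
  expect_true(all(m1$xi == 0))
  expect_error(class_support_masks(c(1, 3), dict2), "labels must lie in 1..2")
})

test_that("ridge coding matches its closed-form limits and an iterative oracle", {
  set.seed(11)
  Dp <- matrix(rnorm(24), 6, 4)
  expect_equal(ridge_code(matrix(0, 6, 3), Dp, 0.01), matrix(0, 4, 3))

  Q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))[, 1:4]   # orthonormal columns
  Zp <- matrix(rnorm(18), 6, 3)
  expect_equal(ridge_code(Zp, Q, 1e-10), crossprod(Q, Zp), tolerance = 1e-6)

  A <- ridge_code(Zp, Dp, 0.01)
  expect_lt(max(abs(A - ridge_gd_oracle(Zp, Dp, 0.01))), 1e-6)
  expect_error(ridge_code(Zp, Dp, 0), "lambda_code")
})

test_that("ISTA coder approaches least squares for tiny penalties and shrinks", {
  set.seed(12)
  Dp <- matrix(rnorm(30), 6, 5)
  Zp <- matrix(rnorm(12), 6, 2)
  A_ls <- qr.solve(Dp, Zp)
  A_tiny <- ista_code(Zp, Dp, 1e-8, max_iter = 5000, tol = 1e-12)
  expect_lt(max(abs(A_tiny - A_ls)), 1e-4)
  A_big <- ista_code(Zp, Dp, 5, max_iter = 5000)
  expect_lt(sum(abs(A_big)), sum(abs(A_tiny)))
})

test_that("reconstruction scatters match hand computation and are PSD", {
  # exact own-class reconstruction -> zero within-class scatter
  D <- diag(2)                              # one atom per class, C = 2
  dict <- dictionary_model(D, 1, 2)
  masks <- class_support_masks(c(1, 2), dict)
  Z <- cbind(c(2, 0), c(0, 3))
  A <- cbind(c(2, 5), c(7, 3))              # own-class rows reconstruct exactly
  sc <- reconstruction_scatters(Z, dict, A, masks)
  expect_equal(sc$Ww, matrix(0, 2, 2), tolerance = 1e-12)

  # n = 1, hand-computed residual outer products
  dict2 <- dictionary_model(cbind(c(1, 0), c(0, 1)), 1, 2)
  m1 <- class_support_masks(1, dict2)
  z <- c(1, 2)
  a <- c(0.5, 0.3)
  sc2 <- reconstruction_scatters(matrix(z), dict2, matrix(a), m1)
  rw <- z - c(0.5, 0)
  rb <- z - c(0, 0.3)
  expect_equal(sc2$Ww, tcrossprod(rw))
  expect_equal(sc2$Wb, tcrossprod(rb))

  set.seed(13)
  dict3 <- dictionary_model(matrix(rnorm(5 * 6), 5, 6), 3, 2)
  m3 <- class_support_masks(rep(1:2, 4), dict3)
  sc3 <- reconstruction_scatters(matrix(rnorm(40), 5, 8), dict3,
                                 matrix(rnorm(48), 6, 8), m3)
  for (W in sc3) {
    expect_equal(W, t(W))
    expect_gte(min(eigen(W, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }
  expect_error(reconstruction_scatters(matrix(0, 5, 8), dict3,
                                       matrix(0, 5, 8), m3), "shape")
})

test_that("band Gram matrix and its rank bound", {
  Z <- cbind(c(1, 0), c(1, 1))
  expect_equal(band_gram(Z), matrix(c(2, 1, 1, 1), 2, 2))
  set.seed(14)
  Z2 <- matrix(rnorm(15), 5, 3)
  expect_equal(qr(band_gram(Z2))$rank, 3L)
})

test_that("stacked operators degenerate correctly and satisfy the trace identity", {
  set.seed(15)
  d <- 4; M <- 3
  Ww <- replicate(M, random_psd(d), simplify = FALSE)
  Wb <- replicate(M, random_psd(d), simplify = FALSE)
  Th <- replicate(M, random_psd(d), simplify = FALSE)
  i0 <- seq_len(d)

  ops1 <- stack_operators(Ww, Wb, Th, sigma = 1)
  expect_equal(ops1$Lambda[i0, ], matrix(0, d, (M + 1) * d))
  for (m in seq_len(M)) {
    im <- m * d + i0
    expect_equal(ops1$Lambda[im, im], Ww[[m]])
    if (m < M) expect_equal(ops1$Lambda[im, (m + 1) * d + i0], matrix(0, d, d))
  }
  ops0 <- stack_operators(Ww, Wb, Th, sigma = 0)
  expect_equal(ops0$Lambda[i0, i0], Reduce(`+`, Ww))
  expect_equal(sum(abs(ops0$Lambda)), sum(abs(Reduce(`+`, Ww))))
  # Theta acts on the shared block only
  expect_equal(ops0$Theta[i0, i0], Reduce(`+`, Th))
  expect_equal(sum(abs(ops0$Theta[-i0, ])), 0)

  for (sigma in c(0, 0.3, 0.7, 1)) {
    ops <- stack_operators(Ww, Wb, Th, sigma)
    expect_equal(ops$Lambda, t(ops$Lambda))
    G <- matrix(rnorm((M + 1) * d * 3), (M + 1) * d, 3)
    parts <- mbcc:::split_projection(G, d, M, sigma)
    lhs_w <- sum(G * (ops$Lambda %*% G))
    lhs_b <- sum(G * (ops$H %*% G))
    rhs_w <- sum(vapply(seq_len(M), function(m)
      sum(parts$Gband[[m]] * (Ww[[m]] %*% parts$Gband[[m]])), numeric(1)))
    rhs_b <- sum(vapply(seq_len(M), function(m)
      sum(parts$Gband[[m]] * (Wb[[m]] %*% parts$Gband[[m]])), numeric(1)))
    expect_equal(lhs_w, rhs_w, tolerance = 1e-10)
    expect_equal(lhs_b, rhs_b, tolerance = 1e-10)
    # the split is consistent with the mixing definition
    for (m in seq_len(M))
      expect_equal(parts$Gband[[m]],
                   (1 - sigma) * parts$G0 + sigma * parts$Gtilde[[m]])
  }
  expect_error(stack_operators(Ww, Wb, Th, sigma = 1.2), "sigma")
})
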