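test_that("band residuals match an independent least-squares oracle", {
  set.seed(40)
  d <- 12; p <- 8
  dict <- dictionary_model(matrix(rnorm(d * 6), d, 6), 3, 2)
  Gm <- random_orthonormal(d, p)
  Z <- matrix(rnorm(d * 5), d, 5)
  res <- mbcc:::band_residuals(Z, Gm, dict, eps = 1e-12)
  Zp <- crossprod(Gm, Z)
  for (j in 1:2) {
    Dj <- crossprod(Gm, dict$D[, mbcc:::class_atoms(dict, j), drop = FALSE])
    R <- Zp - Dj %*% qr.solve(Dj, Zp)   # normal-equation-free least squares
    expect_lt(max(abs(res[j, ] - colSums(R^2))), 1e-8)
  }
  bp <- band_predict(Z[, 1], Gm, dict, eps = 1e-12)
  expect_equal(bp$residuals, res[, 1], tolerance = 1e-12)
  expect_equal(bp$label, which.min(res[, 1]))
})

test_that("noiseless class members score ~zero residual for their class", {
  out <- make_synthetic(synth_config(noise_sd = 0, seed = 41))
  tr <- out$truth
  set.seed(42)
  Gm <- random_orthonormal(20, 10)
  dict <- dictionary_model(tr$B[[1]], 4, 3)   # true mixing as dictionary
  for (j in c(3, 50, 100)) {
    bp <- band_predict(out$test$Z[[1]][, j], Gm, dict)
    expect_equal(bp$label, out$test$labels[j])
    expect_lt(bp$residuals[bp$label], 1e-8)
  }
})

test_that("ties break to the smallest class index", {
  # two one-atom classes along e1 and e2; z = e3 is equidistant from both
  dict <- dictionary_model(cbind(c(1, 0, 0), c(0, 1, 0)), 1, 2)
  bp <- band_predict(c(0, 0, 1), diag(3), dict)
  expect_equal(bp$residuals, c(1, 1), tolerance = 1e-7)
  expect_equal(bp$label, 1L)
})

test_that("majority vote counts, then residual-sums, then smallest index", {
  expect_equal(majority_vote(c(2, 2, 2), matrix(1, 3, 3)), 2L)
  # M = 2 split vote: label 1's winning residual 0.1 beats label 2's 0.5
  expect_equal(majority_vote(c(1, 2), rbind(c(0.1, 0.9), c(0.8, 0.5))), 1L)
  expect_equal(majority_vote(c(2, 1), rbind(c(0.9, 0.1), c(0.5, 0.8))), 2L)
  # full tie on counts and residuals -> smallest index
  expect_equal(majority_vote(c(1, 2), rbind(c(0.3, 0.9), c(0.9, 0.3))), 1L)

  set.seed(43)
  for (i in 1:50) {
    labs <- sample(1:4, 7, replace = TRUE)
    res <- matrix(runif(28), 7, 4)
    counts <- tabulate(labs, nbins = 4)
    if (sum(counts == max(counts)) == 1L)
      expect_equal(majority_vote(labs, res), which.max(counts))
    else
      expect_true(majority_vote(labs, res) %in% which(counts == max(counts)))
  }
})

test_that("predict degenerates to band_predict for M = 1 and is columnwise", {
  syn <- make_synthetic(synth_config(M = 1, d = 12, n_per_class = 12, seed = 44))
  fit <- fit_mbcc(syn$train, mbcc_config(p = 8, atoms_per_class = 3,
                                         max_iter = 3))
  pr <- predict(fit, syn$test, details = TRUE)
  expect_equal(pr$labels, as.integer(pr$band_labels[1, ]))
  single <- band_predict(syn$test$Z[[1]][, 5], fit$projections$Gband[[1]],
                         fit$dictionary)
  expect_equal(pr$labels[5], single$label)

  # permuting test columns permutes predictions identically
  perm <- sample(syn$test$n)
  expect_equal(predict(fit, subset_samples(syn$test, perm)),
               predict(fit, syn$test)[perm])

  wrong_m <- make_synthetic(synth_config(M = 2, d = 12, n_per_class = 4,
                                         seed = 1))$test
  expect_error(predict(fit, wrong_m), "band")
  wrong_d <- make_synthetic(synth_config(M = 1, d = 9, n_per_class = 4,
                                         seed = 1))$test
  expect_error(predict(fit, wrong_d), "features")
})

test_that("noiseless training data are classified almost perfectly", {
  syn <- make_synthetic(separable_preset(noise_sd = 0))
  fit <- fit_mbcc(syn$train, bench_config())
  expect_gte(mean(predict(fit, syn$train) == syn$train$labels), 0.99)
})

test_that("evaluation report satisfies its invariants", {
  syn <- make_synthetic(synth_config(d = 12, n_per_class = 12, seed = 45))
  fit <- fit_mbcc(syn$train, mbcc_config(p = 8, atoms_per_class = 3,
                                         max_iter = 3))
  ev <- evaluate(fit, syn$test)
  expect_equal(sum(ev$confusion), ev$n_test)
  expect_equal(sum(diag(ev$confusion)) / ev$n_test, ev$accuracy)
  expect_true(all(ev$per_band_accuracy >= 0 & ev$per_band_accuracy <= 1))
  # rows are true labels: row sums equal the true class counts
  expect_equal(unname(rowSums(ev$confusion)),
               as.vector(table(syn$test$labels)))
  # independent confusion computation
  ref <- table(factor(syn$test$labels, levels = seq_len(fit$C)),
               factor(ev$predictions, levels = seq_len(fit$C)))
  expect_equal(unname(ev$confusion), matrix(as.integer(ref), fit$C, fit$C))
  fr <- confusion_fractions(ev)
  expect_equal(unname(rowSums(fr)), rep(1, fit$C))
})
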