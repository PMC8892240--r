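#' Synthetic multi-band generator configuration
#'
#' Parameters of the generative model behind [make_synthetic()]: each
#' class owns a block of `k_true` latent atoms; a sample of class `c`
#' draws nonnegative coefficients on its own block only and is observed in
#' band `m` through the mixing `B^m = (1 - sigma_true) B0 + sigma_true
#' Btilde^m` plus isotropic Gaussian noise. This is exactly the
#' shared-plus-specific structure the classifier assumes, so ground truth
#' is available for recovery and ceiling tests.
#'
#' @param M number of bands.
#' @param d feature dimension.
#' @param C number of classes.
#' @param n_per_class samples per class, drawn separately for the train
#'   and test sets.
#' @param k_true atoms per class in the generator.
#' @param sigma_true shared/specific mixing weight in \[0, 1\] (0 = fully
#'   shared mixing across bands).
#' @param noise_sd standard deviation of the additive observation noise.
#' @param seed integer seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(M = 3L, d = 20L, C = 3L, n_per_class = 40L,
                         k_true = 4L, sigma_true = 0.5, noise_sd = 0.05,
                         seed = 1L) {
  if (any(c(M, d, C, n_per_class, k_true) < 1L))
    stop("all counts must be positive integers")
  if (sigma_true < 0 || sigma_true > 1) stop("`sigma_true` must lie in [0, 1]")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(list(M = as.integer(M), d = as.integer(d), C = as.integer(C),
                 n_per_class = as.integer(n_per_class),
                 k_true = as.integer(k_true), sigma_true = sigma_true,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_config")
}

#' The separable benchmark preset
#'
#' The standing test-bench conditions used throughout the package's own
#' checks: 3 bands, 20 features, 3 balanced classes with 40 train and 40
#' test samples each, 4 generator atoms per class, equal shared/specific
#' mixing, and mild noise (sd 0.05 against unit-scale atoms).
#'
#' @param ... overrides passed to [synth_config()].
#' @return A `synth_config`.
#' @export
separable_preset <- function(...) {
  cfg <- synth_config(M = 3L, d = 20L, C = 3L, n_per_class = 40L, k_true = 4L,
                      sigma_true = 0.5, noise_sd = 0.05, seed = 1L)
  over <- list(...)
  for (nm in names(over)) cfg[[nm]] <- over[[nm]]
  do.call(synth_config, unclass(cfg))
}

unit_cols <- function(m) sweep(m, 2L, sqrt(colSums(m^2)), "/")

# draw one dataset (labels, block-sparse nonnegative codes, per-band
# observations) from an existing truth
draw_from_truth <- function(truth, cfg) {
  K <- cfg$C * cfg$k_true
  n <- cfg$C * cfg$n_per_class
  labels <- rep(seq_len(cfg$C), each = cfg$n_per_class)
  A <- matrix(0, K, n)
  for (j in seq_len(n)) {
    blk <- truth$class_blocks[[labels[j]]]
    A[blk, j] <- abs(stats::rnorm(cfg$k_true)) + 0.5
  }
  Z <- lapply(truth$B, function(Bm)
    Bm %*% A + matrix(stats::rnorm(cfg$d * n, sd = cfg$noise_sd), cfg$d, n))
  list(ds = multiband_dataset(Z, labels,
                              band_names = paste0("band", seq_len(cfg$M))),
       codes = A)
}

#' Generate a synthetic multi-band classification problem
#'
#' Draws the common mixing `B0` and band-specific mixings `Btilde^m` with
#' i.i.d. standard normal entries and unit-norm columns, forms the
#' effective per-band mixings `B^m = (1 - sigma_true) B0 + sigma_true
#' Btilde^m`, then samples train and test sets i.i.d. from the block-
#' sparse nonnegative-coefficient model (entries `|N(0,1)| + 0.5` on the
#' sample's class block, zero elsewhere) with additive Gaussian noise.
#' Deterministic given `cfg$seed`.
#'
#' @param cfg a [synth_config()].
#' @return A list with `train` and `test` ([multiband_dataset()]s, each
#'   `C * n_per_class` samples) and `truth`, a `synth_truth` object
#'   carrying `B0`, `Btilde`, the effective `B` per band, per-class atom
#'   index blocks, the drawn codes, `sigma_true` and `noise_sd`.
#' @examples
#' out <- make_synthetic(synth_config(seed = 7))
#' out$train
#' @export
make_synthetic <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  K <- cfg$C * cfg$k_true
  with_seed(cfg$seed, {
    B0 <- unit_cols(matrix(stats::rnorm(cfg$d * K), cfg$d, K))
    Btilde <- replicate(cfg$M, unit_cols(matrix(stats::rnorm(cfg$d * K), cfg$d, K)),
                        simplify = FALSE)
    B <- lapply(Btilde, function(Bt) (1 - cfg$sigma_true) * B0 + cfg$sigma_true * Bt)
    class_blocks <- split(seq_len(K), rep(seq_len(cfg$C), each = cfg$k_true))
    truth <- structure(
      list(B0 = B0, Btilde = Btilde, B = B, class_blocks = class_blocks,
           sigma_true = cfg$sigma_true, noise_sd = cfg$noise_sd),
      class = "synth_truth")
    tr <- draw_from_truth(truth, cfg)
    te <- draw_from_truth(truth, cfg)
  })
  truth$train_codes <- tr$codes
  truth$test_codes <- te$codes
  list(train = tr$ds, test = te$ds, truth = truth)
}

#' Nearest-subspace oracle classifier from generator truth
#'
#' Classifies each sample by the class whose true per-band mixing block
#' gives the smallest least-squares projection residual, summed over
#' bands. At zero noise this is exact by construction; it serves as the
#' performance ceiling for learned models on the same data.
#'
#' @param truth a `synth_truth` from [make_synthetic()].
#' @param ds a [multiband_dataset()] drawn from the same truth.
#' @return Integer vector of predicted labels in `1..C`.
#' @export
oracle_predict <- function(truth, ds) {
  stopifnot(inherits(truth, "synth_truth"), inherits(ds, "multiband_dataset"))
  C <- length(truth$class_blocks)
  res <- matrix(0, C, ds$n)
  for (m in seq_len(ds$M)) {
    Zm <- ds$Z[[m]]
    for (c in seq_len(C)) {
      Bc <- truth$B[[m]][, truth$class_blocks[[c]], drop = FALSE]
      # residual of projection onto span(Bc)
      coef <- solve(crossprod(Bc) + 1e-12 * diag(ncol(Bc)), crossprod(Bc, Zm))
      R <- Zm - Bc %*% coef
      res[c, ] <- res[c, ] + colSums(R^2)
    }
  }
  apply(res, 2L, which.min)
}
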