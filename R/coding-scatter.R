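#' Class-structured dictionary
#'
#' A `d x K` dictionary whose unit-norm columns (atoms) are partitioned
#' into contiguous per-class sub-dictionaries `D_j`.
#'
#' @param D `d x K` numeric matrix; columns are normalized to unit
#'   Euclidean norm.
#' @param atoms_per_class atoms in each class block; `K` must equal
#'   `C * atoms_per_class`.
#' @param C number of classes.
#' @return An object of class `dictionary_model` with elements `D`,
#'   `atoms_per_class`, `C`, `K`, and `atom_class` (class index of each
#'   atom).
#' @export
dictionary_model <- function(D, atoms_per_class, C) {
  D <- as.matrix(D)
  K <- ncol(D)
  if (K != atoms_per_class * C)
    stop("dictionary size must equal atoms_per_class * C")
  nrm <- sqrt(colSums(D^2))
  if (any(nrm == 0)) stop("dictionary atoms must be nonzero")
  D <- sweep(D, 2L, nrm, "/")
  structure(list(D = D, atoms_per_class = as.integer(atoms_per_class),
                 C = as.integer(C), K = as.integer(K),
                 atom_class = rep(seq_len(C), each = atoms_per_class)),
            class = "dictionary_model")
}

# columns of D belonging to class j
class_atoms <- function(dict, j) which(dict$atom_class == j)

# initialize the dictionary from class samples: per class, the
# atoms_per_class columns of the across-band mean feature matrix with the
# largest norms (ties by column index), unit-normalized. Classes with
# fewer samples than atoms recycle their columns. Deterministic.
init_dictionary <- function(ds, atoms_per_class) {
  Zbar <- Reduce(`+`, ds$Z) / ds$M
  cols <- lapply(seq_len(ds$C), function(c) {
    members <- which(ds$labels == c)
    nrm <- sqrt(colSums(Zbar[, members, drop = FALSE]^2))
    ord <- members[order(-nrm, seq_along(members))]
    picked <- ord[((seq_len(atoms_per_class) - 1L) %% length(ord)) + 1L]
    Zc <- Zbar[, picked, drop = FALSE]
    # recycled duplicates get a tiny deterministic tilt so atoms stay distinct
    if (atoms_per_class > length(members))
      Zc <- Zc + 1e-6 * outer(seq_len(ds$d), seq_len(atoms_per_class))
    Zc
  })
  dictionary_model(do.call(cbind, cols), atoms_per_class, ds$C)
}

#' Class-consistent and class-inconsistent coding masks
#'
#' For coding matrix rows indexed by atoms and columns by samples, the
#' delta mask keeps coefficients on atoms of the sample's own class and
#' the xi mask keeps the rest; elementwise, `delta + xi = 1`.
#'
#' @param labels integer labels in `1..C`, one per sample.
#' @param dict a [dictionary_model()] (supplies the atom-to-class map).
#' @return List with `delta` and `xi`, both `K x n` 0/1 matrices.
#' @export
class_support_masks <- function(labels, dict) {
  stopifnot(inherits(dict, "dictionary_model"))
  labels <- as.integer(labels)
  if (any(labels < 1L) || any(labels > dict$C))
    stop(sprintf("labels must lie in 1..%d", dict$C))
  delta <- outer(dict$atom_class, labels, `==`) * 1
  list(delta = delta, xi = 1 - delta)
}

#' Ridge coding against a (projected) dictionary
#'
#' Closed-form minimizer of `||Zp - Dp A||_F^2 + lambda ||A||_F^2`:
#' `A = (Dp^T Dp + lambda I)^{-1} Dp^T Zp`. `lambda > 0` guarantees a
#' unique solution. Inputs are typically already projected into the
#' subspace (`Zp = (G^m)^T Z^m`, `Dp = (G^m)^T D`).
#'
#' @param Zp `p x n` signal matrix.
#' @param Dp `p x K` dictionary matrix.
#' @param lambda_code ridge penalty, > 0.
#' @return `K x n` coefficient matrix.
#' @export
ridge_code <- function(Zp, Dp, lambda_code) {
  if (lambda_code <= 0) stop("`lambda_code` must be > 0")
  Zp <- as.matrix(Zp); Dp <- as.matrix(Dp)
  solve(crossprod(Dp) + lambda_code * diag(ncol(Dp)), crossprod(Dp, Zp))
}

#' ISTA l1 coder
#'
#' Iterative shrinkage-thresholding for
#' `||Zp - Dp A||_F^2 + lambda ||A||_1`, provided for fidelity
#' experiments against the default ridge coder.
#'
#' @inheritParams ridge_code
#' @param lambda_code l1 penalty, > 0.
#' @param max_iter,tol iteration budget and relative-change tolerance.
#' @return `K x n` coefficient matrix.
#' @export
ista_code <- function(Zp, Dp, lambda_code, max_iter = 500L, tol = 1e-8) {
  Zp <- as.matrix(Zp); Dp <- as.matrix(Dp)
  G <- crossprod(Dp)
  L <- max(eigen(G, symmetric = TRUE, only.values = TRUE)$values, 1e-12)
  A <- matrix(0, ncol(Dp), ncol(Zp))
  DtZ <- crossprod(Dp, Zp)
  thr <- lambda_code / (2 * L)
  for (it in seq_len(max_iter)) {
    V <- A - (G %*% A - DtZ) / L
    Anew <- sign(V) * pmax(abs(V) - thr, 0)
    if (max(abs(Anew - A)) <= tol * (1 + max(abs(A)))) { A <- Anew; break }
    A <- Anew
  }
  A
}

#' Within- and between-class reconstruction scatter of one band
#'
#' Residuals of reconstructing each sample from its own-class coefficients
#' (`r_j = z_j - D (a_j * delta_j)`) accumulate the within-class scatter
#' `Ww = sum_j r_j r_j^T`; reconstructing from the other classes'
#' coefficients gives the between-class scatter `Wb`. Both are symmetric
#' positive semidefinite `d x d` matrices in the original feature space.
#'
#' @param Z `d x n` band matrix.
#' @param dict a [dictionary_model()].
#' @param A `K x n` coding matrix for this band.
#' @param masks masks from [class_support_masks()].
#' @return List with `Ww` and `Wb`.
#' @export
reconstruction_scatters <- function(Z, dict, A, masks) {
  Z <- as.matrix(Z)
  if (nrow(A) != dict$K || ncol(A) != ncol(Z))
    stop("coding matrix shape does not match dictionary/data")
  Rw <- Z - dict$D %*% (A * masks$delta)
  Rb <- Z - dict$D %*% (A * masks$xi)
  list(Ww = tcrossprod(Rw), Wb = tcrossprod(Rb))
}

#' Band Gram matrix
#'
#' `Theta^m = Z Z^T`, the uncentered second-moment matrix used by the
#' PCA-like variance-retention regularizer.
#'
#' @param Z `d x n` band matrix.
#' @return Symmetric PSD `d x d` matrix.
#' @export
band_gram <- function(Z) tcrossprod(as.matrix(Z))

#' Stack per-band scatters into block operators
#'
#' Builds the `(M+1)d x (M+1)d` operators acting on the stacked
#' projection `G = [G0; Gtilde^1; ...; Gtilde^M]`. The per-band selector
#' places `(1-sigma) I` at block 0 and `sigma I` at block `m`, so that
#' for any stacked `G`, `Tr(G^T Lambda G) = sum_m Tr((G^m)^T Ww^m G^m)`
#' with `G^m = (1-sigma) G0 + sigma Gtilde^m` (and the analogue for `H`
#' with `Wb`). The Gram regularizer `Theta` lives in block (0,0) only: it
#' acts on the shared component alone.
#'
#' @param Ww,Wb,Theta_band lists of `M` per-band `d x d` scatter/Gram
#'   matrices.
#' @param sigma shared/specific mixing weight in \[0, 1\].
#' @return List with symmetric `(M+1)d x (M+1)d` matrices `Lambda`,
#'   `Theta`, `H`.
#' @export
stack_operators <- function(Ww, Wb, Theta_band, sigma) {
  if (sigma < 0 || sigma > 1) stop("`sigma` must lie in [0, 1]")
  M <- length(Ww)
  d <- nrow(Ww[[1]])
  stack_one <- function(W) {
    S <- matrix(0, (M + 1) * d, (M + 1) * d)
    i0 <- seq_len(d)
    for (m in seq_len(M)) {
      im <- m * d + seq_len(d)
      S[i0, i0] <- S[i0, i0] + (1 - sigma)^2 * W[[m]]
      S[i0, im] <- (1 - sigma) * sigma * W[[m]]
      S[im, i0] <- (1 - sigma) * sigma * W[[m]]
      S[im, im] <- sigma^2 * W[[m]]
    }
    S
  }
  Theta <- matrix(0, (M + 1) * d, (M + 1) * d)
  Theta[seq_len(d), seq_len(d)] <- Reduce(`+`, Theta_band)
  list(Lambda = stack_one(Ww), Theta = Theta, H = stack_one(Wb))
}

# split a stacked (M+1)d x p matrix into shared + specific parts and
# the effective per-band projections G^m = (1-sigma) G0 + sigma Gtilde^m
split_projection <- function(G, d, M, sigma) {
  G0 <- G[seq_len(d), , drop = FALSE]
  Gtilde <- lapply(seq_len(M), function(m) G[m * d + seq_len(d), , drop = FALSE])
  Gband <- lapply(Gtilde, function(Gt) (1 - sigma) * G0 + sigma * Gt)
  list(G0 = G0, Gtilde = Gtilde, Gband = Gband, sigma = sigma, stacked = G)
}
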