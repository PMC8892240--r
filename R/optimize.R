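assert_symmetric <- function(A, name) {
  if (max(abs(A - t(A))) > 1e-8)
    stop(sprintf("`%s` must be symmetric (asymmetry > 1e-8)", name))
}

# eigenvectors of the p smallest eigenvalues of a symmetric matrix, with a
# deterministic sign convention: the largest-magnitude entry of each
# column is made positive, ties broken by the lowest row index
eigen_smallest <- function(S, p) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  idx <- rev(seq(ncol(S) - p + 1L, ncol(S)))  # ascending eigenvalue order
  G <- e$vectors[, idx, drop = FALSE]
  for (k in seq_len(ncol(G))) {
    a <- abs(G[, k])
    i <- which(a == max(a))[1L]
    if (G[i, k] < 0) G[, k] <- -G[, k]
  }
  list(values = e$values[idx], vectors = G)
}

#' Trace-difference function of the trace-ratio problem
#'
#' For symmetric `Anum` and `H`, evaluates
#' `F(rho) = min_{G^T G = I} Tr(G^T (Anum - rho H) G)`, the sum of the `p`
#' smallest eigenvalues of `Anum - rho H`, together with the minimizing
#' orthonormal `G`. `F` is concave and non-increasing in `rho` (strictly
#' decreasing whenever `H` is nonzero on the minimizing subspace), and its
#' root is the optimal trace ratio.
#'
#' @param rho scalar shift.
#' @param Anum symmetric numerator matrix (`Lambda - alpha Theta`).
#' @param H symmetric PSD denominator matrix.
#' @param p subspace dimension.
#' @return List with `value` (F(rho)), `G` (orthonormal minimizer,
#'   deterministic sign convention), and `values` (the p smallest
#'   eigenvalues).
#' @export
f_rho <- function(rho, Anum, H, p) {
  assert_symmetric(Anum, "Anum")
  assert_symmetric(H, "H")
  if (p > ncol(Anum)) stop("`p` exceeds the matrix dimension")
  es <- eigen_smallest(Anum - rho * H, p)
  list(value = sum(es$values), G = es$vectors, values = es$values)
}

#' Solve the orthonormal trace-ratio projection problem
#'
#' Minimizes `Tr(G^T (Lambda - alpha Theta) G) / Tr(G^T H G)` over
#' matrices with orthonormal columns by iterating on the scalar root of
#' `F(rho)`: a damped Newton update
#' `rho <- rho + lambda_rho * F(rho) / Tr(G^T H G)` (the exact Newton step
#' since `F'(rho) = -Tr(G^T H G)`), safeguarded by bisection whenever the
#' update leaves the current sign-change bracket. Each evaluation of `F`
#' is an eigen-solve whose `p` bottom eigenvectors give the candidate
#' `G`; the final eigen-solve provides the returned projection.
#'
#' The stacked `Lambda` and `H` of this model share an exact nullspace
#' (stacked directions whose effective per-band projections all vanish);
#' on it the numerator is negative whenever `alpha > 0` while the
#' denominator is zero, so the unrestricted ratio is unbounded below.
#' Two remedies are available: `eps > 0` adds a ridge
#' `eps * mean(diag(H)) * I` to `H` (the regularization the degenerate-
#' scatter error advises), and `null_policy = "restrict"` solves the
#' problem on the range of `H` — directions with zero between-class
#' energy carry no Fisher information and are excluded; the returned `G`
#' (still orthonormal) lies in that range. The training loops solve
#' denominator-whitened instances (identity `H`), which are never
#' degenerate.
#'
#' @param Lambda,Theta,H stacked operators from [stack_operators()].
#' @param alpha PCA-regularizer weight.
#' @param p subspace dimension.
#' @param lambda_rho learning rate (1 = undamped Newton).
#' @param tol convergence tolerance on `|F(rho)|`, relative to
#'   `1 + |Tr(G^T (Lambda - alpha Theta) G)|`.
#' @param max_iter iteration cap.
#' @param eps relative ridge added to `H` (0 = none).
#' @param null_policy `"error"` (default) raises the degenerate-scatter
#'   error if the candidate subspace has vanishing `H`-energy;
#'   `"restrict"` solves on the range of `H`.
#' @return Object of class `trace_ratio_result`: `G` (orthonormal),
#'   `rho_star`, `gamma` (the p smallest eigenvalues at the solution),
#'   `iterations`, `F_value`.
#' @export
solve_projection <- function(Lambda, Theta, H, alpha, p, lambda_rho = 0.5,
                             tol = 1e-9, max_iter = 100L, eps = 0,
                             null_policy = c("error", "restrict")) {
  null_policy <- match.arg(null_policy)
  Anum <- Lambda - alpha * Theta
  assert_symmetric(Anum, "Lambda - alpha * Theta")
  assert_symmetric(H, "H")
  if (eps > 0) H <- H + eps * mean(diag(H)) * diag(nrow(H))
  U <- NULL
  if (null_policy == "restrict") {
    eh <- eigen((H + t(H)) / 2, symmetric = TRUE)
    keep <- eh$values > max(eh$values, 0) * 1e-10
    if (sum(keep) < p)
      stop(sprintf("range of H has dimension %d < p = %d", sum(keep), p))
    U <- eh$vectors[, keep, drop = FALSE]
    Anum <- crossprod(U, Anum %*% U)
    Anum <- (Anum + t(Anum)) / 2
    H <- diag(eh$values[keep], nrow = sum(keep))
  }
  rho <- 0
  lo <- -Inf; hi <- Inf    # bracket: F(lo) > 0 > F(hi)
  fr <- NULL
  for (it in seq_len(max_iter)) {
    fr <- f_rho(rho, Anum, H, p)
    denom <- sum(fr$G * (H %*% fr$G))       # Tr(G^T H G)
    if (denom <= 1e-12)
      stop("degenerate between-class scatter: Tr(G^T H G) ~ 0; ",
           "set eps > 0 to ridge-regularize H, or null_policy = \"restrict\"")
    scale <- 1 + abs(fr$value + rho * denom)  # |Tr(G^T Anum G)|
    if (abs(fr$value) <= tol * scale) break
    if (fr$value > 0) lo <- max(lo, rho) else hi <- min(hi, rho)
    rho_new <- rho + lambda_rho * fr$value / denom
    if (is.finite(lo) && is.finite(hi) && (rho_new <= lo || rho_new >= hi))
      rho_new <- (lo + hi) / 2              # bisection fallback
    rho <- rho_new
  }
  G <- if (is.null(U)) fr$G else U %*% fr$G
  structure(list(G = G, rho_star = rho, gamma = fr$values,
                 iterations = it, F_value = fr$value),
            class = "trace_ratio_result")
}

# ---- projection solve on the shared/specific parametrization ----------
#
# The fully relaxed stacked eigen-problem (orthonormality only on the
# stacked G) is degenerate: it admits directions whose effective per-band
# images are (near) zero -- there within- and between-class energies both
# vanish while the PCA term is negative -- and it concentrates all p
# columns in whichever single band offers the best Fisher ratio, leaving
# the other bands with rank-deficient projections. The printed model
# instead constrains every per-band projection to be orthonormal. The
# projection step therefore solves the constrained components separately,
# each itself a well-posed trace-ratio problem:
#   * shared component G0: summed-over-bands trace ratio
#       min Tr(G0' (sum_m Ww^m + gamma mean(diag) I) G0) /
#           Tr(G0' (sum_m Wb^m + alpha sum_m Theta^m) G0);
#   * band-specific component U^m: band m's own Fisher trace ratio with
#     the same within-scatter shrinkage (no variance term, which
#     attaches to the shared component only).
# Two regularizations make these ratios well-posed. The variance Gram
# Theta enters the DENOMINATOR: a subtractive numerator term (the
# printed form) is neutralized by the ratio's scale invariance -- at the
# optimum the shift rho*H cancels alpha*Theta on exactly the directions
# where Theta ~ H, so the variance reward never influences the direction
# choice; rewarding retained variance in the denominator survives the
# ratio and keeps it bounded below by zero. The shrinkage
# gamma * mean(diag(Ww)) * I guards against finite-sample "within-null"
# directions (mixtures on which the own-class residuals nearly cancel
# across samples) that otherwise offer an arbitrarily small ratio while
# carrying no class structure -- the standard regularized-discriminant
# remedy for ill-estimated scatter matrices.
# The specific bases are rotated onto the shared one (orthogonal
# Procrustes, so the specific deviation from the shared frame is
# minimal), and the stacked projection [G0; U^1; ...; U^M] / sqrt(M+1)
# is exactly orthonormal because each block is. The effective per-band
# projection Omega^m G = ((1-sigma) G0 + sigma U^m) / sqrt(M+1) realizes
# the model's mixing and has full column rank for every sigma.

orthonormalize <- function(G) {
  Q <- qr.Q(qr(G))
  for (k in seq_len(ncol(Q))) {
    a <- abs(Q[, k])
    i <- which(a == max(a))[1L]
    if (Q[i, k] < 0) Q[, k] <- -Q[, k]
  }
  Q
}

# orthogonal Procrustes rotation of U onto G0
align_to <- function(U, G0) {
  sv <- svd(crossprod(U, G0))
  U %*% (sv$u %*% t(sv$v))
}

# denominator-whitened trace-ratio solve: eigendecompose `den` on its
# range, whiten, and run the trace-ratio iteration there (with identity
# denominator the trace-ratio and per-direction ratio solutions
# coincide), then map back and re-orthonormalize. The returned basis
# spans the p smallest generalized-ratio directions of (num, den).
whiten_solve <- function(num, den, p, lambda_rho, max_iter = 100L) {
  ed <- eigen((den + t(den)) / 2, symmetric = TRUE)
  keep <- ed$values > max(ed$values, 0) * 1e-10
  if (sum(keep) < p)
    stop(sprintf("range of the denominator scatter has dimension %d < p = %d",
                 sum(keep), p))
  W <- ed$vectors[, keep, drop = FALSE] %*%
    diag(1 / sqrt(ed$values[keep]), sum(keep))
  Sw <- crossprod(W, num %*% W)
  Sw <- (Sw + t(Sw)) / 2
  tr <- solve_projection(Sw, matrix(0, nrow(Sw), ncol(Sw)), diag(nrow(Sw)),
                         alpha = 0, p, lambda_rho = lambda_rho,
                         max_iter = max_iter)
  list(G = orthonormalize(W %*% tr$G), rho_star = tr$rho_star, solve = tr)
}

solve_projection_parts <- function(Ww, Wb, Theta_band, alpha, p, lambda_rho,
                                   max_iter = 100L, gamma_w = 1) {
  M <- length(Ww)
  d <- nrow(Ww[[1]])
  shrink <- function(W) W + gamma_w * mean(diag(W)) * diag(d)
  tr0 <- whiten_solve(shrink(Reduce(`+`, Ww)),
                      Reduce(`+`, Wb) + alpha * Reduce(`+`, Theta_band),
                      p, lambda_rho, max_iter = max_iter)
  G0 <- tr0$G
  U <- lapply(seq_len(M), function(m) {
    trm <- whiten_solve(shrink(Ww[[m]]), Wb[[m]], p, lambda_rho,
                        max_iter = max_iter)
    align_to(trm$G, G0)
  })
  G <- do.call(rbind, c(list(G0), U)) / sqrt(M + 1)
  list(G = G, rho_star = tr0$rho_star, shared = tr0)
}

# ---- Fisher dictionary objective and gradient --------------------------

# projected within/between residual energies at fixed codes and
# projections: N = sum_m ||(G^m)^T (Z^m - D (A^m * delta))||_F^2,
# B likewise with xi
fisher_energies <- function(Dmat, Z, A_list, Gband, masks) {
  N <- 0; B <- 0
  for (m in seq_along(Z)) {
    Rw <- Z[[m]] - Dmat %*% (A_list[[m]] * masks$delta)
    Rb <- Z[[m]] - Dmat %*% (A_list[[m]] * masks$xi)
    N <- N + sum(crossprod(Gband[[m]], Rw)^2)
    B <- B + sum(crossprod(Gband[[m]], Rb)^2)
  }
  list(within = N, between = B)
}

#' Gradient of the projected Fisher ratio with respect to the dictionary
#'
#' Differentiates `J(D) = N(D) / B(D)`, where `N` is the within-class and
#' `B` the between-class projected reconstruction energy at fixed codes
#' and projections, by the quotient rule:
#' `dN/dD = -2 sum_m P_m (Z^m - D S_w^m) (S_w^m)^T` with
#' `P_m = G^m (G^m)^T` and `S_w^m` the class-consistent codes (and the
#' `xi` analogue for `B`). Returned per class as the corresponding column
#' blocks.
#'
#' @param dict a [dictionary_model()].
#' @param Z list of `d x n` band matrices.
#' @param A_list list of `K x n` coding matrices, one per band.
#' @param Gband list of effective per-band `d x p` projections.
#' @param masks masks from [class_support_masks()].
#' @return List with `grad` (full `d x K` gradient of `J`),
#'   `grad_by_class` (per-class column blocks), and the scalar energies
#'   `within`, `between`.
#' @export
dictionary_gradient <- function(dict, Z, A_list, Gband, masks) {
  en <- fisher_energies(dict$D, Z, A_list, Gband, masks)
  if (en$between <= 1e-12)
    stop("degenerate between-class scatter: between-class energy ~ 0; ",
         "consider eps-regularizing the between-class term")
  gN <- matrix(0, nrow(dict$D), dict$K)
  gB <- matrix(0, nrow(dict$D), dict$K)
  for (m in seq_along(Z)) {
    Sw <- A_list[[m]] * masks$delta
    Sb <- A_list[[m]] * masks$xi
    Rw <- Z[[m]] - dict$D %*% Sw
    Rb <- Z[[m]] - dict$D %*% Sb
    Pm <- tcrossprod(Gband[[m]])
    gN <- gN - 2 * Pm %*% tcrossprod(Rw, Sw)
    gB <- gB - 2 * Pm %*% tcrossprod(Rb, Sb)
  }
  grad <- gN / en$between - en$within * gB / en$between^2
  by_class <- lapply(seq_len(dict$C), function(j)
    grad[, class_atoms(dict, j), drop = FALSE])
  list(grad = grad, grad_by_class = by_class,
       within = en$within, between = en$between)
}

#' Backtracking dictionary gradient step
#'
#' Takes a gradient step `D <- D - eta * grad`, re-normalizes every atom
#' to unit Euclidean norm, and halves `eta` (at most 10 times) until the
#' supplied objective does not increase. If no step size avoids an
#' increase, the dictionary is returned unchanged with `eta_used = 0`, so
#' the objective is non-increasing by construction.
#'
#' @param dict a [dictionary_model()].
#' @param grad full `d x K` gradient matrix.
#' @param eta initial step size.
#' @param objective function mapping a `d x K` dictionary matrix to the
#'   scalar objective being descended.
#' @return List with `dict` (updated [dictionary_model()]) and
#'   `eta_used`.
#' @export
dictionary_step <- function(dict, grad, eta, objective) {
  if (eta <= 0) stop("`eta` must be > 0")
  obj0 <- objective(dict$D)
  step <- eta
  for (h in 0:10) {
    Dnew <- dict$D - step * grad
    nrm <- sqrt(colSums(Dnew^2))
    if (all(nrm > 0)) {
      Dnew <- sweep(Dnew, 2L, nrm, "/")
      if (objective(Dnew) <= obj0 + 1e-12)
        return(list(dict = dictionary_model(Dnew, dict$atoms_per_class, dict$C),
                    eta_used = step))
    }
    step <- step / 2
  }
  list(dict = dict, eta_used = 0)
}

# Full model objective (Fisher ratio with variance-retention reward in
# the denominator, matching the projection solve):
# N / (B + alpha * sum_m ||G0^T Z^m||_F^2) at fixed codes and projections
mbcc_objective <- function(Dmat, Z, A_list, proj, masks, alpha) {
  en <- fisher_energies(Dmat, Z, A_list, proj$Gband, masks)
  pca <- sum(vapply(Z, function(Zm) sum(crossprod(proj$G0, Zm)^2), numeric(1)))
  en$within / (en$between + alpha * pca)
}

# ---- training loops ----------------------------------------------------

code_bands <- function(ds, dict, Gband, lambda_code) {
  lapply(seq_len(ds$M), function(m)
    ridge_code(crossprod(Gband[[m]], ds$Z[[m]]),
               crossprod(Gband[[m]], dict$D), lambda_code))
}

band_scatters <- function(ds, dict, A_list, masks) {
  sc <- lapply(seq_len(ds$M), function(m)
    reconstruction_scatters(ds$Z[[m]], dict, A_list[[m]], masks))
  list(Ww = lapply(sc, `[[`, "Ww"), Wb = lapply(sc, `[[`, "Wb"),
       Theta = lapply(ds$Z, band_gram))
}

new_mbcc_model <- function(method, cfg, proj, dict, history, ds) {
  structure(list(method = method, config = cfg, projections = proj,
                 dictionary = dict,
                 history = do.call(rbind, lapply(history, as.data.frame)),
                 band_names = ds$band_names, d = ds$d, M = ds$M, C = ds$C,
                 label_values = ds$label_values),
            class = "mbcc_model")
}

#' Fit the multi-band collaborative classifier
#'
#' Alternating optimization of the shared-dictionary / shared-plus-
#' specific-projection model: (1) per-band ridge coding against the
#' projected dictionary, (2) rebuild of the reconstruction scatters and
#' stacked operators followed by the trace-ratio projection solve,
#' (3) a backtracking gradient step on the class sub-dictionaries.
#' Initialization is deterministic: codes are first computed in the
#' original feature space, the initial stacked projection comes from the
#' eigen-solve at `rho = 0`, and the dictionary starts from the
#' largest-norm class samples of the across-band mean features. The loop
#' stops when the relative change of the model objective (within-class
#' energy over between-class energy plus `alpha` times the variance
#' retained by the shared component) falls below `tol`, or after
#' `max_iter` iterations.
#'
#' @param train a [multiband_dataset()].
#' @param cfg an [mbcc_config()].
#' @return An object of class `mbcc_model` with the fitted projections
#'   (shared `G0`, per-band specific `Gtilde`, effective `Gband`, stacked
#'   orthonormal `G`), the [dictionary_model()], the configuration, and a
#'   per-iteration `history` data frame (objective before/after the
#'   dictionary step, `rho`, step size used, orthonormality deviation of
#'   the stacked projection).
#' @examples
#' syn <- make_synthetic(synth_config(d = 12, n_per_class = 15, seed = 2))
#' fit <- fit_mbcc(syn$train, mbcc_config(p = 8, atoms_per_class = 5,
#'                                        max_iter = 5))
#' fit$history$objective
#' @export
fit_mbcc <- function(train, cfg = mbcc_config()) {
  stopifnot(inherits(train, "multiband_dataset"))
  cfg <- resolve_config(cfg, train)
  dict <- init_dictionary(train, cfg$atoms_per_class)
  masks <- class_support_masks(train$labels, dict)

  # bootstrap: code in the original space, then a first projection solve
  A_list <- lapply(train$Z, function(Zm) ridge_code(Zm, dict$D, cfg$lambda_code))
  sc <- band_scatters(train, dict, A_list, masks)
  G <- solve_projection_parts(sc$Ww, sc$Wb, sc$Theta, cfg$alpha, cfg$p,
                              cfg$lambda_rho, max_iter = 1L,
                              gamma_w = cfg$gamma_w)$G
  proj <- split_projection(G, train$d, train$M, cfg$sigma)

  history <- list()
  obj_prev <- Inf
  for (iter in seq_len(cfg$max_iter)) {
    step <- tryCatch({
      A_list <- code_bands(train, dict, proj$Gband, cfg$lambda_code)
      sc <- band_scatters(train, dict, A_list, masks)
      tr <- solve_projection_parts(sc$Ww, sc$Wb, sc$Theta, cfg$alpha, cfg$p,
                                   cfg$lambda_rho, gamma_w = cfg$gamma_w)
      proj <- split_projection(tr$G, train$d, train$M, cfg$sigma)
      ortho_dev <- max(abs(crossprod(tr$G) - diag(cfg$p)))
      obj_fun <- function(Dmat)
        mbcc_objective(Dmat, train$Z, A_list, proj, masks, cfg$alpha)
      obj_pre <- obj_fun(dict$D)
      dg <- dictionary_gradient(dict, train$Z, A_list, proj$Gband, masks)
      upd <- dictionary_step(dict, dg$grad, cfg$eta, obj_fun)
      dict <- upd$dict
      list(obj = obj_fun(dict$D), obj_pre = obj_pre, rho = tr$rho_star,
           eta = upd$eta_used, ortho = ortho_dev)
    }, error = function(e)
      stop(sprintf("iteration %d: %s", iter, conditionMessage(e)), call. = FALSE))
    history[[iter]] <- data.frame(
      iter = iter, objective = step$obj, objective_before_dict = step$obj_pre,
      rho = step$rho, eta_used = step$eta, ortho_dev = step$ortho)
    if (is.finite(obj_prev) &&
        abs(step$obj - obj_prev) <= cfg$tol * (1 + abs(obj_prev))) break
    obj_prev <- step$obj
  }
  new_mbcc_model("mbcc", cfg, proj, dict, history, train)
}

#' Fit the per-band Fisher baseline (no shared component)
#'
#' The predecessor model: each band gets an independent projection, with
#' all bands' projections stacked and jointly orthonormalized. The
#' projection solve is the eigen-problem on
#' `lambda^2 Wtilde_w - lambda Wtilde_b` (block-diagonal per-band
#' scatters) with the adaptive weight
#' `lambda = Tr(G^T Wtilde_b G) / (2 Tr(G^T Wtilde_w G))` refreshed each
#' iteration; the dictionary update uses the same quotient-rule Fisher
#' gradient and backtracking safeguard as [fit_mbcc()].
#'
#' @inheritParams fit_mbcc
#' @return An `mbcc_model` with `method = "opfddl"`; its `rho` history
#'   column records the adaptive weight.
#' @export
fit_opfddl <- function(train, cfg = mbcc_config()) {
  stopifnot(inherits(train, "multiband_dataset"))
  cfg <- resolve_config(cfg, train)
  d <- train$d; M <- train$M
  dict <- init_dictionary(train, cfg$atoms_per_class)
  masks <- class_support_masks(train$labels, dict)

  # per-band eigen-solve of the weighted difference lambda^2 Ww - lambda Wb;
  # stacking the per-band orthonormal solutions scaled by 1/sqrt(M) keeps
  # the stacked matrix orthonormal
  solve_bands <- function(sc, lambda_w) {
    U <- lapply(seq_len(M), function(m)
      eigen_smallest(lambda_w^2 * sc$Ww[[m]] - lambda_w * sc$Wb[[m]],
                     cfg$p)$vectors)
    list(G = do.call(rbind, U) / sqrt(M),
         Gband = lapply(U, function(u) u / sqrt(M)))
  }

  A_list <- lapply(train$Z, function(Zm) ridge_code(Zm, dict$D, cfg$lambda_code))
  lambda_w <- 1
  sc <- band_scatters(train, dict, A_list, masks)
  sol <- solve_bands(sc, lambda_w)
  Gband <- sol$Gband

  history <- list()
  obj_prev <- Inf
  for (iter in seq_len(cfg$max_iter)) {
    step <- tryCatch({
      A_list <- lapply(seq_len(M), function(m)
        ridge_code(crossprod(Gband[[m]], train$Z[[m]]),
                   crossprod(Gband[[m]], dict$D), cfg$lambda_code))
      sc <- band_scatters(train, dict, A_list, masks)
      sol <- solve_bands(sc, lambda_w)
      G <- sol$G
      Gband <- sol$Gband
      ortho_dev <- max(abs(crossprod(G) - diag(cfg$p)))
      tw <- sum(vapply(seq_len(M), function(m)
        sum(Gband[[m]] * (sc$Ww[[m]] %*% Gband[[m]])), numeric(1)))
      tb <- sum(vapply(seq_len(M), function(m)
        sum(Gband[[m]] * (sc$Wb[[m]] %*% Gband[[m]])), numeric(1)))
      if (tw <= 1e-12)
        stop("degenerate within-class scatter: Tr(G^T Ww G) ~ 0")
      lambda_w <- tb / (2 * tw)
      obj_fun <- function(Dmat) {
        en <- fisher_energies(Dmat, train$Z, A_list, Gband, masks)
        en$within / en$between
      }
      obj_pre <- obj_fun(dict$D)
      dg <- dictionary_gradient(dict, train$Z, A_list, Gband, masks)
      upd <- dictionary_step(dict, dg$grad, cfg$eta, obj_fun)
      dict <- upd$dict
      list(obj = obj_fun(dict$D), obj_pre = obj_pre, rho = lambda_w,
           eta = upd$eta_used, ortho = ortho_dev)
    }, error = function(e)
      stop(sprintf("iteration %d: %s", iter, conditionMessage(e)), call. = FALSE))
    history[[iter]] <- data.frame(
      iter = iter, objective = step$obj, objective_before_dict = step$obj_pre,
      rho = step$rho, eta_used = step$eta, ortho_dev = step$ortho)
    if (is.finite(obj_prev) &&
        abs(step$obj - obj_prev) <= cfg$tol * (1 + abs(obj_prev))) break
    obj_prev <- step$obj
  }
  proj <- list(G0 = NULL, Gtilde = Gband, Gband = Gband, sigma = 1, stacked = G)
  new_mbcc_model("opfddl", cfg, proj, dict, history, train)
}

#' @export
print.mbcc_model <- function(x, ...) {
  cat(sprintf("<mbcc_model> method = %s, %d band(s), d = %d, p = %d, %d classes\n",
              x$method, x$M, x$d, ncol(x$projections$Gband[[1]]), x$C))
  cat(sprintf("  dictionary: %d atoms (%d per class)\n",
              x$dictionary$K, x$dictionary$atoms_per_class))
  h <- x$history
  cat(sprintf("  %d iteration(s); final objective %.6g, rho %.6g\n",
              nrow(h), h$objective[nrow(h)], h$rho[nrow(h)]))
  invisible(x)
}

#' Plot the training trajectory
#'
#' Objective value and trace-ratio value (adaptive weight for the
#' baseline) per outer iteration.
#'
#' @param x an `mbcc_model`.
#' @param ... ignored.
#' @export
plot.mbcc_model <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(h$iter, h$objective, type = "b", xlab = "iteration",
       ylab = "objective", main = paste(x$method, "objective"))
  plot(h$iter, h$rho, type = "b", xlab = "iteration",
       ylab = if (x$method == "mbcc") "rho" else "adaptive weight",
       main = "trace-ratio value")
  invisible(x)
}
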