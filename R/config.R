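#' Model configuration
#'
#' Hyperparameters for [fit_mbcc()] and [fit_opfddl()].
#'
#' `alpha` weighs the PCA-like variance-retention reward on the shared
#' projection component: the shared trace-ratio solve minimizes the
#' within-class reconstruction energy relative to the between-class
#' energy *plus* `alpha` times the data variance retained by the shared
#' component (`alpha = 0` disables the reward and leaves a pure Fisher
#' criterion). `sigma` mixes the shared and band-specific projection
#' components, `G^m = (1 - sigma) G0 + sigma Gtilde^m`; when not given it
#' defaults to `1 - alpha`, coupling the two so that a stronger
#' shared-variance reward goes with a stronger shared component.
#' `lambda_code` is the ridge penalty of the coding step;
#' `atoms_per_class` the number of dictionary atoms per class; `p` the
#' subspace dimension (defaults to 90% of the feature dimension once data
#' are seen); `lambda_rho` the learning rate of the trace-ratio root
#' iteration; `eta` the initial dictionary gradient step (halved by
#' backtracking); `max_iter`/`tol` the outer-loop budget and
#' relative-objective stopping tolerance. `gamma_w` shrinks every
#' within-class scatter toward a scaled identity
#' (`Ww + gamma_w mean(diag(Ww)) I`) before the projection solves,
#' guarding the trace ratio against finite-sample within-null directions
#' that carry no class structure; the default intensity 1 (a ridge equal
#' to the scatter's mean diagonal) is scale-free and keeps the shared
#' component anchored to directions with real data energy.
#'
#' @param alpha variance-retention weight, in \[0, 1\].
#' @param sigma shared/specific mixing weight in \[0, 1\]; default `1 - alpha`.
#' @param lambda_code ridge coding penalty, > 0.
#' @param atoms_per_class dictionary atoms per class.
#' @param p subspace dimension, or `NULL` to use `round(0.9 * d)` at fit
#'   time.
#' @param lambda_rho learning rate of the trace-ratio iteration, > 0.
#' @param eta initial dictionary gradient step size, > 0.
#' @param max_iter maximum outer iterations.
#' @param tol relative objective-change stopping tolerance, > 0.
#' @param gamma_w within-scatter shrinkage intensity, >= 0.
#' @param seed integer seed (reserved for stochastic extensions; the
#'   fitting path is deterministic given the data).
#' @return An object of class `mbcc_config` (a validated list).
#' @examples
#' mbcc_config(alpha = 0.4)$sigma   # 0.6
#' @export
mbcc_config <- function(alpha = 0.5, sigma = NULL, lambda_code = 0.01,
                        atoms_per_class = 15L, p = NULL, lambda_rho = 0.5,
                        eta = 1e-2, max_iter = 50L, tol = 1e-6,
                        gamma_w = 1, seed = 1L) {
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stop("`alpha` must lie in [0, 1] (0 disables the variance regularizer)")
  if (is.null(sigma)) sigma <- 1 - alpha
  if (!is.numeric(sigma) || sigma < 0 || sigma > 1)
    stop("`sigma` must lie in [0, 1]")
  if (!is.numeric(lambda_code) || lambda_code <= 0)
    stop("`lambda_code` must be > 0")
  if (atoms_per_class < 1L) stop("`atoms_per_class` must be a positive integer")
  if (!is.null(p) && p < 1L) stop("`p` must be a positive integer")
  if (lambda_rho <= 0) stop("`lambda_rho` must be > 0")
  if (eta <= 0) stop("`eta` must be > 0")
  if (max_iter < 1L) stop("`max_iter` must be a positive integer")
  if (tol <= 0) stop("`tol` must be > 0")
  if (gamma_w < 0) stop("`gamma_w` must be >= 0")
  structure(
    list(alpha = alpha, sigma = sigma, lambda_code = lambda_code,
         atoms_per_class = as.integer(atoms_per_class),
         p = if (is.null(p)) NULL else as.integer(p),
         lambda_rho = lambda_rho, eta = eta,
         max_iter = as.integer(max_iter), tol = tol,
         gamma_w = gamma_w, seed = as.integer(seed)),
    class = "mbcc_config"
  )
}

# resolve data-dependent defaults and sanity-check against a dataset
resolve_config <- function(cfg, ds) {
  stopifnot(inherits(cfg, "mbcc_config"), inherits(ds, "multiband_dataset"))
  if (is.null(cfg$p)) cfg$p <- max(1L, as.integer(round(0.9 * ds$d)))
  if (cfg$p > ds$d)
    stop(sprintf("subspace dimension p = %d exceeds feature dimension d = %d",
                 cfg$p, ds$d))
  if (cfg$atoms_per_class * ds$C > ds$n)
    warning(sprintf(
      "dictionary size %d exceeds sample count %d; consider fewer atoms per class",
      cfg$atoms_per_class * ds$C, ds$n))
  cfg
}

#' @export
print.mbcc_config <- function(x, ...) {
  cat("<mbcc_config>\n")
  cat(sprintf("  alpha = %g, sigma = %g, lambda_code = %g\n",
              x$alpha, x$sigma, x$lambda_code))
  cat(sprintf("  atoms_per_class = %d, p = %s\n", x$atoms_per_class,
              if (is.null(x$p)) "round(0.9 d)" else as.character(x$p)))
  cat(sprintf("  lambda_rho = %g, eta = %g, max_iter = %d, tol = %g\n",
              x$lambda_rho, x$eta, x$max_iter, x$tol))
  invisible(x)
}
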