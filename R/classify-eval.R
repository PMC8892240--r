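#' Per-band sparse-representation residual classification
#'
#' Projects a sample into the band's subspace, `zhat = Gm^T z`, and scores
#' each class by the least-squares residual of reconstructing `zhat` from
#' that class's projected sub-dictionary
#' `Dhat_j = Gm^T D_j`:
#' `residual_j = || zhat - Dhat_j (Dhat_j^T Dhat_j + eps I)^{-1} Dhat_j^T
#' zhat ||^2`. The label is the residual-minimizing class, ties broken by
#' the smallest class index.
#'
#' @param z length-`d` feature vector (one band).
#' @param Gm `d x p` effective projection of that band.
#' @param dict a [dictionary_model()].
#' @param eps ridge regularizer guarding rank-deficient projected
#'   sub-dictionaries.
#' @return List with `label` and `residuals` (length `C`).
#' @export
band_predict <- function(z, Gm, dict, eps = 1e-8) {
  res <- band_residuals(matrix(z, ncol = 1), Gm, dict, eps)[, 1]
  list(label = which.min(res), residuals = res)
}

# residual matrix C x n for a whole band at once
band_residuals <- function(Z, Gm, dict, eps = 1e-8) {
  Zp <- crossprod(Gm, Z)                       # p x n
  res <- matrix(0, dict$C, ncol(Z))
  for (j in seq_len(dict$C)) {
    Dj <- crossprod(Gm, dict$D[, class_atoms(dict, j), drop = FALSE])
    coef <- solve(crossprod(Dj) + eps * diag(ncol(Dj)), crossprod(Dj, Zp))
    R <- Zp - Dj %*% coef
    res[j, ] <- colSums(R^2)
  }
  res
}

#' Majority vote across bands
#'
#' The final label is the modal per-band label. A tie between labels with
#' equal vote counts is broken in favour of the tied label whose voting
#' bands accumulated the smallest total winning residual; any remaining
#' tie goes to the smallest class index.
#'
#' @param band_labels integer vector of per-band labels (length `M`).
#' @param band_residuals `M x C` matrix of per-band class residuals.
#' @return The winning integer label.
#' @export
majority_vote <- function(band_labels, band_residuals) {
  C <- ncol(band_residuals)
  counts <- tabulate(band_labels, nbins = C)
  tied <- which(counts == max(counts))
  if (length(tied) == 1L) return(tied)
  score <- vapply(tied, function(L) {
    voters <- which(band_labels == L)
    sum(band_residuals[voters, L])
  }, numeric(1))
  tied[which.min(score)]
}

#' Predict class labels for a multi-band dataset
#'
#' Runs the per-band residual classifier on every band of every sample,
#' then combines the per-band labels by [majority_vote()].
#'
#' @param object a fitted `mbcc_model`.
#' @param newdata a [multiband_dataset()] with the same band count and
#'   feature dimension as the training data.
#' @param eps ridge regularizer for the projected sub-dictionary solves.
#' @param ... ignored.
#' @return Integer vector of predicted labels in `1..C`. With
#'   `details = TRUE`, a list also carrying the per-band label matrix
#'   (`M x n`) and the residual array (`M x C x n`).
#' @param details return per-band labels and residuals as well.
#' @export
predict.mbcc_model <- function(object, newdata, eps = 1e-8, details = FALSE,
                               ...) {
  stopifnot(inherits(newdata, "multiband_dataset"))
  if (newdata$M != object$M)
    stop(sprintf("dataset has %d band(s) but the model was trained on %d",
                 newdata$M, object$M))
  if (newdata$d != object$d)
    stop(sprintf("dataset has %d features but the model was trained on %d",
                 newdata$d, object$d))
  res <- array(0, dim = c(object$M, object$C, newdata$n))
  band_labels <- matrix(0L, object$M, newdata$n)
  for (m in seq_len(object$M)) {
    r <- band_residuals(newdata$Z[[m]], object$projections$Gband[[m]],
                        object$dictionary, eps)
    res[m, , ] <- r
    band_labels[m, ] <- apply(r, 2L, which.min)
  }
  labels <- vapply(seq_len(newdata$n), function(j)
    majority_vote(band_labels[, j], matrix(res[, , j], object$M, object$C)),
    integer(1))
  if (details)
    list(labels = labels, band_labels = band_labels, residuals = res)
  else labels
}

#' Evaluate a fitted model on labelled data
#'
#' @param model a fitted `mbcc_model`.
#' @param test a labelled [multiband_dataset()].
#' @param eps ridge regularizer for the residual solves.
#' @return Object of class `mbcc_eval`: `accuracy`, `confusion`
#'   (`C x C` counts, rows = true labels, columns = predicted),
#'   `per_band_accuracy` (length `M`), `n_test`, and the prediction
#'   vector.
#' @export
evaluate <- function(model, test, eps = 1e-8) {
  stopifnot(inherits(model, "mbcc_model"))
  pr <- predict(model, test, eps = eps, details = TRUE)
  C <- model$C
  confusion <- table(factor(test$labels, levels = seq_len(C)),
                     factor(pr$labels, levels = seq_len(C)))
  confusion <- matrix(as.integer(confusion), C, C,
                      dimnames = list(true = model$label_values,
                                      predicted = model$label_values))
  per_band <- vapply(seq_len(model$M), function(m)
    mean(pr$band_labels[m, ] == test$labels), numeric(1))
  structure(list(accuracy = mean(pr$labels == test$labels),
                 confusion = confusion,
                 per_band_accuracy = stats::setNames(per_band, model$band_names),
                 n_test = test$n, predictions = pr$labels),
            class = "mbcc_eval")
}

#' Row-normalized confusion matrix
#'
#' @param x an `mbcc_eval`.
#' @return `C x C` matrix of per-true-class prediction fractions.
#' @export
confusion_fractions <- function(x) {
  stopifnot(inherits(x, "mbcc_eval"))
  rs <- rowSums(x$confusion)
  sweep(x$confusion, 1L, ifelse(rs > 0, rs, 1), "/")
}

#' @export
print.mbcc_eval <- function(x, ...) {
  cat(sprintf("<mbcc_eval> accuracy %.4f on %d samples\n", x$accuracy, x$n_test))
  cat("  per-band accuracy:",
      paste(sprintf("%s %.3f", names(x$per_band_accuracy), x$per_band_accuracy),
            collapse = ", "), "\n")
  cat("  confusion (rows = true):\n")
  print(x$confusion)
  invisible(x)
}
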