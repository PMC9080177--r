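# Downstream prediction and the benchmarking metrics.

#' Sufficient predictors
#'
#' Projects the data onto the estimated basis: `U = X %*% V_hat`. These are
#' the fitted sufficient predictors (discriminant scores for a categorical
#' response).
#'
#' @param X n x p matrix.
#' @param basis A `"sparse_basis"` object or p x d matrix.
#' @return n x d score matrix.
#' @export
sufficient_predictors <- function(X, basis) {
  V <- if (inherits(basis, "sparse_basis")) basis$v_hat else as.matrix(basis)
  X <- as.matrix(X)
  if (ncol(X) != nrow(V)) stop("ncol(X) must equal nrow(basis)")
  X %*% V
}

#' Nearest-centroid classification
#'
#' Assigns each test point the class whose training-score centroid is
#' nearest in Euclidean distance. Ties go to the smallest class label in
#' sorted order.
#'
#' @param train_scores n x d training score matrix.
#' @param train_labels Length-n class labels.
#' @param test_scores m x d test score matrix.
#' @return Factor of m predicted labels with the training levels.
#' @export
nearest_centroid <- function(train_scores, train_labels, test_scores) {
  train_scores <- as.matrix(train_scores)
  test_scores <- as.matrix(test_scores)
  if (nrow(train_scores) == 0L) stop("empty training set")
  f <- factor(train_labels)
  cen <- rowsum(train_scores, f) / as.integer(table(f))
  # squared distances m x K
  d2 <- outer(rowSums(test_scores^2), rowSums(cen^2), "+") -
    2 * tcrossprod(test_scores, cen)
  pred <- apply(d2, 1L, which.min)  # which.min takes the first (sorted) label
  factor(levels(f)[pred], levels = levels(f))
}

#' Within-class whitening transform for discriminant scores
#'
#' Computes `W^{-1/2}` where `W` is the pooled within-class covariance of
#' the training scores. Nearest-centroid classification on `U %*% W^{-1/2}`
#' is then the linear discriminant rule in the reduced space: without this
#' sphering, directions with large between-class spread are implicitly
#' over-weighted. Eigenvalues of `W` below a relative floor are clipped to
#' keep the transform defined for degenerate score sets.
#'
#' @param scores n x d training score matrix.
#' @param labels Length-n class labels.
#' @return d x d symmetric transform matrix.
#' @export
within_class_whitener <- function(scores, labels) {
  scores <- as.matrix(scores)
  f <- factor(labels)
  cen <- rowsum(scores, f) / as.integer(table(f))
  R <- scores - cen[as.integer(f), , drop = FALSE]
  W <- crossprod(R) / nrow(scores)
  es <- eigen((W + t(W)) / 2, symmetric = TRUE)
  vals <- pmax(es$values, max(es$values, 0) * 1e-8, 1e-12)
  es$vectors %*% (t(es$vectors) / sqrt(vals))
}

#' Variable-selection rates
#'
#' `tpr` is the fraction of truly active predictors declared active;
#' `fpr` is the fraction of truly inactive predictors declared active.
#'
#' @param est_support Estimated support (integer indices in 1..p).
#' @param true_support True support (nonempty).
#' @param p Total number of predictors.
#' @return List with `tpr` and `fpr`.
#' @export
selection_metrics <- function(est_support, true_support, p) {
  if (!length(true_support)) stop("true support must be nonempty")
  if (length(c(est_support, true_support)) &&
      (max(c(est_support, true_support, 1)) > p ||
       min(c(est_support, true_support, 1)) < 1)) {
    stop("supports must lie in 1..p")
  }
  tp <- length(intersect(est_support, true_support))
  fp <- length(setdiff(est_support, true_support))
  list(tpr = tp / length(true_support), fpr = fp / (p - length(true_support)))
}

#' Mean absolute correlation between true and estimated sufficient predictors
#'
#' Computes, for each true direction, the absolute Pearson correlation
#' between `X %*% v_j` and the best-matching estimated score column; columns
#' are aligned greedily by maximum absolute correlation without
#' replacement. Direction vectors are sign- and scale-indeterminate, so the
#' absolute value is the meaningful quantity. If the estimate has fewer
#' usable columns than the truth, unmatched true directions contribute 0.
#'
#' @param true_basis p x d matrix of true directions.
#' @param est_basis p x d_hat estimated basis (or `"sparse_basis"`).
#' @param X Evaluation sample, n x p.
#' @return Mean absolute correlation in `[0, 1]`.
#' @export
predictor_correlation <- function(true_basis, est_basis, X) {
  Vt <- as.matrix(true_basis)
  Ve <- if (inherits(est_basis, "sparse_basis")) est_basis$v_hat
        else as.matrix(est_basis)
  X <- as.matrix(X)
  Ut <- X %*% Vt
  Ue <- X %*% Ve
  if (any(apply(Ut, 2L, stats::sd) == 0)) {
    stop("a true sufficient predictor is constant (zero variance)")
  }
  keep <- apply(Ue, 2L, stats::sd) > 0
  Ue <- Ue[, keep, drop = FALSE]
  dt <- ncol(Ut)
  got <- numeric(dt)
  if (ncol(Ue)) {
    C <- abs(stats::cor(Ut, Ue))
    for (k in seq_len(min(dt, ncol(Ue)))) {
      ij <- arrayInd(which.max(C), dim(C))
      got[ij[1L]] <- C[ij[1L], ij[2L]]
      C[ij[1L], ] <- -Inf
      C[, ij[2L]] <- -Inf
    }
  }
  mean(got)
}

#' Projection distance between two subspaces
#'
#' `Delta = || P_hat - P ||_F` where `P = V (V'V)^-1 V'` is the orthogonal
#' projector onto the column span. Basis-free: invariant to any change of
#' basis within either span.
#'
#' @param v_hat,v_true p x d full-column-rank matrices (or
#'   `"sparse_basis"` objects).
#' @return Nonnegative distance.
#' @export
projection_distance <- function(v_hat, v_true) {
  proj <- function(V) {
    V <- if (inherits(V, "sparse_basis")) V$v_hat else as.matrix(V)
    if (qr(V)$rank < ncol(V)) stop("basis is rank-deficient")
    V %*% solve(crossprod(V), t(V))
  }
  norm(proj(v_hat) - proj(v_true), "F")
}

#' Misclassification rate
#'
#' Fraction of predicted labels that disagree with the truth.
#'
#' @param pred,truth Label vectors of equal length.
#' @return Proportion in `[0, 1]`.
#' @export
misclassification_rate <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  mean(as.character(pred) != as.character(truth))
}
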