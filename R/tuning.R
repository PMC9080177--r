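# Selection of the sparsity level tau.

#' Candidate grid for the constraint level tau
#'
#' The solution is identically zero once `tau >= max_i ||b_i||_1`, which
#' bounds the useful range. Returns `n_points` log-spaced values strictly
#' inside `(0, tau_max)`, spanning `tau_max * [1e-3, 0.99]`.
#'
#' @param kernel A `"whitened_kernel"` object.
#' @param n_points Grid size (default 25).
#' @return Increasing numeric vector of candidates, with attribute
#'   `tau_max`.
#' @export
tau_grid <- function(kernel, n_points = 25L) {
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("n_points must be at least 2")
  B <- row_targets(kernel)
  tau_max <- max(rowSums(abs(B)))
  if (tau_max <= 0) stop("kernel targets are all zero; nothing to tune")
  grid <- exp(seq(log(tau_max * 1e-3), log(tau_max * 0.99),
                  length.out = n_points))
  attr(grid, "tau_max") <- tau_max
  grid
}

#' BIC-type selection of tau (continuous response)
#'
#' For each candidate the average squared residual is
#' `G(tau) = tr(V' Sigma V - V' M V) / tr(V' M V)` with `V = V_hat(tau)`,
#' and `BIC(tau) = n * log(G(tau)) + log(n) * s(tau)` where `s(tau)` is the
#' number of nonzero rows. Candidates with an all-zero solution, fewer
#' nonzero rows than the structural dimension (a basis with `s < d` rows is
#' rank-deficient and cannot span a d-dimensional subspace), a nonpositive
#' kernel trace, or `G <= 0` are excluded (their score is `NA`). Ties are
#' broken toward the largest tau, i.e. the sparsest model.
#'
#' @param kernel A `"whitened_kernel"` object.
#' @param moments The `"sir_moments"` the kernel was built from.
#' @param grid Candidate tau values (see [tau_grid()]).
#' @param n Sample size used in the penalty; defaults to `moments$n`.
#' @return Object of class `"sir_tuning"`: list with `method = "bic"`,
#'   `grid`, `scores`, `g_values`, `s_values`, `tau_opt`.
#' @export
select_tau_bic <- function(kernel, moments, grid, n = moments$n) {
  stopifnot(inherits(kernel, "whitened_kernel"),
            inherits(moments, "sir_moments"))
  if (!length(grid)) stop("empty candidate grid")
  m <- length(grid)
  scores <- g_values <- rep(NA_real_, m)
  s_values <- integer(m)
  for (j in seq_len(m)) {
    fit <- solve_group_dantzig(kernel, grid[j])
    s_values[j] <- fit$s_tau
    if (fit$s_tau < kernel$d) next
    V <- fit$v_hat
    tr_m <- sum(V * (moments$m_hat %*% V))
    if (tr_m <= 0) next
    tr_s <- sum(V * (moments$sigma_hat %*% V))
    G <- (tr_s - tr_m) / tr_m
    g_values[j] <- G
    if (G <= 0) next
    scores[j] <- n * log(G) + log(n) * s_values[j]
  }
  if (all(is.na(scores))) {
    stop("every tau candidate was excluded (zero solution or G <= 0)")
  }
  best <- min(scores, na.rm = TRUE)
  tau_opt <- max(grid[!is.na(scores) & scores <= best + 1e-12])
  structure(
    list(method = "bic", grid = as.numeric(grid), scores = scores,
         g_values = g_values, s_values = s_values, tau_opt = tau_opt),
    class = "sir_tuning"
  )
}

#' Cross-validated selection of tau (categorical response)
#'
#' K-fold cross-validation of the nearest-centroid misclassification rate.
#' Folds are stratified by class. For each fold and candidate, the basis is
#' fitted on the training portion, held-out samples are projected onto it,
#' and classified by the nearest training-score centroid;
#' `CV(tau) = (1/K) sum_k (#errors_k / n_k)`. Ties are broken toward the
#' largest tau (sparsest model). Candidates whose basis is all-zero in some
#' fold are excluded.
#'
#' @param X n x p predictor matrix.
#' @param y Categorical response.
#' @param grid Candidate tau values (typically from the full-data kernel).
#' @param d Structural dimension; `NULL` uses `rank(M_hat)` per fold
#'   (number of classes minus one).
#' @param K Number of folds (default 5).
#' @param seed Optional seed for the fold assignment.
#' @param use_clime `"auto"` (CLIME when p >= n_train), `"always"`, or
#'   `"never"`.
#' @param c1,c1_grid,lambda CLIME tuning, see [clime_precision()]; the
#'   precision estimate is computed once per training fold and reused
#'   across the whole tau grid.
#' @return Object of class `"sir_tuning"`: list with `method = "cv"`,
#'   `grid`, `scores`, `s_values` (support size on the full data),
#'   `tau_opt`, `folds`.
#' @export
select_tau_cv <- function(X, y, grid, d = NULL, K = 5L, seed = NULL,
                          use_clime = c("auto", "always", "never"),
                          c1 = NULL, c1_grid = c(0.5, 1, 2, 4),
                          lambda = NULL) {
  use_clime <- match.arg(use_clime)
  X <- as.matrix(X)
  n <- nrow(X)
  f <- factor(y)
  if (nlevels(f) < 2L) stop("need at least 2 classes")
  K <- as.integer(K)
  if (K < 2L) stop("K must be at least 2")
  if (min(table(f)) < K) {
    stop("every class needs at least K samples for stratified folds")
  }
  folds <- stratified_folds(f, K, seed = seed)
  m <- length(grid)
  err <- matrix(NA_real_, K, m)
  for (k in seq_len(K)) {
    test <- folds == k
    Xtr <- X[!test, , drop = FALSE]
    Xte <- X[test, , drop = FALSE]
    ytr <- f[!test]
    yte <- f[test]
    if (nlevels(droplevels(ytr)) < nlevels(f)) {
      stop("a class is absent from a training fold")
    }
    ctr <- colMeans(Xtr)
    sl <- sir_slice(ytr, kind = "categorical")
    mo <- sir_moments(Xtr, sl)
    clime_k <- (use_clime == "always") ||
      (use_clime == "auto" && ncol(X) >= nrow(Xtr))
    omega <- if (clime_k) {
      clime_precision(X = Xtr, sigma_hat = mo$sigma_hat, lambda = lambda,
                      c1 = c1, c1_grid = c1_grid, seed = seed)
    } else NULL
    kern <- whitened_kernel(mo, omega = omega, d = d)
    Utr_c <- sweep(Xtr, 2L, ctr, "-")
    Ute_c <- sweep(Xte, 2L, ctr, "-")
    for (j in seq_len(m)) {
      fit <- solve_group_dantzig(kern, grid[j])
      if (fit$s_tau == 0L) next
      Utr <- Utr_c %*% fit$v_hat
      Tm <- within_class_whitener(Utr, ytr)
      pred <- nearest_centroid(Utr %*% Tm, ytr,
                               (Ute_c %*% fit$v_hat) %*% Tm)
      err[k, j] <- mean(pred != yte)
    }
  }
  scores <- colMeans(err)  # NA when any fold had an all-zero basis
  if (all(is.na(scores))) {
    stop("the basis was all-zero for every tau candidate")
  }
  best <- min(scores, na.rm = TRUE)
  tau_opt <- max(grid[!is.na(scores) & scores <= best + 1e-12])
  structure(
    list(method = "cv", grid = as.numeric(grid), scores = scores,
         s_values = NULL, tau_opt = tau_opt, folds = folds),
    class = "sir_tuning"
  )
}

# Stratified fold assignment: within each class, shuffled indices are dealt
# to folds round-robin, so per-fold class proportions are within one
# observation of exact stratification.
stratified_folds <- function(f, K, seed = NULL) {
  n <- length(f)
  folds <- integer(n)
  with_seed(seed, {
    for (lev in levels(f)) {
      idx <- which(f == lev)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(K), length(idx))
    }
    folds
  })
}
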