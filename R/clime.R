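# Constrained l1 inverse-covariance estimation (CLIME) and helpers.
#
# The program  min ||Omega||_1  s.t.  max_kl |(Sigma Omega - I)_kl| <= lambda
# decomposes into p independent column problems (column j targets e_j). All
# columns are solved jointly here by a linearized ADMM iteration on the full
# matrix variable: per iteration two p x p products with Sigma, a
# soft-threshold, and a box projection. The step bound mu >= rho * ||Sigma||^2
# guarantees convergence of the split.

#' Default CLIME constraint level
#'
#' `lambda = c1 * sqrt(log(p) / n)`, the rate-optimal scaling for
#' sub-Gaussian designs; the multiplier `c1` is problem-dependent.
#'
#' @param n Sample size (>= 2).
#' @param p Number of predictors (>= 2).
#' @param c1 Positive multiplier.
#' @return The constraint level.
#' @export
clime_lambda <- function(n, p, c1) {
  if (n < 2 || p < 2) stop("need n >= 2 and p >= 2")
  if (!is.numeric(c1) || length(c1) != 1L || c1 <= 0) {
    stop("c1 must be a positive scalar")
  }
  c1 * sqrt(log(p) / n)
}

#' Solve the CLIME program
#'
#' Minimizes the elementwise l1-norm of `Omega` subject to
#' `max |Sigma %*% Omega - I| <= lambda`. The solution is in general
#' asymmetric; see [clime_symmetrize()]. At `lambda = 0` with an invertible
#' `sigma_hat` the feasible set is the single point `solve(sigma_hat)`,
#' which is returned directly.
#'
#' @param sigma_hat Symmetric p x p covariance estimate.
#' @param lambda Constraint level (>= 0).
#' @param tol Convergence tolerance on the primal residual and iterate change.
#' @param max_iter Iteration cap.
#' @param rho ADMM penalty parameter.
#' @param init Optional warm-start matrix (e.g. the solution at a nearby
#'   lambda).
#' @return p x p matrix `omega_raw` with attributes `lambda`, `iterations`,
#'   `converged`.
#' @export
clime_solve <- function(sigma_hat, lambda, tol = 1e-7, max_iter = 10000L,
                        rho = 1, init = NULL) {
  S <- as.matrix(sigma_hat)
  p <- nrow(S)
  if (ncol(S) != p) stop("sigma_hat must be square")
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8))) {
    stop("sigma_hat must be symmetric")
  }
  if (lambda < 0) stop("lambda must be nonnegative")
  S <- (S + t(S)) / 2

  if (lambda == 0) {
    Omega <- tryCatch(solve(S), error = function(e) {
      stop("lambda = 0 requires an invertible covariance: ",
           conditionMessage(e))
    })
    attr(Omega, "lambda") <- 0
    attr(Omega, "iterations") <- 0L
    attr(Omega, "converged") <- TRUE
    return(Omega)
  }

  I_p <- diag(p)
  smax <- max(abs(eigen(S, symmetric = TRUE, only.values = TRUE)$values))
  mu <- rho * smax^2 * 1.01
  soft <- function(M, t) sign(M) * pmax(abs(M) - t, 0)

  dS <- diag(S)
  Omega <- if (is.null(init)) diag(ifelse(dS > 0, 1 / dS, 1), p)
           else as.matrix(init)
  A <- S %*% Omega - I_p
  Z <- pmin(pmax(A, -lambda), lambda)
  U <- matrix(0, p, p)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    Omega_new <- soft(Omega - (rho / mu) * (S %*% (A - Z + U)), 1 / mu)
    A <- S %*% Omega_new - I_p
    Z <- pmin(pmax(A + U, -lambda), lambda)
    R1 <- A - Z
    U <- U + R1
    dOmega <- max(abs(Omega_new - Omega))
    Omega <- Omega_new
    if (max(abs(R1)) < tol && dOmega < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("CLIME ADMM stopped at max_iter = ", max_iter,
            " (primal residual ", signif(max(abs(S %*% Omega - I_p)) - lambda, 3),
            " above lambda)")
  }
  attr(Omega, "lambda") <- lambda
  attr(Omega, "iterations") <- it
  attr(Omega, "converged") <- converged
  Omega
}

#' Symmetrize a CLIME solution
#'
#' For each pair `(k, l)` both entries are replaced by whichever of
#' `omega[k, l]`, `omega[l, k]` has the smaller magnitude; on ties the
#' upper-triangle entry (`k < l`) wins, matching the `<=` in the defining
#' indicator.
#'
#' @param omega Square matrix.
#' @return Symmetric matrix of the same dimension.
#' @export
clime_symmetrize <- function(omega) {
  omega <- as.matrix(omega)
  p <- nrow(omega)
  if (ncol(omega) != p) stop("omega must be square")
  to <- t(omega)
  picked <- ifelse(abs(omega) <= abs(to), omega, to)  # upper entry wins ties
  res <- omega
  up <- upper.tri(res)
  res[up] <- picked[up]
  res[lower.tri(res)] <- t(res)[lower.tri(res)]
  res
}

#' CLIME precision estimate with data-driven tuning
#'
#' Estimates `Sigma^-1` by CLIME and symmetrizes the solution. The
#' constraint level is `lambda` if given, else `c1 * sqrt(log(p)/n)`; when
#' `c1` is not supplied it is chosen from `c1_grid` by K-fold
#' cross-validation minimizing `||Sigma_test %*% Omega_s - I||_F`.
#'
#' @param X n x p data matrix (required when `c1` must be cross-validated).
#' @param sigma_hat Optional precomputed covariance (divisor n); derived
#'   from `X` when missing.
#' @param lambda Constraint level; overrides `c1`.
#' @param c1 Multiplier for the default level.
#' @param c1_grid Candidate multipliers for cross-validation.
#' @param folds Number of CV folds (default 5).
#' @param seed Optional seed making the fold assignment reproducible.
#' @param cv_tol,cv_max_iter Looser solver settings used inside CV.
#' @param ... Passed to [clime_solve()] for the final solve.
#' @return Object of class `"clime_precision"`: list with `omega_raw`,
#'   `omega_sym`, `lambda`, `c1`, `cv_scores`, `iterations`, `converged`.
#' @export
clime_precision <- function(X = NULL, sigma_hat = NULL, lambda = NULL,
                            c1 = NULL, c1_grid = c(0.5, 1, 2, 4),
                            folds = 5L, seed = NULL,
                            cv_tol = 1e-3, cv_max_iter = 300L, ...) {
  if (is.null(sigma_hat)) {
    if (is.null(X)) stop("supply X or sigma_hat")
    X <- as.matrix(X)
    sigma_hat <- cov_n(X)
  }
  p <- nrow(sigma_hat)
  n <- if (!is.null(X)) nrow(X) else NA_integer_
  cv_scores <- NULL

  if (is.null(lambda)) {
    if (is.null(c1)) {
      if (is.null(X)) stop("cross-validating c1 requires the data matrix X")
      cv_scores <- clime_cv_c1(X, c1_grid, folds = folds, seed = seed,
                               tol = cv_tol, max_iter = cv_max_iter)
      c1 <- c1_grid[which.min(cv_scores)]
    }
    lambda <- clime_lambda(n, p, c1)
  }
  omega_raw <- clime_solve(sigma_hat, lambda, ...)
  omega_sym <- clime_symmetrize(omega_raw)
  structure(
    list(omega_raw = omega_raw, omega_sym = omega_sym, lambda = lambda,
         c1 = c1, cv_scores = cv_scores,
         iterations = attr(omega_raw, "iterations"),
         converged = attr(omega_raw, "converged")),
    class = "clime_precision"
  )
}

# K-fold CV score per c1 candidate: Frobenius distance of Sigma_test Omega_s
# to the identity, averaged over folds.
clime_cv_c1 <- function(X, c1_grid, folds = 5L, seed = NULL,
                        tol = 1e-4, max_iter = 500L) {
  n <- nrow(X)
  p <- ncol(X)
  folds <- as.integer(folds)
  if (folds < 2L || folds > n) stop("folds must be in [2, n]")
  assign_fold <- with_seed(seed, sample(rep_len(seq_len(folds), n)))
  scores <- matrix(NA_real_, folds, length(c1_grid))
  ord <- order(c1_grid, decreasing = TRUE)  # large lambda first, warm-start down
  for (k in seq_len(folds)) {
    test <- assign_fold == k
    S_tr <- cov_n(X[!test, , drop = FALSE])
    S_te <- cov_n(X[test, , drop = FALSE])
    n_tr <- sum(!test)
    Om0 <- NULL
    for (j in ord) {
      lam <- clime_lambda(n_tr, p, c1_grid[j])
      Om <- suppressWarnings(clime_solve(S_tr, lam, tol = tol,
                                         max_iter = max_iter, init = Om0))
      Om0 <- Om
      scores[k, j] <- norm(S_te %*% clime_symmetrize(Om) - diag(p), "F")
    }
  }
  colMeans(scores)
}

# Sample covariance with divisor n.
cov_n <- function(X) {
  Xc <- sweep(X, 2L, colMeans(X), "-")
  S <- crossprod(Xc) / nrow(X)
  (S + t(S)) / 2
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is restored afterwards. With seed = NULL the current
# stream is used (and advanced).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
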