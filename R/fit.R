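# End-to-end sparse SIR fit.

#' Fit coordinate-independent sparse sliced inverse regression
#'
#' Full pipeline: center (optionally scale) the predictors, slice the
#' response, estimate the covariance and SIR kernel, whiten (inverting the
#' sample covariance in the classical regime, or through a CLIME precision
#' estimate when `p >= n` or the covariance is ill-conditioned), select the
#' sparsity level `tau` (cross-validated misclassification for a
#' categorical response, BIC otherwise), solve the group-Dantzig program,
#' and orthonormalize the estimate. All intermediate artifacts are kept on
#' the returned object.
#'
#' @param X n x p numeric predictor matrix.
#' @param y Response: numeric (continuous) or factor/character
#'   (categorical).
#' @param H Slice count for a continuous response (default 5; ignored for
#'   categorical, where slices are the classes).
#' @param d Structural dimension; `NULL` uses the number of classes minus
#'   one (categorical) or the 90%-spectrum rule (continuous).
#' @param tau Constraint level; `NULL` selects it on a log-spaced grid.
#' @param n_tau Grid size for tau selection (default 25).
#' @param K CV folds for categorical tau selection (default 5).
#' @param kind Response kind override (`"continuous"`/`"categorical"`).
#' @param scale Standardize columns of `X` to unit variance (default
#'   FALSE).
#' @param use_clime `"auto"` (CLIME whitening when `p >= n/2` or the
#'   covariance is numerically singular), `"always"`, or `"never"`.
#' @param lambda,c1,c1_grid CLIME tuning; see [clime_precision()].
#' @param clime_tol,clime_max_iter Solver settings for the CLIME stage; the
#'   defaults trade a little constraint accuracy for speed, which is
#'   statistically immaterial here.
#' @param seed Seed for the random parts (fold assignments); the rest of
#'   the pipeline is deterministic.
#' @return Object of class `"sparse_sir"` with elements `basis` (the
#'   orthonormalized `"sparse_basis"`), `basis_raw`, `support`, `tau`, `d`,
#'   `H`, `branch`, `kind`, `moments`, `kernel`, `tuning`, `precision`,
#'   `center`, `scale`, `scores` (training sufficient predictors),
#'   `centroids` and `levels` (categorical only).
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(600), 100, 6)
#' y <- X[, 1] + X[, 2] + rnorm(100)
#' fit <- fit_sparse_sir(X, y, d = 1)
#' fit$support
#' @export
fit_sparse_sir <- function(X, y, H = 5L, d = NULL, tau = NULL, n_tau = 25L,
                           K = 5L, kind = NULL, scale = FALSE,
                           use_clime = c("auto", "always", "never"),
                           lambda = NULL, c1 = NULL,
                           c1_grid = c(0.5, 1, 2, 4),
                           clime_tol = 1e-5, clime_max_iter = 2000L,
                           seed = NULL) {
  use_clime <- match.arg(use_clime)
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("X must be numeric")
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")

  center <- colMeans(X)
  scl <- if (scale) {
    s <- sqrt(colMeans(sweep(X, 2L, center, "-")^2))
    if (any(s == 0)) stop("cannot scale constant predictor columns")
    s
  } else rep(1, p)
  Xw <- sweep(sweep(X, 2L, center, "-"), 2L, scl, "/")

  slices <- sir_slice(y, H = H, kind = kind)
  kind <- slices$kind
  moments <- sir_moments(Xw, slices)

  # Sample-covariance whitening is only trustworthy when p/n is small:
  # the whitened-kernel eigenvectors lose consistency as p/n grows, so the
  # regularized (CLIME) inverse takes over well before p reaches n.
  sing <- {
    ev <- eigen(moments$sigma_hat, symmetric = TRUE, only.values = TRUE)$values
    ev[p] <= max(ev) * 1e-10
  }
  clime_on <- switch(use_clime,
    always = TRUE,
    never = FALSE,
    auto = (p >= n / 2) || sing
  )
  precision <- NULL
  if (clime_on) {
    precision <- clime_precision(X = Xw, sigma_hat = moments$sigma_hat,
                                 lambda = lambda, c1 = c1,
                                 c1_grid = c1_grid, seed = seed,
                                 tol = clime_tol, max_iter = clime_max_iter)
  }
  if (is.null(d) && kind == "categorical") d <- slices$H - 1L
  kernel <- whitened_kernel(moments, omega = precision, d = d)
  d <- kernel$d

  tuning <- NULL
  if (is.null(tau)) {
    grid <- tau_grid(kernel, n_points = n_tau)
    tuning <- if (kind == "categorical") {
      select_tau_cv(Xw, y, grid, d = d, K = K, seed = seed,
                    use_clime = use_clime, c1 = precision$c1,
                    c1_grid = c1_grid, lambda = lambda)
    } else {
      select_tau_bic(kernel, moments, grid)
    }
    tau <- tuning$tau_opt
  }

  basis_raw <- solve_group_dantzig(kernel, tau)
  if (basis_raw$s_tau == 0L) {
    stop("selected tau yields the all-zero solution; supply a smaller tau")
  }
  basis <- gram_schmidt_basis(basis_raw)
  scores <- Xw %*% basis$v_hat

  centroids <- NULL
  y_factor <- NULL
  score_whitener <- NULL
  if (kind == "categorical") {
    y_factor <- factor(y)
    score_whitener <- within_class_whitener(scores, y_factor)
    centroids <- rowsum(scores, y_factor) / as.integer(table(y_factor))
  }

  structure(
    list(basis = basis, basis_raw = basis_raw, support = basis$support,
         tau = tau, d = basis$d, H = slices$H, kind = kind,
         branch = if (clime_on) "precision" else "classical",
         slices = slices, moments = moments, kernel = kernel,
         tuning = tuning, precision = precision,
         center = center, scale = scl, scaled = scale,
         scores = scores, centroids = centroids, y = y_factor,
         score_whitener = score_whitener,
         levels = slices$levels, n = n, p = p, seed = seed,
         call = match.call()),
    class = "sparse_sir"
  )
}

#' @export
print.sparse_sir <- function(x, ...) {
  cat("Sparse sliced inverse regression fit\n")
  cat(sprintf("  n = %d, p = %d, response: %s, slices H = %d\n",
              x$n, x$p, x$kind, x$H))
  cat(sprintf("  whitening branch: %s\n", x$branch))
  cat(sprintf("  structural dimension d = %d\n", x$d))
  cat(sprintf("  tau = %.6g (%s), selected predictors: %d of %d\n",
              x$tau,
              if (is.null(x$tuning)) "user-supplied" else x$tuning$method,
              length(x$support), x$p))
  invisible(x)
}

#' @export
coef.sparse_sir <- function(object, ...) object$basis$v_hat

#' Predict from a sparse SIR fit
#'
#' Projects new data onto the fitted basis (after applying the training
#' centering/scaling). For a categorical fit, `type = "class"` classifies
#' by the nearest training-score centroid.
#'
#' @param object A `"sparse_sir"` fit.
#' @param newdata m x p matrix.
#' @param type `"scores"` (sufficient predictors) or `"class"`.
#' @param ... Unused.
#' @return m x d score matrix, or a factor of predicted classes.
#' @export
predict.sparse_sir <- function(object, newdata,
                               type = c("scores", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) stop("newdata has the wrong column count")
  Xw <- sweep(sweep(newdata, 2L, object$center, "-"), 2L, object$scale, "/")
  scores <- Xw %*% object$basis$v_hat
  if (type == "scores") return(scores)
  if (object$kind != "categorical") {
    stop("class prediction requires a categorical fit")
  }
  Tm <- object$score_whitener
  nearest_centroid(object$scores %*% Tm, object$y, scores %*% Tm)
}
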