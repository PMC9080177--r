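# Whitened kernel and structural-dimension utilities.

#' Whitened SIR kernel and its leading eigen-system
#'
#' Forms `K = R %*% M_hat %*% R` where `R` is the symmetric square root of
#' `Sigma_hat^-1` (classical `p < n` regime) or of a symmetrized CLIME
#' precision estimate (high-dimensional regime), and extracts the top-`d`
#' eigenpairs. The eigenvectors are the non-sparse whitened directions that
#' seed the group-Dantzig program; their signs are fixed so that the
#' largest-magnitude coordinate of each is positive.
#'
#' @param moments A `"sir_moments"` object.
#' @param omega Optional precision estimate: a `"clime_precision"` object or
#'   a symmetric p x p matrix standing for `Sigma^-1`. When `NULL` the sample
#'   covariance is inverted directly and must be numerically invertible.
#' @param d Structural dimension; `NULL` selects it with
#'   [estimate_dimension()].
#' @param dim_threshold Spectrum fraction used when `d` is estimated.
#' @return Object of class `"whitened_kernel"`: list with `k_matrix`,
#'   `v_tilde` (p x d), `lambda_tilde` (length-d eigenvalues), `d`,
#'   `eigenvalues` (full spectrum), `whitening` (the matrix R), and `branch`
#'   (`"classical"` or `"precision"`).
#' @export
whitened_kernel <- function(moments, omega = NULL, d = NULL,
                            dim_threshold = 0.9) {
  if (!inherits(moments, "sir_moments")) {
    stop("moments must come from sir_moments()")
  }
  p <- moments$p
  if (is.null(omega)) {
    es <- eigen(moments$sigma_hat, symmetric = TRUE)
    if (es$values[p] <= max(es$values) * 1e-12 || es$values[p] <= 0) {
      stop("sample covariance is numerically singular; supply a CLIME ",
           "precision estimate (omega) for the p >= n regime")
    }
    R <- es$vectors %*% (t(es$vectors) / sqrt(es$values))
    branch <- "classical"
  } else {
    if (inherits(omega, "clime_precision")) omega <- omega$omega_sym
    omega <- as.matrix(omega)
    if (!isTRUE(all.equal(omega, t(omega), tolerance = 1e-8))) {
      stop("omega must be symmetric (use the symmetrized CLIME estimate)")
    }
    es <- eigen((omega + t(omega)) / 2, symmetric = TRUE)
    if (any(es$values < 1e-10)) {
      warning("precision estimate not positive definite; eigenvalues below ",
              "1e-10 clipped to 1e-10 before the square root")
      es$values <- pmax(es$values, 1e-10)
    }
    R <- es$vectors %*% (t(es$vectors) * sqrt(es$values))
    branch <- "precision"
  }
  R <- (R + t(R)) / 2
  K <- R %*% moments$m_hat %*% R
  K <- (K + t(K)) / 2
  ek <- eigen(K, symmetric = TRUE)
  evals <- ek$values
  tol <- max(evals, 0) * 1e-8
  n_pos <- sum(evals > tol)
  if (n_pos == 0L) stop("whitened kernel has no positive eigenvalues")
  if (is.null(d)) {
    d <- estimate_dimension(pmax(evals, 0), H = moments$H,
                            threshold = dim_threshold)
    d <- min(d, n_pos)
  }
  d <- as.integer(d)
  if (d < 1L) stop("d must be at least 1")
  if (d > n_pos) {
    stop("d = ", d, " exceeds the number of eigenvalues above tolerance (",
         n_pos, ")")
  }
  v_tilde <- fix_signs(ek$vectors[, seq_len(d), drop = FALSE])
  structure(
    list(k_matrix = K, v_tilde = v_tilde, lambda_tilde = evals[seq_len(d)],
         d = d, eigenvalues = evals, whitening = R, branch = branch),
    class = "whitened_kernel"
  )
}

#' Default structural-dimension rule
#'
#' Returns the smallest `d` whose leading eigenvalues capture at least
#' `threshold` of the total spectrum mass, capped at `H - 1` when the slice
#' count is supplied. This is a pragmatic default: the structural dimension
#' is a modelling choice and can always be set explicitly.
#'
#' @param spectrum Nonnegative eigenvalues sorted in decreasing order.
#' @param H Optional slice count (caps `d` at `H - 1`).
#' @param threshold Fraction of total spectrum to capture (default 0.9).
#' @return Integer dimension estimate.
#' @examples
#' estimate_dimension(c(9, 0.9, 0.1))  # 1
#' estimate_dimension(c(5, 5, 0))      # 2
#' @export
estimate_dimension <- function(spectrum, H = NULL, threshold = 0.9) {
  if (any(spectrum < 0)) stop("spectrum must be nonnegative")
  if (is.unsorted(rev(spectrum))) stop("spectrum must be sorted decreasing")
  total <- sum(spectrum)
  if (total <= 0) stop("all-zero spectrum: no direction to estimate")
  d <- which(cumsum(spectrum) / total >= threshold)[1L]
  if (!is.null(H)) d <- min(d, as.integer(H) - 1L)
  max(as.integer(d), 1L)
}

# Deterministic sign convention: flip each column so its largest-magnitude
# entry is positive.
fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}
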