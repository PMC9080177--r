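# Row-sparse group-Dantzig program.
#
# The estimator solves
#   min_V sum_i ||v_i||_2   s.t.   max_i || b_i - Lambda v_i ||_1 <= tau,
# where B = K Vtilde has rows b_i and Lambda holds the top-d eigenvalues of
# the whitened kernel K. The norm in the constraint is the maximum row
# l1-norm, so the program separates into p independent row problems, each
#   min ||v||_2  s.t.  sum_j |b_j - lambda_j v_j| <= tau.
# A row is exactly zero iff ||b_i||_1 <= tau (zero is then feasible and
# optimal); active rows have an exact water-filling solution (see
# dantzig_row below). This gives exact zeros and an exact support rule with
# no thresholding.

#' Row targets of the group-Dantzig constraint
#'
#' `B = K %*% v_tilde`; the i-th row `b_i` is the target the i-th basis row
#' must match within the l1 budget `tau`. When `v_tilde` holds exact
#' eigenvectors of `K`, `B = v_tilde %*% diag(lambda_tilde)`.
#'
#' @param kernel A `"whitened_kernel"` object.
#' @return p x d matrix.
#' @export
row_targets <- function(kernel) {
  stopifnot(inherits(kernel, "whitened_kernel"))
  kernel$k_matrix %*% kernel$v_tilde
}

#' Single-row subproblem of the group-Dantzig program
#'
#' Minimizes `||v||_2` subject to `sum_j |b_j - lambda_j * v_j| <= tau`.
#' Returns the exact minimizer: the zero vector when `||b||_1 <= tau`,
#' otherwise the water-filling allocation from the KKT conditions: residual
#' magnitudes `a_j = max(|b_j| - c * lambda_j^2, 0)` with `c > 0` chosen so
#' they sum to `tau`, and `v_j = sign(b_j) * (|b_j| - a_j) / lambda_j`. For
#' `d = 1` this reduces to soft thresholding,
#' `v = sign(b) * max(|b| - tau, 0) / lambda`.
#'
#' @param b Numeric vector of length d (a row of [row_targets()]).
#' @param lambda_tilde Positive eigenvalues (length d).
#' @param tau Positive constraint level.
#' @return Length-d solution vector.
#' @export
dantzig_row <- function(b, lambda_tilde, tau) {
  if (tau <= 0) stop("tau must be positive")
  if (any(lambda_tilde <= 0)) stop("all eigenvalues must be positive")
  d <- length(b)
  if (length(lambda_tilde) != d) stop("length mismatch between b and lambda")
  ab <- abs(b)
  if (sum(ab) <= tau) return(numeric(d))
  l2 <- lambda_tilde^2
  # f(c) = sum_j max(ab_j - c*l2_j, 0) is piecewise linear, strictly
  # decreasing from sum(ab) > tau at c = 0 to 0; find the segment where it
  # crosses tau.
  brk <- sort(unique(ab / l2))
  cstar <- NA_real_
  lo <- 0
  for (bp in brk) {
    active <- ab / l2 > lo
    A <- sum(ab[active])
    Bsum <- sum(l2[active])
    cc <- (A - tau) / Bsum
    if (cc <= bp + 1e-15) {
      cstar <- cc
      break
    }
    lo <- bp
  }
  if (is.na(cstar)) cstar <- brk[length(brk)]
  a <- pmax(ab - cstar * l2, 0)
  sign(b) * (ab - a) / lambda_tilde
}

#' Solve the row-sparse group-Dantzig program
#'
#' Assembles the full solution from the p independent row subproblems. The
#' support is exactly `{i : ||b_i||_1 > tau}` (the screening rule); all
#' other rows are exact zeros. A feasibility certificate (the maximum row
#' l1-residual) is stored with the solution.
#'
#' @param kernel A `"whitened_kernel"` object.
#' @param tau Positive constraint level.
#' @return Object of class `"sparse_basis"`: list with `v_hat` (p x d),
#'   `tau`, `support` (integer indices), `s_tau`, `d`, `orthonormalized`
#'   (FALSE), `feasibility` (max row residual), `row_l1` (the `||b_i||_1`).
#' @export
solve_group_dantzig <- function(kernel, tau) {
  stopifnot(inherits(kernel, "whitened_kernel"))
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    stop("tau must be a positive scalar")
  }
  B <- row_targets(kernel)
  lam <- kernel$lambda_tilde
  p <- nrow(B)
  d <- ncol(B)
  rn <- rowSums(abs(B))
  active <- which(rn > tau)
  V <- matrix(0, p, d)
  if (length(active)) {
    if (d == 1L) {
      b <- B[active, 1L]
      V[active, 1L] <- sign(b) * (abs(b) - tau) / lam
    } else {
      for (i in active) V[i, ] <- dantzig_row(B[i, ], lam, tau)
    }
  }
  resid <- rowSums(abs(B - V * rep(lam, each = p)))
  structure(
    list(v_hat = V, tau = tau, support = active, s_tau = length(active),
         d = d, orthonormalized = FALSE, feasibility = max(resid),
         row_l1 = rn),
    class = "sparse_basis"
  )
}

#' Gram-Schmidt orthonormalization of a sparse basis
#'
#' Orthonormalizes the columns of the estimated basis by modified
#' Gram-Schmidt. Only column operations are involved, so zero rows remain
#' exactly zero and the row support is unchanged. Columns that are
#' numerically dependent on earlier ones are dropped with a warning.
#'
#' @param basis A `"sparse_basis"` object (or plain matrix).
#' @return The basis with orthonormal columns (`orthonormalized = TRUE`).
#' @export
gram_schmidt_basis <- function(basis) {
  V <- if (inherits(basis, "sparse_basis")) basis$v_hat else as.matrix(basis)
  if (all(V == 0)) stop("cannot orthonormalize an all-zero basis")
  d <- ncol(V)
  scale_ref <- max(sqrt(colSums(V^2)))
  Q <- matrix(0, nrow(V), 0)
  for (j in seq_len(d)) {
    w <- V[, j]
    if (ncol(Q)) w <- w - Q %*% crossprod(Q, w)
    nw <- sqrt(sum(w^2))
    if (nw > scale_ref * 1e-10) {
      Q <- cbind(Q, w / nw)
    } else {
      warning("dropping linearly dependent basis column ", j)
    }
  }
  Q <- fix_signs(Q)
  if (inherits(basis, "sparse_basis")) {
    basis$v_hat <- Q
    basis$d <- ncol(Q)
    basis$orthonormalized <- TRUE
    basis
  } else {
    Q
  }
}
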