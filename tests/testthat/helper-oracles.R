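# Shared fixtures and independent oracles used across the suite.
# Everything here is generated in code at test time; no stored data.

# Wrap a symmetric PSD matrix as a whitened-kernel object with its top-d
# eigenpairs, for exercising the solver in isolation.
make_kernel <- function(K, d) {
  K <- (K + t(K)) / 2
  ek <- eigen(K, symmetric = TRUE)
  V <- ek$vectors[, seq_len(d), drop = FALSE]
  for (j in seq_len(d)) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  structure(
    list(k_matrix = K, v_tilde = V, lambda_tilde = ek$values[seq_len(d)],
         d = as.integer(d), eigenvalues = ek$values,
         whitening = diag(nrow(K)), branch = "classical"),
    class = "whitened_kernel"
  )
}

# Random PSD kernel with a reproducible seed.
random_kernel <- function(p, d, seed) {
  set.seed(seed)
  A <- matrix(rnorm(p * p), p)
  make_kernel(crossprod(A) / p, d)
}

# Monolithic convex oracle for the group-Dantzig program: minimizes
# sum_i ||v_i||_2 subject to max_i ||b_i - Lambda v_i||_1 <= tau over all
# p*d variables at once, via slack variables (T >= +/- residual, row sums
# of T <= tau) and a log-barrier interior method (constrOptim). Nothing is
# shared with the row-decomposed solver under test.
monolithic_dantzig_objective <- function(B, lam, tau) {
  p <- nrow(B)
  d <- ncol(B)
  nv <- p * d
  fn <- function(x) {
    V <- matrix(x[1:nv], p, d)
    sum(sqrt(rowSums(V^2) + 1e-14))
  }
  gr <- function(x) {
    V <- matrix(x[1:nv], p, d)
    rn <- sqrt(rowSums(V^2) + 1e-14)
    c(as.vector(V / rn), rep(0, nv))
  }
  UI <- matrix(0, 2 * nv + p, 2 * nv)
  CI <- numeric(2 * nv + p)
  r <- 0L
  for (i in seq_len(p)) for (j in seq_len(d)) {
    idxv <- (j - 1) * p + i
    idxt <- nv + (j - 1) * p + i
    r <- r + 1L
    UI[r, idxt] <- 1; UI[r, idxv] <- lam[j]; CI[r] <- B[i, j]
    r <- r + 1L
    UI[r, idxt] <- 1; UI[r, idxv] <- -lam[j]; CI[r] <- -B[i, j]
  }
  for (i in seq_len(p)) {
    r <- r + 1L
    UI[r, nv + (0:(d - 1)) * p + i] <- -1
    CI[r] <- -tau
  }
  x0 <- c(as.vector(sweep(B, 2, lam, "/")), rep(tau / (2 * d), nv))
  stopifnot(all(UI %*% x0 - CI > 0))
  o <- stats::constrOptim(x0, fn, grad = gr, ui = UI, ci = CI,
                          method = "BFGS", outer.iterations = 300,
                          outer.eps = 1e-9,
                          control = list(maxit = 1000, reltol = 1e-14))
  o$value
}

# Column-wise CLIME LP oracle via boot::simplex:
#   min 1'(b+ + b-)  s.t.  -lambda <= S(b+ - b-) - e_j <= lambda, b+/- >= 0.
clime_lp_oracle <- function(S, lambda) {
  p <- nrow(S)
  Omega <- matrix(NA_real_, p, p)
  A <- cbind(S, -S)
  for (j in seq_len(p)) {
    ej <- as.numeric(seq_len(p) == j)
    sol <- boot::simplex(a = rep(1, 2 * p),
                         A1 = A, b1 = ej + lambda,
                         A2 = A, b2 = ej - lambda,
                         maxi = FALSE)
    Omega[, j] <- sol$soln[1:p] - sol$soln[(p + 1):(2 * p)]
  }
  Omega
}

# Small labelled Gaussian clouds for classification tests.
two_clouds <- function(n_per = 20, gap = 8, p = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * p), n_per),
             matrix(rnorm(n_per * p), n_per))
  X[(n_per + 1):(2 * n_per), 1] <- X[(n_per + 1):(2 * n_per), 1] + gap
  list(X = X, y = factor(rep(c("a", "b"), each = n_per)))
}
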