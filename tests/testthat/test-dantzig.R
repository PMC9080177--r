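test_that("row targets reduce to the eigen identity", {
  ke <- random_kernel(5, 2, seed = 101)
  B <- row_targets(ke)
  # v_tilde holds exact eigenvectors of K, so B = V Lambda
  expect_equal(B, ke$v_tilde %*% diag(ke$lambda_tilde), tolerance = 1e-10)
  # diagonal case
  ked <- make_kernel(diag(c(4, 1)), 1)
  expect_equal(row_targets(ked), matrix(c(4, 0), 2, 1), tolerance = 1e-12)
  # direct matrix-multiply oracle on a random instance
  ke4 <- random_kernel(4, 2, seed = 102)
  expect_equal(row_targets(ke4), ke4$k_matrix %*% ke4$v_tilde)
})

test_that("row subproblem closed forms hold", {
  expect_equal(dantzig_row(c(0, 0), c(1, 2), 0.7), c(0, 0))
  # d = 1 soft threshold: v = sign(b) max(|b| - tau, 0) / lambda
  expect_equal(dantzig_row(2, 1, 0.5), 1.5)
  expect_equal(dantzig_row(-2, 2, 0.5), -0.75)
  expect_equal(dantzig_row(0.3, 1, 0.5), 0)
  # d = 2 hand case
  expect_equal(dantzig_row(c(3, 0), c(1, 1), 1), c(2, 0))
  expect_error(dantzig_row(c(1, 1), c(1, 1), 0), "positive")
  expect_error(dantzig_row(c(1, 1), c(1, 0), 1), "positive")
})

test_that("row subproblem matches the interior-point oracle", {
  set.seed(103)
  for (case in 1:5) {
    d <- sample(2:3, 1)
    b <- rnorm(d, sd = 2)
    lam <- runif(d, 0.5, 2)
    tau <- runif(1, 0.2, 0.9) * sum(abs(b))
    v <- dantzig_row(b, lam, tau)
    # feasibility with equality at the optimum
    expect_equal(sum(abs(b - lam * v)), tau, tolerance = 1e-9)
    # oracle: 1-row instance of the monolithic program
    obj <- monolithic_dantzig_objective(matrix(b, 1), lam, tau)
    expect_equal(sqrt(sum(v^2)), obj, tolerance = 1e-6)
  }
})

test_that("support obeys the exact screening rule", {
  for (seed in c(201, 202)) {
    ke <- random_kernel(8, 2, seed = seed)
    B <- row_targets(ke)
    rn <- rowSums(abs(B))
    for (q in c(0.15, 0.5, 0.9)) {
      tau <- q * max(rn)
      fit <- solve_group_dantzig(ke, tau)
      expect_identical(fit$support, which(rn > tau))
      expect_equal(fit$s_tau, length(fit$support))
      # rows off the support are exact zeros
      expect_true(all(fit$v_hat[setdiff(1:8, fit$support), ] == 0))
      # feasibility certificate
      expect_lte(fit$feasibility, tau + 1e-9)
    }
    # tau at or above the bound gives the trivial all-zero solution
    expect_equal(solve_group_dantzig(ke, max(rn) + 1e-9)$s_tau, 0L)
    # support is non-increasing along an increasing tau grid
    taus <- seq(0.05, 0.95, length.out = 10) * max(rn)
    sizes <- sapply(taus, function(t) solve_group_dantzig(ke, t)$s_tau)
    expect_true(all(diff(sizes) <= 0))
  }
  expect_error(solve_group_dantzig(random_kernel(4, 1, 1), -1), "positive")
})

test_that("solution approaches the seed eigenvectors as tau shrinks", {
  ke <- random_kernel(6, 2, seed = 301)
  fit <- solve_group_dantzig(ke, 1e-8)
  expect_equal(fit$v_hat, ke$v_tilde, tolerance = 1e-6)
})

test_that("d = 1 solutions equal coordinate-wise soft thresholding", {
  ke <- random_kernel(10, 1, seed = 401)
  b <- drop(row_targets(ke))
  lam <- ke$lambda_tilde
  tau <- 0.4 * max(abs(b))
  fit <- solve_group_dantzig(ke, tau)
  expect_equal(drop(fit$v_hat), sign(b) * pmax(abs(b) - tau, 0) / lam,
               tolerance = 1e-10)
})

test_that("row-decomposed objective matches the monolithic convex oracle", {
  ke <- random_kernel(6, 2, seed = 42)
  B <- row_targets(ke)
  lam <- ke$lambda_tilde
  for (q in c(0.2, 0.5)) {
    tau <- q * max(rowSums(abs(B)))
    ours <- sum(sqrt(rowSums(solve_group_dantzig(ke, tau)$v_hat^2)))
    oracle <- monolithic_dantzig_objective(B, lam, tau)
    expect_equal(ours, oracle, tolerance = 1e-5)
  }
})

test_that("sign flips of seed columns leave support and objective unchanged", {
  ke <- random_kernel(7, 2, seed = 501)
  tau <- 0.3 * max(rowSums(abs(row_targets(ke))))
  base <- solve_group_dantzig(ke, tau)
  for (signs in list(c(-1, 1), c(1, -1), c(-1, -1))) {
    ke2 <- ke
    ke2$v_tilde <- sweep(ke$v_tilde, 2, signs, "*")
    flip <- solve_group_dantzig(ke2, tau)
    expect_identical(flip$support, base$support)
    expect_equal(flip$v_hat, sweep(base$v_hat, 2, signs, "*"),
                 tolerance = 1e-12)
    expect_equal(sum(sqrt(rowSums(flip$v_hat^2))),
                 sum(sqrt(rowSums(base$v_hat^2))), tolerance = 1e-12)
  }
})

test_that("Gram-Schmidt orthonormalizes without touching the row support", {
  ke <- random_kernel(8, 2, seed = 601)
  fit <- solve_group_dantzig(ke, 0.3 * max(rowSums(abs(row_targets(ke)))))
  gs <- gram_schmidt_basis(fit)
  expect_true(gs$orthonormalized)
  expect_equal(crossprod(gs$v_hat), diag(2), tolerance = 1e-10)
  # zero rows remain exactly zero
  zero_rows <- setdiff(1:8, fit$support)
  expect_true(all(gs$v_hat[zero_rows, ] == 0))
  expect_identical(which(rowSums(gs$v_hat^2) > 0), fit$support)
  # orthonormal input comes back unchanged up to the sign convention
  again <- gram_schmidt_basis(gs)
  expect_equal(abs(again$v_hat), abs(gs$v_hat), tolerance = 1e-10)
  # single-column scaling
  V <- matrix(c(1, 1, 0), 3, 1)
  expect_equal(gram_schmidt_basis(V), V / sqrt(2), tolerance = 1e-12)
  # degenerate cases
  expect_error(gram_schmidt_basis(matrix(0, 3, 2)), "all-zero")
  expect_warning(gram_schmidt_basis(cbind(c(1, 0, 0), c(2, 0, 0))),
                 "dependent")
})
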