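test_that("design specs carry consistent truth objects", {
  m9 <- sim_model("m9", n = 100, p = 30)
  expect_equal(m9$true_support, 1:5)
  expect_true(all(m9$true_basis[6:30, ] == 0))
  expect_equal(which(rowSums(m9$true_basis^2) > 0), m9$true_support)
  m7 <- sim_model("m7")
  expect_equal(m7$n, 200L)
  expect_equal(m7$p, 150L)
  expect_equal(m7$d, 1L)
  cat1 <- sim_model("cat1", p = 50, rho = 0.5)
  expect_equal(cat1$true_support, 1:20)
  expect_equal(ncol(cat1$true_basis), 2L)
  expect_error(sim_model("m9", p = 4), "at least 5")
  expect_error(sim_model("cat1", p = 10), "at least 20")
  expect_error(sim_model("cat3", p = 5), "at least 10")
  expect_error(sim_model("cat1", rho = 1.5), "rho")
})

test_that("predictor law matches the stated covariance", {
  # Monte-Carlo check of Sigma_ij = 0.5^|i-j| at the first off-diagonal
  spec <- sim_model("m7", n = 100000, p = 5)
  dat <- sim_generate(spec, seed = 901)
  expect_equal(stats::cor(dat$X[, 1], dat$X[, 2]), 0.5, tolerance = 0.01)
  expect_equal(stats::cor(dat$X[, 1], dat$X[, 3]), 0.25, tolerance = 0.015)
  expect_equal(mean(dat$X), 0, tolerance = 0.01)
  expect_equal(stats::sd(dat$X[, 4]), 1, tolerance = 0.01)
})

test_that("continuous responses follow the stated link functions", {
  spec7 <- sim_model("m7", n = 5000, p = 6)
  d7 <- sim_generate(spec7, seed = 902)
  idx <- (d7$X[, 1] + d7$X[, 2] + d7$X[, 3]) / sqrt(3)
  # y - index = 2*eps with eps ~ N(0,1)
  expect_equal(stats::sd(d7$y - idx), 2, tolerance = 0.06)
  expect_equal(mean(d7$y - idx), 0, tolerance = 0.1)
  d8 <- sim_generate(sim_model("m8", n = 5000, p = 6), seed = 903)
  idx8 <- (d8$X[, 1] + d8$X[, 2] + d8$X[, 3]) / sqrt(3)
  expect_equal(stats::sd(d8$y - 1 - exp(idx8)), 1, tolerance = 0.05)
  d9 <- sim_generate(sim_model("m9", n = 5000, p = 6), seed = 904)
  m <- (d9$X[, 1] + d9$X[, 2] + d9$X[, 3]) /
    (0.5 + (d9$X[, 4] + d9$X[, 5] + 1.5)^2)
  expect_equal(stats::sd(d9$y - m), 0.1, tolerance = 0.02)
})

test_that("categorical designs have exact class structure", {
  spec <- sim_model("cat1", p = 25, rho = 0.5)
  dat <- sim_generate(spec, seed = 905)
  expect_equal(as.integer(table(dat$y)), c(30L, 30L, 30L))
  expect_equal(nrow(dat$X), 90L)
  # class means shift where specified
  big <- sim_generate(sim_model("cat1", n = 4000, p = 25, rho = 0.5),
                      seed = 906)
  mu_hat <- rowsum(big$X, big$y) / 4000
  expect_equal(mu_hat[2, 1:10] - mu_hat[1, 1:10], rep(1, 10),
               tolerance = 0.15, ignore_attr = TRUE)
  expect_equal(mu_hat[3, 11:20] - mu_hat[1, 11:20], rep(-2, 10),
               tolerance = 0.15, ignore_attr = TRUE)
  cat2 <- sim_generate(sim_model("cat2", p = 25), seed = 907)
  expect_equal(as.integer(table(cat2$y)), c(30L, 30L, 30L))
})

test_that("logistic design draws fresh sparse directions with U(0.8,1) weights", {
  spec <- sim_model("cat3", n = 50, p = 15, rho = 0.5)
  d1 <- sim_generate(spec, seed = 908)
  d2 <- sim_generate(spec, seed = 909)
  v1 <- drop(d1$truth$basis)
  expect_equal(which(v1 != 0), 1:10)
  expect_true(all(v1[1:10] >= 0.8 & v1[1:10] <= 1))
  expect_false(isTRUE(all.equal(v1, drop(d2$truth$basis))))
  expect_setequal(levels(d1$y), c("0", "1"))
  # null direction: class probability is exactly 1/2
  set.seed(910)
  null <- cisir:::gen_cat_logistic(spec, n = 4000, v = rep(0, 15))
  expect_equal(mean(null$y == "1"), 0.5, tolerance = 0.05)
})

test_that("population discriminant directions solve the generalized eigenproblem", {
  # equal means: no discriminant directions
  td0 <- true_directions(diag(4), matrix(1, 3, 4))
  expect_equal(ncol(td0$basis), 0L)
  # identity covariance, two classes: direction proportional to mu2 - mu1
  mu <- rbind(c(0, 0, 0), c(1, 2, 0))
  td <- true_directions(diag(3), mu)
  expect_equal(ncol(td$basis), 1L)
  v <- drop(td$basis)
  expect_equal(abs(v / sqrt(sum(v^2))), abs(c(1, 2, 0) / sqrt(5)),
               tolerance = 1e-10)
  # cat1 parameters against a dense generalized-eigensolver oracle
  spec <- sim_model("cat1", p = 30, rho = 0.5)
  pri <- rep(1 / 3, 3)
  mub <- drop(pri %*% spec$class_means)
  ctr <- sweep(spec$class_means, 2, mub)
  M <- crossprod(ctr * sqrt(pri))
  W <- solve(spec$sigma) %*% M           # plain (nonsymmetric) GEV route
  ew <- eigen(W)
  keep <- order(Re(ew$values), decreasing = TRUE)[1:2]
  Vo <- Re(ew$vectors[, keep])
  expect_lt(projection_distance(spec$true_basis, Vo), 1e-8)
  expect_equal(spec$true_support, 1:20)
  expect_error(true_directions(matrix(0, 2, 2), matrix(0, 2, 2)),
               "positive definite")
})

test_that("replication harness is deterministic and reports mean/SE", {
  spec <- sim_model("m7", n = 80, p = 12)
  r1 <- run_replications(spec, reps = 3, seed = 99,
                         fit_args = list(use_clime = "never"))
  r2 <- run_replications(spec, reps = 3, seed = 99,
                         fit_args = list(use_clime = "never"))
  expect_identical(r1$per_rep, r2$per_rep)
  r3 <- run_replications(spec, reps = 3, seed = 100,
                         fit_args = list(use_clime = "never"))
  expect_false(identical(r1$per_rep, r3$per_rep))
  expect_setequal(r1$summary$metric, c("tpr", "fpr", "corr"))
  expect_equal(r1$summary$se,
               apply(r1$per_rep[, -1], 2, stats::sd) / sqrt(3),
               ignore_attr = TRUE)
  # single replication: SE is absent (NA), not zero
  r4 <- run_replications(spec, reps = 1, seed = 7,
                         fit_args = list(use_clime = "never"))
  expect_true(all(is.na(r4$summary$se)))
  expect_equal(nrow(r4$per_rep), 1L)
})
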