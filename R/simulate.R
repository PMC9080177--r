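# Simulation designs with known truth.
#
# Six generative designs are available. Continuous-response models share
# the predictor law X ~ N(0, Sigma) with Sigma_ij = 0.5^|i-j| and
# eps ~ N(0, 1):
#   m7: y = (x1 + x2 + x3)/sqrt(3) + 2*eps              (linear, d = 1)
#   m8: y = 1 + exp((x1 + x2 + x3)/sqrt(3)) + eps       (single index, d = 1)
#   m9: y = (x1 + x2 + x3) / (0.5 + (x4 + x5 + 1.5)^2) + 0.1*eps  (d = 2)
# Categorical designs use a block covariance whose upper s x s (s = 20)
# block is rho*J + (1-rho)*I and identity elsewhere:
#   cat1: three classes, n_k = 30, mean shifts on coords 1-10 (+1) and
#         11-20 (-2); truth = eigenvectors of Sigma^-1 M.
#   cat2: same means; class covariances differ (rho = 0.9 block | AR(0.5) |
#         identity); truth uses the pooled covariance by convention.
#   cat3: binary logistic, Y ~ Bernoulli(logit^-1(v'X)), the 10 nonzero
#         coefficients of v drawn fresh each replication from U(0.8, 1).

#' Describe a simulation design
#'
#' @param model_id One of `"m7"`, `"m8"`, `"m9"`, `"cat1"`, `"cat2"`,
#'   `"cat3"`.
#' @param n Sample size: total for continuous models and cat3 (default 200
#'   and 100), per class for cat1/cat2 (default 30).
#' @param p Number of predictors (default 150 continuous, 50 categorical).
#' @param rho Correlation of the signal block (cat1/cat3; default 0.5).
#' @return Object of class `"sim_model"` describing the design; truth
#'   components that do not depend on the draw (`true_basis`,
#'   `true_support`, `d`) are attached for all models except cat3, whose
#'   direction is drawn per replication.
#' @export
sim_model <- function(model_id = c("m7", "m8", "m9", "cat1", "cat2", "cat3"),
                      n = NULL, p = NULL, rho = 0.5) {
  model_id <- match.arg(model_id)
  continuous <- model_id %in% c("m7", "m8", "m9")
  if (is.null(p)) p <- if (continuous) 150L else 50L
  p <- as.integer(p)
  if (is.null(n)) n <- switch(model_id, cat1 = 30L, cat2 = 30L,
                              cat3 = 100L, 200L)
  n <- as.integer(n)
  if (!continuous && model_id != "cat3" && !(rho > 0 && rho < 1)) {
    stop("rho must be in (0, 1)")
  }
  spec <- list(model_id = model_id, n = n, p = p, rho = rho,
               kind = if (continuous) "continuous" else "categorical")
  if (model_id %in% c("m7", "m8")) {
    if (p < 3L) stop("p must be at least 3")
    v <- matrix(0, p, 1)
    v[1:3, 1] <- 1
    spec$true_basis <- v
    spec$true_support <- 1:3
    spec$d <- 1L
  } else if (model_id == "m9") {
    if (p < 5L) stop("p must be at least 5 for the two-index model")
    v <- matrix(0, p, 2)
    v[1:3, 1] <- 1
    v[4:5, 2] <- 1
    spec$true_basis <- v
    spec$true_support <- 1:5
    spec$d <- 2L
  } else if (model_id %in% c("cat1", "cat2")) {
    if (p < 20L) stop("p must be at least 20 (the signal block)")
    mu <- cat_means(p)
    sig <- if (model_id == "cat1") {
      block_cov(p, rho)
    } else {
      (block_cov(p, 0.9) + ar1_cov(p, 0.5) + diag(p)) / 3  # pooled
    }
    td <- true_directions(sig, mu, priors = rep(1 / 3, 3))
    spec$class_means <- mu
    spec$sigma <- sig
    spec$true_basis <- td$basis
    spec$true_support <- td$support
    spec$d <- 2L
    spec$n_classes <- 3L
  } else {  # cat3
    if (p < 10L) stop("p must be at least 10")
    spec$d <- 1L
    spec$n_classes <- 2L
    spec$true_support <- 1:10
  }
  structure(spec, class = "sim_model")
}

# AR(1) covariance: Sigma_ij = rho^|i-j|.
ar1_cov <- function(p, rho = 0.5) {
  rho^abs(outer(seq_len(p), seq_len(p), "-"))
}

# Block covariance: upper s x s block rho*J + (1-rho)*I, identity elsewhere
# (the block shrinks to p when p < s).
block_cov <- function(p, rho, s = 20L) {
  s <- min(s, p)
  S <- diag(p)
  S[1:s, 1:s] <- rho
  diag(S) <- 1
  S
}

# Class mean matrix for cat1/cat2: rows mu_1 = 0, mu_2 (+1 on 1..10),
# mu_3 (-2 on 11..20).
cat_means <- function(p) {
  mu <- matrix(0, 3, p)
  mu[2, 1:10] <- 1
  mu[3, 11:20] <- -2
  mu
}

#' Population discriminant directions
#'
#' Given the true covariance and class means, forms the between-class
#' kernel `M = sum_k pi_k (mu_k - mu_bar)(mu_k - mu_bar)'` and returns the
#' eigenvectors of `Sigma^-1 M` for its nonzero eigenvalues, together with
#' their joint row support.
#'
#' @param sigma Positive-definite p x p covariance.
#' @param class_means K x p matrix of class means.
#' @param priors Class weights (default equal).
#' @return List with `basis` (p x d), `support`, `eigenvalues`.
#' @export
true_directions <- function(sigma, class_means, priors = NULL) {
  mu <- as.matrix(class_means)
  K <- nrow(mu)
  p <- ncol(mu)
  if (is.null(priors)) priors <- rep(1 / K, K)
  priors <- priors / sum(priors)
  es <- eigen(sigma, symmetric = TRUE)
  if (min(es$values) <= 0) stop("sigma must be positive definite")
  mu_bar <- drop(priors %*% mu)
  ctr <- sweep(mu, 2L, mu_bar, "-")
  M <- crossprod(ctr * sqrt(priors))
  Rinv <- es$vectors %*% (t(es$vectors) / sqrt(es$values))  # Sigma^-1/2
  W <- Rinv %*% M %*% Rinv
  ew <- eigen((W + t(W)) / 2, symmetric = TRUE)
  keep <- ew$values > max(ew$values, 0) * 1e-8
  if (!any(keep)) {
    return(list(basis = matrix(0, p, 0), support = integer(0),
                eigenvalues = ew$values))
  }
  basis <- fix_signs(Rinv %*% ew$vectors[, keep, drop = FALSE])
  rn <- sqrt(rowSums(basis^2))
  support <- which(rn > max(rn) * 1e-8)
  list(basis = basis, support = support, eigenvalues = ew$values)
}

#' Draw one dataset from a simulation design
#'
#' @param spec A `"sim_model"` design.
#' @param seed Seed for the draw (optional but recommended).
#' @return List with `X`, `y`, and `truth` (list: `basis`, `support`,
#'   `d`). For cat3 the truth direction is part of the draw.
#' @export
sim_generate <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "sim_model"))
  with_seed(seed, {
    switch(spec$model_id,
      m7 = , m8 = , m9 = gen_continuous(spec),
      cat1 = , cat2 = gen_cat_means(spec),
      cat3 = gen_cat_logistic(spec)
    )
  })
}

gen_continuous <- function(spec, n = spec$n) {
  p <- spec$p
  R <- chol(ar1_cov(p, 0.5))
  X <- matrix(stats::rnorm(n * p), n, p) %*% R
  idx <- (X[, 1] + X[, 2] + X[, 3]) / sqrt(3)
  eps <- stats::rnorm(n)
  y <- switch(spec$model_id,
    m7 = idx + 2 * eps,
    m8 = 1 + exp(idx) + eps,
    m9 = (X[, 1] + X[, 2] + X[, 3]) /
      (0.5 + (X[, 4] + X[, 5] + 1.5)^2) + 0.1 * eps
  )
  list(X = X, y = y,
       truth = list(basis = spec$true_basis, support = spec$true_support,
                    d = spec$d))
}

gen_cat_means <- function(spec, n_k = spec$n) {
  p <- spec$p
  mu <- cat_means(p)
  covs <- if (spec$model_id == "cat1") {
    rep(list(block_cov(p, spec$rho)), 3)
  } else {
    list(block_cov(p, 0.9), ar1_cov(p, 0.5), diag(p))
  }
  if (length(n_k) == 1L) n_k <- rep(n_k, 3)
  X <- do.call(rbind, lapply(1:3, function(k) {
    Z <- matrix(stats::rnorm(n_k[k] * p), n_k[k], p) %*% chol(covs[[k]])
    sweep(Z, 2L, mu[k, ], "+")
  }))
  y <- factor(rep(1:3, times = n_k))
  list(X = X, y = y,
       truth = list(basis = spec$true_basis, support = spec$true_support,
                    d = spec$d))
}

gen_cat_logistic <- function(spec, n = spec$n, v = NULL) {
  p <- spec$p
  if (is.null(v)) {
    v <- numeric(p)
    v[spec$true_support] <- stats::runif(length(spec$true_support), 0.8, 1)
  }
  X <- matrix(stats::rnorm(n * p), n, p) %*% chol(block_cov(p, spec$rho))
  pr <- stats::plogis(drop(X %*% v))
  y <- factor(stats::rbinom(n, 1L, pr), levels = c(0, 1))
  list(X = X, y = y,
       truth = list(basis = matrix(v, p, 1), support = spec$true_support,
                    d = 1L))
}

#' Run replicated simulations of the full pipeline
#'
#' Per replication: draw a dataset, fit [fit_sparse_sir()] with the
#' design's true dimension and data-driven tau, and evaluate. Continuous
#' designs report selection rates and the predictor correlation on the
#' training draw; categorical designs additionally report the projection
#' distance to the truth and the misclassification rate on an independent
#' test set of `n_test` observations (equal class sizes for cat1/cat2; the
#' marginal logistic model, with the replication's own direction, for
#' cat3). Child seeds are derived deterministically from `seed`.
#'
#' @param spec A `"sim_model"` design.
#' @param reps Number of replications.
#' @param seed Master seed.
#' @param n_test Test-set size for categorical designs (default 900).
#' @param fit_args Named list of extra arguments to [fit_sparse_sir()].
#' @return Object of class `"sir_replications"`: list with `per_rep`
#'   (one row per replication), `summary` (mean and standard error; the SE
#'   is `NA` for a single replication), `spec`, `reps`, `seed`.
#' @export
run_replications <- function(spec, reps, seed = 1L, n_test = 900L,
                             fit_args = list()) {
  stopifnot(inherits(spec, "sim_model"), reps >= 1L)
  seeds <- with_seed(seed, matrix(sample.int(2^31 - 2, 3 * reps), ncol = 3))
  categorical <- spec$kind == "categorical"
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    dat <- sim_generate(spec, seed = seeds[r, 1])
    args <- c(list(X = dat$X, y = dat$y, d = dat$truth$d,
                   seed = seeds[r, 3]), fit_args)
    fit <- do.call(fit_sparse_sir, args)
    sel <- selection_metrics(fit$support, dat$truth$support, spec$p)
    if (categorical) {
      test <- with_seed(seeds[r, 2], {
        if (spec$model_id == "cat3") {
          gen_cat_logistic(spec, n = n_test, v = drop(dat$truth$basis))
        } else {
          gen_cat_means(spec, n_k = rep(n_test %/% spec$n_classes,
                                        spec$n_classes))
        }
      })
      pred <- predict(fit, test$X, type = "class")
      rows[[r]] <- data.frame(
        rep = r,
        delta = projection_distance(fit$basis, dat$truth$basis),
        msr = misclassification_rate(pred, test$y),
        tpr = sel$tpr, fpr = sel$fpr
      )
    } else {
      rows[[r]] <- data.frame(
        rep = r, tpr = sel$tpr, fpr = sel$fpr,
        corr = predictor_correlation(dat$truth$basis, fit$basis, dat$X)
      )
    }
  }
  per_rep <- do.call(rbind, rows)
  metrics <- setdiff(names(per_rep), "rep")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_rep[[m]]), 0),
    se = vapply(metrics, function(m) {
      if (reps < 2L) NA_real_ else stats::sd(per_rep[[m]]) / sqrt(reps)
    }, 0),
    row.names = NULL
  )
  structure(list(per_rep = per_rep, summary = summary, spec = spec,
                 reps = reps, seed = seed),
            class = "sir_replications")
}

#' @export
print.sir_replications <- function(x, ...) {
  cat(sprintf("Simulation: %s (n = %d, p = %d), %d replications\n",
              x$spec$model_id, x$spec$n, x$spec$p, x$reps))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
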