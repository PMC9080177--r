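#' Slice a response vector
#'
#' Partitions the response into `H` slices. For a continuous response the
#' slices are contiguous in the order statistics of `y` with sizes as equal
#' as possible (the first `n %% H` slices receive one extra observation; ties
#' in `y` are broken by their original position via a stable sort). For a
#' categorical response the slices are the classes and `H` is ignored.
#'
#' @param y Response vector, numeric or categorical (factor/character/logical).
#' @param H Number of slices for a continuous response (default 5).
#' @param kind `"continuous"`, `"categorical"`, or `NULL` to infer from the
#'   type of `y` (factors, characters and logicals are categorical).
#' @return An object of class `"sir_slices"`: a list with elements `H`,
#'   `assignment` (integer slice index per observation), `counts`, `kind`,
#'   and `levels` (class labels, categorical only).
#' @examples
#' sir_slice(c(5, 1, 4, 2, 6, 3), H = 2)
#' sir_slice(factor(c("a", "a", "b", "b")))
#' @export
sir_slice <- function(y, H = 5L, kind = NULL) {
  if (is.null(kind)) {
    kind <- if (is.factor(y) || is.character(y) || is.logical(y)) {
      "categorical"
    } else {
      "continuous"
    }
  }
  kind <- match.arg(kind, c("continuous", "categorical"))
  n <- length(y)
  if (n < 2L) stop("need at least 2 observations")
  if (anyNA(y)) stop("missing values in the response are not supported")
  if (length(unique(y)) < 2L) stop("response has fewer than 2 distinct values")

  if (kind == "categorical") {
    f <- factor(y)
    assignment <- as.integer(f)
    counts <- as.integer(table(f))
    return(structure(
      list(H = nlevels(f), assignment = assignment, counts = counts,
           kind = kind, levels = levels(f)),
      class = "sir_slices"
    ))
  }

  H <- as.integer(H)
  if (H < 2L) stop("H must be at least 2")
  if (H > n) stop("H = ", H, " exceeds the number of observations (", n, ")")
  base <- n %/% H
  sizes <- rep.int(base, H) + as.integer(seq_len(H) <= n %% H)
  ord <- order(y)  # stable: ties keep original order
  assignment <- integer(n)
  assignment[ord] <- rep.int(seq_len(H), sizes)
  structure(
    list(H = H, assignment = assignment, counts = sizes, kind = kind,
         levels = NULL),
    class = "sir_slices"
  )
}

#' Sample covariance and sliced-inverse-regression kernel
#'
#' Computes the moment estimates that seed the sparse basis program: the
#' sample covariance `Sigma_hat = n^-1 sum_i (x_i - xbar)(x_i - xbar)^T`
#' (divisor `n`) and the between-slice kernel
#' `M_hat = sum_h (n_h/n)(xbar_h - xbar)(xbar_h - xbar)^T`, the covariance of
#' the centered slice means. The column space of `Sigma^-1 M` spans the
#' central subspace under the linear conditional mean assumption, so `M_hat`
#' carries all first-inverse-moment information about the reduction.
#'
#' @param X Numeric matrix, n samples by p predictors.
#' @param slices A `"sir_slices"` object consistent with `nrow(X)`.
#' @return An object of class `"sir_moments"`: list with `sigma_hat`,
#'   `m_hat` (both p x p symmetric), `grand_mean`, `slice_means` (H x p),
#'   `psi` (H x p centered slice means), `n`, `p`, `H`, `counts`.
#' @export
sir_moments <- function(X, slices) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("X must be numeric")
  if (anyNA(X)) stop("missing values in X are not supported")
  n <- nrow(X)
  p <- ncol(X)
  if (!inherits(slices, "sir_slices")) stop("slices must come from sir_slice()")
  if (length(slices$assignment) != n) stop("slices do not match nrow(X)")

  xbar <- colMeans(X)
  Xc <- sweep(X, 2L, xbar, "-")
  sigma_hat <- crossprod(Xc) / n
  sigma_hat <- (sigma_hat + t(sigma_hat)) / 2

  counts <- slices$counts
  slice_means <- rowsum(X, group = slices$assignment, reorder = TRUE) / counts
  psi <- sweep(slice_means, 2L, xbar, "-")
  w <- counts / n
  m_hat <- crossprod(psi * sqrt(w))
  m_hat <- (m_hat + t(m_hat)) / 2

  structure(
    list(sigma_hat = sigma_hat, m_hat = m_hat, grand_mean = xbar,
         slice_means = slice_means, psi = psi,
         n = n, p = p, H = slices$H, counts = counts),
    class = "sir_moments"
  )
}
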