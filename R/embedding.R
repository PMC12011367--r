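#' Standardize expression columns with the population standard deviation
#'
#' Centers and scales each TF column of `X` and the target vector `y` to
#' mean 0 and standard deviation 1, using the population (divisor M)
#' standard deviation so that `diag(t(X) %*% X / M) = 1` exactly. The
#' training means and scales are stored so the identical transform can be
#' applied to held-out data with [apply_standardization()]. Pairwise
#' Pearson correlations are unchanged by this transform.
#'
#' @param X numeric matrix, M samples (rows) x N TFs (columns), with
#'   column names.
#' @param y numeric response vector of length M (target gene expression).
#' @return Object of class `std_expression`: list with standardized `X`,
#'   `y`, and the training `center`, `scale`, `y_center`, `y_scale`.
#' @export
standardize_expression <- function(X, y) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 samples to standardize")
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  M <- nrow(X)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  scale_ <- sqrt(colMeans(Xc^2))
  if (any(scale_ == 0))
    stop("zero-variance expression column(s): ",
         paste(colnames(X)[scale_ == 0], collapse = ", "))
  y_center <- mean(y)
  y_scale <- sqrt(mean((y - y_center)^2))
  if (y_scale == 0) stop("target expression y is constant")
  structure(list(X = sweep(Xc, 2, scale_, "/"),
                 y = (y - y_center) / y_scale,
                 center = center, scale = scale_,
                 y_center = y_center, y_scale = y_scale),
            class = "std_expression")
}

#' Apply a stored training standardization to new data
#'
#' @param std a `std_expression` from [standardize_expression()].
#' @param X new expression matrix with the same columns as the training data.
#' @param y optional new response vector.
#' @return list with standardized `X` and (if supplied) `y`.
#' @export
apply_standardization <- function(std, X, y = NULL) {
  stopifnot(inherits(std, "std_expression"))
  X <- as.matrix(X)[, names(std$center), drop = FALSE]
  Xs <- sweep(sweep(X, 2, std$center), 2, std$scale, "/")
  out <- list(X = Xs)
  if (!is.null(y)) out$y <- (y - std$y_center) / std$y_scale
  out
}

#' Build the network penalty matrix A from a completed PPIN
#'
#' Forms the degree-normalized, Laplacian-variant penalty matrix
#' `A = D (W . V) D` with `D = diag(1/sqrt(d_i))` and `V = N*I - 11'`,
#' i.e. `A_ij = -w_ij / sqrt(d_i d_j)` off the diagonal and `A_ii = 1`.
#' For a fully connected weighted graph A is symmetric positive
#' semi-definite with null vector `sqrt(d)`, and the quadratic form
#' `c' A c` equals the pairwise penalty
#' `sum_{i<j} w_ij (c_i/sqrt(d_i) - c_j/sqrt(d_j))^2`.
#'
#' @param pp a `ppin_complete` from [subset_and_complete()].
#' @return symmetric N x N penalty matrix with TF dimnames.
#' @export
build_penalty_matrix <- function(pp) {
  stopifnot(inherits(pp, "ppin_complete"))
  if (length(pp$tf_order) < 2)
    stop("penalty matrix requires at least 2 candidate TFs")
  d <- pp$d
  if (any(d <= 0)) stop("nonpositive degree for TF(s): ",
                        paste(names(d)[d <= 0], collapse = ", "))
  A <- -pp$W / sqrt(outer(d, d))
  diag(A) <- 1
  A
}

#' Combine the expression Gram matrix with the network penalty
#'
#' Computes `E = t(X) %*% X / M + beta * A`. With exactly standardized
#' columns the first term is the TF-TF Pearson correlation matrix, so
#' `E_ij = r(x_i, x_j) - beta * w_ij / sqrt(d_i d_j)` off the diagonal and
#' `E_ii = 1 + beta`. E is symmetric positive semi-definite.
#'
#' @param X standardized expression matrix (M x N).
#' @param A penalty matrix from [build_penalty_matrix()].
#' @param beta network prior strength, must be positive. Requests of
#'   `beta <= 0` are replaced by a small floor (1e-6) with a message; the
#'   floor recovers plain (network-free) behavior while keeping E valid.
#' @return symmetric N x N matrix E.
#' @export
build_combined_matrix <- function(X, A, beta = 1) {
  X <- as.matrix(X)
  if (ncol(X) != ncol(A))
    stop("dimension mismatch: X has ", ncol(X), " columns, A is ",
         ncol(A), " x ", ncol(A))
  if (beta <= 0) {
    message("beta <= 0 requested; using floor beta = 1e-6")
    beta <- 1e-6
  }
  crossprod(X) / nrow(X) + beta * A
}

#' Network regression embeddings via truncated SVD of E
#'
#' Eigendecomposes the symmetric PSD matrix `E = U S U'` (for such matrices
#' this coincides with the SVD), zeroes singular values below
#' `tol * s_max` for numerical stability, and forms the embedded design and
#' response
#' \deqn{\tilde X = \sqrt{N}\, S_{trunc}^{1/2} U', \qquad
#'       \tilde y = (\sqrt{N}/M)\, S_{trunc}^{-1/2} U' X' y,}
#' where the pseudo-inverse square root zeroes truncated directions.
#' Column i of `X_tilde` is TF i's embedding. Without truncation the
#' identities `t(X_tilde) %*% X_tilde / N = E` and
#' `t(y_tilde) %*% X_tilde / N = t(y) %*% X / M` hold to machine precision.
#'
#' @param E combined matrix from [build_combined_matrix()].
#' @param X standardized expression matrix used to build E.
#' @param y standardized response vector.
#' @param tol relative truncation threshold for singular values
#'   (default 1e-6).
#' @return Object of class `netreg_embedding`: list with `X_tilde` (N x N),
#'   `y_tilde` (length N), `E`, `U`, `s` (all singular values, descending),
#'   `keep` (logical retained mask), `rank_retained`, `tf_order`, `M`.
#' @export
svd_embed <- function(E, X, y, tol = 1e-6) {
  if (!isTRUE(all.equal(E, t(E), tolerance = 1e-8)))
    stop("E must be symmetric")
  if (tol <= 0 || tol >= 1) stop("tol must be in (0, 1)")
  X <- as.matrix(X)
  N <- ncol(E)
  M <- nrow(X)
  eg <- eigen((E + t(E)) / 2, symmetric = TRUE)
  s <- pmax(eg$values, 0)        # clamp round-off negatives
  U <- eg$vectors
  # deterministic sign: largest-magnitude entry of each column positive
  for (j in seq_len(N)) {
    i <- which.max(abs(U[, j]))
    if (U[i, j] < 0) U[, j] <- -U[, j]
  }
  keep <- s >= tol * max(s)
  if (!any(keep)) stop("all singular values truncated; E is degenerate")
  s_trunc <- ifelse(keep, s, 0)
  X_tilde <- sqrt(N) * (sqrt(s_trunc) * t(U))        # diag(sqrt(s)) %*% t(U)
  inv_half <- ifelse(keep, 1 / sqrt(s), 0)
  y_tilde <- as.numeric((sqrt(N) / M) * (inv_half * t(U)) %*% crossprod(X, y))
  colnames(X_tilde) <- colnames(E)
  structure(list(X_tilde = X_tilde, y_tilde = y_tilde, E = E, U = U, s = s,
                 keep = keep, rank_retained = sum(keep),
                 tf_order = colnames(E), M = M),
            class = "netreg_embedding")
}

#' @export
print.netreg_embedding <- function(x, ...) {
  cat("Network regression embedding:", length(x$tf_order), "TFs,",
      x$rank_retained, "of", length(x$s), "singular values retained\n")
  invisible(x)
}
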