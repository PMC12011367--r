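test_that("standardization centers and scales with the population divisor", {
  std <- standardize_expression(cbind(a = c(1, 2, 3)), c(2, 4, 9))
  expect_equal(as.numeric(std$X), c(-1.224744871, 0, 1.224744871),
               tolerance = 1e-8)
  expect_equal(mean(std$y), 0, tolerance = 1e-12)
  expect_equal(mean(std$y^2), 1, tolerance = 1e-12)

  # idempotence: re-standardizing changes nothing
  std2 <- standardize_expression(std$X, std$y)
  expect_equal(std2$X, std$X, tolerance = 1e-12)

  # Pearson correlations preserved
  set.seed(3)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("g", 1:4)))
  y <- rnorm(50)
  std3 <- standardize_expression(X, y)
  expect_equal(cor(X), cor(std3$X), tolerance = 1e-10,
               ignore_attr = TRUE)

  expect_error(standardize_expression(cbind(g1 = rep(2, 5)), rnorm(5)), "g1")
  expect_error(standardize_expression(cbind(g1 = rnorm(5)), rep(1, 5)),
               "constant")
})

test_that("held-out data reuse the training transform", {
  set.seed(4)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, letters[1:3]))
  std <- standardize_expression(X, rnorm(20))
  new <- apply_standardization(std, X[1:5, ], y = rnorm(5))
  expect_equal(new$X, std$X[1:5, ], tolerance = 1e-12)
})

test_that("penalty matrix has unit diagonal, negative off-diagonals, and the Laplacian null vector", {
  # two nodes: degrees equal the single weight, off-diagonal exactly -1
  net2 <- ppin_network(data.frame(a = "A", b = "B", w = 0.5))
  A2 <- build_penalty_matrix(subset_and_complete(net2, c("A", "B")))
  expect_equal(unname(A2), rbind(c(1, -1), c(-1, 1)))

  pp <- five_tf_complete()
  A <- build_penalty_matrix(pp)
  expect_equal(A["TF1", "TF2"], -0.8 / 0.83, tolerance = 1e-12)
  expect_equal(unname(diag(A)), rep(1, 5))

  for (seed in 1:5) {
    set.seed(seed)
    pp <- random_complete_net(sample(3:15, 1))
    A <- build_penalty_matrix(pp)
    off <- A[row(A) != col(A)]
    expect_true(all(off < 0 & off >= -1))
    expect_equal(unname(diag(A)), rep(1, nrow(A)))
    # A %*% sqrt(d) = 0: null vector of the underlying normalized Laplacian
    expect_lt(max(abs(A %*% sqrt(pp$d))), 1e-10)
    expect_gt(min(eigen(A, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
  }
})

test_that("matrix form of the penalty equals the brute-force pairwise sum", {
  for (seed in 1:5) {
    set.seed(seed)
    pp <- random_complete_net(sample(3:10, 1))
    A <- build_penalty_matrix(pp)
    cvec <- rnorm(nrow(A))
    expect_equal(drop(t(cvec) %*% A %*% cvec), penalty_brute(pp, cvec),
                 tolerance = 1e-10)
  }
})

test_that("combined matrix has 1 + beta diagonal and is PSD", {
  std <- random_instance(M = 80, N = 5, seed = 7)
  pp <- random_complete_net(5)
  A <- build_penalty_matrix(pp)
  for (beta in c(0.01, 1, 10)) {
    E <- build_combined_matrix(std$X, A, beta)
    expect_equal(unname(diag(E)), rep(1 + beta, 5), tolerance = 1e-12)
    expect_gt(min(eigen(E, symmetric = TRUE, only.values = TRUE)$values),
              -1e-8)
  }
  # beta -> 0 limit recovers the correlation matrix
  E0 <- build_combined_matrix(std$X, A, 1e-12)
  expect_equal(unname(E0), unname(cor(std$X)), tolerance = 1e-9)
  expect_message(build_combined_matrix(std$X, A, 0), "floor")
  expect_error(build_combined_matrix(std$X[, 1:3], A), "dimension mismatch")
})

test_that("embedding reproduces E and the cross-moment identities", {
  for (seed in 1:4) {
    std <- random_instance(M = 60 + 10 * seed, N = 4 + seed, seed = seed)
    pp <- random_complete_net(4 + seed)
    A <- build_penalty_matrix(pp)
    E <- build_combined_matrix(std$X, A, beta = 0.5)
    emb <- svd_embed(E, std$X, std$y)
    N <- ncol(E)
    expect_equal(crossprod(emb$X_tilde) / N, E, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(drop(crossprod(emb$y_tilde, emb$X_tilde)) / N,
                 drop(crossprod(std$y, std$X)) / nrow(std$X),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # cosine of embedding columns has the closed form E_ij / sqrt(E_ii E_jj)
    norms <- sqrt(colSums(emb$X_tilde^2))
    cosm <- crossprod(emb$X_tilde) / outer(norms, norms)
    expect_equal(cosm, E / sqrt(outer(diag(E), diag(E))), tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("identity E yields an orthogonal embedding scaled by sqrt(N)", {
  set.seed(11)
  X <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("t", 1:4)))
  E <- diag(4)
  dimnames(E) <- list(paste0("t", 1:4), paste0("t", 1:4))
  emb <- svd_embed(E, X, rnorm(50))
  expect_equal(crossprod(emb$X_tilde), 4 * diag(4), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(emb$rank_retained, 4L)
})

test_that("at vanishing network weight the embedding aligns with principal components", {
  set.seed(12)
  M <- 300
  f <- rnorm(M)
  X <- sapply(c(1.5, 1.0, 0.6, 0.2), function(s) s * f + rnorm(M))
  colnames(X) <- paste0("TF", 1:4)
  std <- standardize_expression(X, rnorm(M))
  A <- build_penalty_matrix(random_complete_net(4))
  E <- build_combined_matrix(std$X, A, beta = 1e-9)
  emb <- svd_embed(E, std$X, std$y)
  pcs <- eigen(crossprod(std$X) / M, symmetric = TRUE)$vectors
  for (k in seq_len(4)) {
    expect_gt(abs(sum(emb$U[, k] * pcs[, k])), 0.999)
  }
})

test_that("degenerate and asymmetric inputs are rejected", {
  std <- random_instance(M = 30, N = 3, seed = 2)
  E <- build_combined_matrix(std$X, build_penalty_matrix(random_complete_net(3)), 1)
  Ebad <- E; Ebad[1, 2] <- Ebad[1, 2] + 1
  expect_error(svd_embed(Ebad, std$X, std$y), "symmetric")
  expect_error(svd_embed(E, std$X, std$y, tol = 2), "tol")
})
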