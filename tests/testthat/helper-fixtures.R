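# Shared fixture builders; everything is generated in code.

# the 5-TF demonstration network: strong TF1-TF2 and TF4-TF5 edges,
# every other pair filled at eta on completion
five_tf_net <- function() {
  ppin_network(data.frame(tf_a = c("TF1", "TF4"), tf_b = c("TF2", "TF5"),
                          weight = c(0.8, 0.95)))
}

five_tf_complete <- function(eta = 0.01) {
  subset_and_complete(five_tf_net(), paste0("TF", 1:5), eta = eta)
}

# random fully connected completed network (weights in (lo, 1])
random_complete_net <- function(n, lo = 0.01) {
  tfs <- paste0("TF", seq_len(n))
  pairs <- t(combn(tfs, 2))
  w <- runif(nrow(pairs), lo, 1)
  net <- ppin_network(data.frame(pairs, weight = w), min_weight = 0)
  subset_and_complete(net, tfs, eta = lo / 2)
}

# small random standardized regression instance
random_instance <- function(M = 100, N = 6, seed = 1) {
  set.seed(seed)
  y <- rnorm(M)
  X <- sapply(seq_len(N), function(i) 0.5 * y + rnorm(M))
  colnames(X) <- paste0("TF", seq_len(N))
  standardize_expression(X, y)
}

# brute-force pairwise network penalty sum_{i<j} w_ij (c_i/sqrt(d_i) - c_j/sqrt(d_j))^2
penalty_brute <- function(pp, cvec) {
  W <- pp$W
  d <- pp$d
  n <- length(d)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + W[i, j] * (cvec[i] / sqrt(d[i]) - cvec[j] / sqrt(d[j]))^2
  unname(tot)
}

# original-space objective of the network-regularized problem
objective_original <- function(X, y, cvec, alpha, beta, A) {
  M <- nrow(X)
  sum((y - X %*% cvec)^2) / (2 * M) + alpha * sum(abs(cvec)) +
    (beta / 2) * drop(t(cvec) %*% A %*% cvec)
}

# embedded-space objective plus the constant linking the two forms
objective_embedded <- function(emb, cvec, alpha) {
  N <- ncol(emb$X_tilde)
  sum((emb$y_tilde - emb$X_tilde %*% cvec)^2) / (2 * N) +
    alpha * sum(abs(cvec))
}
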