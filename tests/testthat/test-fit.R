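make_fit_inputs <- function(seed = 1, M = 200, N = 6, beta = 0.5) {
  set.seed(seed)
  y <- rnorm(M)
  X <- sapply(seq_len(N), function(i) (0.8 - 0.1 * i) * y + rnorm(M))
  colnames(X) <- paste0("TF", seq_len(N))
  std <- standardize_expression(X, y)
  pp <- random_complete_net(N)
  A <- build_penalty_matrix(pp)
  E <- build_combined_matrix(std$X, A, beta)
  list(std = std, emb = svd_embed(E, std$X, std$y), A = A)
}

test_that("penalties at or above the shutdown threshold zero every coefficient", {
  inp <- make_fit_inputs()
  N <- length(inp$emb$tf_order)
  alpha_max <- max(abs(crossprod(inp$emb$X_tilde, inp$emb$y_tilde))) / N
  fit <- fit_lasso_embedded(inp$emb, netreg_control(beta = 0.5,
                                                    alpha = alpha_max * 1.01))
  expect_equal(unname(fit$c_star), rep(0, N))
  expect_equal(fit$n_selected, 0L)
  fit2 <- fit_lasso_embedded(inp$emb, netreg_control(beta = 0.5,
                                                     alpha = alpha_max * 0.5))
  expect_gt(fit2$n_selected, 0L)
})

test_that("solver minimizes the embedded objective (random-restart check)", {
  inp <- make_fit_inputs(seed = 3)
  ctrl <- netreg_control(beta = 0.5, alpha = 0.05)
  fit <- fit_lasso_embedded(inp$emb, ctrl)
  obj_hat <- objective_embedded(inp$emb, fit$c_star, 0.05)
  set.seed(9)
  for (i in 1:25) {
    trial <- fit$c_star + rnorm(length(fit$c_star), sd = 0.02)
    expect_gte(objective_embedded(inp$emb, trial, 0.05), obj_hat - 1e-9)
  }
})

test_that("with the network weight at the floor the fit matches a plain Lasso", {
  set.seed(5)
  M <- 150; N <- 5
  y <- rnorm(M)
  X <- sapply(seq_len(N), function(i) 0.4 * y + rnorm(M))
  colnames(X) <- paste0("TF", seq_len(N))
  net <- five_tf_net()
  alpha <- 0.07
  fit <- fit_one_tg(X, y, net, colnames(X),
                    netreg_control(beta = 1e-6, alpha = alpha))
  std <- standardize_expression(X, y)
  oracle <- glmnet::glmnet(std$X, std$y, standardize = FALSE,
                           intercept = FALSE, thresh = 1e-12,
                           lambda = exp(seq(log(0.5), log(alpha),
                                            length.out = 60)))
  c_plain <- as.numeric(coef(oracle, s = alpha))[-1]
  expect_equal(unname(fit$c_star), c_plain, tolerance = 1e-4)
})

test_that("a perfect linear signal is recovered close to the plain-Lasso oracle", {
  set.seed(6)
  M <- 300
  X <- matrix(rnorm(M * 4), M, 4, dimnames = list(NULL, paste0("TF", 1:4)))
  y <- X[, 1]
  fit <- fit_one_tg(X, y, five_tf_net(), colnames(X),
                    netreg_control(beta = 1e-6, alpha = 1e-3))
  std <- standardize_expression(X, y)
  oracle <- glmnet::glmnet(std$X, std$y, standardize = FALSE,
                           intercept = FALSE, thresh = 1e-12,
                           lambda = exp(seq(log(0.5), log(1e-3),
                                            length.out = 60)))
  c_plain <- as.numeric(coef(oracle, s = 1e-3))[-1]
  expect_lt(abs(fit$c_star[["TF1"]] - c_plain[1]) / abs(c_plain[1]), 0.1)
  expect_gt(fit$c_star[["TF1"]], 0.9)
  expect_lt(fit$mse_train, 0.01)
})

test_that("increasing alpha never increases the number of selected TFs", {
  inp <- make_fit_inputs(seed = 8)
  alphas <- c(0.001, 0.005, 0.02, 0.05, 0.1, 0.2, 0.5)
  nsel <- sapply(alphas, function(a)
    fit_lasso_embedded(inp$emb, netreg_control(beta = 0.5, alpha = a))$n_selected)
  expect_true(all(diff(nsel) <= 0))
})

test_that("solutions are invariant to permutation of TF columns", {
  set.seed(10)
  M <- 120
  y <- rnorm(M)
  X <- sapply(1:5, function(i) (0.9 - 0.15 * i) * y + rnorm(M))
  colnames(X) <- paste0("TF", 1:5)
  ctrl <- netreg_control(beta = 1, alpha = 0.05)
  f1 <- fit_one_tg(X, y, five_tf_net(), colnames(X), ctrl)
  perm <- c(4, 2, 5, 1, 3)
  f2 <- fit_one_tg(X[, perm], y, five_tf_net(), colnames(X)[perm], ctrl)
  expect_equal(f2$c_star[names(f1$c_star)], f1$c_star, tolerance = 1e-6)
})

test_that("coefficient ranks order the selected TFs by magnitude with name tie-break", {
  inp <- make_fit_inputs(seed = 2)
  fit <- fit_lasso_embedded(inp$emb, netreg_control(beta = 0.5, alpha = 0.02))
  sel <- which(fit$c_star != 0)
  expect_setequal(fit$rank[sel], seq_along(sel))
  ord <- sel[order(fit$rank[sel])]
  expect_true(all(diff(abs(fit$c_star[ord])) <= 1e-12))
})

test_that("multi-gene driver restricts candidates, skips failures, and keeps order", {
  set.seed(13)
  M <- 150
  X <- matrix(rnorm(M * 7), M, 7,
              dimnames = list(NULL, c(paste0("TF", 1:5), "TGa", "TGb")))
  X[, "TGa"] <- X[, "TF1"] - 0.5 * X[, "TF4"] + 0.3 * rnorm(M)
  X[, "TGb"] <- -X[, "TF2"] + 0.3 * rnorm(M)
  ctrl <- netreg_control(beta = 0.5, alpha = 0.05)
  fits <- fit_all_tgs(X, c("TGa", "TGb"), five_tf_net(),
                      tf_list = paste0("TF", 1:5), control = ctrl)
  expect_named(fits, c("TGa", "TGb"))

  prior <- data.frame(TF = c("TF1", "TF4", "TF2"),
                      TG = c("TGa", "TGa", "TGb"))
  fits2 <- fit_all_tgs(X, c("TGa", "TGb"), five_tf_net(),
                       prior_grn = prior, control = ctrl)
  expect_equal(length(fits2$TGa$tf_order), 2L)

  # a TG that is also a TF loses its self-column
  Xtf <- X; colnames(Xtf)[6] <- "TF6"
  suppressMessages(
    fits3 <- fit_all_tgs(Xtf, "TF6", five_tf_net(),
                         tf_list = paste0("TF", 1:6), control = ctrl))
  expect_equal(length(fits3$TF6$tf_order), 5L)

  # single-candidate prior cannot be fit; it is skipped, not fatal
  prior_bad <- rbind(prior, data.frame(TF = "TF9", TG = "TGc"))
  Xc <- cbind(X, TGc = rnorm(M))
  suppressMessages(
    fits4 <- fit_all_tgs(Xc, c("TGa", "TGc"), five_tf_net(),
                         prior_grn = prior_bad, control = ctrl))
  status <- attr(fits4, "status")
  expect_equal(status$status, c("ok", "skipped"))
  expect_error(fit_all_tgs(X, character(), five_tf_net()), "empty")
})

test_that("cross-validated alpha is reproducible under a fixed seed", {
  set.seed(14)
  M <- 400
  y <- rnorm(M)
  X <- sapply(1:8, function(i) ifelse(i <= 3, 0.6, 0) * y + rnorm(M))
  colnames(X) <- paste0("TF", 1:8)
  net <- ppin_network(data.frame(a = "TF1", b = "TF2", w = 0.9))
  ctrl <- netreg_control(beta = 0.5, alpha = "cv", seed = 7)
  f1 <- fit_one_tg(X, y, net, colnames(X), ctrl)
  f2 <- fit_one_tg(X, y, net, colnames(X), ctrl)
  expect_identical(f1$c_star, f2$c_star)
  expect_identical(f1$alpha_used, f2$alpha_used)
  expect_gt(f1$alpha_used, 0)
})
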