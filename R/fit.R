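#' Hyperparameter and solver settings
#'
#' @param beta network prior strength (> 0). Larger values weight the PPIN
#'   prior more heavily relative to the expression data.
#' @param alpha Lasso sparsity penalty: a fixed non-negative number, or
#'   `"cv"` to select it by cross-validation on the embedded problem.
#' @param cv_folds number of CV folds (>= 2) when `alpha = "cv"`.
#' @param cv_rule CV selection rule: `"1se"` (default) picks the largest
#'   penalty within one standard error of the minimum CV error — the usual
#'   parsimony convention, appropriate here because the embedded problem
#'   has only N observations and the minimum-error rule overfits it —
#'   `"min"` picks the error-minimizing penalty.
#' @param eta artificial PPIN edge weight for missing TF-TF pairs.
#' @param tol_svd relative singular-value truncation threshold.
#' @param seed integer seed controlling CV fold assignment.
#' @param intercept fit a y-intercept in the embedded Lasso (default off:
#'   standardized data have mean zero by construction).
#' @param n_lambda,lambda_min_ratio Lasso path resolution: number of
#'   log-spaced penalty values and the ratio of the smallest to the largest.
#' @return list of class `netreg_control`.
#' @export
netreg_control <- function(beta = 1, alpha = 0.1, cv_folds = 5,
                           cv_rule = c("1se", "min"), eta = 0.01,
                           tol_svd = 1e-6, seed = 123, intercept = FALSE,
                           n_lambda = 100, lambda_min_ratio = 1e-4) {
  if (is.character(alpha)) {
    alpha <- match.arg(alpha, "cv")
  } else if (!is.numeric(alpha) || alpha < 0) {
    stop("alpha must be a non-negative number or \"cv\"")
  }
  if (beta <= 0) {
    message("beta <= 0 requested; using floor beta = 1e-6")
    beta <- 1e-6
  }
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  structure(list(beta = beta, alpha = alpha, cv_folds = as.integer(cv_folds),
                 cv_rule = match.arg(cv_rule), eta = eta, tol_svd = tol_svd,
                 seed = as.integer(seed), intercept = intercept,
                 n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio),
            class = "netreg_control")
}

# Decreasing log-spaced lambda path ending at (and containing) `target`;
# path points numerically indistinct from the target are dropped so that
# coefficient extraction at the target never interpolates between ties.
lasso_path <- function(lambda_max, target, n_lambda, min_ratio) {
  lo <- max(min(target, lambda_max * min_ratio), lambda_max * 1e-9)
  path <- exp(seq(log(lambda_max), log(lo), length.out = n_lambda))
  path <- path[abs(log(path) - log(target)) > 1e-8]
  sort(c(path, target), decreasing = TRUE)
}

rank_coefficients <- function(c_star, tf_order) {
  nz <- which(c_star != 0)
  ranks <- rep(NA_integer_, length(c_star))
  if (length(nz)) {
    ord <- nz[order(-abs(c_star[nz]), tf_order[nz])]
    ranks[ord] <- seq_along(ord)
  }
  ranks
}

#' Solve the embedded Lasso problem
#'
#' Fits the transformed problem
#' `argmin_c 1/(2N) || y_tilde - X_tilde c ||^2 + alpha ||c||_1`
#' by coordinate descent (glmnet) on the N embedded observations, either at
#' a fixed `alpha` or with `alpha` chosen by k-fold cross-validation over
#' the embedded rows (folds are contiguous blocks of a seeded shuffle).
#' Penalties at or above the shutdown threshold
#' `alpha_max = max|t(X_tilde) y_tilde| / N` give the all-zero solution.
#'
#' @param emb a `netreg_embedding` from [svd_embed()].
#' @param control a [netreg_control()].
#' @return Object of class `netreg_fit`: list with `tg` (NA here),
#'   `tf_order`, `c_star`, `selected` (TFs with nonzero coefficient),
#'   `n_selected`, `alpha_used`, `rank` (1 = largest magnitude; ties broken
#'   by TF name), and NA `mse_train` / `mse_test` placeholders.
#' @export
fit_lasso_embedded <- function(emb, control = netreg_control()) {
  stopifnot(inherits(emb, "netreg_embedding"))
  Xt <- emb$X_tilde
  yt <- emb$y_tilde
  N <- ncol(Xt)
  lambda_max <- max(abs(crossprod(Xt, yt))) / N
  alpha_used <- control$alpha
  if (identical(control$alpha, "cv")) {
    nfolds <- min(control$cv_folds, N)
    set.seed(control$seed)
    foldid <- rep_len(seq_len(nfolds), N)[sample.int(N)]
    cvfit <- glmnet::cv.glmnet(
      Xt, yt, foldid = foldid, standardize = FALSE,
      intercept = control$intercept, grouped = FALSE,
      lambda = lasso_path(lambda_max, lambda_max * control$lambda_min_ratio,
                          control$n_lambda, control$lambda_min_ratio),
      thresh = 1e-12)
    s <- if (control$cv_rule == "min") "lambda.min" else "lambda.1se"
    alpha_used <- cvfit[[s]]
    c_star <- as.numeric(coef(cvfit, s = s))[-1]
  } else if (control$alpha >= lambda_max || lambda_max == 0) {
    c_star <- numeric(N)
  } else {
    fit <- glmnet::glmnet(
      Xt, yt, standardize = FALSE, intercept = control$intercept,
      lambda = lasso_path(lambda_max, control$alpha, control$n_lambda,
                          control$lambda_min_ratio),
      thresh = 1e-12)
    c_star <- as.numeric(coef(fit, s = control$alpha))[-1]
  }
  names(c_star) <- emb$tf_order
  structure(list(tg = NA_character_, tf_order = emb$tf_order,
                 c_star = c_star,
                 selected = emb$tf_order[c_star != 0],
                 n_selected = sum(c_star != 0),
                 alpha_used = as.numeric(alpha_used),
                 rank = rank_coefficients(c_star, emb$tf_order),
                 mse_train = NA_real_, mse_test = NA_real_,
                 embedding = emb),
            class = "netreg_fit")
}

#' Fit the full network-regularized regression pipeline for one target gene
#'
#' Composes PPIN completion, standardization, penalty construction, SVD
#' embedding, and the embedded Lasso solve for a single target gene, and
#' records training (and optionally held-out) mean squared error
#' `MSE = mean((y - X c*)^2)`. Held-out data are standardized with the
#' training means and scales.
#'
#' @param X_raw raw expression matrix (samples x genes) containing the
#'   candidate TF columns.
#' @param y_raw raw target gene expression (length `nrow(X_raw)`).
#' @param net a [ppin_network].
#' @param cand a [candidate_set] or character vector of candidate TF names;
#'   the target gene, if present, is removed from its own candidates.
#' @param control a [netreg_control()].
#' @param X_test,y_test optional held-out raw data for test MSE.
#' @param tg target gene identifier (metadata).
#' @return A `netreg_fit` (see [fit_lasso_embedded()]) with `tg`,
#'   `mse_train`, `mse_test` filled in and the embedding attached.
#' @export
fit_one_tg <- function(X_raw, y_raw, net, cand, control = netreg_control(),
                       X_test = NULL, y_test = NULL, tg = NA_character_) {
  if (is.character(cand)) cand <- candidate_set(ifelse(is.na(tg), "<none>", tg), cand)
  if (!is.na(tg) && tg %in% cand$tfs) {
    message("target gene ", tg, " removed from its own candidate TF list")
    cand <- candidate_set(tg, cand$tfs)
  }
  missing_tfs <- setdiff(cand$tfs, colnames(X_raw))
  if (length(missing_tfs))
    stop("candidate TF(s) absent from expression columns: ",
         paste(missing_tfs, collapse = ", "))
  pp <- subset_and_complete(net, cand, eta = control$eta)
  if (pp$degenerate)
    stop("only one candidate TF for ", tg,
         "; network-regularized fit needs N >= 2")
  X <- as.matrix(X_raw[, pp$tf_order, drop = FALSE])
  std <- standardize_expression(X, y_raw)
  A <- build_penalty_matrix(pp)
  E <- build_combined_matrix(std$X, A, beta = control$beta)
  emb <- svd_embed(E, std$X, std$y, tol = control$tol_svd)
  fit <- fit_lasso_embedded(emb, control)
  fit$tg <- tg
  fit$ppin <- pp
  fit$std <- std
  fit$mse_train <- mean((std$y - as.numeric(std$X %*% fit$c_star))^2)
  if (!is.null(X_test) && !is.null(y_test)) {
    te <- apply_standardization(std, as.matrix(X_test)[, pp$tf_order,
                                                       drop = FALSE], y_test)
    fit$mse_test <- mean((te$y - as.numeric(te$X %*% fit$c_star))^2)
  }
  fit
}

#' Fit every target gene of a cell type
#'
#' Runs [fit_one_tg()] for each requested target gene. When a prior GRN is
#' supplied its TF column restricts the candidates per TG; otherwise every
#' TF in `tf_list` (minus the TG itself) is a candidate. Failures on
#' individual TGs are caught, reported, and skipped.
#'
#' @param X_raw raw expression matrix (samples x genes) holding both TF and
#'   TG columns.
#' @param tg_list character vector of target genes (columns of `X_raw`).
#' @param net a [ppin_network].
#' @param tf_list global candidate TF names; defaults to all columns of
#'   `X_raw` not listed as TGs. TFs that are also TGs must be named
#'   explicitly.
#' @param prior_grn optional data.frame with columns `TF`, `TG` restricting
#'   candidates per target gene.
#' @param control a [netreg_control()].
#' @param X_test,y_test_matrix optional held-out expression (same columns)
#'   for per-TG test MSE; `y_test_matrix` defaults to `X_test`.
#' @return named list of `netreg_fit` objects (successful TGs only), with
#'   attribute `status`: data.frame of per-TG ok/skip and message.
#' @export
fit_all_tgs <- function(X_raw, tg_list, net, tf_list = NULL, prior_grn = NULL,
                        control = netreg_control(), X_test = NULL,
                        y_test_matrix = NULL) {
  if (!length(tg_list)) stop("empty target gene list")
  absent <- setdiff(tg_list, colnames(X_raw))
  if (length(absent))
    stop("target gene(s) absent from expression columns: ",
         paste(absent, collapse = ", "))
  if (is.null(tf_list)) tf_list <- setdiff(colnames(X_raw), tg_list)
  if (!is.null(prior_grn)) {
    names(prior_grn)[1:2] <- c("TF", "TG")
  }
  if (is.null(y_test_matrix)) y_test_matrix <- X_test
  fits <- list()
  status <- data.frame(tg = tg_list, status = "ok", message = "",
                       stringsAsFactors = FALSE)
  for (i in seq_along(tg_list)) {
    tg <- tg_list[i]
    tfs <- if (is.null(prior_grn)) tf_list else
      unique(prior_grn$TF[prior_grn$TG == tg])
    res <- tryCatch({
      cand <- candidate_set(tg, tfs)
      fit_one_tg(X_raw, X_raw[, tg], net, cand, control,
                 X_test = X_test,
                 y_test = if (is.null(X_test)) NULL else y_test_matrix[, tg],
                 tg = tg)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status$status[i] <- "skipped"
      status$message[i] <- conditionMessage(res)
      message("skipping TG ", tg, ": ", conditionMessage(res))
    } else {
      fits[[tg]] <- res
    }
  }
  attr(fits, "status") <- status
  fits
}

#' @export
print.netreg_fit <- function(x, ...) {
  cat("Network-regularized fit", if (!is.na(x$tg)) paste0("for ", x$tg),
      ":", x$n_selected, "of", length(x$tf_order),
      "TFs selected, alpha =", signif(x$alpha_used, 4), "\n")
  if (!is.na(x$mse_train)) cat("  train MSE:", signif(x$mse_train, 4))
  if (!is.na(x$mse_test)) cat("  test MSE:", signif(x$mse_test, 4))
  cat("\n")
  invisible(x)
}
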