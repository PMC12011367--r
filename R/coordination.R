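#' Assemble the signed TF-to-target regulatory network
#'
#' Collects the nonzero coefficients of a set of per-TG fits into a
#' long-format directed link table, optionally filtering weak links
#' (`|coef| > c_min` is required) and dropping targets whose training MSE
#' exceeds `mse_max`.
#'
#' @param fits list of `netreg_fit` objects (e.g. from [fit_all_tgs()]).
#' @param c_min minimum absolute coefficient for a link to be kept
#'   (default 0, i.e. every nonzero coefficient).
#' @param mse_max optional maximum per-TG training MSE; TGs above it are
#'   dropped entirely.
#' @return data.frame of class `regulatory_network` with columns `TF`,
#'   `TG`, `coef`, `sign`, `rank`, `mse_tg`, and attributes `tf_count`,
#'   `tg_count`, `link_count`.
#' @export
assemble_grn <- function(fits, c_min = 0, mse_max = NULL) {
  if (!length(fits)) stop("no fits supplied")
  rows <- lapply(fits, function(f) {
    if (!is.null(mse_max) && !is.na(f$mse_train) && f$mse_train > mse_max)
      return(NULL)
    nz <- which(f$c_star != 0 & abs(f$c_star) > c_min)
    if (!length(nz)) return(NULL)
    data.frame(TF = f$tf_order[nz], TG = f$tg, coef = unname(f$c_star[nz]),
               sign = sign(unname(f$c_star[nz])), rank = f$rank[nz],
               mse_tg = f$mse_train, stringsAsFactors = FALSE)
  })
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
         else NULL
  if (is.null(out))
    out <- data.frame(TF = character(), TG = character(), coef = numeric(),
                      sign = numeric(), rank = integer(), mse_tg = numeric())
  attr(out, "tf_count") <- length(unique(out$TF))
  attr(out, "tg_count") <- length(unique(out$TG))
  attr(out, "link_count") <- nrow(out)
  class(out) <- c("regulatory_network", "data.frame")
  out
}

#' TG-specific TF-TF coordination scores
#'
#' Builds the signed coordination matrix B for one target gene. The sign
#' matrix `C` records coefficient agreement (`C_ij = +1` for co-activators
#' or co-repressors, `-1` for activator-repressor pairs, 0 if either TF is
#' unselected). Raw scores are the coefficient-aware cosine similarity of
#' the TF embeddings, `B0_ij = |cos(X_tilde_i, X_tilde_j)| * C_ij`, so the
#' sign comes solely from coefficient agreement; B is then max-absolute
#' scaled to `[-100, 100]` over all candidate pairs. With fewer than two
#' selected TFs no coordination can be scored and B is all zero.
#'
#' @param emb a `netreg_embedding` over the same TF order as `fit`.
#' @param fit a `netreg_fit` for the same target gene.
#' @return Object of class `coordination_matrix`: list with the symmetric
#'   `B` (zero diagonal), raw `B0`, sign matrix `C`, `tg`, `n_scored`
#'   (= N*(N*-1)/2 nonzero pairs) and `n_pairs` (= N(N-1)/2).
#' @export
coordination_matrix <- function(emb, fit) {
  stopifnot(inherits(emb, "netreg_embedding"), inherits(fit, "netreg_fit"))
  if (!identical(emb$tf_order, fit$tf_order))
    stop("embedding and fit refer to different TF orders")
  N <- length(fit$tf_order)
  sg <- sign(fit$c_star)
  C <- outer(sg, sg)
  diag(C) <- 0
  dimnames(C) <- list(fit$tf_order, fit$tf_order)
  zero <- matrix(0, N, N, dimnames = dimnames(C))
  n_star <- fit$n_selected
  if (n_star < 2)
    return(structure(list(B = zero, B0 = zero, C = C, tg = fit$tg,
                          n_scored = 0L, n_pairs = N * (N - 1) / 2),
                     class = "coordination_matrix"))
  norms <- sqrt(colSums(emb$X_tilde^2))
  if (any(norms == 0)) {
    warning("zero-norm embedding for TF(s) ",
            paste(fit$tf_order[norms == 0], collapse = ", "),
            "; their coordination scores are set to 0")
    norms[norms == 0] <- Inf
  }
  cosm <- crossprod(emb$X_tilde) / outer(norms, norms)
  B0 <- abs(cosm) * C
  diag(B0) <- 0
  mx <- max(abs(B0))
  # divide first: B0/mx <= 1 exactly, so the bound |B| <= 100 is respected
  # at machine precision
  B <- if (mx > 0) 100 * (B0 / mx) else B0
  structure(list(B = B, B0 = B0, C = C, tg = fit$tg,
                 n_scored = as.integer(n_star * (n_star - 1) / 2),
                 n_pairs = N * (N - 1) / 2),
            class = "coordination_matrix")
}

# upper-triangle long view of one B matrix, aligned to a TF universe
b_pairs <- function(B, universe) {
  tfs <- rownames(B)
  idx <- which(upper.tri(B), arr.ind = TRUE)
  data.frame(tf_i = tfs[idx[, 1]], tf_j = tfs[idx[, 2]],
             B = B[idx], stringsAsFactors = FALSE)
}

#' Overall cell-type TF-TF coordination across target genes
#'
#' Aggregates TG-specific coordination matrices into one signed percentile
#' score per unordered TF pair. For each pair the raw aggregate is the sum
#' of its B scores across all G TGs (pairs absent or unscored for a TG
#' contribute 0). Pairs with zero aggregate get `b_bar = 0`; among pairs
#' with nonzero aggregate, `b_bar = sign(f) * percentile_rank(|f|)` where
#' the fractional rank (average rank for ties) is scaled to (0, 100].
#'
#' @param B_list named list (by TG) of `coordination_matrix` objects or
#'   plain B matrices with TF dimnames.
#' @param tf_universe optional character vector of TFs defining the pair
#'   universe; defaults to the union over `B_list`.
#' @return data.frame of class `overall_coordination` with columns `tf_i`,
#'   `tf_j`, `b_bar`, `n_tgs_coregulated`, `aggregate_raw`, and attribute
#'   `G` (number of TGs aggregated).
#' @export
aggregate_coordination <- function(B_list, tf_universe = NULL) {
  if (!length(B_list)) stop("no coordination matrices supplied")
  mats <- lapply(B_list, function(b)
    if (inherits(b, "coordination_matrix")) b$B else b)
  if (is.null(tf_universe))
    tf_universe <- sort(unique(unlist(lapply(mats, rownames))))
  nU <- length(tf_universe)
  agg <- matrix(0, nU, nU, dimnames = list(tf_universe, tf_universe))
  ntg <- matrix(0L, nU, nU, dimnames = list(tf_universe, tf_universe))
  for (B in mats) {
    tfs <- rownames(B)
    bad <- setdiff(tfs, tf_universe)
    if (length(bad))
      stop("TF(s) outside the declared universe: ", paste(bad, collapse = ", "))
    agg[tfs, tfs] <- agg[tfs, tfs] + B
    ntg[tfs, tfs] <- ntg[tfs, tfs] + (B != 0)
  }
  idx <- which(upper.tri(agg), arr.ind = TRUE)
  f <- agg[idx]
  out <- data.frame(tf_i = tf_universe[idx[, 1]],
                    tf_j = tf_universe[idx[, 2]],
                    b_bar = 0, n_tgs_coregulated = ntg[idx],
                    aggregate_raw = f, stringsAsFactors = FALSE)
  nz <- f != 0
  if (any(nz)) {
    pr <- rank(abs(f[nz]), ties.method = "average") / sum(nz) * 100
    out$b_bar[nz] <- sign(f[nz]) * pr
  }
  attr(out, "G") <- length(mats)
  class(out) <- c("overall_coordination", "data.frame")
  out
}

#' Differential TF-TF coordination between two conditions
#'
#' Computes per-(pair, TG) changes in coordination scores between two
#' conditions over their shared target genes
#' (`delta = B_condition2 - B_condition1`; a pair unscored in one condition
#' contributes 0 there), plus a per-pair summary with the mean change, a
#' Welch t-statistic comparing the pair's scores across TGs between
#' conditions, and Benjamini-Hochberg adjusted p-values (reported, not used
#' to filter).
#'
#' @param B_list1,B_list2 named lists (by TG) of coordination matrices for
#'   conditions 1 and 2, over a shared TF universe.
#' @return list with `delta` (long data.frame: `tf_i`, `tf_j`, `TG`,
#'   `delta`) and `summary` (per pair: `mean_delta`, `t_stat`, `p_value`,
#'   `p_adj`).
#' @export
differential_coordination <- function(B_list1, B_list2) {
  shared <- intersect(names(B_list1), names(B_list2))
  if (!length(shared)) stop("no shared target genes between conditions")
  get_mat <- function(b) if (inherits(b, "coordination_matrix")) b$B else b
  universe <- sort(unique(c(
    unlist(lapply(B_list1[shared], function(b) rownames(get_mat(b)))),
    unlist(lapply(B_list2[shared], function(b) rownames(get_mat(b)))))))
  nU <- length(universe)
  expand <- function(b) {
    B <- get_mat(b)
    out <- matrix(0, nU, nU, dimnames = list(universe, universe))
    out[rownames(B), colnames(B)] <- B
    out
  }
  idx <- which(upper.tri(diag(nU)), arr.ind = TRUE)
  delta <- do.call(rbind, lapply(shared, function(tg) {
    d <- expand(B_list2[[tg]]) - expand(B_list1[[tg]])
    data.frame(tf_i = universe[idx[, 1]], tf_j = universe[idx[, 2]],
               TG = tg, delta = d[idx], stringsAsFactors = FALSE)
  }))
  v1 <- sapply(shared, function(tg) expand(B_list1[[tg]])[idx])
  v2 <- sapply(shared, function(tg) expand(B_list2[[tg]])[idx])
  if (length(shared) == 1) { v1 <- matrix(v1, ncol = 1); v2 <- matrix(v2, ncol = 1) }
  summ <- data.frame(tf_i = universe[idx[, 1]], tf_j = universe[idx[, 2]],
                     mean_delta = rowMeans(v2) - rowMeans(v1),
                     t_stat = NA_real_, p_value = NA_real_,
                     stringsAsFactors = FALSE)
  for (k in seq_len(nrow(summ))) {
    a <- v1[k, ]; b <- v2[k, ]
    if (length(shared) >= 2 && (stats::var(a) > 0 || stats::var(b) > 0)) {
      tt <- tryCatch(stats::t.test(b, a), error = function(e) NULL)
      if (!is.null(tt)) {
        summ$t_stat[k] <- unname(tt$statistic)
        summ$p_value[k] <- tt$p.value
      }
    }
  }
  summ$p_adj <- p.adjust(summ$p_value, method = "BH")
  list(delta = delta, summary = summ)
}
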