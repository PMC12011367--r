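link_keys <- function(df, signed = FALSE) {
  if (signed) paste(df[[1]], df[[2]], sign(df$sign), sep = "\r")
  else paste(df[[1]], df[[2]], sep = "\r")
}

pair_keys <- function(df) {
  paste(pmin(df[[1]], df[[2]]), pmax(df[[1]], df[[2]]), sep = "\r")
}

#' Area under the precision-recall curve
#'
#' Step-wise (non-interpolated) integration of the precision-recall curve
#' over a ranked prediction list: at each positive hit, precision at that
#' depth is accumulated against the recall increment.
#'
#' @param scores numeric prediction scores (higher = more confident).
#' @param labels logical/0-1 truth labels, same length.
#' @return AUPR in `[0, 1]`; `NA` when there are no positives.
#' @export
pr_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  if (n_pos == 0) return(NA_real_)
  ord <- order(-scores)
  lab <- labels[ord]
  tp <- cumsum(lab)
  prec <- tp / seq_along(lab)
  sum(prec[lab]) / n_pos
}

#' Score a predicted GRN against a gold standard
#'
#' Classifies every (TF, TG) pair in the declared universe as TP/FP/TN/FN
#' and reports the standard confusion-derived metrics plus the Jaccard
#' similarity of the predicted and true link sets. In signed mode a
#' predicted link counts as a true positive only if both the pair and the
#' regulatory sign match; a correct pair with the wrong sign is a false
#' positive. When `scores` are supplied (e.g. `|coef|`), AUPR over the
#' score-ranked universe is included; in signed mode a signed average AUPR
#' (mean of per-sign-class AUPRs) is also reported.
#'
#' @param predicted data.frame with columns `TF`, `TG` and, for signed
#'   scoring, `sign`; optionally a score column named by `scores`.
#' @param truth data.frame with columns `TF`, `TG` (+ `sign` when signed).
#' @param universe data.frame of all candidate (TF, TG) pairs offered to
#'   the fitter.
#' @param signed score signs as well as pairs (requires `sign` columns).
#' @param scores optional name of a numeric column of `predicted` used to
#'   rank links for AUPR.
#' @return list of class `metric_set` with `tp`, `fp`, `tn`, `fn`,
#'   `precision`, `recall`, `specificity`, `accuracy`,
#'   `balanced_accuracy`, `f1`, `jaccard`, and (when scored) `aupr`,
#'   `aupr_signed`.
#' @export
score_grn <- function(predicted, truth, universe, signed = FALSE,
                      scores = NULL) {
  if (!nrow(universe)) stop("empty evaluation universe")
  if (signed && (is.null(predicted$sign) || is.null(truth$sign)))
    stop("signed scoring requires a `sign` column in predicted and truth")
  uni_key <- link_keys(universe)
  pred_pair <- link_keys(predicted)
  truth_pair <- link_keys(truth)
  stopifnot(all(pred_pair %in% uni_key), all(truth_pair %in% uni_key))
  in_pred <- uni_key %in% pred_pair
  in_truth <- uni_key %in% truth_pair
  if (signed) {
    sign_ok <- link_keys(predicted, TRUE) %in% link_keys(truth, TRUE)
    ok <- uni_key %in% pred_pair[sign_ok]
  } else {
    ok <- in_pred & in_truth
  }
  tp <- sum(in_pred & ok)
  fp <- sum(in_pred & !ok)
  fn <- sum(!in_pred & in_truth)
  tn <- sum(!in_pred & !in_truth)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  pk <- if (signed) link_keys(predicted, TRUE) else pred_pair
  tk <- if (signed) link_keys(truth, TRUE) else truth_pair
  out <- list(tp = tp, fp = fp, tn = tn, fn = fn,
              precision = prec, recall = rec, specificity = spec,
              accuracy = (tp + tn) / length(uni_key),
              balanced_accuracy = mean(c(rec, spec)),
              f1 = if (!is.na(prec) && !is.na(rec) && prec + rec > 0)
                2 * prec * rec / (prec + rec) else NA_real_,
              jaccard = length(intersect(pk, tk)) / length(union(pk, tk)))
  if (!is.null(scores)) {
    sc <- setNames(rep(-Inf, length(uni_key)), uni_key)
    sc[pred_pair] <- predicted[[scores]]
    out$aupr <- pr_auc(unname(sc), in_truth)
    if (signed) {
      per_sign <- vapply(c(1, -1), function(sg) {
        tset <- link_keys(truth[sign(truth$sign) == sg, , drop = FALSE])
        pmask <- pred_pair %in% pred_pair[sign(predicted$sign) == sg]
        sc2 <- setNames(rep(-Inf, length(uni_key)), uni_key)
        psub <- predicted[sign(predicted$sign) == sg, , drop = FALSE]
        sc2[link_keys(psub)] <- psub[[scores]]
        pr_auc(unname(sc2), uni_key %in% tset)
      }, numeric(1))
      out$aupr_signed <- mean(per_sign, na.rm = TRUE)
    }
  }
  class(out) <- "metric_set"
  out
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("tp %d fp %d tn %d fn %d | precision %.3f recall %.3f F1 %.3f BACC %.3f\n",
              x$tp, x$fp, x$tn, x$fn, x$precision, x$recall, x$f1,
              x$balanced_accuracy))
  invisible(x)
}

#' Fraction of top-ranked coordination links present in an evaluation PPIN
#'
#' Ranks TF-TF pairs by `|b_bar|` (ties broken lexicographically by pair),
#' takes the top `k`, and returns the percentage of those pairs found in
#' the evaluation link set.
#'
#' @param bbar an `overall_coordination` table
#'   (from [aggregate_coordination()]).
#' @param eval_ppin data.frame of unordered evaluation pairs (2 columns).
#' @param k number of top links to check; if it exceeds the available
#'   pairs, all are used with a warning.
#' @return percentage in `[0, 100]`.
#' @export
topk_ppi_validation <- function(bbar, eval_ppin, k) {
  stopifnot(k >= 1)
  if (k > nrow(bbar)) {
    warning("k = ", k, " exceeds available pairs (", nrow(bbar),
            "); using all")
    k <- nrow(bbar)
  }
  ord <- order(-abs(bbar$b_bar), bbar$tf_i, bbar$tf_j)
  top <- bbar[ord[seq_len(k)], , drop = FALSE]
  100 * mean(pair_keys(top) %in% pair_keys(eval_ppin))
}

#' Group coordination scores by link status across two PPIN versions
#'
#' Assigns every scored TF-TF pair to one of four groups based on its
#' presence in an older and a newer reference PPIN — absent in both,
#' present in both (TP), removed in the newer version (FP), or newly
#' discovered (FN) — summarizes `|b_bar|` per group, and runs one-sided
#' Welch t-tests (greater) for all ordered group contrasts with
#' Benjamini-Hochberg adjustment. Comparisons involving a group with fewer
#' than 2 members are skipped and noted.
#'
#' @param bbar an `overall_coordination` table.
#' @param ppin_old,ppin_new data.frames of unordered reference pairs.
#' @return list with `groups` (per-pair assignment), `summary` (per-group
#'   n, mean, median of `|b_bar|`) and `tests` (pairwise one-sided Welch
#'   results with `p_adj`).
#' @export
grouped_link_analysis <- function(bbar, ppin_old, ppin_new) {
  key <- pair_keys(bbar)
  in_old <- key %in% pair_keys(ppin_old)
  in_new <- key %in% pair_keys(ppin_new)
  group <- ifelse(in_old & in_new, "present_both_TP",
           ifelse(in_old & !in_new, "removed_FP",
           ifelse(!in_old & in_new, "discovered_FN", "absent_both")))
  ab <- abs(bbar$b_bar)
  groups <- data.frame(tf_i = bbar$tf_i, tf_j = bbar$tf_j,
                       b_bar = bbar$b_bar, group = group,
                       stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(split(ab, group), function(v)
    data.frame(n = length(v), mean_abs = mean(v), median_abs = median(v))))
  summ <- cbind(group = rownames(summ), summ, row.names = NULL)
  lv <- unique(group)
  combs <- expand.grid(greater = lv, lesser = lv, stringsAsFactors = FALSE)
  combs <- combs[combs$greater != combs$lesser, , drop = FALSE]
  tests <- do.call(rbind, lapply(seq_len(nrow(combs)), function(i) {
    g1 <- ab[group == combs$greater[i]]
    g2 <- ab[group == combs$lesser[i]]
    if (length(g1) < 2 || length(g2) < 2)
      return(data.frame(greater = combs$greater[i], lesser = combs$lesser[i],
                        t_stat = NA_real_, p_value = NA_real_,
                        note = "skipped: group too small"))
    tt <- stats::t.test(g1, g2, alternative = "greater")
    data.frame(greater = combs$greater[i], lesser = combs$lesser[i],
               t_stat = unname(tt$statistic), p_value = tt$p.value,
               note = "")
  }))
  tests$p_adj <- p.adjust(tests$p_value, method = "BH")
  list(groups = groups, summary = summ, tests = tests)
}
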