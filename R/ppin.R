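#' Construct a weighted TF-TF interaction network from an edge table
#'
#' Validates and stores an undirected, weighted protein-protein interaction
#' network (PPIN) among transcription factors. Self-loops are removed,
#' duplicate unordered pairs are merged by keeping the maximum weight, and
#' edges at or below `min_weight` are dropped so that only interactions with
#' meaningful confidence remain.
#'
#' @param edges data.frame with at least three columns: two node identifiers
#'   and a numeric confidence weight. Extra columns are ignored.
#' @param min_weight edges with weight `<= min_weight` are discarded
#'   (default 0.01).
#' @param max_scale if `TRUE`, raw weights (e.g. database combined scores)
#'   are divided by the maximum weight so that the largest edge has weight 1.
#' @return An object of class `ppin_network`: a list with `edges`
#'   (data.frame `tf_a`, `tf_b`, `weight`), `nodes`, and `w_min` (smallest
#'   retained weight).
#' @export
ppin_network <- function(edges, min_weight = 0.01, max_scale = FALSE) {
  if (!is.data.frame(edges) || ncol(edges) < 3)
    stop("`edges` must be a data.frame with >= 3 columns (node, node, weight)")
  a <- trimws(as.character(edges[[1]]))
  b <- trimws(as.character(edges[[2]]))
  w <- edges[[3]]
  if (!is.numeric(w)) {
    bad <- which(is.na(suppressWarnings(as.numeric(as.character(w)))))
    stop("non-numeric weight in edge table at line(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  w <- as.numeric(w)
  if (anyNA(w)) stop("missing weight in edge table at line(s): ",
                     paste(utils::head(which(is.na(w)), 5L), collapse = ", "))
  keep <- a != b
  a <- a[keep]; b <- b[keep]; w <- w[keep]
  if (max_scale && length(w)) w <- w / max(w)
  keep <- w > min_weight
  a <- a[keep]; b <- b[keep]; w <- w[keep]
  if (!length(w))
    stop("empty network: no edges remain after filtering at min_weight = ",
         min_weight)
  # canonical unordered storage; duplicates merged conservatively by max
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  w <- tapply(w, key, max)
  pair <- do.call(rbind, strsplit(names(w), "\r", fixed = TRUE))
  out <- list(
    edges = data.frame(tf_a = pair[, 1], tf_b = pair[, 2],
                       weight = as.numeric(w), row.names = NULL,
                       stringsAsFactors = FALSE),
    nodes = sort(unique(c(pair[, 1], pair[, 2]))),
    w_min = min(w)
  )
  class(out) <- "ppin_network"
  out
}

#' Load a PPIN edge list from a delimited file
#'
#' Reads a 2-node + weight edge list (TSV or CSV by extension; gzip
#' transparently supported). A header row is auto-detected from a
#' non-numeric third field on the first line.
#'
#' @param path path to the edge-list file.
#' @inheritParams ppin_network
#' @return A [ppin_network] object.
#' @export
load_ppin <- function(path, min_weight = 0.01, max_scale = FALSE) {
  if (!file.exists(path)) stop("PPIN file not found: ", path)
  sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
  first <- strsplit(readLines(path, n = 1L), sep, fixed = TRUE)[[1]]
  header <- length(first) >= 3 &&
    is.na(suppressWarnings(as.numeric(first[3])))
  tab <- read.table(path, sep = sep, header = header,
                    stringsAsFactors = FALSE, quote = "", comment.char = "")
  if (ncol(tab) < 3)
    stop("edge list must have >= 3 columns (node, node, weight): ", path)
  if (!is.numeric(tab[[3]])) {
    bad <- which(is.na(suppressWarnings(as.numeric(tab[[3]]))))[1]
    stop("non-numeric weight at data line ", bad + header, " of ", path)
  }
  ppin_network(tab, min_weight = min_weight, max_scale = max_scale)
}

#' @export
print.ppin_network <- function(x, ...) {
  cat("TF-TF PPI network:", length(x$nodes), "TFs,",
      nrow(x$edges), "edges, w_min =", signif(x$w_min, 4), "\n")
  invisible(x)
}

#' Candidate TF set for one target gene
#'
#' Holds the candidate transcription factors considered as predictors for a
#' single target gene (TG). If the TG itself appears among the candidates
#' (a TF regulating other genes cannot be its own predictor) it is removed
#' with a message.
#'
#' @param tg target gene identifier.
#' @param tfs character vector of candidate TF identifiers.
#' @return An object of class `candidate_set` with elements `tg` and `tfs`.
#' @export
candidate_set <- function(tg, tfs) {
  tg <- trimws(as.character(tg))
  tfs <- unique(trimws(as.character(tfs)))
  if (tg %in% tfs) {
    message("target gene ", tg, " removed from its own candidate TF list")
    tfs <- setdiff(tfs, tg)
  }
  if (length(tfs) < 1) stop("candidate set for ", tg, " is empty")
  structure(list(tg = tg, tfs = tfs), class = "candidate_set")
}

#' Subset a PPIN to candidate TFs and complete it to a full graph
#'
#' Restricts the input PPIN to the candidate TFs of one target gene and
#' fills every missing pair (including TFs absent from the network) with a
#' small artificial weight `eta`, producing the fully connected prior the
#' regression penalty requires. Node degrees are computed over off-diagonal
#' entries only, and the diagonal is set to `d_i / (N - 1)`.
#'
#' @param net a [ppin_network].
#' @param cand a [candidate_set] (or character vector of TF names).
#' @param eta artificial edge weight for missing pairs; must satisfy
#'   `0 < eta` and should be below the smallest known weight in the subset
#'   (a warning is emitted otherwise).
#' @return An object of class `ppin_complete`: list with `tf_order`, dense
#'   symmetric matrix `W`, degree vector `d`, `eta`, `n_known` (known edges
#'   within the subset), and `degenerate` (`TRUE` when N = 1, in which case
#'   no TF-TF coordination is possible).
#' @export
subset_and_complete <- function(net, cand, eta = 0.01) {
  stopifnot(inherits(net, "ppin_network"))
  if (is.character(cand)) cand <- candidate_set("<none>", cand)
  tfs <- cand$tfs
  N <- length(tfs)
  if (N < 1) stop("no candidate TFs")
  if (eta <= 0) stop("eta must be > 0")
  if (N == 1) {
    W <- matrix(0, 1, 1, dimnames = list(tfs, tfs))
    return(structure(list(tf_order = tfs, W = W, d = setNames(0, tfs),
                          eta = eta, n_known = 0L, degenerate = TRUE),
                     class = "ppin_complete"))
  }
  W <- matrix(eta, N, N, dimnames = list(tfs, tfs))
  e <- net$edges
  inside <- e$tf_a %in% tfs & e$tf_b %in% tfs
  n_known <- sum(inside)
  if (n_known) {
    sub <- e[inside, , drop = FALSE]
    if (eta >= min(sub$weight))
      warning("eta (", eta, ") is not below the smallest known edge weight (",
              min(sub$weight), ") among candidate TFs; artificial edges are ",
              "no longer the weakest")
    W[cbind(sub$tf_a, sub$tf_b)] <- sub$weight
    W[cbind(sub$tf_b, sub$tf_a)] <- sub$weight
  }
  diag(W) <- 0
  d <- rowSums(W)
  diag(W) <- d / (N - 1)
  structure(list(tf_order = tfs, W = W, d = d, eta = eta,
                 n_known = as.integer(n_known), degenerate = FALSE),
            class = "ppin_complete")
}

#' @export
print.ppin_complete <- function(x, ...) {
  cat("Completed TF-TF prior:", length(x$tf_order), "TFs,",
      x$n_known, "known edges, eta =", x$eta, "\n")
  invisible(x)
}
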