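#' Read an expression matrix from TSV/CSV or Matrix Market files
#'
#' Delimited files must carry gene/cell identifiers in the first column and
#' header row; the `orientation` flag states which dimension is which (no
#' silent guessing — conventions differ between tools). Matrix Market
#' triplet input (`.mtx`) requires companion row-name and column-name
#' files (one identifier per line) and is kept sparse until subsetting.
#'
#' @param path expression file (`.tsv`, `.csv`, optionally `.gz`, or
#'   `.mtx`).
#' @param orientation `"cells-rows"` (samples x genes) or `"genes-rows"`
#'   (transposed on read).
#' @param row_names,col_names companion identifier files, required for
#'   `.mtx` input (row/column identifiers of the matrix as stored on disk).
#' @return numeric matrix (or sparse `Matrix`) with cells as rows and
#'   genes as columns.
#' @export
read_expression <- function(path, orientation = c("cells-rows", "genes-rows"),
                            row_names = NULL, col_names = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("expression file not found: ", path)
  if (grepl("\\.mtx(\\.gz)?$", path)) {
    if (is.null(row_names) || is.null(col_names))
      stop("Matrix Market input requires `row_names` and `col_names` files")
    m <- Matrix::readMM(path)
    dimnames(m) <- list(readLines(row_names), readLines(col_names))
  } else {
    sep <- if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"
    tab <- read.table(path, sep = sep, header = TRUE, row.names = 1,
                      check.names = FALSE, quote = "", comment.char = "")
    m <- as.matrix(tab)
  }
  if (orientation == "genes-rows") m <- t(m)
  m
}

#' Write an expression matrix as TSV (cells x genes)
#'
#' @param X matrix with cell row names (generated if absent) and gene
#'   column names.
#' @param path output path.
#' @export
write_expression <- function(X, path) {
  X <- as.matrix(X)
  if (is.null(rownames(X))) rownames(X) <- paste0("cell", seq_len(nrow(X)))
  df <- data.frame(cell = rownames(X), signif(X, 10), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a network edge list as 3-column TSV
#'
#' @param edges data.frame (node, node, weight) or a [ppin_network].
#' @param path output path.
#' @export
write_edge_list <- function(edges, path) {
  if (inherits(edges, "ppin_network")) edges <- edges$edges
  write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a truth / evaluation link set
#'
#' @param path 2- or 3-column TSV (TF, TG[, sign]) with optional header.
#' @param signed require and parse a third sign column.
#' @return data.frame with columns `TF`, `TG` and, if signed, `sign`.
#' @export
read_link_set <- function(path, signed = FALSE) {
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  header <- (length(first) >= 3 &&
               is.na(suppressWarnings(as.numeric(first[3])))) ||
    all(toupper(first[1:2]) %in% c("TF", "TG"))
  tab <- read.table(path, sep = "\t", header = header,
                    stringsAsFactors = FALSE, quote = "")
  if (signed && ncol(tab) < 3)
    stop("signed evaluation requested but ", path, " has no sign column")
  names(tab)[1:2] <- c("TF", "TG")
  if (ncol(tab) >= 3) names(tab)[3] <- "sign"
  if (signed) tab$sign <- sign(as.numeric(tab$sign))
  tab
}

#' Write the regulatory network link table
#' @param grn a `regulatory_network` from [assemble_grn()].
#' @param path output TSV path.
#' @export
write_grn <- function(grn, path) {
  df <- as.data.frame(grn)
  df$coef <- signif(df$coef, 10)
  df$mse_tg <- signif(df$mse_tg, 10)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write TG-specific coordination matrices in long format
#'
#' One row per unordered TF pair per TG, with the coordination score and
#' whether the pair was a known edge (weight above the artificial `eta`)
#' in the completed input PPIN.
#'
#' @param coords named list (by TG) of `coordination_matrix` objects.
#' @param fits matching named list of `netreg_fit` objects (for the
#'   completed PPIN weights).
#' @param path output TSV path.
#' @export
write_coordination <- function(coords, fits, path) {
  rows <- lapply(names(coords), function(tg) {
    cm <- coords[[tg]]
    W <- fits[[tg]]$ppin$W
    eta <- fits[[tg]]$ppin$eta
    idx <- which(upper.tri(cm$B), arr.ind = TRUE)
    tfs <- rownames(cm$B)
    data.frame(TG = tg, TF_i = tfs[idx[, 1]], TF_j = tfs[idx[, 2]],
               B = signif(cm$B[idx], 10),
               known_edge = W[idx] > eta,
               stringsAsFactors = FALSE)
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
}

#' Write the overall coordination table
#' @param bbar an `overall_coordination` from [aggregate_coordination()].
#' @param path output TSV path.
#' @export
write_bbar <- function(bbar, path) {
  df <- as.data.frame(bbar)
  df$b_bar <- signif(df$b_bar, 10)
  df$aggregate_raw <- signif(df$aggregate_raw, 10)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
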