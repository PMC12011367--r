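#' Run the full inference pipeline from files to files
#'
#' Reads expression data and a PPIN edge list (and optionally a prior GRN
#' restricting candidate TFs per target gene), fits the
#' network-regularized regression for every requested target gene, and
#' writes the regulatory network table, the TG-specific coordination
#' scores, the overall coordination table, and a JSON run manifest into
#' `out_dir`. Outputs are deterministic under a fixed seed.
#'
#' @param expression path to the expression file, or an in-memory matrix
#'   (cells x genes).
#' @param ppin path to the PPIN edge list, or a [ppin_network].
#' @param tg_list character vector of target genes, or path to a one-per-
#'   line text file.
#' @param orientation expression orientation on disk (see
#'   [read_expression()]); mandatory for file input.
#' @param tf_list optional explicit global TF list.
#' @param prior_grn optional prior GRN table path or data.frame (columns
#'   TF, TG).
#' @param control a [netreg_control()].
#' @param c_min,mse_max link filters passed to [assemble_grn()].
#' @param out_dir output directory (created if needed).
#' @param row_names,col_names Matrix Market companions, see
#'   [read_expression()].
#' @return invisibly, a list with `fits`, `grn`, `coords`, `bbar`, and the
#'   `manifest`.
#' @export
run_pipeline <- function(expression, ppin, tg_list,
                         orientation = c("cells-rows", "genes-rows"),
                         tf_list = NULL, prior_grn = NULL,
                         control = netreg_control(), c_min = 0,
                         mse_max = NULL, out_dir = ".",
                         row_names = NULL, col_names = NULL) {
  t0 <- Sys.time()
  orientation <- match.arg(orientation)
  X <- if (is.character(expression))
    read_expression(expression, orientation, row_names, col_names)
  else expression
  net <- if (is.character(ppin)) load_ppin(ppin) else ppin
  if (is.character(tg_list) && length(tg_list) == 1 && file.exists(tg_list))
    tg_list <- readLines(tg_list)
  if (is.character(prior_grn) && length(prior_grn) == 1)
    prior_grn <- read_link_set(prior_grn)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  fits <- fit_all_tgs(X, tg_list, net, tf_list = tf_list,
                      prior_grn = prior_grn, control = control)
  grn <- assemble_grn(fits, c_min = c_min, mse_max = mse_max)
  coords <- lapply(fits, function(f) coordination_matrix(f$embedding, f))
  bbar <- aggregate_coordination(coords)

  write_grn(grn, file.path(out_dir, "grn.tsv"))
  write_coordination(coords, fits, file.path(out_dir, "coordination_b.tsv"))
  write_bbar(bbar, file.path(out_dir, "coordination_bbar.tsv"))

  status <- attr(fits, "status")
  status$alpha_used <- NA_real_
  ok <- status$status == "ok"
  status$alpha_used[ok] <- vapply(fits[status$tg[ok]],
                                  function(f) f$alpha_used, numeric(1))
  manifest <- list(
    software = list(package = "tfcoord",
                    version = as.character(packageVersion("tfcoord"))),
    config = list(beta = control$beta, alpha = control$alpha,
                  cv_folds = control$cv_folds, eta = control$eta,
                  tol_svd = control$tol_svd, seed = control$seed,
                  intercept = control$intercept, c_min = c_min,
                  mse_max = mse_max, orientation = orientation,
                  n_tgs_requested = length(tg_list),
                  n_tfs_global = length(if (is.null(tf_list))
                    setdiff(colnames(X), tg_list) else tf_list)),
    targets = status,
    links = attr(grn, "link_count"),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(fits = fits, grn = grn, coords = coords, bbar = bbar,
                 manifest = manifest))
}
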