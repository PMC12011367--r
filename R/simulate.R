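#' Configuration for the single-TG expression simulator
#'
#' @param n_cells number of cells (default 10,000, the scale of the
#'   proof-of-concept study).
#' @param r_targets target Pearson correlations between each TF and the TG
#'   (all strictly inside (-1, 1)); default `c(0.9, 0.5, 0.4, -0.3, -0.8)`.
#' @param dropout_rate fraction of the data zeroed to mimic single-cell
#'   sparsity (default 0.4).
#' @param dropout_unit `"cell"` zeroes whole cells (one shared mask across
#'   genes, which leaves pairwise correlations of the observed data at
#'   their targets); `"entry"` zeroes entries independently (which
#'   attenuates them).
#' @param train_fraction fraction of cells in the training split
#'   (default 0.7).
#' @param seed integer master seed; sub-streams for data, dropout mask, and
#'   split are derived from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 10000,
                       r_targets = c(0.9, 0.5, 0.4, -0.3, -0.8),
                       dropout_rate = 0.4, dropout_unit = c("cell", "entry"),
                       train_fraction = 0.7, seed = 1) {
  if (any(abs(r_targets) >= 1))
    stop("infeasible correlation target(s): all |r| must be < 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must be in (0, 1)")
  structure(list(n_cells = as.integer(n_cells), r_targets = r_targets,
                 dropout_rate = dropout_rate,
                 dropout_unit = match.arg(dropout_unit),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "sim_config")
}

# one master seed fans out to independent sub-stream seeds
substream_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

apply_dropout <- function(X, y, rate, unit, seed) {
  if (rate <= 0) return(list(X = X, y = y))
  set.seed(seed)
  n <- nrow(X)
  if (unit == "cell") {
    idx <- sample.int(n, round(rate * n))
    X[idx, ] <- 0
    if (!is.null(y)) y[idx] <- 0
  } else {
    X[matrix(runif(length(X)) < rate, n)] <- 0
    if (!is.null(y)) y[runif(n) < rate] <- 0
  }
  list(X = X, y = y)
}

#' Simulate expression for N TFs and one target gene
#'
#' Draws the TG `y` from a standard normal and each TF as
#' `x_i = r_i * y + sqrt(1 - r_i^2) * noise` with independent standard
#' normal noise, so TFs are conditionally independent given y, each TF-TG
#' Pearson correlation converges to its target, and the TF-TF correlations
#' converge to `r_i * r_j`. A dropout mask then zeroes the configured
#' fraction of the data, and cells are split into train/test sets.
#'
#' @param cfg a [sim_config()].
#' @return list with `X` (cells x TFs, columns `TF1..TFN`), `y`,
#'   `train_idx`, `test_idx`, and the `config`. Deterministic under the
#'   configured seed.
#' @export
simulate_single_tg <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- substream_seeds(cfg$seed, 3)
  n <- cfg$n_cells
  r <- cfg$r_targets
  set.seed(seeds[1])
  y <- rnorm(n)
  X <- vapply(r, function(ri) ri * y + sqrt(1 - ri^2) * rnorm(n), numeric(n))
  colnames(X) <- paste0("TF", seq_along(r))
  dd <- apply_dropout(X, y, cfg$dropout_rate, cfg$dropout_unit, seeds[2])
  set.seed(seeds[3])
  train_idx <- sort(sample.int(n, round(cfg$train_fraction * n)))
  list(X = dd$X, y = dd$y, train_idx = train_idx,
       test_idx = setdiff(seq_len(n), train_idx), config = cfg)
}

#' Random signed toy gene regulatory network
#'
#' Draws a ground-truth GRN in which each target gene is regulated by a
#' fixed number of randomly chosen TFs with signed effect sizes of random
#' sign and magnitude uniform in `effect_range`.
#'
#' @param n_tfs,n_tgs numbers of TFs (`TF1..`) and target genes (`TG1..`).
#' @param regulators_per_tg number of true regulators per TG.
#' @param effect_range range of absolute effect sizes.
#' @param seed integer seed.
#' @return list of class `toy_grn` with `links` (data.frame `TF`, `TG`,
#'   `effect_sign`, `effect_size`), `tf_list`, `tg_list`.
#' @export
make_toy_grn <- function(n_tfs = 20, n_tgs = 50, regulators_per_tg = 3,
                         effect_range = c(0.5, 1.5), seed = 1) {
  stopifnot(regulators_per_tg >= 1, regulators_per_tg <= n_tfs)
  set.seed(seed)
  tf_list <- paste0("TF", seq_len(n_tfs))
  tg_list <- paste0("TG", seq_len(n_tgs))
  links <- do.call(rbind, lapply(tg_list, function(tg) {
    tfs <- sample(tf_list, regulators_per_tg)
    data.frame(TF = tfs, TG = tg,
               effect_sign = sample(c(-1, 1), regulators_per_tg, replace = TRUE),
               effect_size = runif(regulators_per_tg, effect_range[1],
                                   effect_range[2]),
               stringsAsFactors = FALSE)
  }))
  structure(list(links = links, tf_list = tf_list, tg_list = tg_list),
            class = "toy_grn")
}

#' Simulate multi-gene expression from a signed toy GRN
#'
#' TF columns are exogenous standard normals; each target gene is the
#' signed linear combination of its regulators plus Gaussian noise. A
#' dropout mask is applied to the full matrix. The ground-truth signed
#' links are returned alongside for evaluation.
#'
#' @param grn a [make_toy_grn()] object (TFs exogenous; no TG regulates
#'   itself).
#' @param n_cells number of cells.
#' @param noise_sd standard deviation of the additive TG noise.
#' @param dropout_rate,dropout_unit as in [sim_config()].
#' @param seed integer seed.
#' @return list with `expression` (cells x (TFs + TGs)), `truth` (signed
#'   link table), `tf_list`, `tg_list`.
#' @export
simulate_multi_tg <- function(grn, n_cells = 1000, noise_sd = 1,
                              dropout_rate = 0.4,
                              dropout_unit = c("cell", "entry"), seed = 1) {
  stopifnot(inherits(grn, "toy_grn"))
  dropout_unit <- match.arg(dropout_unit)
  seeds <- substream_seeds(seed, 2)
  set.seed(seeds[1])
  TFs <- matrix(rnorm(n_cells * length(grn$tf_list)), n_cells,
                dimnames = list(NULL, grn$tf_list))
  TGs <- matrix(0, n_cells, length(grn$tg_list),
                dimnames = list(NULL, grn$tg_list))
  for (tg in grn$tg_list) {
    li <- grn$links[grn$links$TG == tg, , drop = FALSE]
    if (!nrow(li)) {
      warning("target gene ", tg, " has no regulators; generated as noise")
      TGs[, tg] <- noise_sd * rnorm(n_cells)
      next
    }
    signal <- TFs[, li$TF, drop = FALSE] %*% (li$effect_sign * li$effect_size)
    TGs[, tg] <- signal + noise_sd * rnorm(n_cells)
  }
  expr <- cbind(TFs, TGs)
  dd <- apply_dropout(expr, NULL, dropout_rate, dropout_unit, seeds[2])
  list(expression = dd$X, truth = grn$links, tf_list = grn$tf_list,
       tg_list = grn$tg_list)
}

#' The five-TF proof-of-concept study bundle
#'
#' Generates the complete five-TF, one-TG demonstration: 10,000 cells with
#' TF-TG correlation targets `[0.9, 0.5, 0.4, -0.3, -0.8]`, ~40% dropout,
#' a 70/30 train/test split, and the known PPIN with two strong edges
#' TF1-TF2 (0.8) and TF4-TF5 (0.95), together with default settings
#' (beta = 1, alpha = 0.1, eta = 0.01, no intercept) ready for
#' [fit_one_tg()].
#'
#' @param seed integer seed.
#' @return list with `sim` (from [simulate_single_tg()]), `ppin`
#'   (a [ppin_network] with the two known edges), and `control`.
#' @export
make_five_tf_study <- function(seed = 1) {
  sim <- simulate_single_tg(sim_config(seed = seed))
  ppin <- ppin_network(data.frame(tf_a = c("TF1", "TF4"),
                                  tf_b = c("TF2", "TF5"),
                                  weight = c(0.8, 0.95)))
  list(sim = sim, ppin = ppin,
       control = netreg_control(beta = 1, alpha = 0.1, eta = 0.01,
                                intercept = FALSE, seed = seed))
}

#' Fit the five-TF study
#'
#' Convenience wrapper: runs [fit_one_tg()] on a [make_five_tf_study()]
#' bundle using its train/test split and returns the fit together with the
#' TG-specific coordination matrix.
#'
#' @param study a [make_five_tf_study()] bundle.
#' @return list with `fit` (a `netreg_fit`) and `coord`
#'   (a `coordination_matrix`).
#' @export
fit_five_tf_study <- function(study = make_five_tf_study()) {
  sim <- study$sim
  tr <- sim$train_idx; te <- sim$test_idx
  fit <- fit_one_tg(sim$X[tr, ], sim$y[tr], study$ppin,
                    colnames(sim$X), study$control,
                    X_test = sim$X[te, ], y_test = sim$y[te], tg = "TG")
  list(fit = fit, coord = coordination_matrix(fit$embedding, fit))
}
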