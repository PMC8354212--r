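#' Random-forest configuration
#'
#' Defaults mirror the R randomForest classification defaults: 500 trees,
#' `mtry = floor(sqrt(n))` candidate features per split, bootstrap resamples
#' of size 2m drawn with replacement.
#'
#' @param n_trees Number of trees (>= 1).
#' @param mtry Features tried per split; `NULL` = `floor(sqrt(n_genes))`,
#'   resolved when the forest is fitted.
#' @param sample_size Bootstrap size; `NULL` = number of training rows.
#' @param seed Integer master seed; sub-seeds for the column permutation, the
#'   forest fit and the MDA permutations are derived from it.
#' @param scale_mda If `TRUE`, divide each gene's MDA by its standard error
#'   over trees (randomForest's scaled importance). The selection rule
#'   (MDA > 0) depends only on sign, which scaling preserves whenever the
#'   standard error is nonzero; default is the raw mean.
#' @return Object of class `ForestConfig`.
#' @export
forest_config <- function(n_trees = 500, mtry = NULL, sample_size = NULL,
                          seed = 1, scale_mda = FALSE) {
  n_trees <- as.integer(n_trees)
  if (is.na(n_trees) || n_trees < 1) stop("n_trees must be >= 1")
  if (!is.null(mtry) && mtry < 1) stop("mtry must be >= 1")
  structure(list(n_trees = n_trees, mtry = mtry, sample_size = sample_size,
                 seed = as.integer(seed), scale_mda = isTRUE(scale_mda)),
            class = "ForestConfig")
}

#' Fit a real-vs-permuted random-forest classifier
#'
#' Trains a classification forest (via the randomForest package) on the
#' stacked training set, keeping per-tree in-bag counts and the full forest so
#' that out-of-bag membership and per-tree predictions are available for the
#' MDA computation.
#'
#' @param ts A `TrainingSet` from [build_training_set()].
#' @param cfg A [forest_config()].
#' @return Object of class `ForestModel` wrapping the fitted forest; exposes
#'   `oob_vote_accuracy` (accuracy of the aggregated majority-vote OOB
#'   prediction) and, through the kept forest, per-tree in-bag/OOB row sets.
#'   Note that on a real-vs-permuted training set the vote accuracy is a
#'   diagnostic of the aggregated classifier only -- see the package vignette
#'   for why it inverts there, while the per-tree OOB accuracies reported by
#'   [compute_mda()] stay near 1/2.
#' @export
fit_forest <- function(ts, cfg = forest_config()) {
  stopifnot(inherits(ts, "TrainingSet"), inherits(cfg, "ForestConfig"))
  if (length(unique(ts$labels)) < 2)
    stop("training labels are single-class; cannot fit a classifier")
  n <- ncol(ts$features)
  mtry <- if (is.null(cfg$mtry)) max(1L, floor(sqrt(n))) else as.integer(cfg$mtry)
  if (mtry > n) stop("mtry (", mtry, ") exceeds the number of genes (", n, ")")
  sampsize <- if (is.null(cfg$sample_size)) nrow(ts$features)
              else as.integer(cfg$sample_size)
  y <- factor(ts$labels, levels = c(0L, 1L))
  set.seed(derive_seeds(cfg$seed, 2)[1])
  rf <- randomForest::randomForest(
    x = ts$features, y = y,
    ntree = cfg$n_trees, mtry = mtry, replace = TRUE, sampsize = sampsize,
    importance = TRUE, keep.forest = TRUE, keep.inbag = TRUE)
  structure(list(rf = rf,
                 config = cfg,
                 mtry = mtry,
                 gene_ids = ts$gene_ids,
                 oob_vote_accuracy = mean(rf$predicted == y)),
            class = "ForestModel")
}

#' @export
print.ForestModel <- function(x, ...) {
  cat(sprintf("ForestModel: %d trees, mtry %d, OOB vote accuracy %.3f\n",
              x$config$n_trees, x$mtry, x$oob_vote_accuracy))
  invisible(x)
}

#' Out-of-bag mean decrease accuracy per gene
#'
#' For each tree t with out-of-bag rows O_t: the baseline accuracy a_t of t on
#' O_t is compared with the accuracy a_tj after permuting gene j's values
#' within O_t; the gene's MDA is the mean of the drops d_tj = a_t - a_tj over
#' trees. A gene the forest never splits on has MDA exactly 0 (permuting it
#' changes no prediction). Trees with an empty OOB set are skipped with a
#' warning; if every tree is skipped, an error is raised.
#'
#' @param model A `ForestModel` from [fit_forest()].
#' @param ts The `TrainingSet` the model was fitted on.
#' @param seed Integer seed for the OOB permutations; defaults to a sub-seed
#'   of the model's configured seed.
#' @return Object of class `ImportanceReport`: `mda` (named per-gene vector,
#'   scaled if the config says so), `raw_mda`, `mda_se`,
#'   `per_tree_oob_accuracy` (baseline accuracy a_t per tree, `NA` for skipped
#'   trees), `oob_accuracy` (the mean of a_t over used trees -- the baseline
#'   level the accuracy drops are measured against), `forest_vote_accuracy`
#'   (accuracy of the aggregated majority-vote OOB prediction),
#'   `n_trees_used`, `config`.
#' @export
compute_mda <- function(model, ts, seed = NULL) {
  stopifnot(inherits(model, "ForestModel"), inherits(ts, "TrainingSet"))
  rf <- model$rf
  if (nrow(ts$features) != nrow(rf$inbag))
    stop("training set does not match the fitted model")
  if (is.null(seed)) seed <- derive_seeds(model$config$seed, 2)[2]
  fr <- rf$forest
  storage.mode(fr$nodestatus) <- "integer"
  storage.mode(fr$bestvar) <- "integer"
  storage.mode(fr$nodepred) <- "integer"
  left <- matrix(as.integer(fr$treemap[, 1, ]), nrow = fr$nrnodes)
  right <- matrix(as.integer(fr$treemap[, 2, ]), nrow = fr$nrnodes)
  # class indices as stored in nodepred: position in levels(y) = c("0","1")
  y_class <- as.integer(ts$labels) + 1L
  set.seed(as.integer(seed))
  res <- .mda_cpp(ts$features, y_class,
                  matrix(as.integer(rf$inbag), nrow = nrow(rf$inbag)),
                  as.integer(fr$ndbigtree),
                  fr$nodestatus, fr$bestvar, fr$xbestsplit, fr$nodepred,
                  left, right)
  if (res$n_trees_skipped > 0)
    warning(res$n_trees_skipped,
            " tree(s) skipped: empty out-of-bag set")
  raw <- stats::setNames(res$mda, ts$gene_ids)
  se <- stats::setNames(res$sd / sqrt(res$n_trees_used), ts$gene_ids)
  mda <- raw
  if (model$config$scale_mda) {
    # genes with zero SE keep their raw value (sign preserved)
    nz <- se > .Machine$double.eps
    mda[nz] <- raw[nz] / se[nz]
  }
  structure(list(mda = mda, raw_mda = raw, mda_se = se,
                 per_tree_oob_accuracy = res$tree_accuracy,
                 oob_accuracy = mean(res$tree_accuracy, na.rm = TRUE),
                 forest_vote_accuracy = model$oob_vote_accuracy,
                 n_trees_used = res$n_trees_used,
                 config = model$config),
            class = "ImportanceReport")
}

#' @export
print.ImportanceReport <- function(x, ...) {
  cat(sprintf(
    "ImportanceReport: %d genes, OOB accuracy %.3f, %d genes with MDA > 0\n",
    length(x$mda), x$oob_accuracy, sum(x$mda > 0)))
  invisible(x)
}

#' Select genes with positive MDA
#'
#' Strict inequality: genes with MDA exactly 0 (in particular constant genes
#' the forest never used) are excluded. An empty selection is returned as an
#' empty [gene_set()] with a warning, not an error.
#'
#' @param report An `ImportanceReport`.
#' @return A [gene_set()] ordered by descending MDA (ties by gene id).
#' @export
select_genes <- function(report) {
  stopifnot(inherits(report, "ImportanceReport"))
  keep <- report$mda > 0
  if (!any(keep)) {
    warning("no gene has MDA > 0; returning an empty gene set")
    return(gene_set())
  }
  gene_set(names(report$mda)[keep], unname(report$mda[keep]))
}

#' RFCell gene selection
#'
#' The full pipeline: build the real-vs-permuted training set, fit the random
#' forest, compute per-gene out-of-bag MDA, and keep genes with MDA > 0. Fully
#' determined by the expression matrix and `cfg$seed`.
#'
#' @param x An [expression_matrix()] of nonnegative normalized values.
#' @param cfg A [forest_config()].
#' @param shared_permutation Passed to [build_training_set()]; keep the
#'   default `FALSE` for the method proper.
#' @return List with elements `gene_set` (the selection) and `report` (the
#'   [compute_mda()] output).
#' @examples
#' \donttest{
#' ds <- generate_synthetic(synthetic_config(m_cells = 60, n_informative = 10,
#'                                           n_noise = 40, seed = 7))
#' res <- rfcell_select(ds$x, forest_config(n_trees = 100, seed = 7))
#' res$gene_set
#' }
#' @export
rfcell_select <- function(x, cfg = forest_config(), shared_permutation = FALSE) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(cfg, "ForestConfig"))
  seeds <- derive_seeds(cfg$seed, 3)
  ts <- build_training_set(x, seed = seeds[1],
                           shared_permutation = shared_permutation)
  fit_cfg <- cfg
  fit_cfg$seed <- seeds[2]
  model <- fit_forest(ts, fit_cfg)
  report <- compute_mda(model, ts, seed = seeds[3])
  report$config <- cfg
  list(gene_set = select_genes(report), report = report)
}
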