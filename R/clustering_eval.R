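#' Expr baseline: genes with the highest average expression
#'
#' Ranks genes by their mean log1p value across cells and keeps the top
#' `k_genes` (ties broken by gene id). The standard "Expr" baseline selector.
#'
#' @param x An [expression_matrix()].
#' @param k_genes Number of genes to keep (1..n).
#' @return A [gene_set()] scored by mean log1p expression.
#' @export
expr_select <- function(x, k_genes) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  n <- n_genes(x)
  if (k_genes < 1 || k_genes > n)
    stop("k_genes must be in 1..", n)
  means <- colMeans(log1p(x$values))
  ord <- order(-means, names(means))
  keep <- ord[seq_len(k_genes)]
  gene_set(names(means)[keep], unname(means[keep]))
}

#' Cell-cell Spearman similarity matrix
#'
#' S[u, v] is the Spearman rank correlation between the expression vectors of
#' cells u and v (average ranks for ties). Symmetric with unit diagonal. A
#' cell with zero variance across genes has no defined rank correlation; its
#' off-diagonal similarities are set to 0 with a warning.
#'
#' @param x An [expression_matrix()] with at least 2 genes.
#' @return m x m numeric matrix with cell ids as dimnames.
#' @export
spearman_similarity <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  if (n_genes(x) < 2) stop("need at least 2 genes for rank correlation")
  s <- suppressWarnings(stats::cor(t(x$values), method = "spearman"))
  if (anyNA(s)) {
    degenerate <- x$cell_ids[apply(x$values, 1, function(r) stats::var(r) == 0)]
    warning("cells with zero variance across genes; their similarities set to 0: ",
            paste(degenerate, collapse = ", "))
    s[is.na(s)] <- 0
  }
  diag(s) <- 1
  dimnames(s) <- list(x$cell_ids, x$cell_ids)
  s
}

#' Hierarchical clustering of a similarity matrix
#'
#' Agglomerative clustering with distance 1 - similarity and complete linkage
#' (R's hclust default), with the tree cut into k clusters.
#'
#' @param s Symmetric similarity matrix.
#' @param k Number of clusters, 2..m.
#' @return Integer vector of cluster labels, named by the matrix dimnames.
#' @export
hierarchical_cluster <- function(s, k) {
  if (!is.matrix(s) || nrow(s) != ncol(s) || !isSymmetric(unname(s), tol = 1e-8))
    stop("similarity matrix must be square and symmetric")
  m <- nrow(s)
  if (k < 2 || k > m) stop("k must be in 2..", m)
  hc <- stats::hclust(stats::as.dist(1 - s), method = "complete")
  stats::cutree(hc, k = k)
}

#' k-means clustering with seeded restarts
#'
#' Lloyd's algorithm with `nstart` random initializations drawn from a seeded
#' RNG; the partition with the lowest total within-cluster sum of squares is
#' kept. Starts that collapse to an empty cluster are dropped (at least one
#' valid start is required).
#'
#' @param x Numeric matrix, rows = observations.
#' @param k Number of clusters, 2..m.
#' @param seed Integer seed.
#' @param nstart Number of restarts (default 10).
#' @return Integer vector of cluster labels, named by row names of `x`.
#' @export
kmeans_cluster <- function(x, k, seed, nstart = 10) {
  if (!is.matrix(x)) x <- as.matrix(x)
  m <- nrow(x)
  if (k < 2 || k > m) stop("k must be in 2..", m)
  set.seed(as.integer(seed))
  best <- NULL
  for (i in seq_len(nstart)) {
    fit <- tryCatch(
      withCallingHandlers(
        stats::kmeans(x, centers = k, iter.max = 100, algorithm = "Lloyd"),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best))
    stop("k-means failed in every restart (empty clusters); is k too large?")
  stats::setNames(best$cluster, rownames(x))
}

#' Evaluation configuration for the repeat protocol
#'
#' @param k Number of clusters handed to the clusterer (set to the true
#'   number of cell types).
#' @param repeats Number of repeats (default 10; selection is rerun and the
#'   resulting NMI/ARI averaged).
#' @param seeds Integer vector of per-repeat seeds, length `repeats`; default
#'   derived from `base_seed`.
#' @param clusterer `"kmeans"` or `"hclust"` (Spearman similarity + complete
#'   linkage).
#' @param base_seed Master seed used when `seeds` is NULL.
#' @return Object of class `EvalConfig`.
#' @export
eval_config <- function(k, repeats = 10, seeds = NULL,
                        clusterer = c("kmeans", "hclust"), base_seed = 1) {
  clusterer <- match.arg(clusterer)
  if (k < 2) stop("k must be >= 2")
  if (repeats < 1) stop("repeats must be >= 1")
  if (is.null(seeds)) seeds <- derive_seeds(base_seed, repeats)
  if (length(seeds) != repeats) stop("need one seed per repeat")
  structure(list(k = as.integer(k), repeats = as.integer(repeats),
                 seeds = as.integer(seeds), clusterer = clusterer),
            class = "EvalConfig")
}

cluster_cells <- function(x_sub, cfg, seed) {
  if (cfg$clusterer == "kmeans") {
    kmeans_cluster(log1p(x_sub$values), k = cfg$k, seed = seed)
  } else {
    hierarchical_cluster(spearman_similarity(x_sub), k = cfg$k)
  }
}

subset_genes <- function(x, gene_ids) {
  expression_matrix(x$values[, gene_ids, drop = FALSE], unit = x$unit)
}

#' Run the repeat-evaluation protocol for one selector
#'
#' For each repeat r (seed s_r): select genes with the chosen selector (the
#' forest selector is reseeded with s_r each repeat; `expr` and `all_genes`
#' are deterministic), subset the matrix to the selected genes, cluster the
#' cells (on log1p values for k-means; Spearman similarity + complete-linkage
#' hclust otherwise), and score the partition against the true labels with
#' NMI and ARI. Reports per-run values and their means. A run whose selection
#' is empty is recorded as failed and excluded from the means, with a warning.
#'
#' @param x An [expression_matrix()].
#' @param truth Vector of true cell labels aligned to the cells of `x`.
#' @param selector `"rfcell"`, `"expr"` or `"all_genes"`.
#' @param cfg An [eval_config()]; `cfg$k` should be the true cluster count.
#' @param forest_cfg A [forest_config()] (selector `"rfcell"` only; its seed
#'   is replaced by the per-repeat seed).
#' @param expr_n_genes Gene count for the `expr` selector. Convention: match
#'   the size of the forest selection in the same experiment.
#' @return Object of class `EvalResult`: `per_run` data.frame (seed,
#'   n_selected, nmi, ari, failed), `mean_nmi`, `mean_ari`, `selector`.
#' @export
evaluate_selection <- function(x, truth,
                               selector = c("rfcell", "expr", "all_genes"),
                               cfg, forest_cfg = forest_config(),
                               expr_n_genes = NULL) {
  stopifnot(inherits(x, "ExpressionMatrix"), inherits(cfg, "EvalConfig"))
  selector <- match.arg(selector)
  if (length(truth) != n_cells(x))
    stop("truth labels must align to the cells of x")
  if (selector == "expr" && is.null(expr_n_genes))
    stop("selector 'expr' needs expr_n_genes")

  runs <- lapply(cfg$seeds, function(s) {
    genes <- switch(selector,
      rfcell = {
        fc <- forest_cfg; fc$seed <- s
        rfcell_select(x, fc)$gene_set$gene_ids
      },
      expr = expr_select(x, expr_n_genes)$gene_ids,
      all_genes = x$gene_ids)
    if (length(genes) == 0) {
      warning("run with seed ", s, " selected no genes; excluded from means")
      return(data.frame(seed = s, n_selected = 0L, nmi = NA_real_,
                        ari = NA_real_, failed = TRUE))
    }
    part <- cluster_cells(subset_genes(x, genes), cfg, seed = s)
    data.frame(seed = s, n_selected = length(genes),
               nmi = nmi(part, truth), ari = adjusted_rand_index(part, truth),
               failed = FALSE)
  })
  per_run <- do.call(rbind, runs)
  ok <- !per_run$failed
  structure(list(per_run = per_run,
                 mean_nmi = if (any(ok)) mean(per_run$nmi[ok]) else NA_real_,
                 mean_ari = if (any(ok)) mean(per_run$ari[ok]) else NA_real_,
                 selector = selector, config = cfg),
            class = "EvalResult")
}

#' @export
print.EvalResult <- function(x, ...) {
  cat(sprintf("EvalResult [%s]: %d runs, mean NMI %.3f, mean ARI %.3f\n",
              x$selector, nrow(x$per_run), x$mean_nmi, x$mean_ari))
  invisible(x)
}

#' Compare the forest selector against the all-genes and Expr baselines
#'
#' Runs [evaluate_selection()] for the forest selector, then for the
#' `all_genes` baseline and for the `expr` baseline size-matched to the mean
#' number of genes the forest selected (rounded), all under the same
#' evaluation config and seeds.
#'
#' @inheritParams evaluate_selection
#' @return Named list of `EvalResult`s: `rfcell`, `all_genes`, `expr`.
#' @export
compare_selectors <- function(x, truth, cfg, forest_cfg = forest_config()) {
  rf <- evaluate_selection(x, truth, "rfcell", cfg, forest_cfg)
  n_sel <- round(mean(rf$per_run$n_selected[!rf$per_run$failed]))
  n_sel <- max(1L, min(n_genes(x), as.integer(n_sel)))
  list(rfcell = rf,
       all_genes = evaluate_selection(x, truth, "all_genes", cfg),
       expr = evaluate_selection(x, truth, "expr", cfg,
                                 expr_n_genes = n_sel))
}
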