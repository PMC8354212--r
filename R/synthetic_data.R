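#' Configuration for the synthetic scRNA-seq generator
#'
#' The generator emulates what the selection method needs to exploit: a small
#' set of informative genes whose (log-scale) mean expression depends on the
#' cell's cluster, a large majority of i.i.d. noise genes, log-normal
#' biological/technical spread, and independent dropout zeros.
#'
#' @param m_cells Number of cells (default 200).
#' @param n_clusters Number of cell clusters (default 3).
#' @param cluster_proportions Simplex vector of cluster proportions; default
#'   uniform.
#' @param n_informative Genes with cluster-dependent means (default 50).
#' @param n_noise Genes with a single global mean (default 950).
#' @param effect_size SD of cluster-specific log-mean shifts around a gene's
#'   baseline, i.e. the between-cluster spread on the log scale (default 2.0;
#'   0 makes informative genes indistinguishable from noise).
#' @param dispersion Log-normal SD within a (cluster, gene) cell group
#'   (default 1.0).
#' @param dropout_rate Probability that any entry is zeroed (default 0.3).
#' @param seed Integer RNG seed.
#' @return Object of class `SyntheticConfig`.
#' @export
synthetic_config <- function(m_cells = 200, n_clusters = 3,
                             cluster_proportions = NULL,
                             n_informative = 50, n_noise = 950,
                             effect_size = 2.0, dispersion = 1.0,
                             dropout_rate = 0.3, seed = 1) {
  if (is.null(cluster_proportions))
    cluster_proportions <- rep(1 / n_clusters, n_clusters)
  if (length(cluster_proportions) != n_clusters)
    stop("cluster_proportions must have length n_clusters")
  if (abs(sum(cluster_proportions) - 1) > 1e-8)
    stop("cluster_proportions must sum to 1")
  if (any(cluster_proportions <= 0)) stop("cluster proportions must be > 0")
  if (n_informative + n_noise < 2) stop("need at least 2 genes in total")
  if (m_cells < n_clusters) stop("m_cells must be >= n_clusters")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  structure(list(m_cells = as.integer(m_cells),
                 n_clusters = as.integer(n_clusters),
                 cluster_proportions = cluster_proportions,
                 n_informative = as.integer(n_informative),
                 n_noise = as.integer(n_noise),
                 effect_size = effect_size, dispersion = dispersion,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "SyntheticConfig")
}

#' Generate a synthetic clustered scRNA-seq dataset
#'
#' Cells are assigned to clusters by the configured proportions (deterministic
#' rounded counts, so every cluster is present). Each gene gets a baseline
#' log-mean mu_j ~ Normal(1, 1) on the normalized-unit scale. Informative gene
#' j additionally gets a cluster-specific log-mean mu_cj ~ Normal(mu_j,
#' effect_size) drawn once per (cluster, gene); noise genes use mu_j for every
#' cell. Expression is exp(Normal(mu, dispersion)) and each entry is then
#' independently zeroed with probability `dropout_rate`. Informative genes are
#' placed at random column positions.
#'
#' The cluster signal lives in the association between cell identity and the
#' informative columns; independently permuting each column destroys exactly
#' this association while preserving per-gene marginals, which is what the
#' real-vs-permuted classifier detects.
#'
#' @param cfg A [synthetic_config()].
#' @return Object of class `SyntheticDataset`: list with `x` (an
#'   [expression_matrix()], unit `"synthetic"`), `truth` (named character
#'   vector of cluster labels), `informative_mask` (named logical vector over
#'   genes), `config`.
#' @export
generate_synthetic <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  m <- cfg$m_cells
  n <- cfg$n_informative + cfg$n_noise
  set.seed(cfg$seed)

  sizes <- diff(c(0L, round(cumsum(cfg$cluster_proportions) * m)))
  if (any(sizes < 1))
    stop("a cluster received no cells; increase m_cells or rebalance proportions")
  cluster <- rep(seq_len(cfg$n_clusters), times = sizes)

  gene_ids <- sprintf("gene%04d", seq_len(n))
  cell_ids <- sprintf("cell%03d", seq_len(m))
  informative <- rep(FALSE, n)
  informative[sample.int(n, cfg$n_informative)] <- TRUE

  mu0 <- stats::rnorm(n, mean = 1, sd = 1)          # baseline log-mean per gene
  # per-cell log-mean matrix
  mu <- matrix(mu0, nrow = m, ncol = n, byrow = TRUE)
  if (cfg$n_informative > 0) {
    shifts <- matrix(stats::rnorm(cfg$n_clusters * cfg$n_informative,
                                  mean = 0, sd = cfg$effect_size),
                     nrow = cfg$n_clusters)
    mu[, informative] <- mu[, informative] + shifts[cluster, , drop = FALSE]
  }
  values <- exp(mu + stats::rnorm(m * n, sd = cfg$dispersion))
  if (cfg$dropout_rate > 0)
    values[stats::runif(m * n) < cfg$dropout_rate] <- 0
  dimnames(values) <- list(cell_ids, gene_ids)

  structure(list(
    x = expression_matrix(values, unit = "synthetic"),
    truth = stats::setNames(paste0("cluster", cluster), cell_ids),
    informative_mask = stats::setNames(informative, gene_ids),
    config = cfg), class = "SyntheticDataset")
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat(sprintf(
    "SyntheticDataset: %d cells x %d genes, %d clusters, %d informative genes\n",
    n_cells(x$x), n_genes(x$x), x$config$n_clusters,
    sum(x$informative_mask)))
  invisible(x)
}

#' F-like diagnostic of the planted cluster signal
#'
#' For each informative gene, on the log1p scale: the variance of the
#' per-cluster means divided by the mean within-cluster variance. Returns the
#' average over informative genes -- a difficulty label for fixtures, near 0
#' when `effect_size = 0` and increasing with it.
#'
#' @param ds A `SyntheticDataset`.
#' @export
planted_signal_strength <- function(ds) {
  stopifnot(inherits(ds, "SyntheticDataset"))
  v <- log1p(ds$x$values[, ds$informative_mask, drop = FALSE])
  cl <- factor(ds$truth)
  ratios <- apply(v, 2, function(g) {
    mns <- tapply(g, cl, mean)
    wv <- tapply(g, cl, stats::var)
    wv_mean <- mean(wv, na.rm = TRUE)
    if (!is.finite(wv_mean) || wv_mean == 0) return(NA_real_)
    stats::var(mns) / wv_mean
  })
  mean(ratios, na.rm = TRUE)
}
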