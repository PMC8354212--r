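test_that("Expr baseline ranks genes by mean log1p expression", {
  v <- cbind(g1 = c(1, 1, 1), g2 = c(50, 60, 70), g3 = c(2, 3, 4))
  rownames(v) <- paste0("c", 1:3)
  x <- expression_matrix(v)
  expect_identical(expr_select(x, 1)$gene_ids, "g2")
  expect_setequal(expr_select(x, 3)$gene_ids, c("g1", "g2", "g3"))
  expect_error(expr_select(x, 0), "k_genes")
  expect_error(expr_select(x, 4), "k_genes")

  # exact tie on means: lexicographically smaller id wins
  vt <- cbind(gB = c(2, 4), gA = c(4, 2), gC = c(0, 0))
  rownames(vt) <- c("c1", "c2")
  expect_identical(expr_select(expression_matrix(vt), 1)$gene_ids, "gA")
})

test_that("Spearman similarity matches the rank-then-Pearson oracle", {
  set.seed(14)
  v <- matrix(rexp(3 * 20), 3, 20)
  x <- make_expr(v)
  s <- spearman_similarity(x)
  oracle <- cor(apply(t(v), 2, rank))
  expect_equal(unname(s), unname(oracle), tolerance = 1e-12)
  expect_true(isSymmetric(s))
  expect_equal(unname(diag(s)), rep(1, 3))

  # duplicated cell and rank-reversed cell
  v2 <- rbind(v[1, ], v[1, ], rev(sort(v[1, ])), sort(v[1, ]))
  s2 <- spearman_similarity(make_expr(v2))
  expect_equal(s2[1, 2], 1)
  expect_equal(s2[3, 4], -1)
})

test_that("zero-variance cells get zero similarity with a warning", {
  v <- rbind(c(1, 2, 3), c(5, 5, 5), c(3, 2, 1))
  expect_warning(s <- spearman_similarity(make_expr(v)), "zero variance")
  expect_equal(unname(s[2, c(1, 3)]), c(0, 0))
  expect_equal(s[2, 2], 1)
})

test_that("hierarchical clustering recovers block structure", {
  m <- 12
  s <- matrix(0.1, m, m)
  s[1:6, 1:6] <- 0.9; s[7:12, 7:12] <- 0.9; diag(s) <- 1
  dimnames(s) <- list(paste0("c", 1:m), paste0("c", 1:m))
  part <- hierarchical_cluster(s, k = 2)
  expect_equal(adjusted_rand_index(part, rep(1:2, each = 6)), 1)
  expect_equal(length(unique(hierarchical_cluster(s, k = m))), m)
  expect_error(hierarchical_cluster(s, k = 1), "k must be")
  s_bad <- s; s_bad[1, 2] <- 0.5
  expect_error(hierarchical_cluster(s_bad, k = 2), "symmetric")
})

test_that("k-means separates well-separated blobs and is deterministic", {
  set.seed(15)
  truth <- rep(1:2, each = 20)
  x <- matrix(rnorm(40 * 3, mean = truth * 10), 40, 3)
  rownames(x) <- paste0("c", 1:40)
  p1 <- kmeans_cluster(x, k = 2, seed = 1)
  expect_equal(adjusted_rand_index(p1, truth), 1)
  expect_identical(p1, kmeans_cluster(x, k = 2, seed = 1))
  # duplicated rows always co-cluster
  xd <- rbind(x, x[1, , drop = FALSE])
  rownames(xd) <- c(rownames(x), "dup")
  pd <- kmeans_cluster(xd, k = 2, seed = 2)
  expect_equal(unname(pd["dup"]), unname(pd["c1"]))
  expect_error(kmeans_cluster(x, k = 1, seed = 1), "k must be")
})

test_that("the repeat protocol is reproducible and averages per-run metrics", {
  ds <- generate_synthetic(synthetic_config(m_cells = 45, n_informative = 12,
                                            n_noise = 18, dropout_rate = 0.1,
                                            seed = 33))
  cfg <- eval_config(k = 3, repeats = 2, seeds = c(5L, 6L))
  r1 <- evaluate_selection(ds$x, ds$truth, "all_genes", cfg)
  r2 <- evaluate_selection(ds$x, ds$truth, "all_genes", cfg)
  expect_identical(r1$per_run, r2$per_run)
  expect_equal(r1$mean_nmi, mean(r1$per_run$nmi))
  expect_equal(r1$mean_ari, mean(r1$per_run$ari))

  expect_error(evaluate_selection(ds$x, ds$truth, "expr", cfg),
               "expr_n_genes")
  re <- evaluate_selection(ds$x, ds$truth, "expr", cfg, expr_n_genes = 10)
  expect_true(all(re$per_run$n_selected == 10))
})

test_that("hclust-based evaluation runs end to end", {
  ds <- generate_synthetic(synthetic_config(m_cells = 45, n_informative = 12,
                                            n_noise = 18, dropout_rate = 0.1,
                                            seed = 34))
  cfg <- eval_config(k = 3, repeats = 1, seeds = 9L, clusterer = "hclust")
  r <- evaluate_selection(ds$x, ds$truth, "all_genes", cfg)
  expect_false(any(r$per_run$failed))
  expect_true(r$mean_nmi >= 0 && r$mean_nmi <= 1)
})

test_that("selector comparison size-matches the Expr baseline", {
  ds <- generate_synthetic(synthetic_config(m_cells = 40, n_informative = 10,
                                            n_noise = 20, dropout_rate = 0.1,
                                            seed = 35))
  cmp <- compare_selectors(ds$x, ds$truth,
                           eval_config(k = 3, repeats = 2, base_seed = 4),
                           forest_config(n_trees = 60))
  n_rf <- round(mean(cmp$rfcell$per_run$n_selected))
  expect_true(all(cmp$expr$per_run$n_selected == n_rf))
  expect_true(all(cmp$all_genes$per_run$n_selected == 30))
})
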