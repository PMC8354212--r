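test_that("a label-copy feature yields near-perfect OOB vote accuracy", {
  set.seed(2)
  labels <- rep(c(0L, 1L), each = 30)
  feats <- cbind(labels + rnorm(60, sd = 0.05), matrix(rnorm(60 * 4), 60))
  ts <- make_training_set(abs(feats), labels)
  model <- fit_forest(ts, forest_config(n_trees = 100, seed = 2))
  expect_gte(model$oob_vote_accuracy, 0.95)
})

test_that("unpaired pure-noise features give chance-level OOB vote accuracy", {
  accs <- vapply(1:5, function(s) {
    set.seed(s)
    ts <- make_training_set(matrix(abs(rnorm(200 * 10)), 200),
                            rep(c(0L, 1L), each = 100))
    fit_forest(ts, forest_config(n_trees = 200, seed = s))$oob_vote_accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("forest fitting and MDA are deterministic in the seed", {
  x <- make_expr(matrix(rexp(30 * 8), 30, 8))
  # structureless data may legitimately select nothing; only determinism matters
  suppressWarnings({
    r1 <- rfcell_select(x, forest_config(n_trees = 60, seed = 5))
    r2 <- rfcell_select(x, forest_config(n_trees = 60, seed = 5))
  })
  expect_identical(r1$report$mda, r2$report$mda)
  expect_identical(r1$gene_set, r2$gene_set)

  ts <- build_training_set(x, seed = 9)
  m1 <- fit_forest(ts, forest_config(n_trees = 60, seed = 9))
  m2 <- fit_forest(ts, forest_config(n_trees = 60, seed = 9))
  expect_identical(m1$rf$inbag, m2$rf$inbag)
})

test_that("degenerate inputs are rejected", {
  one_cell <- make_expr(matrix(c(1, 2, 3), 1, 3))
  expect_error(rfcell_select(one_cell, forest_config(n_trees = 10)),
               "at least 2 cells")
  ts <- make_training_set(matrix(runif(20), 10), rep(1L, 10))
  expect_error(fit_forest(ts, forest_config(n_trees = 10)), "single-class")
  expect_error(forest_config(n_trees = 0), "n_trees")
})

test_that("constant genes have MDA exactly zero and are never selected", {
  set.seed(3)
  labels <- rep(c(0L, 1L), each = 25)
  feats <- cbind(labels + rnorm(50, sd = 0.1),   # informative
                 rep(2.5, 50),                    # constant
                 rnorm(50))                       # noise
  ts <- make_training_set(abs(feats) + 0.1, labels)
  model <- fit_forest(ts, forest_config(n_trees = 80, seed = 3))
  rep_ <- compute_mda(model, ts, seed = 4)
  expect_identical(unname(rep_$mda["g2"]), 0)
  gs <- select_genes(rep_)
  expect_false("g2" %in% gs$gene_ids)
})

test_that("a single discriminative gene gets the top positive MDA", {
  set.seed(6)
  labels <- rep(c(0L, 1L), each = 40)
  feats <- cbind(matrix(abs(rnorm(80 * 6)), 80), labels + runif(80, 0, 0.3))
  ts <- make_training_set(feats, labels)
  model <- fit_forest(ts, forest_config(n_trees = 150, seed = 6))
  rep_ <- compute_mda(model, ts, seed = 7)
  expect_equal(names(which.max(rep_$mda)), "g7")
  expect_gt(rep_$mda["g7"], 0)
})

test_that("our per-tree OOB MDA agrees with randomForest's importance", {
  # independent cross-check: same fitted forest, library's own raw
  # MeanDecreaseAccuracy (different internal permutation draws, so agreement
  # is statistical, not bitwise)
  set.seed(8)
  labels <- rep(c(0L, 1L), each = 50)
  feats <- cbind(labels + rnorm(100, sd = 0.5),
                 labels * 2 + rnorm(100, sd = 1),
                 matrix(rnorm(100 * 8), 100))
  ts <- make_training_set(abs(feats) + 0.01, labels)
  model <- fit_forest(ts, forest_config(n_trees = 300, seed = 8))
  ours <- compute_mda(model, ts, seed = 9)$raw_mda
  theirs <- randomForest::importance(model$rf, type = 1, scale = FALSE)[, 1]
  expect_gt(cor(ours, theirs), 0.95)
  expect_lt(max(abs(ours - theirs)), 0.05)
})

test_that("MDA>0 selection rule is strict with lexicographic ties", {
  mk_report <- function(mda) {
    structure(list(mda = mda, raw_mda = mda,
                   mda_se = rep(1, length(mda)),
                   per_tree_oob_accuracy = 0.5, oob_accuracy = 0.5,
                   forest_vote_accuracy = 0.5, n_trees_used = 10L,
                   config = forest_config(n_trees = 10)),
              class = "ImportanceReport")
  }
  r <- mk_report(c(gene1 = 0.02, gene2 = -0.01, gene3 = 0.0))
  expect_identical(select_genes(r)$gene_ids, "gene1")

  r0 <- mk_report(c(gene1 = -0.1, gene2 = 0.0))
  expect_warning(gs <- select_genes(r0), "no gene")
  expect_length(gs, 0)

  rt <- mk_report(c(gB = 0.5, gA = 0.5, gC = 0.5))
  expect_identical(select_genes(rt)$gene_ids, c("gA", "gB", "gC"))
})

test_that("scaling MDA never changes which genes are selected (SE > 0)", {
  x <- make_expr(matrix(rexp(40 * 10), 40, 10))
  raw_cfg <- forest_config(n_trees = 80, seed = 12, scale_mda = FALSE)
  sc_cfg <- forest_config(n_trees = 80, seed = 12, scale_mda = TRUE)
  r_raw <- rfcell_select(x, raw_cfg)$report
  r_sc <- rfcell_select(x, sc_cfg)$report
  nz <- r_raw$mda_se > .Machine$double.eps
  expect_identical(sign(r_raw$mda[nz]), sign(r_sc$mda[nz]))
  expect_setequal(names(r_raw$mda)[nz][r_raw$mda[nz] > 0],
                  names(r_sc$mda)[nz][r_sc$mda[nz] > 0])
})

test_that("MDA ranking recovers planted genes when per-gene structure is crisp", {
  # same 50/950 informative split as the default benchmark but with tight
  # within-cluster spread and no dropout: the permutation contrast is then
  # easy for the forest, and the ranking should be near-perfect
  ds <- generate_synthetic(synthetic_config(dispersion = 0.3,
                                            dropout_rate = 0, seed = 17))
  res <- rfcell_select(ds$x, forest_config(n_trees = 500, seed = 17))
  expect_gte(auroc(res$report$mda, ds$informative_mask), 0.9)
})
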