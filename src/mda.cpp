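#include <Rcpp.h>
using namespace Rcpp;

// Route one row down tree t; if gene `perm_gene` >= 0, its value is taken
// from `perm_val` instead of the matrix.
static inline int predict_row(const NumericMatrix& x, int row, int t,
                              const IntegerMatrix& nodestatus,
                              const IntegerMatrix& bestvar,
                              const NumericMatrix& xbestsplit,
                              const IntegerMatrix& nodepred,
                              const IntegerMatrix& left,
                              const IntegerMatrix& right,
                              int perm_gene, double perm_val) {
  int k = 0;
  while (nodestatus(k, t) != -1) {  // -1 marks a terminal node
    int v = bestvar(k, t) - 1;
    double val = (v == perm_gene) ? perm_val : x(row, v);
    k = (val <= xbestsplit(k, t)) ? left(k, t) - 1 : right(k, t) - 1;
  }
  return nodepred(k, t);
}

// Per-tree out-of-bag permutation importance (mean decrease accuracy).
// For each tree: baseline OOB accuracy, then for each gene permute that
// gene's values within the tree's OOB rows (R RNG; seed set by the caller)
// and record the accuracy drop. Returns per-gene mean and SD of the drops
// over trees, per-tree baseline accuracies, and the number of trees skipped
// for having an empty OOB set.
// [[Rcpp::export(name = ".mda_cpp")]]
List mda_cpp(const NumericMatrix& x, const IntegerVector& y_class,
             const IntegerMatrix& inbag,
             const IntegerVector& ndbigtree,
             const IntegerMatrix& nodestatus,
             const IntegerMatrix& bestvar,
             const NumericMatrix& xbestsplit,
             const IntegerMatrix& nodepred,
             const IntegerMatrix& left,
             const IntegerMatrix& right) {
  const int n_rows = x.nrow(), n_genes = x.ncol(), n_trees = ndbigtree.size();
  NumericVector d_sum(n_genes), d_sumsq(n_genes);
  NumericVector tree_acc(n_trees, NA_REAL);
  int used = 0, skipped = 0;

  std::vector<int> oob;
  oob.reserve(n_rows);
  std::vector<int> base_pred(n_rows);
  std::vector<double> perm_vals;

  for (int t = 0; t < n_trees; ++t) {
    oob.clear();
    for (int i = 0; i < n_rows; ++i)
      if (inbag(i, t) == 0) oob.push_back(i);
    const int n_oob = (int) oob.size();
    if (n_oob == 0) { ++skipped; continue; }
    ++used;

    int correct = 0;
    for (int u = 0; u < n_oob; ++u) {
      int p = predict_row(x, oob[u], t, nodestatus, bestvar, xbestsplit,
                          nodepred, left, right, -1, 0.0);
      base_pred[u] = p;
      if (p == y_class[oob[u]]) ++correct;
    }
    const double a_t = (double) correct / n_oob;
    tree_acc[t] = a_t;

    perm_vals.resize(n_oob);
    for (int j = 0; j < n_genes; ++j) {
      // Fisher-Yates over the OOB values of gene j
      for (int u = 0; u < n_oob; ++u) perm_vals[u] = x(oob[u], j);
      for (int u = n_oob - 1; u > 0; --u) {
        int w = (int) (unif_rand() * (u + 1));
        if (w > u) w = u;
        std::swap(perm_vals[u], perm_vals[w]);
      }
      int correct_j = 0;
      for (int u = 0; u < n_oob; ++u) {
        int p = predict_row(x, oob[u], t, nodestatus, bestvar, xbestsplit,
                            nodepred, left, right, j, perm_vals[u]);
        if (p == y_class[oob[u]]) ++correct_j;
      }
      const double d = a_t - (double) correct_j / n_oob;
      d_sum[j] += d;
      d_sumsq[j] += d * d;
    }
  }

  if (used == 0) stop("every tree had an empty out-of-bag set");

  NumericVector mda(n_genes), sd(n_genes);
  for (int j = 0; j < n_genes; ++j) {
    const double mean = d_sum[j] / used;
    mda[j] = mean;
    sd[j] = used > 1
      ? std::sqrt(std::max(0.0, (d_sumsq[j] - used * mean * mean) / (used - 1)))
      : 0.0;
  }
  return List::create(_["mda"] = mda, _["sd"] = sd,
                      _["tree_accuracy"] = tree_acc,
                      _["n_trees_used"] = used, _["n_trees_skipped"] = skipped);
}
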