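#' Column-permuted negative cells
#'
#' Builds the negative-sample matrix Z: each gene column of the real matrix is
#' independently and uniformly permuted. Per-gene marginal distributions are
#' preserved exactly (each column of Z is a rearrangement of the same values),
#' while gene-gene structure tied to cell identity is destroyed -- this is
#' what makes real cells separable from negatives by a classifier.
#'
#' Permutations are drawn column by column from a single seeded RNG stream, so
#' results are deterministic given `seed` but not stable under column
#' reordering of the input.
#'
#' @param x An [expression_matrix()].
#' @param seed Integer RNG seed.
#' @param shared_permutation If `TRUE`, apply one shared row permutation to
#'   every column instead of independent per-column shuffles. This preserves
#'   inter-gene structure (the negatives are then just reordered real cells)
#'   and exists only for comparison experiments; the default `FALSE` is the
#'   method.
#' @return m x n numeric matrix of negative cells, gene columns named, row
#'   names prefixed `"neg:"`.
#' @export
permute_columns <- function(x, seed, shared_permutation = FALSE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  m <- n_cells(x)
  if (m < 2)
    stop("need at least 2 cells to permute (m = ", m, ")")
  v <- x$values
  set.seed(as.integer(seed))
  if (shared_permutation) {
    z <- v[sample.int(m), , drop = FALSE]
  } else {
    z <- v
    for (j in seq_len(ncol(v))) z[, j] <- v[sample.int(m), j]
  }
  dimnames(z) <- list(paste0("neg:", x$cell_ids), x$gene_ids)
  z
}

#' Assemble the real-vs-permuted training set
#'
#' Stacks the real matrix X on top of its column-permuted copy Z and attaches
#' binary labels: the first m rows (real cells) are labeled 1, the last m
#' (negatives) 0. For every gene the multiset of values in the negative half
#' equals that in the real half.
#'
#' @inheritParams permute_columns
#' @return Object of class `TrainingSet`: list with `features` (2m x n
#'   matrix), `labels` (integer 0/1, length 2m), `gene_ids`, `seed`.
#' @examples
#' v <- matrix(runif(12), 3, 4,
#'             dimnames = list(paste0("c", 1:3), paste0("g", 1:4)))
#' ts <- build_training_set(expression_matrix(v), seed = 1)
#' dim(ts$features)  # 6 x 4
#' ts$labels         # 1 1 1 0 0 0
#' @export
build_training_set <- function(x, seed, shared_permutation = FALSE) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  z <- permute_columns(x, seed = seed, shared_permutation = shared_permutation)
  m <- n_cells(x)
  ts <- structure(
    list(features = rbind(x$values, z),
         labels = rep(c(1L, 0L), each = m),
         gene_ids = x$gene_ids,
         seed = as.integer(seed)),
    class = "TrainingSet")
  ts
}

#' @export
print.TrainingSet <- function(x, ...) {
  cat(sprintf("TrainingSet: %d rows (%d real + %d permuted) x %d genes, seed %d\n",
              nrow(x$features), sum(x$labels == 1L), sum(x$labels == 0L),
              ncol(x$features), x$seed))
  invisible(x)
}
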