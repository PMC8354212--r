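# Independent brute-force oracles for the agreement statistics. These work
# from first principles (explicit sums, exhaustive pair enumeration) and never
# touch the package's contingency-based implementations.

bf_entropy <- function(p) {
  f <- as.numeric(table(as.character(p))) / length(p)
  f <- f[f > 0]
  -sum(f * log(f))
}

bf_mutual_information <- function(p1, p2) {
  m <- length(p1)
  acc <- 0
  for (a in unique(p1)) {
    for (b in unique(p2)) {
      pxy <- sum(p1 == a & p2 == b) / m
      if (pxy > 0) {
        px <- sum(p1 == a) / m
        py <- sum(p2 == b) / m
        acc <- acc + pxy * log(pxy / (px * py))
      }
    }
  }
  acc
}

bf_nmi <- function(p1, p2) {
  2 * bf_mutual_information(p1, p2) / (bf_entropy(p1) + bf_entropy(p2))
}

# exhaustive enumeration over all unordered pairs
bf_pair_counts <- function(p1, p2) {
  m <- length(p1)
  a <- b <- cc <- d <- 0L
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      same1 <- p1[i] == p1[j]
      same2 <- p2[i] == p2[j]
      if (same1 && same2) a <- a + 1L
      else if (!same1 && !same2) b <- b + 1L
      else if (same1) cc <- cc + 1L
      else d <- d + 1L
    }
  }
  list(a = a, b = b, c = cc, d = d)
}

bf_rand_index <- function(p1, p2) {
  pc <- bf_pair_counts(p1, p2)
  (pc$a + pc$b) / (pc$a + pc$b + pc$c + pc$d)
}

# chance-corrected pair agreement from enumerated pair counts
bf_adjusted_rand_index <- function(p1, p2) {
  pc <- bf_pair_counts(p1, p2)
  total <- pc$a + pc$b + pc$c + pc$d
  sum_i <- pc$a + pc$c
  sum_j <- pc$a + pc$d
  e <- sum_i * sum_j / total
  mx <- (sum_i + sum_j) / 2
  (pc$a - e) / (mx - e)
}

random_partition <- function(m, k_max = 5) {
  sample.int(sample(2:k_max, 1), m, replace = TRUE)
}

make_expr <- function(v, cells = NULL, genes = NULL, unit = "test") {
  if (is.null(cells)) cells <- paste0("c", seq_len(nrow(v)))
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(v)))
  dimnames(v) <- list(cells, genes)
  expression_matrix(v, unit = unit)
}

# hand-built training set (container use only; not via permutation)
make_training_set <- function(features, labels, seed = 0L) {
  colnames(features) <- paste0("g", seq_len(ncol(features)))
  rownames(features) <- paste0("r", seq_len(nrow(features)))
  structure(list(features = features, labels = as.integer(labels),
                 gene_ids = colnames(features), seed = as.integer(seed)),
            class = "TrainingSet")
}
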