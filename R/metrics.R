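#' Contingency table of two partitions
#'
#' Entry (i, j) counts the cells placed in cluster i of `p1` and cluster j of
#' `p2`. Basis for all agreement statistics in the package.
#'
#' @param p1,p2 Vectors of cluster labels (any atomic type), equal length.
#' @return Integer matrix with row/column names taken from the labels.
#' @export
contingency <- function(p1, p2) {
  if (length(p1) != length(p2))
    stop("partitions have different lengths (", length(p1), " vs ",
         length(p2), ")")
  if (length(p1) < 1) stop("partitions are empty")
  unclass(table(as.character(p1), as.character(p2)))
}

#' Entropy of a partition (nats)
#'
#' H = -sum_i (m_i/m) log(m_i/m) over cluster sizes m_i, with 0 log 0 := 0.
#' Natural logarithm throughout.
#'
#' @param p Vector of cluster labels.
#' @export
partition_entropy <- function(p) {
  if (length(p) < 1) stop("partition is empty")
  f <- as.numeric(table(as.character(p))) / length(p)
  f <- f[f > 0]
  -sum(f * log(f))
}

#' Mutual information between two partitions (nats)
#'
#' I = sum_ij (n_ij/m) log[(n_ij/m) / ((n_i/m)(n_j/m))]; zero-count cells
#' contribute 0.
#'
#' @inheritParams contingency
#' @export
mutual_information <- function(p1, p2) {
  ct <- contingency(p1, p2)
  m <- sum(ct)
  pij <- ct / m
  pi_ <- rowSums(ct) / m
  p_j <- colSums(ct) / m
  outer_p <- outer(pi_, p_j)
  nz <- pij > 0
  max(0, sum(pij[nz] * log(pij[nz] / outer_p[nz])))
}

#' Normalized mutual information
#'
#' NMI = 2 I(p1, p2) / (H(p1) + H(p2)), in `[0, 1]`; 1 means the partitions
#' are identical up to relabeling. When both partitions are single-cluster
#' (H(p1) + H(p2) = 0, a 0/0 case) the convention is: 1 if they are identical
#' up to relabeling, else 0 -- with both entropies zero the partitions are
#' necessarily both trivial, so 1 is returned.
#'
#' @inheritParams contingency
#' @export
nmi <- function(p1, p2) {
  h1 <- partition_entropy(p1)
  h2 <- partition_entropy(p2)
  if (h1 + h2 == 0) {
    return(if (identical_up_to_relabeling(p1, p2)) 1 else 0)
  }
  val <- 2 * mutual_information(p1, p2) / (h1 + h2)
  min(1, max(0, val))
}

identical_up_to_relabeling <- function(p1, p2) {
  ct <- contingency(p1, p2)
  sum(ct > 0) == max(nrow(ct), ncol(ct)) &&
    all(rowSums(ct > 0) == 1) && all(colSums(ct > 0) == 1)
}

#' Pair concordance counts between two partitions
#'
#' Over all m(m-1)/2 unordered cell pairs: `a` pairs together in both
#' partitions, `b` apart in both, `c` together in the first only, `d`
#' together in the second only. Computed from contingency-table identities;
#' equal to exhaustive enumeration.
#'
#' @inheritParams contingency
#' @return List with integers `a`, `b`, `c`, `d` (a + b + c + d = C(m, 2)).
#' @export
pair_counts <- function(p1, p2) {
  m <- length(p1)
  if (m < 2) stop("need at least 2 elements to form pairs")
  ct <- contingency(p1, p2)
  total <- choose(m, 2)
  a <- sum(choose(ct, 2))
  sum_i <- sum(choose(rowSums(ct), 2))
  sum_j <- sum(choose(colSums(ct), 2))
  cc <- sum_i - a
  dd <- sum_j - a
  list(a = a, b = total - a - cc - dd, c = cc, d = dd)
}

#' Rand index
#'
#' RI = (a + b) / C(m, 2): the fraction of cell pairs on which the two
#' partitions agree (together in both, or apart in both).
#'
#' @inheritParams contingency
#' @export
rand_index <- function(p1, p2) {
  pc <- pair_counts(p1, p2)
  (pc$a + pc$b) / choose(length(p1), 2)
}

#' Adjusted Rand index
#'
#' Chance-corrected pair agreement:
#' ARI = (Index - E) / (Max - E) with Index = sum_ij C(n_ij, 2),
#' E = sum_i C(n_i, 2) sum_j C(n_j, 2) / C(m, 2), and
#' Max = (sum_i C(n_i, 2) + sum_j C(n_j, 2)) / 2.
#' When Max = E (both partitions trivial: all-singletons or single-cluster)
#' the formula is 0/0; the convention is 1 if the partitions are identical up
#' to relabeling, else 0.
#'
#' @inheritParams contingency
#' @export
adjusted_rand_index <- function(p1, p2) {
  m <- length(p1)
  if (m < 2) stop("need at least 2 elements to form pairs")
  ct <- contingency(p1, p2)
  index <- sum(choose(ct, 2))
  sum_i <- sum(choose(rowSums(ct), 2))
  sum_j <- sum(choose(colSums(ct), 2))
  e <- sum_i * sum_j / choose(m, 2)
  mx <- (sum_i + sum_j) / 2
  if (mx == e) {
    return(if (identical_up_to_relabeling(p1, p2)) 1 else 0)
  }
  (index - e) / (mx - e)
}
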