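#' Area under the ROC curve by rank statistic
#'
#' Mann-Whitney formulation: the probability that a randomly chosen positive
#' scores higher than a randomly chosen negative, with ties counting 1/2.
#'
#' @param scores Numeric vector.
#' @param positive Logical vector aligned to `scores` (TRUE = positive class).
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, positive) {
  positive <- as.logical(positive)
  stopifnot(length(scores) == length(positive))
  n_pos <- sum(positive)
  n_neg <- sum(!positive)
  if (n_pos == 0L || n_neg == 0L)
    stop("auroc needs both positive and negative examples")
  r <- rank(scores)  # average ranks for ties
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Derive k reproducible sub-seeds from one master seed. Used to give the
# permutation, forest and MDA stages independent RNG streams.
derive_seeds <- function(seed, k) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, k)
}
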