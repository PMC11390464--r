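#' @keywords internal
sigmoid <- function(x) 1 / (1 + exp(-x))

#' @keywords internal
lrelu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)

#' @keywords internal
lrelu_grad <- function(x, slope = 0.2) ifelse(x > 0, 1, slope)

# Row-wise softmax with max subtraction (shift-invariant, overflow-safe).
#' @keywords internal
softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

#' @keywords internal
softmax_vec <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Row-normalize a nonnegative matrix; all-zero rows are left at zero.
#' @keywords internal
row_normalize <- function(A) {
  rs <- rowSums(A)
  A / ifelse(rs > 0, rs, 1)
}

#' @keywords internal
frobenius <- function(A) sqrt(sum(A^2))

# Deterministic per-item seed derived from a base seed and a counter, so a
# dataset is reproducible regardless of generation order. Kept below 2^31.
#' @keywords internal
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + counter * 16807 + 12345) %%
    2147483647)
}

# Rank-based (Mann-Whitney) AUC: probability a random positive scores above a
# random negative, ties counted 1/2. Used for graph-recovery scoring; the
# evaluation module's per-class AUROC goes through pROC instead.
#' @keywords internal
rank_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}
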