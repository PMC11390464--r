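# Joint objective: focal prediction loss plus Laplacian smoothness, degree
# and sparsity graph regularizers.

#' Focal loss of one prediction
#'
#' \code{-alpha_y (1 - p_y)^gamma log(p_y)}; \code{gamma = 0} with unit
#' weights recovers cross-entropy. Probabilities are clamped at 1e-12
#' inside the log.
#'
#' @param p Class probability vector (or matrix, one row per sample).
#' @param y True class index (1-based; vector for a batch).
#' @param alpha Per-class weight vector (recycled scalar allowed).
#' @param gamma Focusing exponent >= 0.
#' @return Scalar loss (mean over samples for a batch).
#' @export
focal_loss <- function(p, y, alpha = 1, gamma = 2) {
  stopifnot(gamma >= 0)
  p <- rbind(p)
  py <- pmax(p[cbind(seq_len(nrow(p)), y)], 1e-12)
  a <- if (length(alpha) > 1) alpha[y] else alpha
  mean(-a * (1 - py)^gamma * log(py))
}

#' Inverse-frequency class weights
#'
#' Reciprocal class counts, rescaled so the weights sum to the number of
#' classes (keeping the loss magnitude comparable to unweighted
#' cross-entropy while preserving the weight ratios).
#'
#' @param counts Per-class sample counts, all > 0.
#' @return Weight vector alpha of the same length.
#' @export
class_weights <- function(counts) {
  if (any(counts <= 0)) stop("weight error: every class count must be > 0")
  a <- 1 / counts
  a * length(a) / sum(a)
}

#' Laplacian smoothness loss
#'
#' \code{(1 / 2n^2) sum_ij A_ij ||x_i - x_j||^2}, equal to
#' \code{(1 / n^2) trace(X' L X)} with the combinatorial Laplacian
#' \code{L = D - A} when A is symmetric. Penalizes feature differences
#' across strongly connected nodes.
#'
#' @param A Nonnegative adjacency, n x n.
#' @param X Node feature matrix, n x F.
#' @return Scalar >= 0 for symmetric A.
#' @export
smoothness_loss <- function(A, X) {
  n <- nrow(A)
  sq <- rowSums(X^2)
  # sum_ij A_ij ||x_i - x_j||^2 = sum_ij A_ij (|x_i|^2 + |x_j|^2) - 2 tr(X' A X)
  (sum(A * outer(sq, rep(1, n))) + sum(A * outer(rep(1, n), sq)) -
     2 * sum(X * (A %*% X))) / (2 * n^2)
}

#' Degree regularization loss
#'
#' \code{-(beta / n) 1' log(A 1)}: the negative mean log row degree,
#' penalizing near-isolated nodes. Row sums are floored at 1e-12.
#'
#' @param A Nonnegative adjacency.
#' @param beta Weight >= 0.
#' @return Scalar.
#' @export
degree_loss <- function(A, beta) {
  n <- nrow(A)
  -(beta / n) * sum(log(pmax(rowSums(A), 1e-12)))
}

#' Sparsity regularization loss
#'
#' \code{(theta / n^2) ||A||_F^2}.
#'
#' @param A Adjacency.
#' @param theta Weight >= 0.
#' @return Scalar >= 0.
#' @export
sparsity_loss <- function(A, theta) {
  theta * sum(A^2) / nrow(A)^2
}

#' Assemble the joint loss breakdown
#'
#' \code{L_G = omega L_smooth + L_degree + L_sparsity} and
#' \code{L_total = L_pred + L_G} (exact identities).
#'
#' @param L_pred Prediction (focal) loss.
#' @param L_smooth,L_degree,L_sparsity Graph regularizer values.
#' @param omega Smoothness weight.
#' @return List with all components, \code{L_G} and \code{L_total}.
#' @export
joint_loss <- function(L_pred, L_smooth, L_degree, L_sparsity, omega) {
  L_G <- omega * L_smooth + L_degree + L_sparsity
  list(L_pred = L_pred, L_smooth = L_smooth, L_degree = L_degree,
       L_sparsity = L_sparsity, L_G = L_G, L_total = L_pred + L_G)
}
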