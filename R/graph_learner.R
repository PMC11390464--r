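# Iterative graph structure learning: multi-head attention similarity
# metric, softmax normalization, head aggregation, mixing with the anchor
# graph, and the convergence test. The weighted-cosine metric of the
# original iterative-deep-graph-learning formulation is included as a
# comparison variant.

#' Initialize attention parameters
#'
#' Per head k: an elementwise feature weight vector \code{w^k} and the two
#' halves \code{aL^k}, \code{aR^k} of the learned linear score map applied
#' to the concatenated weighted pair features, so
#' \code{e_ij = aL . (w \* h_i) + aR . (w \* h_j)}.
#'
#' @param K Number of heads.
#' @param dim Feature dimension the heads attend on.
#' @param init_sd Spread of the score-map initialization.
#' @return List with K x dim matrices \code{w}, \code{aL}, \code{aR}.
#' @export
attention_params <- function(K, dim, init_sd = 1 / sqrt(dim)) {
  stopifnot(K >= 1, dim >= 1)
  list(w = matrix(stats::rnorm(K * dim, mean = 1, sd = 0.1), K, dim),
       aL = matrix(stats::rnorm(K * dim, sd = init_sd), K, dim),
       aR = matrix(stats::rnorm(K * dim, sd = init_sd), K, dim))
}

#' Raw attention scores of one head
#'
#' @param H Node feature (or embedding) matrix, C x dim.
#' @param params Attention parameter list (see
#'   \code{\link{attention_params}}).
#' @param k Head index.
#' @return C x C matrix of raw scores \code{e^k} over all ordered pairs
#'   (dense neighborhood).
#' @export
attention_scores <- function(H, params, k) {
  if (ncol(H) != ncol(params$w)) {
    stop("parameter error: feature dimension ", ncol(H),
         " does not match attention parameters (", ncol(params$w), ")")
  }
  U <- sweep(H, 2L, params$w[k, ], `*`)
  s1 <- drop(U %*% params$aL[k, ])
  s2 <- drop(U %*% params$aR[k, ])
  outer(s1, rep(1, nrow(H))) + outer(rep(1, nrow(H)), s2)
}

#' Softmax normalization of attention scores
#'
#' \code{a_ij = exp(LReLU(e_ij)) / sum_j exp(LReLU(e_ij))} with row-wise
#' max subtraction (the result is invariant to adding a constant per row).
#'
#' @param e Raw score matrix.
#' @param slope LeakyReLU negative slope (default 0.2).
#' @return Row-stochastic matrix with entries in (0, 1].
#' @export
normalize_attention <- function(e, slope = 0.2) {
  stopifnot(all(is.finite(e)))
  softmax_rows(lrelu(e, slope))
}

#' Aggregate per-head attention matrices
#'
#' @param heads List of K same-shaped row-stochastic matrices.
#' @return Their elementwise mean (row-stochastic when every head is).
#' @export
aggregate_heads <- function(heads) {
  stopifnot(length(heads) >= 1)
  Reduce(`+`, heads) / length(heads)
}

#' Weighted-cosine similarity graph (comparison variant)
#'
#' \code{s_ij = (1/Q) sum_p cos(w_p \* v_i, w_p \* v_j)}; negative values
#' are clipped to 0 so the result can serve as an adjacency.
#'
#' @param H Node feature matrix, C x dim.
#' @param w Q x dim matrix of per-head weight vectors.
#' @param clip Clip negatives to zero (default TRUE).
#' @return C x C similarity matrix.
#' @export
cosine_similarity_graph <- function(H, w, clip = TRUE) {
  w <- rbind(w)
  C <- nrow(H)
  S <- matrix(0, C, C)
  for (p in seq_len(nrow(w))) {
    U <- sweep(H, 2L, w[p, ], `*`)
    nrm <- sqrt(rowSums(U^2))
    if (any(nrm <= 0)) {
      stop("similarity undefined error: zero-norm weighted feature vector")
    }
    S <- S + (U %*% t(U)) / outer(nrm, nrm)
  }
  S <- S / nrow(w)
  if (clip) S[S < 0] <- 0
  S
}

#' Mix learned, first-iteration and anchor graphs
#'
#' The iterative structure update
#' \code{A~ = lambda L0 + (1 - lambda) (eta f(A_m) + (1 - eta) f(A_1))},
#' where \code{f} is row normalization (or symmetric degree normalization)
#' and \code{L0} is used as given (already normalized).
#'
#' @param A_m Learned adjacency of the current iteration.
#' @param A_1 Learned adjacency of the first iteration.
#' @param L0 Normalized anchor adjacency.
#' @param lambda,eta Mixing weights in [0, 1].
#' @param mix_norm \code{"row"} (default) or \code{"sym"}.
#' @return Mixed adjacency of the same shape.
#' @export
mix_graphs <- function(A_m, A_1, L0, lambda, eta, mix_norm = c("row", "sym")) {
  mix_norm <- match.arg(mix_norm)
  stopifnot(lambda >= 0, lambda <= 1, eta >= 0, eta <= 1)
  f <- if (mix_norm == "row") row_normalize else normalize_adjacency
  lambda * L0 + (1 - lambda) * (eta * f(A_m) + (1 - eta) * f(A_1))
}

#' Graph convergence test
#'
#' True when the relative Frobenius change
#' \code{||A_m - A_prev||_F / ||A_m||_F} drops below \code{delta}
#' (strict inequality, so \code{delta = 0} never converges).
#'
#' @param A_m,A_prev Consecutive learned adjacencies.
#' @param delta Relative tolerance.
#' @return Logical scalar.
#' @export
graph_converged <- function(A_m, A_prev, delta) {
  nrm <- frobenius(A_m)
  if (nrm == 0) stop("convergence-undefined error: all-zero adjacency")
  frobenius(A_m - A_prev) / nrm < delta
}
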