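# Gated graph propagation: GRU-style update of node states over the
# current adjacency, with tied weights across propagation steps, and a
# permutation-invariant classification readout.

#' Initialize gated-propagator parameters
#'
#' Square hidden x hidden recurrence matrices for the update gate (Wz, Uz),
#' reset gate (Wr, Ur) and candidate state (Wh, Uh), plus one bias vector
#' broadcast across nodes. Glorot-uniform initialization.
#'
#' @param hidden_size Hidden width.
#' @return List of class \code{ggnn_params}.
#' @export
ggnn_params <- function(hidden_size) {
  g <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  structure(list(Wz = g(hidden_size, hidden_size), Uz = g(hidden_size, hidden_size),
                 Wr = g(hidden_size, hidden_size), Ur = g(hidden_size, hidden_size),
                 Wh = g(hidden_size, hidden_size), Uh = g(hidden_size, hidden_size),
                 b = numeric(hidden_size)),
            class = "ggnn_params")
}

#' One gated propagation step
#'
#' Node states are rows. The step computes the aggregated message
#' \code{a = A' H + b}, the update and reset gates
#' \code{z = sigma(a Wz + H Uz)}, \code{r = sigma(a Wr + H Ur)}, the
#' candidate \code{htil = tanh(a Wh + (r \* H) Uh)}, and the convex
#' combination \code{H' = (1 - z) \* H + z \* htil}.
#'
#' @param H Node state matrix, C x hidden.
#' @param A Adjacency, C x C (the current mixed graph).
#' @param params A \code{ggnn_params} list.
#' @param cache Return intermediate gates for backpropagation.
#' @return Updated C x hidden state matrix (with attributes when
#'   \code{cache}).
#' @export
propagate_step <- function(H, A, params, cache = FALSE) {
  if (!all(is.finite(H)) || !all(is.finite(A))) {
    stop("numeric error: non-finite propagation input")
  }
  a <- t(A) %*% H + matrix(params$b, nrow(H), length(params$b), byrow = TRUE)
  z <- sigmoid(a %*% params$Wz + H %*% params$Uz)
  r <- sigmoid(a %*% params$Wr + H %*% params$Ur)
  htil <- tanh(a %*% params$Wh + (r * H) %*% params$Uh)
  Hn <- (1 - z) * H + z * htil
  if (cache) {
    attr(Hn, "cache") <- list(a = a, z = z, r = r, htil = htil, H_prev = H)
  }
  Hn
}

#' Run several tied propagation steps
#'
#' @param H0 Initial node states (input features after projection to the
#'   hidden width), C x hidden.
#' @param A Adjacency, C x C.
#' @param params A \code{ggnn_params} list shared by every step.
#' @param T_prop Number of steps (>= 1).
#' @param cache Keep per-step caches for backpropagation.
#' @return Final state matrix; with \code{cache}, attribute \code{"steps"}
#'   holds the per-step caches.
#' @export
propagate <- function(H0, A, params, T_prop = 2L, cache = FALSE) {
  stopifnot(T_prop >= 1L)
  H <- H0
  steps <- vector("list", T_prop)
  for (t in seq_len(T_prop)) {
    H <- propagate_step(H, A, params, cache = cache)
    if (cache) {
      steps[[t]] <- attr(H, "cache")
      attr(H, "cache") <- NULL
    }
  }
  if (cache) attr(H, "steps") <- steps
  H
}

#' Classification readout
#'
#' Mean-pool over nodes, linear map, softmax. Permutation-invariant in the
#' node order.
#'
#' @param H Final node states, C x hidden.
#' @param W hidden x n_classes weight matrix.
#' @param b Length-n_classes bias.
#' @return Probability vector summing to 1.
#' @export
readout <- function(H, W, b) {
  pooled <- colMeans(H)
  softmax_vec(drop(pooled %*% W) + b)
}
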