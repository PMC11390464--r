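# Shared fixtures and independent oracles used across the test files.

# Random symmetric nonnegative adjacency with unit diagonal.
rand_sym_adj <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(runif(n * n), n, n)
  A <- (A + t(A)) / 2
  diag(A) <- 1
  A
}

# Small config for fast model-level tests.
tiny_cfg <- function(...) {
  iggcn_config(hidden_size = 6L, M = 2L, K = 2L, epoch = 2L, batch_size = 4L,
               num_node = 4L, n_classes = 3L, T_prop = 2L, delta = 1e-12, ...)
}

tiny_instance <- function(C = 4L, F_dim = 3L, seed = 11L, cfg = tiny_cfg()) {
  set.seed(seed)
  X <- matrix(runif(C * F_dim), C, F_dim)
  L0 <- normalize_adjacency(rand_sym_adj(C))
  params <- iggcn_init_params(cfg, F_dim, seed = seed + 1L)
  list(X = X, L0 = L0, params = params, cfg = cfg)
}

# Literal, loop-based evaluation of one gated propagation step: scalar
# arithmetic over nodes and hidden units, independent of the vectorized
# implementation.
ggnn_step_loops <- function(H, A, p) {
  C <- nrow(H)
  hd <- ncol(H)
  Hn <- matrix(0, C, hd)
  for (i in seq_len(C)) {
    a_i <- numeric(hd)
    for (d in seq_len(hd)) {
      s <- 0
      for (j in seq_len(C)) s <- s + A[j, i] * H[j, d]
      a_i[d] <- s + p$b[d]
    }
    for (d in seq_len(hd)) {
      zpre <- 0; rpre <- 0
      for (e in seq_len(hd)) {
        zpre <- zpre + a_i[e] * p$Wz[e, d] + H[i, e] * p$Uz[e, d]
        rpre <- rpre + a_i[e] * p$Wr[e, d] + H[i, e] * p$Ur[e, d]
      }
      z <- 1 / (1 + exp(-zpre))
      r <- 1 / (1 + exp(-rpre))
      hpre <- 0
      for (e in seq_len(hd)) {
        # reset gate of unit e for node i
        rpre_e <- 0
        for (f in seq_len(hd)) {
          rpre_e <- rpre_e + a_i[f] * p$Wr[f, e] + H[i, f] * p$Ur[f, e]
        }
        r_e <- 1 / (1 + exp(-rpre_e))
        hpre <- hpre + a_i[e] * p$Wh[e, d] + r_e * H[i, e] * p$Uh[e, d]
      }
      htil <- tanh(hpre)
      Hn[i, d] <- (1 - z) * H[i, d] + z * htil
    }
  }
  Hn
}

# Brute-force normalized cross-correlation maximized over all lags
# (direct lagged sums; independent of the FFT implementation).
xcorr_brute <- function(xi, xj) {
  xi <- xi - mean(xi)
  xj <- xj - mean(xj)
  n <- length(xi)
  best <- 0
  for (lag in -(n - 1L):(n - 1L)) {
    s <- 0
    for (t in seq_len(n)) {
      u <- t + lag
      if (u >= 1L && u <= n) s <- s + xi[t] * xj[u]
    }
    best <- max(best, abs(s))
  }
  best / sqrt(sum(xi^2) * sum(xj^2))
}
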