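# Full model: iterative attention graph learning feeding a gated graph
# propagator, joint focal + graph-regularization objective. The forward
# pass stores intermediates; the backward pass computes analytic gradients
# for every parameter (verified against central finite differences in the
# test suite).

#' Initialize all model parameters
#'
#' Two attention parameter sets (iteration 1 attends on the raw feature
#' matrix, later iterations on the hidden embeddings, whose dimension
#' differs), an input projection to the hidden width, the gated-propagator
#' recurrences and the readout head. Deterministic given the seed.
#'
#' @param cfg An \code{iggcn_config}.
#' @param n_features Spectral feature dimension F of the node features.
#' @param seed Integer seed.
#' @return Nested parameter list.
#' @export
iggcn_init_params <- function(cfg, n_features, seed = 0L) {
  set.seed(seed)
  glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  hd <- cfg$hidden_size
  list(
    attn_feat = attention_params(cfg$K, n_features),
    attn_emb = attention_params(cfg$K, hd),
    Win = glorot(n_features, hd),
    bin = numeric(hd),
    ggnn = unclass(ggnn_params(hd)),
    Wout = glorot(hd, cfg$n_classes),
    bout = numeric(cfg$n_classes)
  )
}

#' @keywords internal
zero_like <- function(p) {
  rapply(p, function(x) x * 0, how = "replace")
}

#' @keywords internal
add_grads <- function(a, b) {
  for (nm in names(b)) {
    a[[nm]] <- if (is.list(b[[nm]])) add_grads(a[[nm]], b[[nm]]) else a[[nm]] + b[[nm]]
  }
  a
}

#' @keywords internal
scale_grads <- function(a, s) rapply(a, function(x) x * s, how = "replace")

# Pairwise squared feature distances ||x_i - x_j||^2.
#' @keywords internal
pair_dist2 <- function(X) {
  sq <- rowSums(X^2)
  d <- outer(sq, rep(1, nrow(X))) + outer(rep(1, nrow(X)), sq) - 2 * X %*% t(X)
  pmax(d, 0)
}

#' Forward pass of the full model on one clip
#'
#' Runs up to \code{cfg$M} graph-learning iterations. Iteration m learns an
#' adjacency by multi-head attention (on the raw features at m = 1, on the
#' previous iteration's embeddings after), mixes it with the normalized
#' initial graph and the first learned graph, propagates the projected
#' features over the mixed graph, reads out class probabilities, and
#' accumulates the joint loss. The inner loop stops early when consecutive
#' learned graphs converge in relative Frobenius norm.
#'
#' @param X Node feature matrix, C x F.
#' @param L0 Normalized initial adjacency, C x C.
#' @param y True class index (1-based), or \code{NULL} for prediction only.
#' @param params Parameter list from \code{\link{iggcn_init_params}}.
#' @param cfg An \code{iggcn_config}.
#' @param alpha Per-class focal weights (default 1).
#' @param keep_cache Store intermediates for \code{\link{iggcn_backward}}.
#' @return List with \code{probs} (last iteration), \code{loss} (a
#'   \code{\link{joint_loss}} breakdown aggregated over iterations),
#'   \code{m_used}, per-iteration graphs, and caches when requested.
#' @export
iggcn_forward <- function(X, L0, y, params, cfg, alpha = 1, keep_cache = FALSE) {
  C <- nrow(X)
  H0h <- X %*% params$Win +
    matrix(params$bin, C, cfg$hidden_size, byrow = TRUE)
  iters <- vector("list", cfg$M)
  A_prev <- NULL
  A_1 <- NULL
  fA_1 <- NULL
  m_used <- 0L
  for (m in seq_len(cfg$M)) {
    Hatt <- if (m == 1L) X else iters[[m - 1L]]$Hemb
    ap <- if (m == 1L) params$attn_feat else params$attn_emb
    heads <- vector("list", cfg$K)
    for (k in seq_len(cfg$K)) {
      e <- attention_scores(Hatt, ap, k)
      heads[[k]] <- list(e = e, a = normalize_attention(e, cfg$lrelu_slope))
    }
    A_m <- aggregate_heads(lapply(heads, `[[`, "a"))
    if (m == 1L) {
      A_1 <- A_m
      fA_1 <- row_normalize(A_1)
    }
    At <- cfg$lambda * L0 +
      (1 - cfg$lambda) * (cfg$eta * row_normalize(A_m) + (1 - cfg$eta) * fA_1)
    Hemb <- propagate(H0h, At, params$ggnn, cfg$T_prop, cache = keep_cache)
    steps <- attr(Hemb, "steps")
    attr(Hemb, "steps") <- NULL
    probs <- readout(Hemb, params$Wout, params$bout)
    Areg <- if (cfg$reg_graph == "learned") A_m else At
    it <- list(
      A_m = A_m, At = At, Hemb = Hemb, probs = probs,
      L_smooth = smoothness_loss(Areg, Hatt),
      L_degree = degree_loss(Areg, cfg$beta),
      L_sparsity = sparsity_loss(Areg, cfg$theta),
      L_pred = if (is.null(y)) NA_real_ else
        focal_loss(probs, y, alpha, cfg$gamma)
    )
    if (keep_cache) {
      it$heads <- heads
      it$steps <- steps
      it$Hatt_is_X <- (m == 1L)
    }
    iters[[m]] <- it
    m_used <- m
    if (m > 1L && graph_converged(A_m, A_prev, cfg$delta)) break
    A_prev <- A_m
  }
  iters <- iters[seq_len(m_used)]
  sel <- if (cfg$loss_agg == "mean") seq_len(m_used) else m_used
  agg <- function(field) mean(vapply(iters[sel], `[[`, numeric(1), field))
  loss <- if (is.null(y)) NULL else
    joint_loss(agg("L_pred"), agg("L_smooth"), agg("L_degree"),
               agg("L_sparsity"), cfg$omega)
  out <- list(probs = iters[[m_used]]$probs, loss = loss, m_used = m_used,
              A_final = iters[[m_used]]$A_m, At_final = iters[[m_used]]$At,
              iters = iters)
  if (keep_cache) {
    out$X <- X
    out$L0 <- L0
    out$y <- y
    out$H0h <- H0h
    out$alpha <- alpha
  }
  out
}

# d focal / d p_y at the (clamped) predicted probability.
#' @keywords internal
focal_dp <- function(py, a, gamma) {
  py <- pmax(py, 1e-12)
  t1 <- if (gamma > 0) gamma * (1 - py)^(gamma - 1) * log(py) else 0
  a * (t1 - (1 - py)^gamma / py)
}

# Backward through row normalization F = A / rowsum(A).
#' @keywords internal
rownorm_backward <- function(dF, A) {
  rs <- rowSums(A)
  Fm <- row_normalize(A)
  inner <- rowSums(dF * Fm)
  out <- (dF - inner) / rs
  out[rs <= 0, ] <- 0
  out
}

# Backward through the tied gated propagation steps.
#' @keywords internal
ggnn_backward <- function(dH_final, steps, A, pg) {
  g <- lapply(pg, function(x) x * 0)
  dH <- dH_final
  dA <- matrix(0, nrow(A), ncol(A))
  for (t in rev(seq_along(steps))) {
    cc <- steps[[t]]
    dz <- dH * (cc$htil - cc$H_prev)
    dhtil <- dH * cc$z
    dHp <- dH * (1 - cc$z)
    dph <- dhtil * (1 - cc$htil^2)
    g$Wh <- g$Wh + crossprod(cc$a, dph)
    da <- dph %*% t(pg$Wh)
    drH <- dph %*% t(pg$Uh)
    g$Uh <- g$Uh + crossprod(cc$r * cc$H_prev, dph)
    dr <- drH * cc$H_prev
    dHp <- dHp + drH * cc$r
    dpr <- dr * cc$r * (1 - cc$r)
    g$Wr <- g$Wr + crossprod(cc$a, dpr)
    da <- da + dpr %*% t(pg$Wr)
    g$Ur <- g$Ur + crossprod(cc$H_prev, dpr)
    dHp <- dHp + dpr %*% t(pg$Ur)
    dpz <- dz * cc$z * (1 - cc$z)
    g$Wz <- g$Wz + crossprod(cc$a, dpz)
    da <- da + dpz %*% t(pg$Wz)
    g$Uz <- g$Uz + crossprod(cc$H_prev, dpz)
    dHp <- dHp + dpz %*% t(pg$Uz)
    # a = t(A) H_prev + b
    g$b <- g$b + colSums(da)
    dA <- dA + cc$H_prev %*% t(da)
    dHp <- dHp + A %*% da
    dH <- dHp
  }
  list(dH0 = dH, dA = dA, grads = g)
}

#' Backward pass: analytic gradients of the joint loss
#'
#' Differentiates the aggregated joint loss of \code{\link{iggcn_forward}}
#' (run with \code{keep_cache = TRUE}) with respect to every parameter,
#' propagating through the readout, the gated steps, the graph mixing, the
#' regularizers, the per-head softmax attention and the embedding feedback
#' between iterations.
#'
#' @param fw Cached forward result.
#' @param params Parameter list used in the forward pass.
#' @param cfg The same \code{iggcn_config}.
#' @return Gradient list with the same structure as \code{params}.
#' @export
iggcn_backward <- function(fw, params, cfg) {
  if (cfg$mix_norm != "row") {
    stop("analytic gradients are implemented for mix_norm = \"row\"")
  }
  C <- nrow(fw$X)
  m_used <- fw$m_used
  wts <- if (cfg$loss_agg == "mean") rep(1 / m_used, m_used) else
    c(rep(0, m_used - 1L), 1)
  grads <- zero_like(params)
  dH0h <- matrix(0, C, cfg$hidden_size)
  d_fA1 <- matrix(0, C, C)
  dHemb_next <- NULL
  a_y <- if (length(fw$alpha) > 1) fw$alpha[fw$y] else fw$alpha
  for (m in rev(seq_len(m_used))) {
    it <- fw$iters[[m]]
    wm <- wts[m]
    Hatt <- if (it$Hatt_is_X) fw$X else fw$iters[[m - 1L]]$Hemb
    # readout + focal
    p <- it$probs
    py <- p[fw$y]
    gp <- wm * focal_dp(py, a_y, cfg$gamma)
    ind <- as.numeric(seq_along(p) == fw$y)
    dlog <- gp * py * (ind - p)
    pooled <- colMeans(it$Hemb)
    grads$Wout <- grads$Wout + outer(pooled, dlog)
    grads$bout <- grads$bout + dlog
    dpooled <- drop(params$Wout %*% dlog)
    dHm <- matrix(dpooled / C, C, cfg$hidden_size, byrow = TRUE)
    if (!is.null(dHemb_next)) dHm <- dHm + dHemb_next
    # gated propagation
    bk <- ggnn_backward(dHm, it$steps, it$At, params$ggnn)
    grads$ggnn <- add_grads(grads$ggnn, bk$grads)
    dH0h <- dH0h + bk$dH0
    dAt <- bk$dA
    # graph regularizers (on the raw learned or the mixed graph)
    Areg <- if (cfg$reg_graph == "learned") it$A_m else it$At
    rs <- rowSums(Areg)
    dist2 <- pair_dist2(Hatt)
    dAreg <- wm * (cfg$omega / (2 * C^2)) * dist2 +
      matrix(wm * (-cfg$beta / C) / pmax(rs, 1e-12) * (rs > 1e-12), C, C) +
      wm * (2 * cfg$theta / C^2) * Areg
    dr <- rowSums(Areg)
    dc <- colSums(Areg)
    dHatt_sm <- wm * (cfg$omega / C^2) *
      ((dr + dc) * Hatt - (Areg + t(Areg)) %*% Hatt)
    if (cfg$reg_graph == "mixed") {
      dAt <- dAt + dAreg
      dA_m <- matrix(0, C, C)
    } else {
      dA_m <- dAreg
    }
    # mixing: At = lambda L0 + (1-lambda)(eta f(A_m) + (1-eta) f(A_1))
    dA_m <- dA_m + rownorm_backward((1 - cfg$lambda) * cfg$eta * dAt, it$A_m)
    d_fA1 <- d_fA1 + (1 - cfg$lambda) * (1 - cfg$eta) * dAt
    if (m == 1L) {
      dA_m <- dA_m + rownorm_backward(d_fA1, it$A_m)
    }
    # attention backward
    ap <- if (it$Hatt_is_X) params$attn_feat else params$attn_emb
    set_nm <- if (it$Hatt_is_X) "attn_feat" else "attn_emb"
    dHatt <- dHatt_sm
    for (k in seq_len(cfg$K)) {
      hd <- it$heads[[k]]
      da <- dA_m / cfg$K
      rs_k <- rowSums(da * hd$a)
      dz <- hd$a * (da - rs_k)
      de <- dz * lrelu_grad(hd$e, cfg$lrelu_slope)
      ds1 <- rowSums(de)
      ds2 <- colSums(de)
      U <- sweep(Hatt, 2L, ap$w[k, ], `*`)
      grads[[set_nm]]$aL[k, ] <- grads[[set_nm]]$aL[k, ] + drop(crossprod(U, ds1))
      grads[[set_nm]]$aR[k, ] <- grads[[set_nm]]$aR[k, ] + drop(crossprod(U, ds2))
      dU <- outer(ds1, ap$aL[k, ]) + outer(ds2, ap$aR[k, ])
      grads[[set_nm]]$w[k, ] <- grads[[set_nm]]$w[k, ] + colSums(dU * Hatt)
      dHatt <- dHatt + sweep(dU, 2L, ap$w[k, ], `*`)
    }
    dHemb_next <- if (!it$Hatt_is_X) dHatt else NULL
  }
  # input projection
  grads$Win <- grads$Win + crossprod(fw$X, dH0h)
  grads$bin <- grads$bin + colSums(dH0h)
  grads
}

#' Batch loss and gradients
#'
#' Mean joint loss and mean gradients over a set of clips.
#'
#' @param Xs,L0s Lists of feature matrices and normalized priors.
#' @param ys Integer class labels (1-based).
#' @param params,cfg,alpha As in \code{\link{iggcn_forward}}.
#' @return List with \code{loss} (mean breakdown), \code{grads},
#'   \code{probs} matrix.
#' @export
iggcn_batch_grad <- function(Xs, L0s, ys, params, cfg, alpha = 1) {
  n <- length(Xs)
  grads <- NULL
  comps <- NULL
  probs <- matrix(NA_real_, n, cfg$n_classes)
  for (i in seq_len(n)) {
    fw <- iggcn_forward(Xs[[i]], L0s[[i]], ys[i], params, cfg, alpha,
                        keep_cache = TRUE)
    g <- iggcn_backward(fw, params, cfg)
    grads <- if (is.null(grads)) g else add_grads(grads, g)
    comps <- if (is.null(comps)) unlist(fw$loss) else comps + unlist(fw$loss)
    probs[i, ] <- fw$probs
  }
  list(loss = as.list(comps / n), grads = scale_grads(grads, 1 / n),
       probs = probs)
}

#' Finite-difference gradient check
#'
#' Compares the analytic gradient of the joint loss with central finite
#' differences on a subset of parameters.
#'
#' @param X,L0,y,params,cfg,alpha Forward-pass inputs.
#' @param h Step size (default 1e-5).
#' @param n_sample Number of coordinates checked per parameter tensor
#'   (default 5; \code{Inf} checks all).
#' @param seed Seed for coordinate sampling.
#' @return Data frame with per-coordinate analytic/numeric values and
#'   relative errors.
#' @export
iggcn_grad_check <- function(X, L0, y, params, cfg, alpha = 1, h = 1e-5,
                             n_sample = 5L, seed = 0L) {
  flat <- unlist(params)
  loss_at <- function(v) {
    p <- utils::relist(v, params)
    iggcn_forward(X, L0, y, p, cfg, alpha)$loss$L_total
  }
  fw <- iggcn_forward(X, L0, y, params, cfg, alpha, keep_cache = TRUE)
  ana <- unlist(iggcn_backward(fw, params, cfg))
  set.seed(seed)
  sizes <- lengths(list_leaves(params))
  offsets <- cumsum(c(0, sizes))
  rows <- list()
  for (t in seq_along(sizes)) {
    n_t <- min(n_sample, sizes[t])
    idx <- offsets[t] + sort(sample.int(sizes[t], n_t))
    for (i in idx) {
      v <- flat
      v[i] <- flat[i] + h
      up <- loss_at(v)
      v[i] <- flat[i] - h
      dn <- loss_at(v)
      num <- (up - dn) / (2 * h)
      # floor the denominator so near-zero gradients are compared at an
      # absolute scale the central difference can actually resolve
      denom <- max(abs(num), abs(ana[i]), 1e-6)
      rows[[length(rows) + 1L]] <- data.frame(
        tensor = names(sizes)[t], index = i, analytic = ana[i],
        numeric = num, rel_err = abs(num - ana[i]) / denom)
    }
  }
  do.call(rbind, rows)
}

#' @keywords internal
list_leaves <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(p[[nm]])) {
      out <- c(out, list_leaves(p[[nm]], key))
    } else {
      out[[key]] <- p[[nm]]
    }
  }
  out
}
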