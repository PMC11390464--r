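# Training loop: per-clip graphs, joint loss, Adam, per-epoch validation
# with best-checkpoint selection. Fully deterministic given a seed.

#' Prepare clips for the model
#'
#' Computes spectral node features and the per-clip initial graph (signal
#' cross-correlation by default, normalized to the anchor graph).
#'
#' @param clips List of \code{eeg_clip}s.
#' @param labels Character labels, parallel to \code{clips} (defaults to
#'   the clips' own labels).
#' @param levels Class levels fixing the integer coding.
#' @param prior \code{"correlation"} (default) or \code{"distance"}.
#' @param layout Electrode layout for the distance prior.
#' @param max_lag Lag bound for the correlation prior (NULL = all lags).
#' @return List with \code{X}, \code{A0}, \code{L0} (lists), \code{y}
#'   (integer), \code{levels}.
#' @export
prepare_clips <- function(clips, labels = NULL, levels = NULL,
                          prior = c("correlation", "distance"),
                          layout = NULL, max_lag = NULL) {
  prior <- match.arg(prior)
  if (is.null(labels)) labels <- vapply(clips, `[[`, character(1), "label")
  if (is.null(levels)) levels <- sort(unique(labels))
  X <- lapply(clips, compute_features)
  if (prior == "correlation") {
    A0 <- lapply(clips, function(cl) correlation_graph(cl$signal, max_lag))
  } else {
    if (is.null(layout)) layout <- electrode_layout()
    A <- distance_graph(layout)
    A0 <- rep(list(A), length(clips))
  }
  L0 <- lapply(A0, normalize_adjacency)
  list(X = X, A0 = A0, L0 = L0, y = match(labels, levels), levels = levels)
}

#' Train the model
#'
#' Mini-batch Adam on the joint objective. Each clip carries its own
#' learned graph; gradients are averaged within a batch. After every epoch
#' the weighted F1 on the validation partition is computed and the best
#' checkpoint retained.
#'
#' @param train,val Prepared data (see \code{\link{prepare_clips}}).
#' @param cfg An \code{iggcn_config}.
#' @param seed Seed controlling initialization and batch shuffling.
#' @param class_weighting \code{"inverse"} (reciprocal class frequency,
#'   default) or \code{"uniform"} focal weights.
#' @param verbose Print per-epoch progress.
#' @return List of class \code{iggcn_model}: best \code{params}, \code{cfg},
#'   \code{alpha}, \code{levels}, and a per-epoch \code{history} data frame.
#' @export
iggcn_train <- function(train, val, cfg, seed = 0L,
                        class_weighting = c("inverse", "uniform"),
                        verbose = FALSE) {
  class_weighting <- match.arg(class_weighting)
  validate_config(cfg)
  n <- length(train$X)
  stopifnot(n >= 1L, length(val$X) >= 1L)
  counts <- tabulate(train$y, nbins = cfg$n_classes)
  alpha <- if (class_weighting == "inverse") {
    class_weights(pmax(counts, 1L))
  } else rep(1, cfg$n_classes)
  params <- iggcn_init_params(cfg, ncol(train$X[[1L]]), seed = seed)
  flat <- unlist(params)
  m_adam <- v_adam <- numeric(length(flat))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  best <- list(f1 = -Inf, flat = flat)
  history <- vector("list", cfg$epoch)
  set.seed(seed + 1L)
  for (ep in seq_len(cfg$epoch)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      bg <- iggcn_batch_grad(train$X[bt], train$L0[bt], train$y[bt],
                             utils::relist(flat, params), cfg, alpha)
      if (!is.finite(bg$loss$L_total)) {
        stop("training aborted: non-finite loss at epoch ", ep,
             " (L_pred=", bg$loss$L_pred, ", L_G=", bg$loss$L_G, ")")
      }
      g <- unlist(bg$grads)
      step <- step + 1L
      m_adam <- b1 * m_adam + (1 - b1) * g
      v_adam <- b2 * v_adam + (1 - b2) * g^2
      mh <- m_adam / (1 - b1^step)
      vh <- v_adam / (1 - b2^step)
      flat <- flat - cfg$learning_rate * mh / (sqrt(vh) + eps)
      ep_loss <- ep_loss + bg$loss$L_total * length(bt)
    }
    cur <- utils::relist(flat, params)
    vp <- iggcn_predict_params(val$X, val$L0, cur, cfg)
    vm <- classification_metrics(val$y, max.col(vp, ties.method = "first"), cfg$n_classes)
    if (vm$f1_weighted > best$f1) best <- list(f1 = vm$f1_weighted, flat = flat)
    history[[ep]] <- data.frame(epoch = ep, train_loss = ep_loss / n,
                                val_f1 = vm$f1_weighted,
                                val_accuracy = vm$accuracy)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  val F1 %.3f", ep,
                      ep_loss / n, vm$f1_weighted))
    }
  }
  structure(list(params = utils::relist(best$flat, params), cfg = cfg,
                 alpha = alpha, levels = train$levels,
                 history = do.call(rbind, history)),
            class = "iggcn_model")
}

#' @keywords internal
iggcn_predict_params <- function(Xs, L0s, params, cfg) {
  probs <- matrix(NA_real_, length(Xs), cfg$n_classes)
  for (i in seq_along(Xs)) {
    probs[i, ] <- iggcn_forward(Xs[[i]], L0s[[i]], NULL, params, cfg)$probs
  }
  probs
}

#' Predict class probabilities (and optionally graphs)
#'
#' @param model An \code{iggcn_model}.
#' @param data Prepared data (see \code{\link{prepare_clips}}).
#' @param keep_graphs Also return each clip's final learned and mixed
#'   adjacencies.
#' @return List with \code{probs} (clips x classes), \code{class}
#'   (predicted labels), and optionally \code{A_final}, \code{At_final}.
#' @export
iggcn_predict <- function(model, data, keep_graphs = FALSE) {
  cfg <- model$cfg
  n <- length(data$X)
  probs <- matrix(NA_real_, n, cfg$n_classes)
  A_final <- At_final <- if (keep_graphs) vector("list", n) else NULL
  for (i in seq_len(n)) {
    fw <- iggcn_forward(data$X[[i]], data$L0[[i]], NULL, model$params, cfg)
    probs[i, ] <- fw$probs
    if (keep_graphs) {
      A_final[[i]] <- fw$A_final
      At_final[[i]] <- fw$At_final
    }
  }
  out <- list(probs = probs, class = model$levels[max.col(probs, ties.method = "first")])
  if (keep_graphs) {
    out$A_final <- A_final
    out$At_final <- At_final
  }
  out
}

#' Export a clip's adjacency at a given iteration
#'
#' Runs the forward pass on one clip and returns (or writes as CSV) the
#' initial, learned or mixed adjacency for before/after-optimization
#' inspection.
#'
#' @param model An \code{iggcn_model}.
#' @param data Prepared data.
#' @param clip Clip index.
#' @param iteration Graph iteration m (defaults to the last one used).
#' @param role \code{"learned"}, \code{"mixed"} or \code{"initial"}.
#' @param file Optional CSV path.
#' @return The adjacency matrix, invisibly when written to file.
#' @export
export_graph <- function(model, data, clip = 1L, iteration = NULL,
                         role = c("learned", "mixed", "initial"), file = NULL) {
  role <- match.arg(role)
  fw <- iggcn_forward(data$X[[clip]], data$L0[[clip]], NULL, model$params,
                      model$cfg)
  if (is.null(iteration)) iteration <- fw$m_used
  stopifnot(iteration >= 1L, iteration <= fw$m_used)
  A <- switch(role,
              learned = fw$iters[[iteration]]$A_m,
              mixed = fw$iters[[iteration]]$At,
              initial = data$A0[[clip]])
  if (!is.null(file)) {
    utils::write.csv(as.data.frame(A), file, row.names = FALSE)
    return(invisible(A))
  }
  A
}
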