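#' IGGCN run configuration
#'
#' Collects every tunable of the model and training loop in one flat list.
#' Defaults are the published hyperparameter setting for the four-class
#' seizure task (hidden size 256, M = 10 graph iterations, 8 attention
#' heads, focal exponent 2, graph-mixing weights lambda = 0.3 / eta = 0.4,
#' regularizer weights omega = 0.5, beta = 0.01, theta = 0.3, 150 epochs,
#' batch size 64, Adam at 1e-3, 19 channels).
#'
#' @param hidden_size Hidden embedding width of the gated propagator.
#' @param M Maximum number of graph-learning iterations per forward pass.
#' @param epoch Number of training epochs.
#' @param batch_size Clips per optimizer step.
#' @param omega Weight of the Laplacian smoothness loss inside the graph
#'   regularizer.
#' @param beta Weight of the degree (log node-degree) regularizer.
#' @param theta Weight of the sparsity (squared Frobenius) regularizer.
#' @param K Number of attention heads.
#' @param gamma Focal-loss focusing exponent (0 recovers cross-entropy).
#' @param num_node Number of graph nodes (EEG channels).
#' @param lambda Mixing weight of the normalized initial graph in the
#'   iterative graph update.
#' @param eta Mixing weight between the current and first-iteration learned
#'   graphs.
#' @param learning_rate Adam learning rate.
#' @param T_prop Gated propagation steps per graph iteration (tied weights).
#' @param delta Relative Frobenius tolerance of the graph convergence test.
#' @param lrelu_slope Negative slope of the LeakyReLU in the attention scores.
#' @param n_classes Number of output classes.
#' @param loss_agg Aggregation of the per-iteration joint losses: "mean"
#'   over iterations (default) or "last" iteration only.
#' @param reg_graph Which adjacency feeds the graph regularizers: the raw
#'   "learned" attention graph (default) or the "mixed" graph.
#' @param mix_norm Normalization f() applied to learned graphs before
#'   mixing: "row" (A / rowsum, default) or "sym" (D^-1/2 A D^-1/2).
#' @param seeds Integer vector of seeds for multi-seed runs.
#' @return A list of class \code{iggcn_config}.
#' @export
iggcn_config <- function(hidden_size = 256L, M = 10L, epoch = 150L,
                         batch_size = 64L, omega = 0.5, beta = 0.01,
                         theta = 0.3, K = 8L, gamma = 2, num_node = 19L,
                         lambda = 0.3, eta = 0.4, learning_rate = 1e-3,
                         T_prop = 2L, delta = 1e-3, lrelu_slope = 0.2,
                         n_classes = 4L, loss_agg = c("mean", "last"),
                         reg_graph = c("learned", "mixed"),
                         mix_norm = c("row", "sym"),
                         seeds = 0:4) {
  loss_agg <- match.arg(loss_agg)
  reg_graph <- match.arg(reg_graph)
  mix_norm <- match.arg(mix_norm)
  cfg <- list(
    hidden_size = as.integer(hidden_size), M = as.integer(M),
    epoch = as.integer(epoch), batch_size = as.integer(batch_size),
    omega = omega, beta = beta, theta = theta, K = as.integer(K),
    gamma = gamma, num_node = as.integer(num_node), lambda = lambda,
    eta = eta, learning_rate = learning_rate, T_prop = as.integer(T_prop),
    delta = delta, lrelu_slope = lrelu_slope, n_classes = as.integer(n_classes),
    loss_agg = loss_agg, reg_graph = reg_graph, mix_norm = mix_norm,
    seeds = as.integer(seeds)
  )
  validate_config(cfg)
  structure(cfg, class = "iggcn_config")
}

#' @keywords internal
validate_config <- function(cfg) {
  stopifnot(
    cfg$hidden_size >= 1L, cfg$M >= 1L, cfg$epoch >= 1L, cfg$batch_size >= 1L,
    cfg$K >= 1L, cfg$gamma >= 0, cfg$num_node >= 2L,
    cfg$beta >= 0, cfg$theta >= 0,
    cfg$lambda >= 0, cfg$lambda <= 1, cfg$eta >= 0, cfg$eta <= 1,
    cfg$learning_rate > 0, cfg$T_prop >= 1L, cfg$delta >= 0,
    cfg$n_classes >= 2L, length(cfg$seeds) >= 1L
  )
  invisible(cfg)
}

#' Read a flat key=value configuration file
#'
#' Lines of the form \code{key = value} (\code{#} comments allowed) override
#' the defaults of \code{\link{iggcn_config}}. Keys use the published symbol
#' names transliterated to ASCII (omega, beta, theta, gamma, lambda, eta).
#'
#' @param path Path to the configuration file.
#' @return An \code{iggcn_config} list.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  args <- list()
  for (p in kv) {
    if (length(p) != 2L) stop("malformed config line: ", paste(p, collapse = "="))
    key <- trimws(p[1L])
    val <- trimws(p[2L])
    num <- suppressWarnings(as.numeric(strsplit(val, "[ ,]+")[[1L]]))
    args[[key]] <- if (anyNA(num)) val else num
  }
  do.call(iggcn_config, args)
}
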