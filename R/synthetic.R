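# Class-conditional VAR(1) synthetic EEG generator. Each class has its own
# symmetric coupling graph; clips are draws from x_t = rho * Ahat %*% x_{t-1}
# + eps_t with Ahat the row-normalized class adjacency, so the cross-channel
# correlation structure of a clip is analytically tied to the class graph
# that a graph-learning classifier is supposed to recover.

#' Specification of one synthetic class graph
#'
#' @param class_id Label of the class (character).
#' @param adjacency Symmetric nonnegative coupling matrix, zero diagonal.
#' @param density Fraction of off-diagonal channel pairs that are coupled.
#' @param coupling_strength Spectral-radius bound rho in [0, 1) of the VAR
#'   drift matrix after row normalization.
#' @return A list of class \code{class_graph_spec}.
#' @export
class_graph_spec <- function(class_id, adjacency, density, coupling_strength) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) stop("adjacency must be square")
  if (any(adjacency < 0)) stop("adjacency entries must be nonnegative")
  if (max(abs(adjacency - t(adjacency))) > 1e-12) stop("adjacency must be symmetric")
  if (coupling_strength < 0 || coupling_strength >= 1) {
    stop("coupling_strength must lie in [0, 1) for a stationary process")
  }
  structure(list(class_id = as.character(class_id), adjacency = adjacency,
                 density = density, coupling_strength = coupling_strength),
            class = "class_graph_spec")
}

#' Specification of a synthetic clip dataset
#'
#' @param n_channels Number of channels (default 19, the 10-20 montage size).
#' @param clip_seconds Clip duration in seconds (default 12).
#' @param sample_rate Sampling rate in Hz (default 128).
#' @param class_counts Named integer vector, clips per class label.
#' @param noise_sd Innovation standard deviation of the VAR process.
#' @param seed Base seed; per-clip seeds are derived by a counter scheme.
#' @return A list of class \code{synthetic_dataset_spec}.
#' @export
synthetic_dataset_spec <- function(n_channels = 19L, clip_seconds = 12,
                                   sample_rate = 128, class_counts = integer(),
                                   noise_sd = 1, seed = 0L) {
  n_samples <- round(sample_rate * clip_seconds)
  stopifnot(n_channels >= 1L, all(class_counts >= 0L), n_samples >= 2L,
            noise_sd >= 0)
  structure(list(n_channels = as.integer(n_channels),
                 clip_seconds = clip_seconds, sample_rate = sample_rate,
                 class_counts = class_counts, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_dataset_spec")
}

#' Draw distinct class coupling graphs
#'
#' Samples, for each class, \code{round(density * choose(n_channels, 2))}
#' coupled channel pairs with Uniform(0.5, 1) symmetric weights. Classes
#' cycle through three topology families emulating the connectivity
#' topographies of different seizure types: \code{"distributed"} (edges
#' uniform over all pairs, a generalized-seizure-like topology),
#' \code{"hub"} (edges concentrated on a few hub channels), and
#' \code{"cluster"} (edges confined to a contiguous focal cluster, a
#' focal-seizure-like topology). All families share the same edge count
#' and weight law, so classes differ in how coupling is organized rather
#' than in how much there is. With \code{self_coupling} (default) the
#' diagonal is set to 1, giving every channel self-dynamics whose strength
#' after row normalization reflects its local connectivity — this is what
#' makes per-channel spectra informative about the topology. Graphs are
#' pairwise distinct (resampled on collision).
#'
#' @param n_classes Number of classes (>= 2).
#' @param n_channels Number of channels (>= 2).
#' @param density Fraction of off-diagonal pairs coupled, in (0, 1].
#' @param seed Integer seed; output is deterministic given it.
#' @param coupling_strength Spectral-radius bound rho passed to each spec.
#' @param families Topology family per class, recycled over classes.
#' @param self_coupling Put a unit diagonal on each class adjacency.
#' @return List of \code{class_graph_spec}, one per class, labelled
#'   "class1", "class2", ...
#' @export
make_class_graphs <- function(n_classes, n_channels, density, seed,
                              coupling_strength = 0.85,
                              families = c("distributed", "hub", "cluster"),
                              self_coupling = TRUE) {
  if (n_channels < 2L) stop("invalid spec: n_channels must be at least 2")
  if (n_classes < 2L) stop("invalid spec: n_classes must be at least 2")
  if (density <= 0 || density > 1) stop("invalid spec: density must be in (0, 1]")
  families <- match.arg(families, several.ok = TRUE)
  n_pairs <- choose(n_channels, 2L)
  n_edges <- round(density * n_pairs)
  pairs <- which(upper.tri(diag(n_channels)), arr.ind = TRUE)
  graphs <- vector("list", n_classes)
  seen <- character(0)
  counter <- 0L
  for (cl in seq_len(n_classes)) {
    fam <- families[(cl - 1L) %% length(families) + 1L]
    repeat {
      set.seed(derive_seed(seed, counter))
      counter <- counter + 1L
      A <- matrix(0, n_channels, n_channels)
      if (n_edges > 0L) {
        sel <- sample_edges(fam, n_channels, n_edges, pairs)
        A[pairs[sel, , drop = FALSE]] <- runif(n_edges, 0.5, 1)
        A <- A + t(A)
      }
      if (self_coupling) diag(A) <- 1
      key <- paste(signif(A, 12), collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        break
      }
    }
    graphs[[cl]] <- class_graph_spec(paste0("class", cl), A, density,
                                     coupling_strength)
  }
  names(graphs) <- vapply(graphs, `[[`, character(1), "class_id")
  graphs
}

# Pick n_edges off-diagonal pairs according to the topology family.
# pairs is the upper-triangle index table; the RNG is already seeded.
#' @keywords internal
sample_edges <- function(family, n_channels, n_edges, pairs) {
  n_pairs <- nrow(pairs)
  if (n_edges >= n_pairs) return(seq_len(n_pairs))
  switch(family,
    distributed = sample.int(n_pairs, n_edges),
    hub = {
      n_hubs <- max(2L, ceiling(n_channels / 6))
      hubs <- sample.int(n_channels, n_hubs)
      inc <- (pairs[, 1L] %in% hubs) | (pairs[, 2L] %in% hubs)
      cand <- which(inc)
      if (length(cand) >= n_edges) {
        sample(cand, n_edges)
      } else {
        c(cand, sample(which(!inc), n_edges - length(cand)))
      }
    },
    cluster = {
      # smallest contiguous node cluster whose internal pairs cover n_edges
      size <- 2L
      while (choose(size, 2L) < n_edges && size < n_channels) size <- size + 1L
      members <- sample.int(n_channels, size)
      cand <- which(pairs[, 1L] %in% members & pairs[, 2L] %in% members)
      sample(cand, n_edges)
    })
}

#' Simulate one clip from a class graph
#'
#' Runs the stationary VAR(1) recursion
#' \code{x_t = rho * Ahat x_{t-1} + eps_t} with \code{Ahat} the
#' row-normalized class adjacency and Gaussian innovations, discarding a
#' 200-sample burn-in so the retained window starts near the stationary
#' distribution.
#'
#' @param spec A \code{class_graph_spec}.
#' @param dataset_spec A \code{synthetic_dataset_spec}.
#' @param seed Integer seed; clips are bitwise-reproducible given it.
#' @param burn_in Samples discarded at the start (default 200).
#' @return An \code{eeg_clip}: list with \code{signal} (channels x samples),
#'   \code{sample_rate}, \code{label}, \code{source}.
#' @export
simulate_clip <- function(spec, dataset_spec, seed, burn_in = 200L) {
  C <- dataset_spec$n_channels
  if (nrow(spec$adjacency) != C) stop("adjacency size does not match n_channels")
  Tn <- round(dataset_spec$sample_rate * dataset_spec$clip_seconds)
  B <- spec$coupling_strength * row_normalize(spec$adjacency)
  # row-stochastic scaling bounds the spectral radius by rho < 1
  ev <- max(abs(eigen(B, only.values = TRUE)$values))
  if (ev >= 1) stop("simulation-stability error: drift spectral radius >= 1")
  set.seed(seed)
  total <- Tn + burn_in
  eps <- matrix(rnorm(C * total, sd = dataset_spec$noise_sd), nrow = C)
  x <- matrix(0, C, total)
  x[, 1L] <- eps[, 1L]
  for (t in 2:total) x[, t] <- B %*% x[, t - 1L] + eps[, t]
  structure(list(signal = x[, (burn_in + 1L):total, drop = FALSE],
                 sample_rate = dataset_spec$sample_rate,
                 label = spec$class_id,
                 source = list(record_id = paste0("synthetic-", seed),
                               window = 1L)),
            class = "eeg_clip")
}

#' Generate a labeled synthetic dataset
#'
#' @param dataset_spec A \code{synthetic_dataset_spec}; its
#'   \code{class_counts} names must be a subset of the class graph ids.
#' @param class_graphs List of \code{class_graph_spec} from
#'   \code{\link{make_class_graphs}}.
#' @return List with \code{clips} (list of \code{eeg_clip}), \code{labels}
#'   (character vector), and \code{truth} (named list of ground-truth
#'   adjacency matrices per class, for recovery scoring).
#' @export
generate_dataset <- function(dataset_spec, class_graphs) {
  counts <- dataset_spec$class_counts
  if (length(counts) > 0 &&
      !all(names(counts) %in% names(class_graphs))) {
    stop("class_counts keys must be a subset of class graph ids")
  }
  clips <- list()
  labels <- character(0)
  counter <- 0L
  for (cl in names(counts)) {
    for (i in seq_len(counts[[cl]])) {
      counter <- counter + 1L
      clip <- simulate_clip(class_graphs[[cl]], dataset_spec,
                            seed = derive_seed(dataset_spec$seed, counter))
      clip$source$record_id <- sprintf("syn-%s-%03d", cl, i)
      clips[[counter]] <- clip
      labels <- c(labels, cl)
    }
  }
  truth <- lapply(class_graphs, `[[`, "adjacency")
  list(clips = clips, labels = labels, truth = truth)
}
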