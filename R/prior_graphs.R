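# Prior (pre-learning) graphs over EEG channels: a distance kernel on the
# electrode layout, or signal cross-correlation, plus the symmetric degree
# normalization used as the anchor graph of the iterative update.

#' Standard 10-20 electrode layout
#'
#' Loads the packaged schematic 10-20 head coordinates (unit-circle layout).
#'
#' @param channels Channels to keep, in montage order.
#' @param tau Kernel scale of the distance graph (default 1).
#' @return List with \code{coords} (channels x 2/3 matrix) and \code{tau}.
#' @export
electrode_layout <- function(channels = tusz_montage(), tau = 1.0) {
  path <- system.file("extdata", "electrodes_1020.csv", package = "iggcn")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(channels, tab$channel)
  if (length(missing) > 0) {
    stop("no coordinates for channel(s): ", paste(missing, collapse = ", "))
  }
  rownames(tab) <- tab$channel
  coords <- as.matrix(tab[channels, c("x", "y", "z")])
  list(coords = coords, tau = tau)
}

#' Distance-kernel prior graph
#'
#' \code{a_ij = exp(-dist(v_i, v_j)^2 / tau^2)} on the pairwise electrode
#' distances; symmetric, unit diagonal, entries in (0, 1].
#'
#' @param layout List with \code{coords} (per-channel coordinates) and
#'   \code{tau} > 0, e.g. from \code{\link{electrode_layout}}.
#' @return Channels x channels adjacency matrix.
#' @export
distance_graph <- function(layout) {
  if (is.null(layout$tau) || layout$tau <= 0) stop("config error: tau must be > 0")
  d <- as.matrix(stats::dist(layout$coords))
  exp(-d^2 / layout$tau^2)
}

#' Cross-correlation prior graph
#'
#' \code{a_ij} is the absolute value of the lag-maximizing normalized
#' cross-correlation between channels i and j (signals centered per
#' channel), clipped to [0, 1]; unit diagonal. With \code{max_lag = 0} only
#' the lag-0 correlation is used. All-zero (constant) channels get zero
#' rows/columns with a warning.
#'
#' @param signal Channels x samples matrix (an \code{eeg_clip$signal}).
#' @param max_lag Maximum lag searched in samples; \code{NULL} (default)
#'   searches all lags.
#' @return Channels x channels nonnegative symmetric adjacency.
#' @export
correlation_graph <- function(signal, max_lag = NULL) {
  if (inherits(signal, "eeg_clip")) signal <- signal$signal
  C <- nrow(signal)
  Tn <- ncol(signal)
  stopifnot(Tn >= 2)
  x <- signal - rowMeans(signal)
  nrm <- sqrt(rowSums(x^2))
  dead <- nrm <= 0
  if (any(dead)) {
    warning("degenerate (constant) channel(s): ",
            paste(which(dead), collapse = ", "), "; rows/cols set to 0")
    nrm[dead] <- 1
  }
  npad <- stats::nextn(2L * Tn, 2L)
  Fx <- stats::mvfft(rbind(t(x), matrix(0, npad - Tn, C)))
  A <- diag(1, C)
  lags_ok <- if (is.null(max_lag)) rep(TRUE, npad) else {
    l <- c(0:(npad %/% 2), -((npad - npad %/% 2 - 1):1))
    abs(l) <= max_lag
  }
  for (i in seq_len(C - 1L)) {
    for (j in (i + 1L):C) {
      cc <- Re(stats::fft(Fx[, i] * Conj(Fx[, j]), inverse = TRUE)) / npad
      a <- max(abs(cc[lags_ok])) / (nrm[i] * nrm[j])
      A[i, j] <- A[j, i] <- min(a, 1)
    }
  }
  if (any(dead)) {
    A[dead, ] <- 0
    A[, dead] <- 0
  }
  A
}

#' Symmetric degree normalization of an adjacency
#'
#' \code{L = D^{-1/2} A D^{-1/2}} with \code{D} the diagonal of row sums;
#' the anchor graph of the iterative structure update.
#'
#' @param A Nonnegative adjacency with strictly positive row sums.
#' @return Normalized adjacency of the same shape.
#' @export
normalize_adjacency <- function(A) {
  if (any(A < 0)) stop("adjacency must be nonnegative")
  d <- rowSums(A)
  if (any(d <= 0)) {
    stop("isolated-node error: zero-degree row(s) ",
         paste(which(d <= 0), collapse = ", "),
         "; add self-loops or prune before normalizing")
  }
  s <- 1 / sqrt(d)
  A * outer(s, s)
}
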