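# Preprocessing: annotated recordings -> fixed-length clips with merged
# 4-class labels and per-channel log-amplitude spectral features.

#' The 19-channel 10-20 montage
#'
#' Channel order is fixed across the whole pipeline.
#' @return Character vector of 19 channel names.
#' @export
tusz_montage <- function() {
  c("FP1", "FP2", "F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2",
    "F7", "F8", "T3", "T4", "T5", "T6", "FZ", "CZ", "PZ")
}

#' Merge raw seizure annotations into the four model classes
#'
#' Focal non-specific, simple partial and complex partial seizures are
#' combined (CFSZ); tonic and tonic-clonic are combined (CTSZ); generalized
#' non-specific (GNSZ) and absence (ABSZ) stay as-is; myoclonic (MYSZ) is
#' excluded and maps to \code{NA}.
#'
#' @param raw_label Character vector of raw labels (FNSZ, GNSZ, SPSZ, CPSZ,
#'   ABSZ, TNSZ, TCSZ, MYSZ).
#' @return Character vector of merged labels (CFSZ, GNSZ, ABSZ, CTSZ) with
#'   \code{NA} for excluded types.
#' @export
map_label <- function(raw_label) {
  table <- c(FNSZ = "CFSZ", SPSZ = "CFSZ", CPSZ = "CFSZ",
             GNSZ = "GNSZ", ABSZ = "ABSZ",
             TNSZ = "CTSZ", TCSZ = "CTSZ", MYSZ = NA_character_)
  unknown <- setdiff(unique(raw_label), names(table))
  if (length(unknown) > 0) {
    stop("label-mapping error: unknown raw label(s) ", paste(unknown, collapse = ", "))
  }
  unname(table[raw_label])
}

#' Slice a seizure event into fixed-length clips
#'
#' Non-overlapping consecutive windows of \code{window_s} seconds starting
#' at the event onset; a trailing remainder shorter than the window is
#' discarded, so events shorter than \code{window_s} yield no clips.
#' Windows are half-open in seconds; sample indices are
#' \code{floor(seconds * rate)}, 0-based.
#'
#' @param event List/row with \code{record_id}, \code{patient_id},
#'   \code{start_s}, \code{stop_s}, \code{raw_label}.
#' @param signal Full-record channels x samples matrix.
#' @param sample_rate Sampling rate in Hz.
#' @param window_s Window length in seconds (default 12).
#' @return List of \code{eeg_clip} objects (possibly empty) carrying the
#'   merged label, or empty when the label is excluded.
#' @export
slice_event <- function(event, signal, sample_rate, window_s = 12) {
  stopifnot(window_s > 0, event$stop_s > event$start_s, event$start_s >= 0)
  n_total <- ncol(signal)
  if (floor(event$stop_s * sample_rate) > n_total) {
    stop("annotation-bounds error: event extends past end of record ",
         event$record_id)
  }
  label <- map_label(event$raw_label)
  if (is.na(label)) return(list())
  win <- round(sample_rate * window_s)
  n_win <- floor((event$stop_s - event$start_s) / window_s)
  if (n_win <= 0) return(list())
  lapply(seq_len(n_win), function(i) {
    s0 <- floor((event$start_s + (i - 1) * window_s) * sample_rate)
    structure(list(signal = signal[, (s0 + 1L):(s0 + win), drop = FALSE],
                   sample_rate = sample_rate, label = label,
                   source = list(record_id = event$record_id,
                                 patient_id = event$patient_id,
                                 window = i)),
              class = "eeg_clip")
  })
}

#' Select and reorder channels by montage
#'
#' @param signal Channels x samples matrix with rownames giving channel
#'   names of the record.
#' @param montage Character vector of channel names; rows of the output are
#'   in exactly this order.
#' @return Reordered \code{length(montage)} x samples matrix.
#' @export
select_channels <- function(signal, montage = tusz_montage()) {
  missing <- setdiff(montage, rownames(signal))
  if (length(missing) > 0) {
    stop("montage error: channel(s) missing from record: ",
         paste(missing, collapse = ", "))
  }
  signal[montage, , drop = FALSE]
}

#' Spectral node features of a clip
#'
#' Per channel: FFT of the raw window, keep the positive-frequency bins
#' (DC excluded; the Nyquist bin is excluded for even-length windows),
#' take \code{log(|coefficient| + eps)}, then min-max scale. Scaling is per
#' channel by default (removing inter-channel amplitude offsets) or over
#' the whole clip. Degenerate constant ranges scale to 0.
#'
#' @param clip An \code{eeg_clip} (or a channels x samples matrix).
#' @param eps Additive guard inside the log (default 1e-8).
#' @param scale_group \code{"channel"} (default) or \code{"clip"}.
#' @return Channels x F feature matrix with entries in [0, 1]; bin j of a
#'   row corresponds to frequency j / clip-duration Hz.
#' @export
compute_features <- function(clip, eps = 1e-8, scale_group = c("channel", "clip")) {
  scale_group <- match.arg(scale_group)
  signal <- if (inherits(clip, "eeg_clip")) clip$signal else clip
  Tn <- ncol(signal)
  stopifnot(Tn >= 2)
  n_keep <- if (Tn %% 2L == 0L) Tn %/% 2L - 1L else (Tn - 1L) %/% 2L
  spec <- t(stats::mvfft(t(signal)))          # row-wise DFT
  amp <- Mod(spec[, 2L:(n_keep + 1L), drop = FALSE])
  feat <- log(amp + eps)
  minmax <- function(x) {
    rng <- range(x)
    if (rng[2] - rng[1] <= 0) return(x * 0)
    (x - rng[1]) / (rng[2] - rng[1])
  }
  if (scale_group == "channel") {
    feat <- t(apply(feat, 1L, minmax))
  } else {
    feat <- minmax(feat)
  }
  feat
}

#' Patient-disjoint train/validation/test split
#'
#' Patients (not clips) are randomly partitioned, so no patient contributes
#' clips to more than one split.
#'
#' @param clips List of \code{eeg_clip}s with \code{source$patient_id}.
#' @param fractions Numeric vector summing to 1, named or in
#'   train/validation/test order.
#' @param seed Integer seed.
#' @return Named list of integer index vectors into \code{clips}.
#' @export
split_by_patient <- function(clips, fractions = c(train = 0.8, validation = 0.1,
                                                  test = 0.1), seed = 0L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8)
  if (is.null(names(fractions))) {
    names(fractions) <- c("train", "validation", "test")[seq_along(fractions)]
  }
  patients <- vapply(clips, function(cl) as.character(cl$source$patient_id),
                     character(1))
  uniq <- sort(unique(patients))
  n_parts <- sum(fractions > 0)
  if (length(uniq) < n_parts) {
    stop("partition error: fewer patients (", length(uniq),
         ") than partitions (", n_parts, ")")
  }
  set.seed(seed)
  shuffled <- sample(uniq)
  cuts <- round(cumsum(fractions) * length(uniq))
  cuts[length(cuts)] <- length(uniq)
  out <- list()
  lo <- 0L
  for (k in seq_along(fractions)) {
    ids <- if (cuts[k] > lo) shuffled[(lo + 1L):cuts[k]] else character(0)
    out[[names(fractions)[k]]] <- which(patients %in% ids)
    lo <- cuts[k]
  }
  out
}
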