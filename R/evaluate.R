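# Evaluation: accuracy / precision / recall / weighted F1, per-class
# one-vs-rest AUROC, normalized confusion matrix, multi-seed confidence
# intervals, and graph-recovery scoring against ground-truth connectivity.

#' Core classification metrics
#'
#' @param y_true,y_pred Integer class labels (1-based).
#' @param n_classes Number of classes.
#' @return List with accuracy, per-class precision/recall/F1, macro and
#'   weighted averages, and the row-normalized confusion matrix.
#' @export
classification_metrics <- function(y_true, y_pred, n_classes) {
  cm <- matrix(0, n_classes, n_classes)
  for (i in seq_along(y_true)) cm[y_true[i], y_pred[i]] <- cm[y_true[i], y_pred[i]] + 1
  support <- rowSums(cm)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  w <- support / sum(support)
  present <- support > 0
  cm_norm <- cm
  cm_norm[present, ] <- cm[present, , drop = FALSE] / support[present]
  list(accuracy = sum(tp) / length(y_true),
       precision = prec, recall = rec, f1 = f1,
       precision_macro = mean(prec[present]), recall_macro = mean(rec[present]),
       precision_weighted = sum(w * prec), recall_weighted = sum(w * rec),
       f1_weighted = sum(w * f1),
       support = support, confusion = cm_norm)
}

#' Evaluate a trained model on a partition
#'
#' Arg-max predictions feed the count metrics; the class probabilities feed
#' per-class one-vs-rest AUROC (via pROC). A class absent from the
#' partition gets \code{NA} AUROC and is excluded from averages.
#'
#' @param model An \code{iggcn_model}.
#' @param data Prepared partition (see \code{\link{prepare_clips}}).
#' @return A metrics report list; \code{auroc} is named by class level.
#' @export
iggcn_evaluate <- function(model, data) {
  stopifnot(length(data$X) >= 1L)
  pred <- iggcn_predict(model, data)
  met <- classification_metrics(data$y, max.col(pred$probs, ties.method = "first"), model$cfg$n_classes)
  auroc <- rep(NA_real_, model$cfg$n_classes)
  for (c in seq_len(model$cfg$n_classes)) {
    pos <- data$y == c
    if (any(pos) && any(!pos)) {
      auroc[c] <- as.numeric(pROC::auc(pROC::roc(
        response = factor(as.integer(pos), levels = c(0, 1)),
        predictor = pred$probs[, c], quiet = TRUE,
        direction = "<", levels = c("0", "1"))))
    }
  }
  names(auroc) <- model$levels
  met$auroc <- auroc
  met$auroc_macro <- mean(auroc, na.rm = TRUE)
  met$probs <- pred$probs
  met
}

#' Multi-seed metric summary
#'
#' Runs \code{runner(seed)} for each seed and reports, per scalar metric,
#' the mean and the normal-approximation 95% confidence half-width
#' \code{1.96 sd / sqrt(n)}.
#'
#' @param seeds Integer vector of seeds.
#' @param runner Function seed -> named list/vector of scalar metrics.
#' @return Data frame with metric, mean, ci_halfwidth, n_seeds.
#' @export
seed_ensemble <- function(seeds, runner) {
  stopifnot(length(seeds) >= 1L)
  vals <- lapply(seeds, function(s) unlist(runner(s)))
  tab <- do.call(rbind, vals)
  ci <- if (length(seeds) >= 2L) {
    1.96 * apply(tab, 2L, stats::sd) / sqrt(length(seeds))
  } else rep(NA_real_, ncol(tab))
  data.frame(metric = colnames(tab), mean = colMeans(tab),
             ci_halfwidth = ci, n_seeds = length(seeds),
             row.names = NULL)
}

#' Graph-recovery score
#'
#' Ranks the symmetrized off-diagonal weights of each adjacency against the
#' true edge presence of its class graph (one-vs-rest AUROC via the rank
#' statistic) and averages over clips.
#'
#' @param adjs List of learned/prior adjacency matrices, one per clip.
#' @param truths Either one ground-truth adjacency or a list parallel to
#'   \code{adjs}.
#' @return Mean ranking score in [0, 1]; \code{NA} (with a warning) for
#'   degenerate ground truths where all edges are present or absent.
#' @export
graph_recovery_score <- function(adjs, truths) {
  if (is.matrix(truths)) truths <- rep(list(truths), length(adjs))
  stopifnot(length(adjs) == length(truths))
  ut <- upper.tri(adjs[[1L]])
  scores <- vapply(seq_along(adjs), function(i) {
    A <- (adjs[[i]] + t(adjs[[i]])) / 2
    lab <- truths[[i]][ut] > 0
    if (all(lab) || !any(lab)) return(NA_real_)
    rank_auc(A[ut], lab)
  }, numeric(1))
  if (anyNA(scores)) {
    warning("degenerate ground truth for ", sum(is.na(scores)),
            " clip(s); excluded from the mean")
  }
  mean(scores, na.rm = TRUE)
}
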