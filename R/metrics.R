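# Shared evaluation metrics.

#' Majority vote over per-time-point predictions
#'
#' Returns the most frequent label. With an odd number of time points (the
#' default T = 35) binary ties are impossible; a tie among more labels is
#' broken toward the alphabetically first, deterministically.
#'
#' @param timepoint_preds Vector of predicted labels.
#' @return The winning label (character scalar).
#' @export
majority_vote <- function(timepoint_preds) {
  if (length(timepoint_preds) == 0)
    stop("majority_vote on an empty prediction vector", call. = FALSE)
  tab <- table(as.character(timepoint_preds))
  winners <- sort(names(tab)[tab == max(tab)])
  winners[1]
}

#' Classification metrics with per-class breakdown
#'
#' Accuracy (fraction correct) plus macro-averaged (unweighted) precision,
#' recall and F1, with per-class values. Classes never predicted get
#' precision 0 rather than NaN.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @return List with `accuracy`, `precision`, `recall`, `f1`, a `per_class`
#'   data frame and the `confusion` table.
#' @export
classification_metrics <- function(y_true, y_pred) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred lengths differ", call. = FALSE)
  if (length(y_true) == 0) stop("empty input", call. = FALSE)
  lev <- sort(unique(c(y_true, y_pred)))
  tt <- factor(y_true, levels = lev); pp <- factor(y_pred, levels = lev)
  conf <- table(truth = tt, pred = pp)
  per <- lapply(lev, function(cl) {
    tp <- conf[cl, cl]
    fp <- sum(conf[, cl]) - tp
    fn <- sum(conf[cl, ]) - tp
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = cl, n = tp + fn, precision = prec, recall = rec, f1 = f1)
  })
  per <- do.call(rbind, per)
  list(accuracy = mean(y_true == y_pred),
       precision = mean(per$precision),
       recall = mean(per$recall),
       f1 = mean(per$f1),
       per_class = per,
       confusion = conf)
}
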