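# Thresholded confusion counting, the metric suite and rank-based AUROC.

#' Confusion counts at a probability threshold
#'
#' A sample is called positive when its score is greater than or equal to
#' the threshold (ties count as positive calls).
#'
#' @param scores Per-sample positive-class probabilities.
#' @param labels 0/1 labels of the same length.
#' @param threshold Decision threshold in `[0, 1]`.
#' @return An object of class `confusion_counts` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0.5) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length")
  stopifnot(threshold >= 0, threshold <= 1, all(labels %in% c(0, 1)))
  call_pos <- scores >= threshold
  structure(list(
    TP = sum(call_pos & labels == 1),
    TN = sum(!call_pos & labels == 0),
    FP = sum(call_pos & labels == 0),
    FN = sum(!call_pos & labels == 1)
  ), class = "confusion_counts")
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 and the
#' Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FN)(TP+FP)(TN+FP)(TN+FN))`. Undefined `0/0`
#' cells (e.g. precision with no predicted positives) and an MCC with a zero
#' denominator factor return 0, with a warning.
#'
#' @param counts A [confusion_counts()] result.
#' @return An object of class `metrics_report` with `ACC`, `P`, `R`, `F1`,
#'   `MCC` (no AUROC; see [auroc()]).
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- as.numeric(counts$TP); tn <- as.numeric(counts$TN)
  fp <- as.numeric(counts$FP); fn <- as.numeric(counts$FN)
  total <- tp + tn + fp + fn
  if (total < 1) stop("empty confusion counts")
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined (0/0); returning 0")
      0
    } else num / den
  }
  acc <- (tp + tn) / total
  p <- safe_div(tp, tp + fp, "precision")
  r <- safe_div(tp, tp + fn, "recall")
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  denom <- (tp + fn) * (tp + fp) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) {
    warning("MCC denominator has a zero factor; returning 0")
    0
  } else (tp * tn - fp * fn) / sqrt(denom)
  structure(list(ACC = acc, P = p, R = r, F1 = f1, MCC = mcc,
                 counts = counts),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  vals <- unlist(x[intersect(c("ACC", "P", "R", "F1", "MCC", "AUROC"),
                             names(x))])
  cat(paste(sprintf("%s=%.4f", names(vals), vals), collapse = "  "), "\n")
  invisible(x)
}

#' Area under the ROC curve (exact Mann-Whitney form)
#'
#' Computed via midranks: the fraction of (positive, negative) pairs where
#' the positive outscores the negative, ties counting one half. Invariant
#' under strictly monotone transforms of the scores.
#'
#' @param scores Per-sample scores (higher = more positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return A scalar in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("AUROC requires at least one positive and one negative")
  r <- rank(scores)  # midranks for ties
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Full metric report for scored samples
#'
#' @inheritParams confusion_counts
#' @return A `metrics_report` including `AUROC` and the confusion counts.
#' @export
evaluate_scores <- function(scores, labels, threshold = 0.5) {
  rep <- compute_metrics(confusion_counts(scores, labels, threshold))
  rep$AUROC <- auroc(scores, labels)
  rep$threshold <- threshold
  rep
}

metrics_row <- function(rep) {
  data.frame(ACC = rep$ACC, P = rep$P, R = rep$R, F1 = rep$F1,
             MCC = rep$MCC, AUROC = rep$AUROC %||% NA_real_)
}
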