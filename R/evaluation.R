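# Confusion-matrix metrics, rank-based AUC, and the head-count sweep
# harness. Class 1 is the positive class (AD in AD vs CN, pMCI in
# pMCI vs sMCI, ...); the decision threshold on its predicted
# probability is 0.5. Metrics with zero denominators are reported as NA,
# never coerced to 0.

#' Confusion counts
#'
#' @param labels,predictions Binary vectors (0/1) of equal length; class
#'   1 is positive.
#' @return An object of class `mmdda_confusion` with integer fields `tp`,
#'   `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(labels, predictions) {
  if (length(labels) != length(predictions))
    stop_mmdda("confusion_counts: length mismatch", "mmdda_shape_error")
  if (!all(labels %in% c(0, 1)) || !all(predictions %in% c(0, 1)))
    stop_mmdda("confusion_counts: inputs must be binary 0/1", "mmdda_config_error")
  structure(list(tp = sum(labels == 1 & predictions == 1),
                 tn = sum(labels == 0 & predictions == 0),
                 fp = sum(labels == 0 & predictions == 1),
                 fn = sum(labels == 1 & predictions == 0)),
            class = "mmdda_confusion")
}

#' Metrics from confusion counts
#'
#' `ACC = (TP+TN)/(TP+TN+FP+FN)`, `SEN = TP/(TP+FN)` (recall),
#' `SPE = TN/(TN+FP)`, `F1 = 2 * Precision * Recall /
#' (Precision + Recall)` with `Precision = TP/(TP+FP)`.
#'
#' @param cc An [confusion_counts()] object.
#' @return Named list with `acc`, `sen`, `spe`, `f1` (NA where the
#'   denominator vanishes).
#' @export
classification_metrics <- function(cc) {
  stopifnot(inherits(cc, "mmdda_confusion"))
  n <- cc$tp + cc$tn + cc$fp + cc$fn
  sen <- if (cc$tp + cc$fn > 0) cc$tp / (cc$tp + cc$fn) else NA_real_
  spe <- if (cc$tn + cc$fp > 0) cc$tn / (cc$tn + cc$fp) else NA_real_
  prec <- if (cc$tp + cc$fp > 0) cc$tp / (cc$tp + cc$fp) else NA_real_
  f1 <- if (!is.na(prec) && !is.na(sen) && prec + sen > 0)
    2 * prec * sen / (prec + sen) else NA_real_
  list(acc = if (n > 0) (cc$tp + cc$tn) / n else NA_real_,
       sen = sen, spe = spe, f1 = f1)
}

#' Rank-based AUC
#'
#' The probability that a uniformly drawn positive sample outscores a
#' uniformly drawn negative one, with ties counting one half — the
#' Mann-Whitney form of the area under the ROC curve.
#'
#' @param labels Binary 0/1 vector; both classes must be present.
#' @param scores Numeric scores for the positive class.
#' @return A scalar in `[0, 1]`.
#' @export
rank_auc <- function(labels, scores) {
  if (length(labels) != length(scores))
    stop_mmdda("rank_auc: length mismatch", "mmdda_shape_error")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop_mmdda("rank_auc: both classes must be present", "mmdda_config_error")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Full metric report from scores
#'
#' Thresholds the positive-class probabilities at `threshold`, counts the
#' confusion matrix, and reports ACC/SEN/SPE/AUC/F1 together with the
#' counts.
#'
#' @param labels Binary 0/1 vector.
#' @param scores Positive-class probabilities or scores.
#' @param threshold Decision threshold on the score; default 0.5.
#' @return An object of class `mmdda_metric_report`.
#' @export
metric_report <- function(labels, scores, threshold = 0.5) {
  preds <- as.integer(scores > threshold)
  cc <- confusion_counts(labels, preds)
  m <- classification_metrics(cc)
  auc <- if (sum(labels == 1) > 0 && sum(labels == 0) > 0)
    rank_auc(labels, scores) else NA_real_
  structure(list(acc = m$acc, sen = m$sen, spe = m$spe, auc = auc,
                 f1 = m$f1, confusion = cc, n = length(labels)),
            class = "mmdda_metric_report")
}

#' @export
print.mmdda_metric_report <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.4f", v)
  cat(sprintf("Metric report (n = %d)\n", x$n))
  cat(sprintf("  ACC %s  SEN %s  SPE %s  AUC %s  F1 %s\n",
              fmt(x$acc), fmt(x$sen), fmt(x$spe), fmt(x$auc), fmt(x$f1)))
  cat(sprintf("  TP %d  TN %d  FP %d  FN %d\n",
              x$confusion$tp, x$confusion$tn, x$confusion$fp, x$confusion$fn))
  invisible(x)
}

#' Head-count sweep
#'
#' Trains and evaluates the full model once per attention head count on
#' the same data and seed, returning one row per configuration. Every
#' count must divide the sequence feature dimension `E = 2C`.
#'
#' @param data List with `source` and `target` sample lists (e.g. the two
#'   domains of [generate_dataset()] output).
#' @param head_counts Integer vector of head counts to try.
#' @param config A [train_config()]; its `heads` entry is overridden per
#'   row.
#' @return A data frame with columns `heads`, `acc`, `sen`, `spe`, `auc`,
#'   `f1`.
#' @export
head_sweep <- function(data, head_counts, config = train_config()) {
  E <- 2L * config$encoder$channels[length(config$encoder$channels)]
  bad <- head_counts[E %% as.integer(head_counts) != 0]
  if (length(bad))
    stop_mmdda(sprintf("head count(s) %s do not divide E = %d",
                       paste(bad, collapse = ", "), E), "mmdda_config_error")
  rows <- lapply(head_counts, function(h) {
    cfg <- config
    cfg$heads <- as.integer(h)
    rep <- run_variant("MMDDA", data, cfg)
    data.frame(heads = as.integer(h), acc = rep$acc, sen = rep$sen,
               spe = rep$spe, auc = rep$auc, f1 = rep$f1)
  })
  do.call(rbind, rows)
}
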