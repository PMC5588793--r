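#' Confusion counts
#'
#' Counts with the ERRP class as positive: TP = true ERRPs predicted ERRP,
#' TN = non-ERRPs predicted non-ERRP, FP = non-ERRPs predicted ERRP,
#' FN = ERRPs predicted non-ERRP.
#'
#' @param y_true,y_pred equal-length vectors of `"positive"` / `"negative"`.
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusion <- function(y_true, y_pred) {
  if (length(y_true) == 0L) input_error("confusion: empty input")
  if (length(y_true) != length(y_pred)) {
    input_error("confusion: label vectors differ in length")
  }
  ok <- function(v) all(v %in% c("positive", "negative"))
  if (!ok(y_true) || !ok(y_pred)) {
    input_error("confusion: labels must be 'positive' or 'negative'")
  }
  c(TP = sum(y_true == "positive" & y_pred == "positive"),
    TN = sum(y_true == "negative" & y_pred == "negative"),
    FP = sum(y_true == "negative" & y_pred == "positive"),
    FN = sum(y_true == "positive" & y_pred == "negative"))
}

#' Classification metrics from confusion counts
#'
#' Sensitivity `100*TP/(TP+FN)`, specificity `100*TN/(TN+FP)`, accuracy
#' `100*(TP+TN)/total` (all percentages) and the Matthews correlation
#' coefficient `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`.
#' A percentage with zero denominator is reported as `NA` (undefined);
#' an MCC with any zero factor under the square root is 0 by the standard
#' convention.
#'
#' @param counts named vector from [confusion()].
#' @return A single numeric value.
#' @export
sensitivity <- function(counts) {
  d <- counts[["TP"]] + counts[["FN"]]
  if (d == 0) return(NA_real_)
  100 * counts[["TP"]] / d
}

#' @rdname sensitivity
#' @export
specificity <- function(counts) {
  d <- counts[["TN"]] + counts[["FP"]]
  if (d == 0) return(NA_real_)
  100 * counts[["TN"]] / d
}

#' @rdname sensitivity
#' @export
accuracy <- function(counts) {
  d <- sum(counts[c("TP", "TN", "FP", "FN")])
  if (d == 0) return(NA_real_)
  100 * (counts[["TP"]] + counts[["TN"]]) / d
}

#' @rdname sensitivity
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); tn <- as.numeric(counts[["TN"]])
  fp <- as.numeric(counts[["FP"]]); fn <- as.numeric(counts[["FN"]])
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

eval_metrics <- function(counts) {
  list(counts = counts,
       sensitivity = sensitivity(counts),
       specificity = specificity(counts),
       accuracy = accuracy(counts),
       mcc = mcc(counts))
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over all distinct scores and returns the
#' operating points (1 - specificity, sensitivity) from (0,0) to (1,1),
#' with the area under the curve by trapezoidal integration. The trapezoid
#' area equals the rank statistic: the probability that a random positive
#' outscores a random negative, ties counted one half.
#'
#' @param scores numeric decision scores, higher = more positive.
#' @param y_true labels `"positive"` / `"negative"`.
#' @return A list with `points` (`data.frame` columns `threshold`, `fpr`,
#'   `tpr`) and `auc`.
#' @export
roc_auc <- function(scores, y_true) {
  if (length(scores) != length(y_true)) {
    input_error("roc_auc: scores and labels differ in length")
  }
  if (any(!is.finite(scores))) input_error("roc_auc: scores must be finite")
  pos <- y_true == "positive"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    input_error("roc_auc: both classes must be present")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # one operating point after each distinct score value
  keep <- c(s[-length(s)] != s[-1L], TRUE)
  tpr <- cumsum(p)[keep] / n_pos
  fpr <- cumsum(!p)[keep] / n_neg
  points <- data.frame(threshold = c(Inf, s[keep]),
                       fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(points$fpr) * (points$tpr[-1L] + points$tpr[-nrow(points)]) / 2)
  list(points = points, auc = auc)
}

#' Leave-one-out cross-validation of the full pipeline
#'
#' Each record is held out once; the classifier is trained on the remaining
#' records and scores the held-out one. The confusion table is pooled over
#' all folds (with test sets of size one, pooling is the only well-defined
#' aggregate) and sensitivity, specificity, accuracy, MCC and the ROC/AUC
#' are computed from the pooled held-out predictions.
#'
#' Hyperparameters (`gamma`, `cost_ratio`) left at their data-dependent
#' defaults are resolved once on the full dataset and held fixed across
#' folds, so every fold trains the same model family. With fixed
#' hyperparameters, removing a non-support-vector from the training set
#' leaves the SVM solution unchanged (the Karush-Kuhn-Tucker conditions
#' still hold), so those folds reuse the full-data model's score and only
#' support-vector folds are retrained; `exact = FALSE` disables the
#' shortcut and retrains every fold (identical results, slower).
#'
#' @param records labelled, validated protein record `data.frame` with both
#'   classes present.
#' @param config an [svm_config()]; its `scheme` selects the encoding.
#' @param threshold decision threshold applied to held-out scores.
#' @param exact use the non-support-vector shortcut (default `TRUE`).
#' @return A list of class `erpred_eval`: confusion `counts`,
#'   `sensitivity`, `specificity`, `accuracy`, `mcc`, `roc` (points +
#'   `auc`), and `predictions` (`data.frame` id, label, score, pred).
#' @export
loocv <- function(records, config = svm_config(), threshold = NULL,
                  exact = TRUE) {
  y <- factor(records$label, levels = c("positive", "negative"))
  if (anyNA(y)) input_error("loocv: all records must be labelled")
  if (nlevels(droplevels(y)) < 2L) input_error("loocv: both classes required")
  if (nrow(records) < 2L) input_error("loocv: need at least two records")
  threshold <- threshold %||% config$threshold
  X <- encode_batch(records, config$scheme, n = config$n,
                    lambda = config$lambda, w = config$w)
  N <- nrow(X)
  full <- train_model(X, y, config)
  config$gamma <- full$gamma
  config$cost_ratio <- full$cost_ratio
  score <- numeric(N)
  if (exact) {
    refit <- sort(full$fit$index)
    keep <- setdiff(seq_len(N), refit)
    if (length(keep)) {
      score[keep] <- predict_model(full, X[keep, , drop = FALSE])$score
    }
  } else {
    refit <- seq_len(N)
  }
  for (i in refit) {
    model <- train_model(X[-i, , drop = FALSE], y[-i], config)
    score[i] <- predict_model(model, X[i, , drop = FALSE])$score
  }
  pred <- ifelse(score >= threshold, "positive", "negative")
  counts <- confusion(as.character(y), pred)
  roc <- roc_auc(score, as.character(y))
  structure(c(eval_metrics(counts),
              list(roc = roc,
                   predictions = data.frame(id = records$id,
                                            label = as.character(y),
                                            score = score, pred = pred,
                                            stringsAsFactors = FALSE))),
            class = "erpred_eval")
}

#' @export
print.erpred_eval <- function(x, ...) {
  cat("<erpred_eval> pooled leave-one-out performance\n")
  cat(sprintf("  TP=%d TN=%d FP=%d FN=%d\n", x$counts[["TP"]],
              x$counts[["TN"]], x$counts[["FP"]], x$counts[["FN"]]))
  cat(sprintf("  sensitivity %.2f%%  specificity %.2f%%  accuracy %.2f%%\n",
              x$sensitivity, x$specificity, x$accuracy))
  cat(sprintf("  MCC %.2f  AUC %.2f\n", x$mcc, x$roc$auc))
  invisible(x)
}

#' Write an evaluation report as TSV
#'
#' @param eval an `erpred_eval`.
#' @param path metrics output path.
#' @param roc_path optional path for the ROC operating points.
#' @return `path`, invisibly.
#' @export
write_eval_tsv <- function(eval, path, roc_path = NULL) {
  df <- data.frame(metric = c("TP", "TN", "FP", "FN", "sensitivity",
                              "specificity", "accuracy", "mcc", "auc"),
                   value = c(eval$counts[["TP"]], eval$counts[["TN"]],
                             eval$counts[["FP"]], eval$counts[["FN"]],
                             round(eval$sensitivity, 2),
                             round(eval$specificity, 2),
                             round(eval$accuracy, 2),
                             round(eval$mcc, 2), round(eval$roc$auc, 2)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(roc_path)) {
    utils::write.table(eval$roc$points, roc_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
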