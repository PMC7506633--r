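# Classification evaluation: confusion counts, the three ratio metrics,
# ROC/AUC, and a macro one-vs-rest multi-class report.

#' Confusion counts for a designated positive class
#'
#' Tallies the four prediction states (TP, FP, TN, FN) of a classifier
#' against reference labels, treating `positive_class` as the positive
#' condition and everything else as negative.
#'
#' @param labels reference class labels.
#' @param predictions predicted class labels, same length.
#' @param positive_class the class counted as positive.
#' @return An object of class `confusion_counts`: list with `tp`, `fp`,
#'   `tn`, `fn` and `positive_class`.
#' @examples
#' confusion_counts(c("P", "P", "N", "N"), c("P", "N", "P", "N"), "P")
#' @export
confusion_counts <- function(labels, predictions, positive_class) {
  if (length(labels) != length(predictions))
    stop("labels (", length(labels), ") and predictions (",
         length(predictions), ") differ in length")
  labels <- as.character(labels)
  predictions <- as.character(predictions)
  classes <- unique(c(labels, predictions))
  if (!as.character(positive_class) %in% classes)
    stop("positive_class '", positive_class, "' absent from the class set")
  ap <- labels == positive_class
  pp <- predictions == positive_class
  structure(list(tp = sum(ap & pp), fp = sum(!ap & pp),
                 tn = sum(!ap & !pp), fn = sum(ap & !pp),
                 positive_class = as.character(positive_class)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("confusion counts (positive = ", x$positive_class, "): ",
      "TP=", x$tp, " FP=", x$fp, " TN=", x$tn, " FN=", x$fn, "\n", sep = "")
  invisible(x)
}

undefined_metric <- function(what, denom_desc) {
  warning(what, " is undefined: ", denom_desc, " is zero", call. = FALSE)
  NA_real_
}

#' Accuracy, sensitivity and specificity from confusion counts
#'
#' `accuracy = (TP + TN) / (TP + TN + FP + FN)`,
#' `sensitivity = TP / (TP + FN)` (true positive rate),
#' `specificity = TN / (TN + FP)` (true negative rate).
#' A zero denominator yields `NA` with a warning rather than a silent 0.
#'
#' @param counts a [confusion_counts()] result.
#' @return A number in `[0, 1]`, or `NA` if undefined.
#' @export
accuracy <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  total <- counts$tp + counts$tn + counts$fp + counts$fn
  if (total == 0) return(undefined_metric("accuracy", "total count"))
  (counts$tp + counts$tn) / total
}

#' @rdname accuracy
#' @export
sensitivity <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$tp + counts$fn == 0)
    return(undefined_metric("sensitivity", "TP + FN"))
  counts$tp / (counts$tp + counts$fn)
}

#' @rdname accuracy
#' @export
specificity <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$tn + counts$fp == 0)
    return(undefined_metric("specificity", "TN + FP"))
  counts$tn / (counts$tn + counts$fp)
}

#' ROC curve and AUC
#'
#' Builds the ROC curve by sweeping a decision threshold over all distinct
#' score values (ties grouped at one threshold) and integrates the area
#' under it by the trapezoidal rule. With ties grouped this way the
#' trapezoidal AUC equals the Mann-Whitney concordance probability: the
#' probability that a random positive outscores a random negative, ties
#' counted 1/2.
#'
#' @param scores numeric scores, higher meaning more positive.
#' @param labels binary labels: logical, 0/1 numeric, or any two-level
#'   vector together with `positive_class`.
#' @param positive_class which label value is positive (required when
#'   `labels` is not logical/0-1).
#' @return List with `curve` (data frame: threshold, fpr, tpr; thresholds
#'   descending, endpoints (0,0) and (1,1) included) and `auc`.
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$auc  # 1
#' @export
roc_auc <- function(scores, labels, positive_class = NULL) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length")
  if (is.null(positive_class)) {
    if (is.logical(labels)) {
      pos <- labels
    } else if (is.numeric(labels) && all(labels %in% c(0, 1))) {
      pos <- labels == 1
    } else stop("supply positive_class for non-binary label encodings")
  } else {
    pos <- as.character(labels) == as.character(positive_class)
  }
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("ROC needs at least one positive and one negative label")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # group tied scores at a single threshold
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  cum_tp <- cumsum(p)[last_of_group]
  cum_fp <- cumsum(!p)[last_of_group]
  curve <- data.frame(
    threshold = c(Inf, s[last_of_group]),
    fpr = c(0, cum_fp / n_neg),
    tpr = c(0, cum_tp / n_pos)
  )
  auc <- sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) +
                                  utils::tail(curve$tpr, -1)) / 2)
  list(curve = curve, auc = auc)
}

#' One-vs-rest multi-class evaluation report
#'
#' Derives hard predictions by argmax over the score rows (softmax
#' outputs), then evaluates each class one-vs-rest: confusion counts,
#' accuracy, sensitivity, specificity from the argmax predictions, and AUC
#' from that class's score column. Macro metrics are unweighted means over
#' classes; overall accuracy is the fraction of correct argmax labels.
#'
#' @param labels reference labels, length n.
#' @param scores n x K numeric matrix of class scores whose rows sum to 1;
#'   columns follow `class_set`.
#' @param class_set character vector of the K classes (defaults to the
#'   score matrix's column names).
#' @param tol tolerance on the row-sum check.
#' @return List with `per_class` (data frame), `macro` (named list:
#'   accuracy, sensitivity, specificity, auc), `overall_accuracy`, and
#'   `confusion_matrix` (reference in rows, prediction in columns).
#' @export
multiclass_report <- function(labels, scores, class_set = colnames(scores),
                              tol = 1e-6) {
  scores <- as.matrix(scores)
  if (is.null(class_set)) stop("class_set is required when scores has no colnames")
  if (ncol(scores) != length(class_set))
    stop("scores has ", ncol(scores), " columns but class_set has ",
         length(class_set), " classes")
  if (nrow(scores) != length(labels))
    stop("labels and score rows differ in length")
  bad <- abs(rowSums(scores) - 1) > tol
  if (any(bad))
    stop("score rows must sum to 1 (row ", which(bad)[1], " sums to ",
         format(rowSums(scores)[which(bad)[1]]), ")")
  labels <- as.character(labels)
  if (!all(labels %in% class_set))
    stop("labels contain classes outside class_set")
  pred <- class_set[max.col(scores, ties.method = "first")]
  per <- lapply(seq_along(class_set), function(k) {
    cls <- class_set[k]
    cc <- confusion_counts(labels, pred, cls)
    auc_k <- if (any(labels == cls) && any(labels != cls)) {
      roc_auc(scores[, k], labels == cls)$auc
    } else NA_real_
    data.frame(class = cls, tp = cc$tp, fp = cc$fp, tn = cc$tn, fn = cc$fn,
               accuracy = accuracy(cc),
               sensitivity = if (cc$tp + cc$fn > 0) sensitivity(cc) else NA_real_,
               specificity = if (cc$tn + cc$fp > 0) specificity(cc) else NA_real_,
               auc = auc_k, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  cm <- table(factor(labels, levels = class_set),
              factor(pred, levels = class_set), dnn = c("reference", "prediction"))
  list(
    per_class = per,
    macro = list(accuracy = mean(per$accuracy, na.rm = TRUE),
                 sensitivity = mean(per$sensitivity, na.rm = TRUE),
                 specificity = mean(per$specificity, na.rm = TRUE),
                 auc = mean(per$auc, na.rm = TRUE)),
    overall_accuracy = mean(pred == labels),
    confusion_matrix = cm
  )
}
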