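test_that("confusion counts match enumeration and the per-item oracle", {
  cc <- confusion_counts(rep("P", 5), rep("P", 5), "P")
  expect_equal(c(cc$tp, cc$fp, cc$tn, cc$fn), c(5, 0, 0, 0))
  cc2 <- confusion_counts(c("P", "P", "N", "N"), c("P", "N", "P", "N"), "P")
  expect_equal(c(cc2$tp, cc2$fp, cc2$tn, cc2$fn), c(1, 1, 1, 1))

  set.seed(31)
  labels <- sample(c("benign", "malignant"), 200, replace = TRUE)
  preds <- sample(c("benign", "malignant"), 200, replace = TRUE)
  cc3 <- confusion_counts(labels, preds, "benign")
  expect_equal(c(tp = cc3$tp, fp = cc3$fp, tn = cc3$tn, fn = cc3$fn),
               oracle_confusion(labels, preds, "benign"))
  expect_equal(cc3$tp + cc3$fp + cc3$tn + cc3$fn, 200)

  expect_error(confusion_counts(c("P", "N"), "P", "P"), "length")
  expect_error(confusion_counts(c("P", "N"), c("P", "N"), "Q"), "absent")
})

test_that("accuracy, sensitivity, specificity follow the ratio definitions", {
  cc <- structure(list(tp = 3, fp = 1, tn = 4, fn = 2, positive_class = "P"),
                  class = "confusion_counts")
  expect_equal(accuracy(cc), 0.7)
  expect_equal(sensitivity(cc), 0.6)
  expect_equal(specificity(cc), 0.8)

  perfect <- confusion_counts(c("P", "P", "N"), c("P", "P", "N"), "P")
  expect_equal(accuracy(perfect), 1)
  expect_equal(sensitivity(perfect), 1)
  expect_equal(specificity(perfect), 1)

  no_pos <- structure(list(tp = 0, fp = 2, tn = 3, fn = 0,
                           positive_class = "P"), class = "confusion_counts")
  expect_warning(s <- sensitivity(no_pos), "undefined")
  expect_true(is.na(s))
})

test_that("accuracy is the prevalence-weighted mix of sensitivity and specificity", {
  set.seed(17)
  for (rep in 1:20) {
    cc <- structure(as.list(c(stats::setNames(as.numeric(
      sample(1:30, 4, replace = TRUE)), c("tp", "fp", "tn", "fn")))),
      class = "confusion_counts")
    cc$positive_class <- "P"
    n <- cc$tp + cc$fp + cc$tn + cc$fn
    prev <- (cc$tp + cc$fn) / n
    expect_equal(accuracy(cc),
                 prev * sensitivity(cc) + (1 - prev) * specificity(cc),
                 tolerance = 1e-12)
  }
})

test_that("ROC endpoints, monotonicity, and AUC of separable / tied scores", {
  r <- roc_auc(c(0.9, 0.8, 0.7, 0.3, 0.2), c(1, 1, 1, 0, 0))
  expect_equal(r$auc, 1)
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(utils::tail(r$curve$fpr, 1), 1)
  expect_equal(utils::tail(r$curve$tpr, 1), 1)
  expect_true(all(diff(r$curve$tpr) >= 0) && all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$threshold) <= 0))

  tied <- roc_auc(rep(0.5, 10), rep(c(0, 1), 5))
  expect_equal(tied$auc, 0.5)

  expect_error(roc_auc(1:3, c(1, 1, 1)), "at least one")
})

test_that("trapezoidal AUC equals the pairwise concordance oracle", {
  set.seed(41)
  for (rep in 1:10) {
    n <- 50
    labels <- c(rep(1, 20), rep(0, 30))
    scores <- round(stats::rnorm(n), sample(c(1, 6), 1))  # force some ties
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, oracle_auc_pairwise(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under monotone transforms; label swap maps to 1 - AUC", {
  set.seed(43)
  scores <- stats::rnorm(60)
  labels <- stats::rbinom(60, 1, 0.4)
  if (sum(labels) %in% c(0, 60)) labels[1:2] <- c(0, 1)
  a <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(exp(2 * scores) + 5, labels)$auc, a, tolerance = 1e-12)
  expect_equal(roc_auc(scores, 1 - labels)$auc, 1 - a, tolerance = 1e-12)
  cc <- confusion_counts(ifelse(labels == 1, "P", "N"),
                         ifelse(scores > 0, "P", "N"), "P")
  cc_sw <- confusion_counts(ifelse(labels == 1, "P", "N"),
                            ifelse(scores > 0, "P", "N"), "N")
  expect_equal(sensitivity(cc), specificity(cc_sw))
  expect_equal(specificity(cc), sensitivity(cc_sw))
})

test_that("our AUC agrees with an independent ROC package", {
  skip_if_not_installed("pROC")
  set.seed(47)
  scores <- stats::rnorm(80)
  labels <- stats::rbinom(80, 1, 0.5)
  if (sum(labels) %in% c(0, 80)) labels[1:2] <- c(0, 1)
  ours <- roc_auc(scores, labels)$auc
  theirs <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("multiclass report: perfect predictions, binary consistency, macro oracle", {
  classes <- c("normal", "benign", "insitu", "invasive")
  labels <- rep(classes, each = 5)
  scores <- matrix(0.01, 20, 4, dimnames = list(NULL, classes))
  for (i in seq_along(labels)) scores[i, labels[i]] <- 0.97
  rep_ <- multiclass_report(labels, scores)
  expect_equal(rep_$overall_accuracy, 1)
  expect_true(all(rep_$per_class$sensitivity == 1))
  expect_equal(rep_$macro$auc, 1)

  # binary case reduces to the binary operations
  set.seed(53)
  p <- stats::runif(40)
  scores2 <- cbind(neg = 1 - p, pos = p)
  labels2 <- ifelse(stats::rbinom(40, 1, 0.5) == 1, "pos", "neg")
  rep2 <- multiclass_report(labels2, scores2)
  cc <- confusion_counts(labels2, ifelse(p > 0.5, "pos", "neg"), "pos")
  expect_equal(rep2$per_class$sensitivity[rep2$per_class$class == "pos"],
               sensitivity(cc))
  expect_equal(rep2$per_class$auc[rep2$per_class$class == "pos"],
               roc_auc(p, labels2 == "pos")$auc)

  # macro = mean of independently computed per-class one-vs-rest values
  set.seed(59)
  lab4 <- sample(classes, 100, replace = TRUE)
  raw <- matrix(stats::rexp(400), 100, 4)
  sm <- raw / rowSums(raw)
  colnames(sm) <- classes
  rep4 <- multiclass_report(lab4, sm)
  pred4 <- classes[max.col(sm, ties.method = "first")]
  sens_each <- vapply(classes, function(cl)
    sensitivity(confusion_counts(lab4, pred4, cl)), 1)
  auc_each <- vapply(seq_along(classes), function(k)
    roc_auc(sm[, k], lab4 == classes[k])$auc, 1)
  expect_equal(rep4$macro$sensitivity, mean(sens_each))
  expect_equal(rep4$macro$auc, mean(auc_each))
  expect_equal(rep4$overall_accuracy, mean(pred4 == lab4))

  expect_error(multiclass_report(lab4, raw, classes), "sum to 1")
})
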