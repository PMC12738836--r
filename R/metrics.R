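# Classification metric suite: confusion matrix, weighted/macro precision,
# recall, F1, MCC, ROC-AUC (via pROC) and average precision.

#' Compute the full metric suite from predictions
#'
#' @param truth Character/factor vector of true labels.
#' @param predicted Character/factor vector of predicted labels.
#' @param score_positive Numeric score (probability) of the positive class,
#'   used for ROC-AUC, average precision and curve points. The positive class
#'   is the second element of `classes`.
#' @param classes Class levels; defaults to the sorted union of labels.
#' @return A `metrics_report` object.
#' @export
compute_metrics <- function(truth, predicted, score_positive = NULL,
                            classes = NULL) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (is.null(classes)) classes <- sort(unique(c(truth, predicted)))
  truth_f <- factor(truth, levels = classes)
  pred_f <- factor(predicted, levels = classes)
  cm <- table(truth = truth_f, predicted = pred_f)
  n <- sum(cm)
  cm_pct <- sweep(cm, 1, pmax(rowSums(cm), 1), "/") * 100

  support <- rowSums(cm)
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  w <- support / n
  per_class <- tibble(
    class = classes, precision = as.numeric(prec), recall = as.numeric(rec),
    f1 = as.numeric(f1), support = as.integer(support)
  )

  mcc <- if (length(classes) == 2) {
    TP <- cm[2, 2]; TN <- cm[1, 1]; FP <- cm[1, 2]; FN <- cm[2, 1]
    den <- sqrt(as.numeric(TP + FP)) * sqrt(as.numeric(TP + FN)) *
      sqrt(as.numeric(TN + FP)) * sqrt(as.numeric(TN + FN))
    if (den == 0) 0 else (as.numeric(TP) * TN - as.numeric(FP) * FN) / den
  } else {
    NA_real_
  }

  single_class <- length(unique(truth)) < 2
  roc_auc <- ap <- NA_real_
  roc_curve <- pr_curve <- NULL
  if (!is.null(score_positive) && !single_class && length(classes) == 2) {
    pos <- classes[2]
    y <- as.integer(truth == pos)
    r <- pROC::roc(y, score_positive, quiet = TRUE, direction = "<",
                   levels = c(0, 1))
    roc_auc <- as.numeric(pROC::auc(r))
    roc_curve <- tibble(
      fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities)
    )
    ap <- average_precision(y, score_positive)
    pr_curve <- pr_curve_points(y, score_positive)
  }

  structure(
    list(
      confusion = cm, confusion_pct = cm_pct, n = n,
      accuracy = sum(tp) / n,
      per_class = per_class,
      precision_weighted = sum(w * prec), recall_weighted = sum(w * rec),
      f1_weighted = sum(w * f1),
      precision_macro = mean(prec), recall_macro = mean(rec),
      f1_macro = mean(f1),
      mcc = mcc, roc_auc = roc_auc, average_precision = ap,
      roc_curve = roc_curve, pr_curve = pr_curve,
      single_class = single_class, classes = classes
    ),
    class = "metrics_report"
  )
}

# step-integrated average precision (sum over ranks of dRecall * precision)
average_precision <- function(y, score) {
  ord <- order(score, decreasing = TRUE)
  y <- y[ord]
  P <- sum(y)
  if (P == 0) return(NA_real_)
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  rec <- tp / P
  drec <- diff(c(0, rec))
  sum(drec * prec)
}

pr_curve_points <- function(y, score) {
  ord <- order(score, decreasing = TRUE)
  y <- y[ord]
  P <- sum(y)
  tp <- cumsum(y)
  tibble(
    recall = tp / max(P, 1),
    precision = tp / seq_along(y),
    threshold = score[ord]
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report> n =", x$n, "\n")
  print(x$confusion)
  cat(sprintf(
    "accuracy %.4f | weighted P/R/F1 %.4f/%.4f/%.4f | MCC %.4f | AUC %s | AP %s\n",
    x$accuracy, x$precision_weighted, x$recall_weighted, x$f1_weighted,
    x$mcc,
    ifelse(is.na(x$roc_auc), "NA", sprintf("%.4f", x$roc_auc)),
    ifelse(is.na(x$average_precision), "NA", sprintf("%.4f", x$average_precision))
  ))
  if (x$single_class) cat("note: single-class truth; ROC-AUC/AP undefined\n")
  invisible(x)
}

#' Export a metrics report as JSON and TSV
#'
#' Writes the scalar metrics to `<prefix>.json` and `<prefix>.tsv`, and the
#' ROC / precision-recall curve points (when present) to
#' `<prefix>_roc.tsv` / `<prefix>_pr.tsv`.
#'
#' @param report A `metrics_report`.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_metrics <- function(report, prefix) {
  stopifnot(inherits(report, "metrics_report"))
  td <- tidy(report)
  jsonlite::write_json(setNames(as.list(td$value), td$metric),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  write.table(as.data.frame(td), paste0(prefix, ".tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (!is.null(report$roc_curve)) {
    write.table(as.data.frame(report$roc_curve), paste0(prefix, "_roc.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(as.data.frame(report$pr_curve), paste0(prefix, "_pr.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(prefix)
}

#' @describeIn compute_metrics Long tibble of the scalar metrics.
#' @param x A `metrics_report`.
#' @param ... Unused.
#' @export
tidy.metrics_report <- function(x, ...) {
  tibble(
    metric = c("accuracy", "precision_weighted", "recall_weighted",
               "f1_weighted", "precision_macro", "recall_macro", "f1_macro",
               "mcc", "roc_auc", "average_precision"),
    value = c(x$accuracy, x$precision_weighted, x$recall_weighted,
              x$f1_weighted, x$precision_macro, x$recall_macro, x$f1_macro,
              x$mcc, x$roc_auc, x$average_precision)
  )
}

#' @describeIn compute_metrics One-row summary tibble.
#' @export
glance.metrics_report <- function(x, ...) {
  tibble(
    n = x$n, accuracy = x$accuracy, f1_weighted = x$f1_weighted,
    mcc = x$mcc, roc_auc = x$roc_auc, average_precision = x$average_precision
  )
}
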