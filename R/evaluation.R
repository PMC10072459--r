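# Multi-class evaluation: confusion matrices, per-class one-vs-rest
# precision / sensitivity / F1 with macro averages, the squared-macro-F1
# score, and per-class ROC / PR curves with AUC.

#' Confusion matrix of true vs predicted labels
#'
#' @param true_labels,predicted_labels Equal-length label vectors drawn
#'   from `class_names`.
#' @param class_names Ordered class vector; defaults to the sorted union of
#'   observed labels.
#' @return Integer matrix: entry (i, j) counts beats of true class i
#'   predicted as class j.
#' @export
confusion_matrix <- function(true_labels, predicted_labels,
                             class_names = NULL) {
  true_labels <- as.character(true_labels)
  predicted_labels <- as.character(predicted_labels)
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors differ in length")
  if (is.null(class_names))
    class_names <- sort(unique(c(true_labels, predicted_labels)))
  bad <- setdiff(unique(c(true_labels, predicted_labels)), class_names)
  if (length(bad) > 0)
    stop("unknown label(s): ", paste(bad, collapse = ", "))
  tf <- factor(true_labels, levels = class_names)
  pf <- factor(predicted_labels, levels = class_names)
  m <- table(tf, pf)
  cm <- matrix(as.integer(m), nrow = length(class_names),
               dimnames = list(true = class_names, predicted = class_names))
  cm
}

#' Per-class and macro metrics from a confusion matrix
#'
#' For every class c taken one-vs-rest: TP is the diagonal entry, FP the
#' rest of column c, FN the rest of row c, TN the remainder. Precision =
#' TP/(TP+FP), Sensitivity = TP/(TP+FN), F1 their harmonic mean; cells with
#' zero denominator yield 0 with a warning. Macro values are unweighted
#' means over classes; overall accuracy is trace/total and the score is the
#' squared macro F1.
#'
#' @param confusion Square count matrix (rows true, columns predicted).
#' @return An `ecg_eval_report`: `confusion`, `per_class` data frame,
#'   `macro` list (accuracy, precision, sensitivity, f1) and `score`.
#' @export
metrics_from_confusion <- function(confusion) {
  cm <- as.matrix(confusion)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0)) stop("confusion matrix entries must be non-negative")
  total <- sum(cm)
  if (total == 0) stop("all-zero confusion matrix")
  classes <- rownames(cm)
  if (is.null(classes)) classes <- as.character(seq_len(nrow(cm)))
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe_div <- function(num, den, what) {
    out <- ifelse(den > 0, num / den, 0)
    if (any(den == 0))
      warning("zero denominator in ", what, " for class(es) ",
              paste(classes[den == 0], collapse = ", "),
              "; reporting 0", call. = FALSE)
    out
  }
  precision <- safe_div(tp, tp + fp, "precision")
  sensitivity <- safe_div(tp, tp + fn, "sensitivity")
  f1 <- ifelse(precision + sensitivity > 0,
               2 * precision * sensitivity / (precision + sensitivity), 0)
  macro <- list(accuracy = sum(tp) / total,
                precision = mean(precision),
                sensitivity = mean(sensitivity),
                f1 = mean(f1))
  structure(list(confusion = cm,
                 per_class = data.frame(class = classes,
                                        precision = unname(precision),
                                        sensitivity = unname(sensitivity),
                                        f1 = unname(f1)),
                 macro = macro, score = mean(f1)^2),
            class = "ecg_eval_report")
}

#' @export
print.ecg_eval_report <- function(x, ...) {
  cat("<ecg_eval_report> ", sum(x$confusion), " beats\n", sep = "")
  print(x$confusion)
  print(x$per_class, row.names = FALSE, digits = 4)
  cat(sprintf(
    "accuracy %.4f  macro precision %.4f  sensitivity %.4f  F1 %.4f  score %.4f\n",
    x$macro$accuracy, x$macro$precision, x$macro$sensitivity, x$macro$f1,
    x$score))
  invisible(x)
}

#' Evaluate a trained model on a test set
#'
#' @param model A [train_model()] result.
#' @param test_set A [beat_dataset()].
#' @return An `ecg_eval_report` (see [metrics_from_confusion()]).
#' @export
evaluate_model <- function(model, test_set) {
  stopifnot(inherits(model, "cdecg_model"), inherits(test_set, "beat_dataset"))
  pred <- predict(model, test_set)
  metrics_from_confusion(
    confusion_matrix(test_set$labels, pred$labels,
                     class_names = model$classes))
}

#' Per-class one-vs-rest ROC and PR curves
#'
#' For every class, the class-probability column is used as the score for
#' that class against all others pooled. ROC points are (FPR, TPR) over all
#' score thresholds with trapezoidal AUC (ties handled by grouping equal
#' scores, so label-independent constant scores give the chance diagonal
#' and AUC 0.5); PR points are (recall, precision). Classes without both a
#' positive and a negative example are skipped with a note.
#'
#' @param probabilities Matrix (n x n_classes), rows summing to 1.
#' @param true_labels Length-n label vector.
#' @param class_names Classes, in the column order of `probabilities`;
#'   defaults to column names or sorted unique labels.
#' @return Named list per class: `roc` (data frame fpr/tpr), `pr` (data
#'   frame recall/precision), `auc`; skipped classes are `NULL`.
#' @export
roc_pr_curves <- function(probabilities, true_labels, class_names = NULL) {
  P <- as.matrix(probabilities)
  if (is.null(class_names))
    class_names <- colnames(P)
  if (is.null(class_names))
    class_names <- sort(unique(as.character(true_labels)))
  if (length(class_names) != ncol(P))
    stop("class_names length does not match probability columns")
  true_labels <- as.character(true_labels)
  out <- stats::setNames(vector("list", length(class_names)), class_names)
  for (ci in seq_along(class_names)) {
    pos <- true_labels == class_names[ci]
    n_pos <- sum(pos); n_neg <- sum(!pos)
    if (n_pos == 0 || n_neg == 0) {
      message("class ", class_names[ci],
              " lacks positives or negatives; curves skipped")
      next
    }
    sc <- P[, ci]
    ord <- order(sc, decreasing = TRUE)
    sp <- sc[ord]; yp <- pos[ord]
    # group tied scores so each threshold is a single operating point
    grp_last <- c(which(diff(sp) != 0), length(sp))
    tp <- cumsum(yp)[grp_last]
    fpv <- cumsum(!yp)[grp_last]
    tpr <- c(0, tp / n_pos)
    fpr <- c(0, fpv / n_neg)
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    prec <- c(1, tp / (tp + fpv))
    rec <- tpr
    out[[ci]] <- list(roc = data.frame(fpr = fpr, tpr = tpr),
                      pr = data.frame(recall = rec, precision = prec),
                      auc = auc)
  }
  out
}
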