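#' Stratified train/validation/test split
#'
#' Within each class the (seeded) shuffled records are allocated to the
#' three splits by largest-remainder apportionment: each split first gets
#' `floor(n_c * fraction)` records, then leftovers go to the splits with the
#' largest fractional remainders (ties broken in split order:
#' train, validation, test). The three splits partition the input exactly.
#'
#' @param manifest Data frame with a `label` column; every class needs at
#'   least 3 members.
#' @param fractions Length-3 positive fractions summing to 1 (default
#'   `c(0.70, 0.15, 0.15)`).
#' @param seed Integer seed.
#' @return Named list `train`, `val`, `test` of row-subsets of `manifest`.
#' @export
stratified_split <- function(manifest, fractions = c(0.70, 0.15, 0.15),
                             seed = 0) {
  stopifnot(length(fractions) == 3, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-9)
  set.seed(as.integer(seed))
  out <- list(train = integer(0), val = integer(0), test = integer(0))
  for (cl in sort(unique(manifest$label))) {
    idx <- which(manifest$label == cl)
    if (length(idx) < 3)
      stop("class '", cl, "' has fewer than 3 members")
    idx <- idx[sample.int(length(idx))]
    ideal <- length(idx) * fractions
    sizes <- floor(ideal)
    rem <- ideal - sizes
    leftover <- length(idx) - sum(sizes)
    if (leftover > 0) {
      give <- order(-rem, seq_along(rem))[seq_len(leftover)]
      sizes[give] <- sizes[give] + 1
    }
    cuts <- cumsum(sizes)
    out$train <- c(out$train, idx[seq_len(sizes[1])])
    if (sizes[2] > 0) out$val <- c(out$val, idx[(cuts[1] + 1):cuts[2]])
    if (sizes[3] > 0) out$test <- c(out$test, idx[(cuts[2] + 1):cuts[3]])
  }
  lapply(out, function(i) {
    m <- manifest[sort(i), , drop = FALSE]
    rownames(m) <- NULL
    m
  })
}

#' Confusion matrix
#'
#' Entry (i, j) counts records of true class i predicted as class j; row
#' sums equal the class supports and the trace over the total is the
#' accuracy.
#'
#' @param y_true,y_pred Equal-length label vectors.
#' @param class_set Class order (default: sorted union).
#' @return m x m integer matrix with dimnames (rows = true).
#' @export
confusion_matrix <- function(y_true, y_pred,
                             class_set = sort(unique(c(y_true, y_pred)))) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) == 0) stop("empty inputs")
  if (!all(c(y_true, y_pred) %in% class_set))
    stop("labels outside class_set")
  as.matrix(table(factor(y_true, levels = class_set),
                  factor(y_pred, levels = class_set)))
}

#' Classification report
#'
#' Per-class precision `TP / (TP + FP)`, recall `TP / (TP + FN)`, F1
#' (harmonic mean) and support, plus accuracy and macro/weighted averages
#' (weighted by support). Undefined ratios (no predictions or no members of
#' a class) are reported as 0 with a warning so that the averages stay
#' defined.
#'
#' @inheritParams confusion_matrix
#' @return Object of class `metrics_report`: `per_class` data frame,
#'   `accuracy`, `macro` and `weighted` average rows, `confusion`.
#' @export
classification_report <- function(y_true, y_pred,
                                  class_set = sort(unique(c(y_true, y_pred)))) {
  cm <- confusion_matrix(y_true, y_pred, class_set)
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  undef <- class_set[predicted == 0 | support == 0]
  if (length(undef))
    warning("precision/recall undefined for: ",
            paste(undef, collapse = ", "), " (reported as 0)", call. = FALSE)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- data.frame(class = class_set, precision = precision,
                          recall = recall, f1 = f1, support = support,
                          row.names = NULL)
  wts <- support / sum(support)
  structure(list(
    per_class = per_class,
    accuracy = sum(tp) / sum(cm),
    macro = c(precision = mean(precision), recall = mean(recall),
              f1 = mean(f1)),
    weighted = c(precision = sum(wts * precision),
                 recall = sum(wts * recall), f1 = sum(wts * f1)),
    confusion = cm
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Accuracy: %.4f\n", x$accuracy))
  print(transform(x$per_class, precision = round(precision, 4),
                  recall = round(recall, 4), f1 = round(f1, 4)))
  cat(sprintf("macro    P %.4f R %.4f F1 %.4f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"]))
  cat(sprintf("weighted P %.4f R %.4f F1 %.4f\n",
              x$weighted["precision"], x$weighted["recall"],
              x$weighted["f1"]))
  invisible(x)
}

# AUC of scores vs binary truth via the rank (Mann-Whitney) formula,
# equivalent to trapezoidal integration of the empirical ROC with tied
# thresholds handled by average ranks
binary_auc <- function(truth, scores) {
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' One-vs-rest ROC AUC
#'
#' Per class, the AUC of that class's predicted probability against the
#' binary indicator "true class == this class" (Mann-Whitney form). The
#' macro AUC is the unweighted mean over classes with both positive and
#' negative examples; classes without are excluded with a warning rather
#' than imputed.
#'
#' @param y_true Label vector.
#' @param probabilities n x m row-stochastic matrix, columns in `class_set`
#'   order.
#' @param class_set Class order (default: column names).
#' @return List with `per_class` (named numeric, NA where undefined) and
#'   `macro`.
#' @export
roc_auc_ovr <- function(y_true, probabilities,
                        class_set = colnames(probabilities)) {
  probabilities <- as.matrix(probabilities)
  if (length(y_true) != nrow(probabilities)) stop("length mismatch")
  if (is.null(class_set)) stop("class_set required (or name the columns)")
  if (ncol(probabilities) != length(class_set)) stop("column count mismatch")
  aucs <- vapply(seq_along(class_set), function(j)
    binary_auc(y_true == class_set[j], probabilities[, j]), numeric(1))
  names(aucs) <- class_set
  if (anyNA(aucs))
    warning("AUC undefined (no positives or no negatives) for: ",
            paste(class_set[is.na(aucs)], collapse = ", "), call. = FALSE)
  list(per_class = aucs, macro = mean(aucs, na.rm = TRUE))
}

# serializable form of a metrics report (plus optional AUCs)
report_to_list <- function(report, auc = NULL) {
  out <- list(
    accuracy = report$accuracy,
    per_class = report$per_class,
    macro = as.list(report$macro),
    weighted = as.list(report$weighted),
    confusion = unname(apply(report$confusion, 1, as.integer,
                             simplify = FALSE)),
    class_set = rownames(report$confusion)
  )
  if (!is.null(auc)) {
    out$auc_per_class <- as.list(auc$per_class)
    out$auc_macro <- auc$macro
  }
  out
}
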