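#' One-vs-rest confusion counts
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param positive_class label treated as positive.
#' @return An object of class `tf_confusion`: integers `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(y_true, y_pred, positive_class = 1L) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred must have the same length")
  if (length(y_true) == 0L) stop("empty label sequences")
  tp <- sum(y_true == positive_class & y_pred == positive_class)
  fp <- sum(y_true != positive_class & y_pred == positive_class)
  fn <- sum(y_true == positive_class & y_pred != positive_class)
  tn <- sum(y_true != positive_class & y_pred != positive_class)
  confusion_counts(tp, fp, fn, tn)
}

#' Construct confusion counts directly
#'
#' @param tp,fp,fn non-negative integers; `tn` may be `NA` when unknown.
#' @param tn true negatives (optional).
#' @return An object of class `tf_confusion`.
#' @export
confusion_counts <- function(tp, fp, fn, tn = NA_integer_) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, is.na(tn) || tn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn), tn = as.integer(tn)),
            class = "tf_confusion")
}

#' @export
print.tf_confusion <- function(x, ...) {
  cat(sprintf("<tf_confusion> tp=%d fp=%d fn=%d tn=%s\n", x$tp, x$fp, x$fn,
              ifelse(is.na(x$tn), "?", x$tn)))
  invisible(x)
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = tp/(tp+fp)`, `recall = tp/(tp+fn)`,
#' `f1 = 2PR/(P+R)`; any 0/0 is defined as 0.
#'
#' @param counts a `tf_confusion` object (see [confusion()]).
#' @return list with `precision`, `recall`, `f1` (unrounded; see
#'   [round_metrics()] for 3-decimal reporting).
#' @examples
#' precision_recall_f1(confusion_counts(tp = 802, fp = 183, fn = 99))
#' @export
precision_recall_f1 <- function(counts) {
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  p <- safe_div(counts$tp, counts$tp + counts$fp)
  r <- safe_div(counts$tp, counts$tp + counts$fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(precision = p, recall = r, f1 = f1)
}

#' Micro-averaged F1 over a class subset
#'
#' Pools tp/fp/fn one-vs-rest over the classes in `class_subset`, then
#' computes F1 from the pooled counts — the convention used for three-way
#' medication-intake tweet tasks, where classes 1 and 2 (definite and
#' possible intake) are scored jointly.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param class_subset non-empty vector of class labels to pool.
#' @return micro-averaged F1 (numeric scalar).
#' @export
micro_f1 <- function(y_true, y_pred, class_subset) {
  if (length(class_subset) == 0L) stop("class_subset must be non-empty")
  tp <- fp <- fn <- 0L
  for (cl in class_subset) {
    cc <- confusion(y_true, y_pred, positive_class = cl)
    tp <- tp + cc$tp; fp <- fp + cc$fp; fn <- fn + cc$fn
  }
  precision_recall_f1(confusion_counts(tp, fp, fn))$f1
}

#' Round metrics half-up to 3 decimals for reporting
#'
#' @param m list of numerics (e.g. a [precision_recall_f1()] result).
#' @return the list with each element rounded half-up to 3 decimals.
#' @export
round_metrics <- function(m) {
  lapply(m, function(v) floor(v * 1000 + 0.5) / 1000)
}
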