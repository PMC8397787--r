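#' Multiclass confusion matrix
#'
#' `counts[t, p]` is the number of cases with true class `t` predicted as
#' class `p` (rows = truth, columns = prediction).
#'
#' @param true_labels,predicted_labels Integer vectors in
#'   `1..n_classes` of equal length (class labels from [oral_classes()]
#'   are also accepted).
#' @param n_classes Number of classes (default 5).
#' @return An `n_classes x n_classes` integer matrix of class
#'   `confusion_matrix`.
#' @export
#' @examples
#' confusion_matrix(c(1, 2, 3), c(1, 2, 2))
confusion_matrix <- function(true_labels, predicted_labels, n_classes = 5L) {
  to_int <- function(v) {
    if (is.character(v) || is.factor(v)) {
      i <- match(canonical_label(v), oral_classes())
      if (anyNA(i)) stop("unknown class label in input")
      i
    } else as.integer(v)
  }
  t_ <- to_int(true_labels); p_ <- to_int(predicted_labels)
  if (length(t_) != length(p_))
    stop("true and predicted labels differ in length (", length(t_), " vs ",
         length(p_), ")")
  if (length(t_) && (min(t_, p_) < 1 || max(t_, p_) > n_classes))
    stop("labels must lie in 1..", n_classes)
  lev <- seq_len(n_classes)
  m <- table(factor(t_, levels = lev), factor(p_, levels = lev))
  m <- matrix(as.integer(m), n_classes, n_classes,
              dimnames = list(true = oral_classes()[lev],
                              predicted = oral_classes()[lev]))
  structure(m, class = c("confusion_matrix", "matrix"))
}

cm_components <- function(cm, i) {
  total <- sum(cm)
  tp <- cm[i, i]
  fn <- sum(cm[i, ]) - tp
  fp <- sum(cm[, i]) - tp
  tn <- total - tp - fn - fp
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

safe_rate <- function(num, den) {
  if (den == 0) list(value = 0, defined = FALSE)
  else list(value = num / den, defined = TRUE)
}

#' Per-class sensitivity, specificity and precision
#'
#' One-vs-rest rates for class `i`:
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`,
#' `precision = TP / (TP + FP)`. A rate whose denominator is zero is
#' reported as 0 and flagged in the `defined` attribute, keeping macro
#' averages well defined on degenerate test sets without hiding the
#' degeneracy.
#'
#' @param cm A [confusion_matrix()].
#' @param class_index Class index in `1..nrow(cm)`.
#' @return Named numeric vector `(sensitivity, specificity, precision)`
#'   with a logical `defined` attribute of the same length.
#' @export
per_class_rates <- function(cm, class_index) {
  stopifnot(class_index >= 1, class_index <= nrow(cm))
  k <- cm_components(cm, class_index)
  se <- safe_rate(k["tp"], k["tp"] + k["fn"])
  sp <- safe_rate(k["tn"], k["tn"] + k["fp"])
  pr <- safe_rate(k["tp"], k["tp"] + k["fp"])
  structure(c(sensitivity = unname(se$value), specificity = unname(sp$value),
              precision = unname(pr$value)),
            defined = c(sensitivity = se$defined, specificity = sp$defined,
                        precision = pr$defined))
}

#' Macro-averaged multiclass metrics
#'
#' Unweighted means over the `C` classes of per-class sensitivity,
#' specificity and precision, plus the F1 computed as the harmonic mean
#' of the macro sensitivity and macro precision:
#' `F1 = 2 * SE_macro * Pr_macro / (SE_macro + Pr_macro)`.
#' Note this is deliberately *not* the mean of per-class F1 scores — the
#' two definitions differ.
#'
#' @param cm A [confusion_matrix()].
#' @return A `macro_metrics` list: `se_macro`, `sp_macro`, `pr_macro`,
#'   `f1`, and the `per_class` matrix.
#' @export
macro_metrics <- function(cm) {
  C <- nrow(cm)
  per <- t(vapply(seq_len(C), function(i) per_class_rates(cm, i),
                  c(sensitivity = 0, specificity = 0, precision = 0)))
  rownames(per) <- rownames(cm)
  se <- mean(per[, "sensitivity"])
  sp <- mean(per[, "specificity"])
  pr <- mean(per[, "precision"])
  f1 <- if (se + pr > 0) 2 * se * pr / (se + pr) else 0
  structure(list(se_macro = se, sp_macro = sp, pr_macro = pr, f1 = f1,
                 per_class = per), class = "macro_metrics")
}

check_ovr_inputs <- function(scores, true_labels, class_index) {
  scores <- as.matrix(scores)
  stopifnot(nrow(scores) == length(true_labels),
            class_index >= 1, class_index <= ncol(scores))
  pos <- as.integer(true_labels) == class_index
  if (!any(pos) || all(pos))
    stop("class ", class_index, " is degenerate: needs at least one ",
         "positive and one negative case")
  list(s = scores[, class_index], pos = pos)
}

#' One-vs-rest AUC
#'
#' Area under the ROC curve of the class-`k` probability for separating
#' class `k` from all other classes pooled, computed as the normalized
#' Mann-Whitney statistic with half credit for ties (average ranks).
#'
#' @param scores `n x C` matrix of per-case class probabilities.
#' @param true_labels Integer labels in `1..C`.
#' @param class_index The positive class `k`.
#' @return AUC in `[0, 1]`.
#' @export
ovr_auc <- function(scores, true_labels, class_index) {
  z <- check_ovr_inputs(scores, true_labels, class_index)
  n_pos <- sum(z$pos); n_neg <- sum(!z$pos)
  r <- rank(z$s)  # average ranks give the tie-half-credit convention
  (sum(r[z$pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' DeLong confidence interval for the one-vs-rest AUC
#'
#' Nonparametric variance of the Mann-Whitney AUC from the DeLong
#' structural components: with kernel `psi(x, y)` equal to 1, 1/2, 0 as a
#' positive score `x` exceeds / ties / trails a negative score `y`,
#' `V10_i = mean_j psi(x_i, y_j)` and `V01_j = mean_i psi(x_i, y_j)`,
#' `var = var(V10)/m + var(V01)/n`, and the interval is
#' `auc +/- z * sqrt(var)` clipped to `[0, 1]`. Perfect separation yields
#' zero variance and a degenerate interval, with a warning.
#'
#' @inheritParams ovr_auc
#' @param level Confidence level (default 0.95).
#' @return An `auc_result` list: `auc`, `ci_low`, `ci_high`, `var`,
#'   `class_index`, `level`.
#' @export
delong_ci <- function(scores, true_labels, class_index, level = 0.95) {
  z <- check_ovr_inputs(scores, true_labels, class_index)
  x <- z$s[z$pos]; y <- z$s[!z$pos]
  m <- length(x); n <- length(y)
  # psi via ranks: for each x_i, count of y below it plus half ties
  v10 <- vapply(x, function(xi)
    (sum(y < xi) + 0.5 * sum(y == xi)) / n, 0)
  v01 <- vapply(y, function(yj)
    (sum(x > yj) + 0.5 * sum(x == yj)) / m, 0)
  auc <- mean(v10)
  v <- (if (m > 1) stats::var(v10) / m else 0) +
    (if (n > 1) stats::var(v01) / n else 0)
  if (v <= 0)
    warning("zero DeLong variance (perfect separation); degenerate CI")
  zq <- stats::qnorm(1 - (1 - level) / 2)
  structure(list(auc = auc,
                 ci_low = max(0, auc - zq * sqrt(v)),
                 ci_high = min(1, auc + zq * sqrt(v)),
                 var = v, class_index = class_index, level = level),
            class = "auc_result")
}

#' Full evaluation report
#'
#' Confusion matrix, per-class and macro metrics, and per-class
#' one-vs-rest AUC with DeLong confidence intervals, from per-case class
#' probabilities and true labels.
#'
#' @param scores `n x C` matrix of class probabilities.
#' @param true_labels Integer labels in `1..C`.
#' @param level Confidence level for the AUC intervals.
#' @return List with `confusion`, `macro`, and `auc` (one `auc_result`
#'   per class, `NULL` for degenerate classes).
#' @export
evaluate_predictions <- function(scores, true_labels, level = 0.95) {
  scores <- as.matrix(scores)
  pred <- max.col(scores, ties.method = "first")
  cm <- confusion_matrix(true_labels, pred, n_classes = ncol(scores))
  auc <- lapply(seq_len(ncol(scores)), function(k) {
    tryCatch(suppressWarnings(delong_ci(scores, true_labels, k, level)),
             error = function(e) NULL)
  })
  names(auc) <- colnames(scores) %||% paste0("class", seq_len(ncol(scores)))
  list(confusion = cm, macro = macro_metrics(cm), auc = auc)
}
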