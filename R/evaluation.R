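# Diagnostic evaluation: binary confusion counts with ABNORMAL as the
# positive class, the derived rate metrics, and ROC analysis.

#' Confusion counts for the binary diagnosis
#'
#' ABNORMAL (or POSITIVE) is the positive class.
#'
#' @param truth,predicted vectors of `"NORMAL"`/`"ABNORMAL"` (or
#'   `"NEGATIVE"`/`"POSITIVE"`) of equal length.
#' @return one-row tibble with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("`truth` and `predicted` must have the same length", call. = FALSE)
  }
  norm <- function(x) {
    x <- toupper(as.character(x))
    x[x == "POSITIVE"] <- "ABNORMAL"
    x[x == "NEGATIVE"] <- "NORMAL"
    if (!all(x %in% c("NORMAL", "ABNORMAL"))) stop("labels must be NORMAL/ABNORMAL", call. = FALSE)
    x == "ABNORMAL"
  }
  t <- norm(truth); p <- norm(predicted)
  confusion_counts(tp = sum(t & p), fp = sum(!t & p),
                   tn = sum(!t & !p), fn = sum(t & !p))
}

#' Construct confusion counts directly
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return one-row `confusion_counts` tibble.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  out <- tibble::tibble(tp = as.integer(tp), fp = as.integer(fp),
                        tn = as.integer(tn), fn = as.integer(fn))
  class(out) <- c("confusion_counts", class(out))
  out
}

#' Diagnostic metrics from confusion counts
#'
#' Sensitivity `100*TP/(TP+FN)`, specificity `100*TN/(TN+FP)`, accuracy
#' `100*(TP+TN)/total`, with FNR = 100 - sensitivity, FPR = 100 -
#' specificity and classification error = 100 - accuracy. Values are
#' percentages; `digits` rounds only the report (raw fractions are exact
#' functions of the counts).
#'
#' @param counts a [confusion_counts()] row.
#' @param digits decimals for reporting (default 2); `NA` for unrounded.
#' @return one-row tibble: `sensitivity`, `specificity`, `accuracy`, `fnr`,
#'   `fpr`, `error`.
#' @export
metrics <- function(counts, digits = 2) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (tp + fn == 0 || tn + fp == 0) {
    stop("metrics undefined: empty positive or negative stratum", call. = FALSE)
  }
  sens <- 100 * tp / (tp + fn)
  spec <- 100 * tn / (tn + fp)
  acc <- 100 * (tp + tn) / (tp + tn + fp + fn)
  out <- tibble::tibble(sensitivity = sens, specificity = spec, accuracy = acc,
                        fnr = 100 - sens, fpr = 100 - spec, error = 100 - acc)
  if (!is.na(digits)) out <- dplyr::mutate(out, dplyr::across(
    dplyr::everything(), ~ round(.x + 1e-12, digits)))
  out
}

#' ROC curve and AUC for the abnormal-posterior score
#'
#' Thresholds sweep the unique scores; the curve is the usual monotone
#' staircase and AUC is computed by the trapezoid rule (equal to the
#' Mann-Whitney concordance statistic).
#'
#' @param truth binary truth (`NORMAL`/`ABNORMAL` or logical with TRUE =
#'   abnormal).
#' @param scores numeric scores, larger = more abnormal.
#' @return a `roc_curve` tibble (`threshold`, `fpr`, `tpr`) with attribute
#'   `auc`.
#' @export
roc_curve <- function(truth, scores) {
  if (is.logical(truth)) pos <- truth
  else {
    t <- toupper(as.character(truth))
    t[t == "POSITIVE"] <- "ABNORMAL"; t[t == "NEGATIVE"] <- "NORMAL"
    pos <- t == "ABNORMAL"
  }
  if (all(pos) || !any(pos)) stop("AUC undefined: single-class truth", call. = FALSE)
  stopifnot(length(pos) == length(scores))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  out <- tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr)
  attr(out, "auc") <- auc
  class(out) <- c("roc_curve", class(out))
  out
}

#' @method glance roc_curve
#' @export
glance.roc_curve <- function(x, ...) tibble::tibble(auc = attr(x, "auc"))

#' @rdname roc_curve
#' @param object a `roc_curve`.
#' @param ... ignored.
#' @method autoplot roc_curve
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", attr(object, "auc")))
}

#' Plot an SA search trace
#'
#' @param trace the `trace` tibble from [sa_select()].
#' @return a ggplot object.
#' @export
plot_sa_trace <- function(trace) {
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$iteration)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$error), colour = "grey70") +
    ggplot2::geom_line(ggplot2::aes(y = .data$best_error), colour = "black") +
    ggplot2::labs(x = "Iteration", y = "CV error",
                  title = "Simulated-annealing feature search")
}
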