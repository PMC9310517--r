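# Hierarchical precision/recall/F over ancestor-augmented label sets.
# For instance i, Ci is the set of nodes on the true path (terminal node plus
# all its ancestors, root excluded) and Zi the same for the predicted path:
#   hP = sum_i |Zi ∩ Ci| / sum_i |Zi|
#   hR = sum_i |Zi ∩ Ci| / sum_i |Ci|
#   hF = 2 hP hR / (hP + hR)
# Aggregation is micro: the sums run over instances before the ratio is
# taken. Because paths are chains keyed by full-path prefixes, |Zi ∩ Ci| is
# the length of the longest common prefix of the two paths.

common_prefix_len <- function(a, b) {
  ta <- split_path(a)
  tb <- split_path(b)
  mapply(function(x, y) {
    k <- min(length(x), length(y))
    if (k == 0L) return(0L)
    same <- x[seq_len(k)] == y[seq_len(k)]
    if (all(same)) k else which.min(same) - 1L
  }, ta, tb)
}

check_metric_paths <- function(truth, estimate) {
  if (length(truth) == 0L) abort("empty collection of instances")
  if (length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must have equal length")
  }
  if (anyNA(truth) || any(!nzchar(truth))) abort("every true path must be non-empty")
  if (anyNA(estimate) || any(!nzchar(estimate))) {
    abort("every predicted path must be non-empty")
  }
  invisible(NULL)
}

#' Hierarchical precision, recall and F-measure
#'
#' Micro-averaged over instances: each instance contributes its
#' ancestor-augmented true set Ci and predicted set Zi (root excluded), and
#' the intersection/denominator sums are taken over all instances before the
#' ratios are formed. A prediction deeper than the truth lowers hP but not
#' hR; a truncated (partial-depth) prediction lowers hR but not hP.
#'
#' @param truth Character vector of true `/`-joined label paths.
#' @param estimate Character vector of predicted label paths, same length.
#' @return A single value in `[0, 1]`; `hier_metrics()` returns a one-row
#'   tibble with columns `hP`, `hR`, `hF`. `hF` is defined as 0 when
#'   `hP + hR = 0`.
#' @examples
#' hierarchical_precision("A/A1", "A/A2")  # 0.5
#' hier_metrics(c("A/A1", "B"), c("A/A2", "B"))
#' @export
hierarchical_precision <- function(truth, estimate) {
  check_metric_paths(truth, estimate)
  sum(common_prefix_len(truth, estimate)) / sum(path_depth(estimate))
}

#' @rdname hierarchical_precision
#' @export
hierarchical_recall <- function(truth, estimate) {
  check_metric_paths(truth, estimate)
  sum(common_prefix_len(truth, estimate)) / sum(path_depth(truth))
}

#' @rdname hierarchical_precision
#' @export
hierarchical_f <- function(truth, estimate) {
  hf_from(hierarchical_precision(truth, estimate),
          hierarchical_recall(truth, estimate))
}

hf_from <- function(hp, hr) {
  if (hp + hr == 0) return(0)
  2 * hp * hr / (hp + hr)
}

#' @rdname hierarchical_precision
#' @export
hier_metrics <- function(truth, estimate) {
  hp <- hierarchical_precision(truth, estimate)
  hr <- hierarchical_recall(truth, estimate)
  tibble(hP = hp, hR = hr, hF = hf_from(hp, hr))
}

mcc_from_confusion <- function(cm) {
  # multiclass Matthews correlation from the confusion matrix
  c_sum <- sum(diag(cm))
  s <- sum(cm)
  p_k <- colSums(cm)   # predicted per class
  t_k <- rowSums(cm)   # true per class
  num <- c_sum * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) return(NA_real_)
  num / den
}

macro_ovr_auc <- function(truth, scores) {
  if (!requireNamespace("pROC", quietly = TRUE)) {
    warn("pROC not available; AUC omitted")
    return(NA_real_)
  }
  cls <- colnames(scores)
  aucs <- vapply(cls, function(cl) {
    pos <- truth == cl
    if (!any(pos) || all(pos)) return(NA_real_)
    as.numeric(pROC::auc(pROC::roc(response = pos, predictor = scores[, cl],
                                   levels = c(FALSE, TRUE), direction = "<",
                                   quiet = TRUE)))
  }, numeric(1))
  mean(aucs, na.rm = TRUE)
}

#' Flat multiclass metrics for one level
#'
#' Balanced accuracy (mean per-class recall over classes present in the
#' truth), multiclass Matthews correlation coefficient, macro F1 (classes
#' with no predictions score F1 = 0), and optionally macro one-vs-rest AUC
#' when class scores are supplied.
#'
#' @param truth Character vector of true class labels.
#' @param estimate Character vector of predicted labels, same length.
#' @param scores Optional numeric matrix of class scores, columns named by
#'   class.
#' @return A one-row tibble with `balanced_accuracy`, `mcc`, `macro_f1` and,
#'   if `scores` given, `auc`. With a single-class truth, MCC is undefined
#'   and returned as `NA` with a warning.
#' @export
flat_level_metrics <- function(truth, estimate, scores = NULL) {
  if (length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must have equal length")
  }
  lev <- sort(union(truth, estimate), method = "radix")
  tf <- factor(truth, levels = lev)
  ef <- factor(estimate, levels = lev)
  cm <- table(truth = tf, estimate = ef)
  present <- rowSums(cm) > 0
  recall <- diag(cm)[present] / rowSums(cm)[present]
  precision <- ifelse(colSums(cm) > 0, diag(cm) / colSums(cm), 0)
  f1 <- ifelse(recall + precision[present] > 0,
               2 * recall * precision[present] / (recall + precision[present]), 0)
  if (length(unique(truth)) < 2L) {
    warn("single-class truth: MCC is undefined")
    mcc <- NA_real_
  } else {
    mcc <- mcc_from_confusion(unclass(cm))
  }
  out <- tibble(balanced_accuracy = mean(recall), mcc = mcc,
                macro_f1 = mean(f1))
  if (!is.null(scores)) out$auc <- macro_ovr_auc(truth, scores)
  out
}
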