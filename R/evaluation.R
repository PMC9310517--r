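# Cross-validated comparison of the hierarchical approaches. Folds are
# stratified by each instance's deepest available class and shared across
# approaches within one run, so per-fold metric differences are paired and a
# paired t-test across folds is valid.

#' Stratified k-fold assignment
#'
#' @param strata Character vector of class keys, one per instance.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold indices in `1..k`; per-class fold counts
#'   differ by at most 1.
#' @export
stratified_folds <- function(strata, k = 10, seed = 1L) {
  counts <- table(strata)
  short <- names(counts)[counts < k]
  if (length(short)) {
    abort(sprintf(
      "class '%s' has %d < k = %d instances; filter with filter_min_samples(min_n >= k) first",
      short[[1]], counts[[short[[1]]]], k))
  }
  set.seed(seed)
  fold <- integer(length(strata))
  for (cl in sort(names(counts), method = "radix")) {
    idx <- which(strata == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Cross-validated evaluation of hierarchical approaches
#'
#' Runs stratified k-fold cross-validation (stratum = deepest available class
#' per instance), training every requested approach on the same folds. Per
#' fold and approach it records hierarchical precision/recall/F on the full
#' predicted paths and flat per-level metrics (balanced accuracy, MCC,
#' macro F1) on the instances whose true label reaches each level; a
#' predicted path shallower than the level counts as a miss there.
#'
#' @param data A hierarchical dataset tibble.
#' @param learner A `base_learner` factory.
#' @param approaches Character subset of
#'   `c("global", "per_level", "per_node")`.
#' @param k Number of folds. Default 10.
#' @param seed Integer seed driving fold assignment and model fits;
#'   identical seeds give identical folds and metrics.
#' @param leaf_policy,confidence_threshold Passed to per-node prediction.
#' @param mode Passed to per-level prediction.
#' @param path_col Name of the label-path column.
#' @return A `hier_cv` object with `$hier` (fold x approach hP/hR/hF),
#'   `$flat` (fold x approach x level metrics), `$folds`, `$k`, `$seed`.
#' @export
cross_validate <- function(data, learner,
                           approaches = c("global", "per_level", "per_node"),
                           k = 10, seed = 1L,
                           leaf_policy = "mandatory",
                           confidence_threshold = 0,
                           mode = "path_constrained",
                           path_col = "path") {
  check_hier_data(data, path_col)
  approaches <- match.arg(approaches, several.ok = TRUE)
  paths <- data[[path_col]]
  fold <- stratified_folds(paths, k = k, seed = seed)
  hier_rows <- list()
  flat_rows <- list()
  for (f in seq_len(k)) {
    train <- data[fold != f, , drop = FALSE]
    test <- data[fold == f, , drop = FALSE]
    truth <- test[[path_col]]
    depth <- max(path_depth(train[[path_col]]))
    for (ap in approaches) {
      m <- train_hier(train, learner, seed = seed + 101L * f, approach = ap,
                      path_col = path_col)
      pr <- predict(m, test, mode = mode, leaf_policy = leaf_policy,
                    confidence_threshold = confidence_threshold)
      est <- pr$.pred_path
      usable <- !is.na(est) & nzchar(est)
      hm <- hier_metrics(truth[usable], est[usable])
      hier_rows[[length(hier_rows) + 1L]] <-
        dplyr::bind_cols(tibble(fold = f, approach = ap), hm)
      for (lv in seq_len(depth)) {
        at <- path_depth(truth) >= lv
        if (!any(at)) next
        t_lv <- path_at_level(truth[at], lv)
        e_raw <- est[at]
        e_lv <- ifelse(!is.na(e_raw) & path_depth(e_raw) >= lv,
                       path_at_level(e_raw, lv), "<none>")
        fm <- suppressWarnings(flat_level_metrics(t_lv, e_lv))
        flat_rows[[length(flat_rows) + 1L]] <-
          dplyr::bind_cols(tibble(fold = f, approach = ap, level = lv), fm)
      }
    }
  }
  structure(
    list(hier = dplyr::bind_rows(hier_rows),
         flat = dplyr::bind_rows(flat_rows),
         folds = fold, k = k, seed = seed, approaches = approaches,
         learner = as_base_learner(learner)$name),
    class = "hier_cv")
}

#' @export
print.hier_cv <- function(x, ...) {
  cat(sprintf("<hier_cv> %d-fold, learner = %s, seed = %d\n", x$k, x$learner,
              x$seed))
  print(glance(x))
  invisible(x)
}

#' Per-fold metric table of a cross-validation run
#'
#' @param x A `hier_cv`.
#' @param ... Unused.
#' @return A long tibble: `fold`, `approach`, `level` (`NA` for the
#'   hierarchical metrics, which use the full path), `metric`, `value`.
#' @export
tidy.hier_cv <- function(x, ...) {
  h <- tidyr::pivot_longer(x$hier, cols = c("hP", "hR", "hF"),
                           names_to = "metric", values_to = "value")
  h$level <- NA_integer_
  f <- tidyr::pivot_longer(x$flat,
                           cols = setdiff(names(x$flat),
                                          c("fold", "approach", "level")),
                           names_to = "metric", values_to = "value")
  dplyr::bind_rows(h[c("fold", "approach", "level", "metric", "value")],
                   f[c("fold", "approach", "level", "metric", "value")])
}

#' Aggregate cross-validation summary
#'
#' @param x A `hier_cv`.
#' @param ... Unused.
#' @return One row per approach: mean and SD of per-fold hF, hP, hR.
#' @export
glance.hier_cv <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$hier, .data$approach),
    mean_hF = mean(.data$hF), sd_hF = stats::sd(.data$hF),
    mean_hP = mean(.data$hP), mean_hR = mean(.data$hR),
    .groups = "drop")
}

#' @rdname tidy.hier_cv
#' @param object A `hier_cv`.
#' @export
autoplot.hier_cv <- function(object, ...) {
  ggplot2::ggplot(object$hier,
                  ggplot2::aes(x = .data$approach, y = .data$hF)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "hierarchical F-measure (per fold)",
                  title = sprintf("%d-fold cross-validation", object$k)) +
    ggplot2::theme_minimal()
}

cv_metric_vector <- function(x, metric, approach = NULL) {
  stopifnot(inherits(x, "hier_cv"))
  if (is.null(approach)) {
    if (length(x$approaches) != 1L) {
      abort("result holds several approaches; name one with `approach`")
    }
    approach <- x$approaches
  }
  if (metric %in% names(x$hier)) {
    tab <- x$hier[x$hier$approach == approach, , drop = FALSE]
    tab <- tab[order(tab$fold), , drop = FALSE]
    return(tab[[metric]])
  }
  abort(sprintf("unknown metric '%s' (available: hP, hR, hF)", metric))
}

#' Paired comparison of two cross-validation results
#'
#' A two-sided paired Student's t-test on per-fold metric values, paired by
#' fold index. Both results must come from runs with identical fold counts
#' (share folds by using the same data and seed so the pairing is valid).
#'
#' @param result_a,result_b `hier_cv` objects, or a single `hier_cv` run over
#'   several approaches passed twice with `approach_a` / `approach_b` naming
#'   the pair.
#' @param metric Metric column to compare. Default `"hF"`.
#' @param approach_a,approach_b Approach names when a result holds several.
#' @return A one-row tibble: `mean_diff` (a minus b), `t`, `df`, `p_value`,
#'   `zero_variance`. When every per-fold difference is identical the t-test
#'   is degenerate: `p_value` is 1 for a zero shift and 0 otherwise, with
#'   `zero_variance = TRUE`.
#' @export
compare_approaches <- function(result_a, result_b = NULL, metric = "hF",
                               approach_a = NULL, approach_b = NULL) {
  if (is.null(result_b)) result_b <- result_a
  a <- cv_metric_vector(result_a, metric, approach_a)
  b <- cv_metric_vector(result_b, metric, approach_b)
  if (length(a) != length(b)) abort("fold counts differ; results are not paired")
  if (length(a) < 2L) abort("need at least 2 folds for a paired test")
  d <- a - b
  if (stats::sd(d) == 0) {
    return(tibble(mean_diff = mean(d), t = NA_real_, df = length(d) - 1,
                  p_value = if (mean(d) == 0) 1 else 0, zero_variance = TRUE))
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  tibble(mean_diff = mean(d), t = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value,
         zero_variance = FALSE)
}

#' Wall-time and peak-memory accounting for a call
#'
#' Informational plumbing: wraps a call, reporting elapsed wall time and the
#' peak R heap (from `gc()` max-used counters, reset before the call).
#'
#' @param fn A function of no arguments to execute.
#' @return A list with `value` (the call's result), `wall_seconds` and
#'   `peak_bytes`.
#' @export
resource_profile <- function(fn) {
  stopifnot(is.function(fn))
  invisible(gc(reset = TRUE))
  t0 <- proc.time()[["elapsed"]]
  value <- fn()
  secs <- proc.time()[["elapsed"]] - t0
  g <- gc()
  peak <- g["Ncells", "max used"] * 56 + g["Vcells", "max used"] * 8
  list(value = value, wall_seconds = secs, peak_bytes = unname(peak))
}
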