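# Decision engine recommending a hierarchical classification approach from
# dataset properties: labelling depth (full vs partial), last-level class
# imbalance measured by the Variation coefficient V, available computational
# resources, and the prediction goal. V <= 1 (the V of an exponential
# distribution) is treated as the low-variance branch.

#' Build a dataset profile for the recommendation engine
#'
#' `profile_dataset()` measures the profile from a dataset;
#' `dataset_profile()` constructs one directly from known properties.
#'
#' @param data A hierarchical dataset tibble.
#' @param resources `"ample"` or `"limited"` computational resources.
#' @param goal Prediction goal: `"unspecified"`, `"sensitivity"` or
#'   `"specificity"`.
#' @param path_col Name of the label-path column.
#' @return A `hc_profile`: `labeling_depth` (`"FD"` if every path reaches the
#'   maximum observed depth, else `"PD"`), `v_last` (Variation coefficient of
#'   class sizes at the last level), `unbalanced` (`v_last > 1`), plus the
#'   stated `resources` and `goal`.
#' @export
profile_dataset <- function(data, resources = c("ample", "limited"),
                            goal = c("unspecified", "sensitivity", "specificity"),
                            path_col = "path") {
  check_hier_data(data, path_col)
  s <- summarize_levels(data, path_col)
  v_last <- s$v[nrow(s)]
  depths <- path_depth(data[[path_col]])
  dataset_profile(
    labeling_depth = if (any(depths < max(depths))) "PD" else "FD",
    v_last = v_last,
    resources = match.arg(resources),
    goal = match.arg(goal))
}

#' @rdname profile_dataset
#' @param labeling_depth `"FD"` (every instance labelled to a leaf) or
#'   `"PD"` (some instances stop at internal nodes).
#' @param v_last Variation coefficient of last-level class sizes.
#' @export
dataset_profile <- function(labeling_depth = c("FD", "PD"), v_last,
                            resources = c("ample", "limited"),
                            goal = c("unspecified", "sensitivity", "specificity")) {
  labeling_depth <- match.arg(labeling_depth)
  if (!is.finite(v_last) || v_last < 0) abort("`v_last` must be finite and >= 0")
  structure(
    list(labeling_depth = labeling_depth, v_last = v_last,
         unbalanced = v_last > 1,
         resources = match.arg(resources), goal = match.arg(goal)),
    class = "hc_profile")
}

#' @export
print.hc_profile <- function(x, ...) {
  cat(sprintf(
    "<hc_profile> labeling = %s, V(last level) = %.2f (%s), resources = %s, goal = %s\n",
    x$labeling_depth, x$v_last,
    if (x$unbalanced) "unbalanced" else "balanced", x$resources, x$goal))
  invisible(x)
}

rule <- function(id, statement) tibble(rule = id, statement = statement)

refine_local <- function(p) {
  if (p$v_last <= 1) {
    list(approach = "local_per_level",
         trace = rule("V-low", sprintf(
           "V = %.2f <= 1: the Local per Level approach is enough", p$v_last)))
  } else if (p$resources == "limited") {
    list(approach = "local_per_level",
         trace = rule("V-high-limited", sprintf(
           "V = %.2f > 1 but resources are limited: Local per Level", p$v_last)))
  } else {
    list(approach = "local_per_node",
         trace = rule("V-high-ample", sprintf(
           "V = %.2f > 1 and resources are ample: Local per Node", p$v_last)))
  }
}

#' Recommend a hierarchical classification approach
#'
#' Applies the decision rules in order: (1) an unbalanced last level
#' (V > 1) calls for semi-balancing preprocessing; (2) partial-depth
#' labelling points to a Local approach, Local per Level when V <= 1 or when
#' resources are limited, Local per Node otherwise; (3) full-depth labelling
#' branches on the goal — a Global approach for sensitivity, a Local approach
#' (refined by the same V logic) for specificity. With an unspecified goal on
#' full-depth data both branches are reported: the Global branch as
#' `approach` and the V-refined Local branch as `alternative`.
#'
#' @param profile A `hc_profile` (from [profile_dataset()] or
#'   [dataset_profile()]).
#' @return A `hc_recommendation`: `preprocessing` (`"none"` or
#'   `"semi_balance"`), `approach`, `alternative` (`NA` unless the goal is
#'   unspecified on FD data) and a `trace` tibble of fired rules.
#' @examples
#' recommend(dataset_profile("PD", v_last = 3.01, resources = "ample"))
#' @export
recommend <- function(profile) {
  stopifnot(inherits(profile, "hc_profile"))
  p <- profile
  trace <- list()
  if (p$unbalanced) {
    preprocessing <- "semi_balance"
    trace[[1]] <- rule("balance", sprintf(
      "V = %.2f > 1 at the last level: apply semi-balancing before modelling",
      p$v_last))
  } else {
    preprocessing <- "none"
    trace[[1]] <- rule("balance", sprintf(
      "V = %.2f <= 1 at the last level: no balancing needed", p$v_last))
  }
  alternative <- NA_character_
  if (p$labeling_depth == "PD") {
    trace[[2]] <- rule("PD", "partial-depth labelling: adopt a Local approach")
    ref <- refine_local(p)
    approach <- ref$approach
    trace[[3]] <- ref$trace
  } else if (p$goal == "sensitivity") {
    approach <- "global"
    trace[[2]] <- rule("FD-sensitivity",
                       "full-depth labelling with a sensitivity goal: Global approach")
  } else if (p$goal == "specificity") {
    trace[[2]] <- rule("FD-specificity",
                       "full-depth labelling with a specificity goal: consider Local approaches")
    ref <- refine_local(p)
    approach <- ref$approach
    trace[[3]] <- ref$trace
  } else {
    ref <- refine_local(p)
    approach <- "global"
    alternative <- ref$approach
    trace[[2]] <- rule("FD-unspecified-global",
                       "goal unspecified: a sensitivity goal would indicate the Global approach")
    trace[[3]] <- rule("FD-unspecified-local", sprintf(
      "goal unspecified: a specificity goal would indicate %s", ref$approach))
  }
  structure(
    list(preprocessing = preprocessing, approach = approach,
         alternative = alternative, profile = p,
         trace = dplyr::bind_rows(trace)),
    class = "hc_recommendation")
}

#' @export
print.hc_recommendation <- function(x, ...) {
  cat("<hc_recommendation>\n")
  cat(sprintf("  preprocessing: %s\n", x$preprocessing))
  cat(sprintf("  approach:      %s%s\n", x$approach,
              if (!is.na(x$alternative)) sprintf(" (alternative: %s)", x$alternative) else ""))
  cat("  trace:\n")
  for (i in seq_len(nrow(x$trace))) {
    cat(sprintf("    [%s] %s\n", x$trace$rule[[i]], x$trace$statement[[i]]))
  }
  invisible(x)
}

#' @rdname recommend
#' @param x A `hc_recommendation`.
#' @param ... Unused.
#' @export
tidy.hc_recommendation <- function(x, ...) x$trace
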