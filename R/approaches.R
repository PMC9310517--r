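# The three hierarchical classification approaches over an injected flat
# learner:
#   global    - one flat model whose classes are entire label paths;
#   per_level - one multiclass model per hierarchy level;
#   per_node  - one multiclass model per parent node, applied top-down.
# Every predicted path is by construction a valid chain from the root, so the
# hierarchy constraint (a predicted class implies all its superclasses) holds
# under every approach.

model_scope_seed <- function(seed, i) as.integer((seed + 7919L * i) %% .Machine$integer.max)

fit_scope <- function(factory, seed, i, x, y) {
  learner <- factory$make(model_scope_seed(seed, i))
  t0 <- proc.time()[["elapsed"]]
  fit <- learner$fit(x, y)
  secs <- proc.time()[["elapsed"]] - t0
  list(learner = learner, fit = fit, classes = sort(unique(y), method = "radix"),
       secs = secs)
}

new_hier_model <- function(approach, hierarchy, models, meta, learner_name,
                           path_col, features) {
  structure(
    list(approach = approach, hierarchy = hierarchy, models = models,
         meta = meta, learner_name = learner_name, path_col = path_col,
         features = features),
    class = "hier_model")
}

#' Train a hierarchical classification model
#'
#' `train_hier()` dispatches on `approach`; `train_global()`,
#' `train_local_per_level()` and `train_local_per_node()` are the explicit
#' entry points.
#'
#' * **global**: a single flat learner whose classes are the full observed
#'   label paths; a partial-depth path is its own (shorter) class.
#' * **per_level**: one learner per level, trained on the instances whose
#'   label reaches that level (partial-depth instances are excluded from the
#'   levels they do not reach); a level with a single observed class becomes a
#'   pass-through.
#' * **per_node**: one learner per parent node with at least two children
#'   carrying data, trained on all instances under that parent and labelled by
#'   the immediate child ("siblings" policy); single-child parents are
#'   pass-throughs.
#'
#' @param data A hierarchical dataset tibble (numeric features + a path
#'   column).
#' @param learner A `base_learner` factory (see [base_learner()]) or a
#'   `function(seed)` returning a learner.
#' @param seed Integer seed forwarded (with a per-model offset) to the
#'   factory.
#' @param approach One of `"global"`, `"per_level"`, `"per_node"`.
#' @param path_col Name of the label-path column.
#' @return A `hier_model`: the approach tag, the hierarchy built from the
#'   training paths, the fitted learners keyed by scope (the single global
#'   scope, `level_<l>`, or the parent-node path with `""` for the root), and
#'   a metadata table (`scope`, `n_train`, `n_classes`, `secs`).
#' @examples
#' d <- generate_hier_data(synth_spec(depth = 2, branching = 2, n0 = 15, seed = 1))
#' m <- train_hier(d, learner_rpart(), seed = 1, approach = "per_node")
#' count_models(m)
#' @export
train_hier <- function(data, learner, seed = 1L,
                       approach = c("global", "per_level", "per_node"),
                       path_col = "path") {
  approach <- match.arg(approach)
  check_hier_data(data, path_col)
  factory <- as_base_learner(learner)
  fc <- feature_cols(data, path_col)
  if (length(fc) == 0L) abort("no numeric feature columns found")
  x <- as.matrix(data[fc])
  paths <- data[[path_col]]
  h <- build_hierarchy(paths)
  switch(approach,
    global = train_global_impl(x, paths, h, factory, seed, path_col, fc),
    per_level = train_per_level_impl(x, paths, h, factory, seed, path_col, fc),
    per_node = train_per_node_impl(x, paths, h, factory, seed, path_col, fc))
}

#' @rdname train_hier
#' @export
train_global <- function(data, learner, seed = 1L, path_col = "path") {
  train_hier(data, learner, seed, "global", path_col)
}

#' @rdname train_hier
#' @export
train_local_per_level <- function(data, learner, seed = 1L, path_col = "path") {
  train_hier(data, learner, seed, "per_level", path_col)
}

#' @rdname train_hier
#' @export
train_local_per_node <- function(data, learner, seed = 1L, path_col = "path") {
  train_hier(data, learner, seed, "per_node", path_col)
}

train_global_impl <- function(x, paths, h, factory, seed, path_col, fc) {
  if (length(unique(paths)) < 2L) {
    abort("global approach needs at least 2 distinct label paths")
  }
  sc <- fit_scope(factory, seed, 1L, x, paths)
  meta <- tibble(scope = "global", type = "model", n_train = nrow(x),
                 n_classes = length(sc$classes), secs = sc$secs)
  new_hier_model("global", h, list(global = sc), meta, factory$name,
                 path_col, fc)
}

train_per_level_impl <- function(x, paths, h, factory, seed, path_col, fc) {
  depth <- h$depth
  dp <- path_depth(paths)
  models <- list()
  meta <- list()
  for (lv in seq_len(depth)) {
    idx <- which(dp >= lv)
    y <- path_at_level(paths[idx], lv)
    key <- sprintf("level_%d", lv)
    if (length(unique(y)) >= 2L) {
      sc <- fit_scope(factory, seed, lv, x[idx, , drop = FALSE], y)
      models[[key]] <- sc
      meta[[key]] <- tibble(scope = key, type = "model", n_train = length(idx),
                            n_classes = length(sc$classes), secs = sc$secs)
    } else {
      models[[key]] <- list(passthrough = unique(y))
      meta[[key]] <- tibble(scope = key, type = "passthrough",
                            n_train = length(idx), n_classes = 1L, secs = 0)
    }
  }
  new_hier_model("per_level", h, models, dplyr::bind_rows(meta),
                 factory$name, path_col, fc)
}

train_per_node_impl <- function(x, paths, h, factory, seed, path_col, fc) {
  dp <- path_depth(paths)
  parents <- c("", h$nodes$path[h$nodes$path %in% h$nodes$parent])
  models <- list()
  meta <- list()
  for (i in seq_along(parents)) {
    p <- parents[[i]]
    lv <- if (identical(p, "")) 0L else path_depth(p)
    idx <- if (lv == 0L) which(dp >= 1L) else {
      which(dp > lv & path_at_level(paths, lv) == p)
    }
    y <- path_at_level(paths[idx], lv + 1L)
    key <- if (identical(p, "")) "<root>" else p
    children <- sort(unique(y), method = "radix")
    if (length(children) >= 2L) {
      sc <- fit_scope(factory, seed, i, x[idx, , drop = FALSE], y)
      models[[key]] <- sc
      meta[[key]] <- tibble(scope = key, type = "model", n_train = length(idx),
                            n_classes = length(children), secs = sc$secs)
    } else {
      models[[key]] <- list(passthrough = children)
      meta[[key]] <- tibble(scope = key, type = "passthrough",
                            n_train = length(idx), n_classes = 1L, secs = 0)
    }
  }
  new_hier_model("per_node", h, models, dplyr::bind_rows(meta),
                 factory$name, path_col, fc)
}

#' Number of fitted learners in a hierarchical model
#'
#' Pass-through scopes (single-class levels, single-child parents) are not
#' counted. On any hierarchy of depth >= 2 with branching >= 2,
#' per_node >= per_level >= global = 1.
#'
#' @param model A `hier_model`.
#' @return Integer count of fitted learners.
#' @export
count_models <- function(model) {
  stopifnot(inherits(model, "hier_model"))
  sum(model$meta$type == "model")
}

#' @export
print.hier_model <- function(x, ...) {
  cat(sprintf("<hier_model> approach = %s, learner = %s\n", x$approach,
              x$learner_name))
  cat(sprintf("  %d fitted model(s), %d pass-through scope(s); hierarchy depth %d\n",
              count_models(x), sum(x$meta$type == "passthrough"),
              x$hierarchy$depth))
  invisible(x)
}

check_predict_features <- function(model, new_data) {
  missing <- setdiff(model$features, names(new_data))
  if (length(missing)) {
    abort(sprintf("new data lacks %d training feature column(s): %s",
                  length(missing), toString(utils::head(missing, 5))))
  }
  as.matrix(new_data[model$features])
}

#' Predict label paths with a trained hierarchical model
#'
#' All approaches return paths that are valid chains of the training
#' hierarchy.
#'
#' @param object A `hier_model`.
#' @param new_data Tibble containing the training feature columns.
#' @param mode For per-level models: `"path_constrained"` (default) assembles
#'   a path by accepting each level's prediction only when it is a child of
#'   the previous accepted node, truncating otherwise; `"raw"` returns each
#'   level's independent prediction without reconciliation.
#' @param leaf_policy For per-node models: `"mandatory"` (default) descends
#'   until a leaf; `"non_mandatory"` additionally stops at a node when the
#'   learner's maximum class confidence falls below `confidence_threshold`.
#' @param confidence_threshold Stop threshold in `[0, 1]` for
#'   `leaf_policy = "non_mandatory"`; ignored when the learner provides no
#'   confidences. Default 0 (never stop early).
#' @param ... Unused.
#' @return A tibble with column `.pred_path` (and, for per-level models,
#'   `.pred_level_<l>` columns holding each level's raw prediction;
#'   `.pred_path` is `NA` for rows whose level-1 prediction is unavailable,
#'   which cannot occur with the built-in learners).
#' @export
predict.hier_model <- function(object, new_data,
                               mode = c("path_constrained", "raw"),
                               leaf_policy = c("mandatory", "non_mandatory"),
                               confidence_threshold = 0, ...) {
  mode <- match.arg(mode)
  leaf_policy <- match.arg(leaf_policy)
  x <- check_predict_features(object, new_data)
  switch(object$approach,
    global = predict_global_impl(object, x),
    per_level = predict_per_level_impl(object, x, mode),
    per_node = predict_per_node_impl(object, x, leaf_policy,
                                     confidence_threshold))
}

#' @rdname predict.hier_model
#' @param model A `hier_model` of the matching approach.
#' @export
predict_global <- function(model, new_data) {
  stopifnot(model$approach == "global")
  predict(model, new_data)
}

#' @rdname predict.hier_model
#' @export
predict_local_per_level <- function(model, new_data,
                                    mode = c("path_constrained", "raw")) {
  stopifnot(model$approach == "per_level")
  predict(model, new_data, mode = match.arg(mode))
}

#' @rdname predict.hier_model
#' @export
predict_local_per_node <- function(model, new_data,
                                   leaf_policy = c("mandatory", "non_mandatory"),
                                   confidence_threshold = 0) {
  stopifnot(model$approach == "per_node")
  predict(model, new_data, leaf_policy = match.arg(leaf_policy),
          confidence_threshold = confidence_threshold)
}

predict_global_impl <- function(object, x) {
  sc <- object$models$global
  tibble(.pred_path = sc$learner$predict(sc$fit, x))
}

scope_predict <- function(sc, x) {
  if (!is.null(sc$passthrough)) rep(sc$passthrough, nrow(x))
  else sc$learner$predict(sc$fit, x)
}

predict_per_level_impl <- function(object, x, mode) {
  depth <- object$hierarchy$depth
  raw <- lapply(seq_len(depth), function(lv) {
    scope_predict(object$models[[sprintf("level_%d", lv)]], x)
  })
  out <- tibble::as_tibble(stats::setNames(raw, sprintf(".pred_level_%d", seq_len(depth))))
  if (mode == "raw") return(out)
  assembled <- raw[[1]]
  if (depth > 1L) {
    alive <- rep(TRUE, nrow(x))
    for (lv in 2:depth) {
      ok <- alive & path_at_level(raw[[lv]], lv - 1L) == assembled &
        path_depth(raw[[lv]]) == lv
      assembled[ok] <- raw[[lv]][ok]
      alive <- ok
    }
  }
  out$.pred_path <- assembled
  out
}

predict_per_node_impl <- function(object, x, leaf_policy, threshold) {
  n <- nrow(x)
  pred <- rep(NA_character_, n)
  route <- function(node_key, idx, prefix) {
    if (length(idx) == 0L) return()
    sc <- object$models[[node_key]]
    if (is.null(sc)) { pred[idx] <<- prefix; return() }  # leaf: no children
    if (!is.null(sc$passthrough)) {
      child <- sc$passthrough
      pred[idx] <<- child
      route(child, idx, child)
      return()
    }
    xs <- x[idx, , drop = FALSE]
    if (leaf_policy == "non_mandatory" && threshold > 0 &&
        !is.null(sc$learner$predict_confidences)) {
      conf <- sc$learner$predict_confidences(sc$fit, xs)
      keep <- apply(conf, 1L, max) >= threshold
    } else {
      keep <- rep(TRUE, length(idx))
    }
    stopped <- idx[!keep]
    if (length(stopped)) pred[stopped] <<- prefix
    go <- idx[keep]
    if (length(go) == 0L) return()
    child <- scope_predict(sc, x[go, , drop = FALSE])
    pred[go] <<- child
    for (ch in unique(child)) route(ch, go[child == ch], ch)
  }
  route("<root>", seq_len(n), "")
  pred[pred == ""] <- NA_character_
  tibble(.pred_path = pred)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-scope metadata of a hierarchical model
#'
#' @param x A `hier_model`.
#' @param ... Unused.
#' @return A tibble: one row per scope with `scope`, `type`, `n_train`,
#'   `n_classes`, `secs`.
#' @export
tidy.hier_model <- function(x, ...) x$meta

#' One-row summary of a hierarchical model
#'
#' @param x A `hier_model`.
#' @param ... Unused.
#' @return A tibble with `approach`, `learner`, `n_models`, `n_passthrough`,
#'   `depth`, `n_classes_total`.
#' @export
glance.hier_model <- function(x, ...) {
  tibble(approach = x$approach, learner = x$learner_name,
         n_models = count_models(x),
         n_passthrough = sum(x$meta$type == "passthrough"),
         depth = x$hierarchy$depth,
         n_classes_total = nrow(x$hierarchy$nodes))
}
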