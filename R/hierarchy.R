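# Class hierarchies are rooted trees. Nodes are keyed by their full path from
# level 1 ("A/A1/..."), because bare tokens may repeat across branches (EC
# numbers reuse digits under different parents). The root is a synthetic
# sentinel at level 0 and is never a class: it is excluded from ancestor sets,
# metrics and model counts.

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

hc_delim <- "/"

split_path <- function(path) strsplit(path, hc_delim, fixed = TRUE)

join_path <- function(tokens) paste(tokens, collapse = hc_delim)

path_depth <- function(path) {
  lengths(split_path(path))
}

#' Truncate label paths to a given level
#'
#' @param path Character vector of `/`-joined label paths.
#' @param level Target level (1-based). Paths shallower than `level` are
#'   returned unchanged.
#' @return Character vector of truncated paths.
#' @export
path_at_level <- function(path, level) {
  stopifnot(level >= 1)
  vapply(split_path(path), function(tok) {
    join_path(tok[seq_len(min(level, length(tok)))])
  }, character(1))
}

#' All prefixes of a label path
#'
#' The ancestor-augmented label set of a path: every node on the chain from
#' level 1 down to the path's terminal node, root excluded.
#'
#' @param path A single `/`-joined label path.
#' @return Character vector of full-path keys, ordered from level 1 down.
#' @export
path_prefixes <- function(path) {
  tok <- split_path(path)[[1]]
  vapply(seq_along(tok), function(i) join_path(tok[seq_len(i)]), character(1))
}

normalize_paths <- function(paths) {
  if (is.list(paths)) {
    bad <- vapply(paths, function(p) any(grepl(hc_delim, p, fixed = TRUE)), logical(1))
    if (any(bad)) {
      abort(sprintf("label tokens must not contain the reserved delimiter '%s'", hc_delim))
    }
    paths <- vapply(paths, join_path, character(1))
  }
  paths <- as.character(paths)
  if (length(paths) == 0L) abort("at least one label path is required")
  tok <- split_path(paths)
  if (any(vapply(tok, function(t) length(t) == 0L || any(!nzchar(t)), logical(1)))) {
    abort("label paths must be non-empty and contain no empty tokens")
  }
  paths
}

#' Build a class hierarchy from observed label paths
#'
#' Returns the minimal rooted tree containing every path: each prefix of an
#' observed path becomes a node. Rebuilding from the tree's own node paths
#' yields an equal tree.
#'
#' @param paths Character vector of `/`-joined paths (e.g. `"A/A1"`), or a
#'   list of token vectors.
#' @return A `class_hierarchy` object: a node table (`path`, `label`, `level`,
#'   `parent`) in deterministic (radix) path order, plus the tree depth.
#' @examples
#' h <- build_hierarchy(c("A/A1", "A/A2", "B/B1"))
#' hierarchy_depth(h)
#' @export
build_hierarchy <- function(paths) {
  paths <- normalize_paths(paths)
  all_paths <- unique(unlist(lapply(unique(paths), path_prefixes)))
  all_paths <- all_paths[order(all_paths, method = "radix")]
  tok <- split_path(all_paths)
  level <- lengths(tok)
  parent <- ifelse(level == 1L, "",
                   vapply(tok, function(t) join_path(t[-length(t)]), character(1)))
  nodes <- tibble(
    path = all_paths,
    label = vapply(tok, function(t) t[length(t)], character(1)),
    level = as.integer(level),
    parent = parent
  )
  structure(
    list(nodes = nodes, depth = max(nodes$level)),
    class = "class_hierarchy"
  )
}

#' @export
print.class_hierarchy <- function(x, ...) {
  cat(sprintf("<class_hierarchy> %d nodes, depth %d\n", nrow(x$nodes), x$depth))
  per_level <- table(x$nodes$level)
  cat("  nodes per level:", paste(sprintf("L%s=%d", names(per_level), per_level),
                                  collapse = ", "), "\n")
  invisible(x)
}

#' @export
format.class_hierarchy <- function(x, ...) {
  sprintf("<class_hierarchy> %d nodes, depth %d", nrow(x$nodes), x$depth)
}

is_hierarchy <- function(x) inherits(x, "class_hierarchy")

#' Hierarchy accessors
#'
#' `hierarchy_depth()` returns the maximum level; `hierarchy_paths()` returns
#' every node's full-path key (a serialization round-trips through
#' [build_hierarchy()]); `hierarchy_leaves()` returns paths of nodes without
#' children.
#'
#' @param h A `class_hierarchy`.
#' @return An integer (depth) or character vector of full-path keys.
#' @export
hierarchy_depth <- function(h) {
  stopifnot(is_hierarchy(h))
  h$depth
}

#' @rdname hierarchy_depth
#' @export
hierarchy_paths <- function(h) {
  stopifnot(is_hierarchy(h))
  h$nodes$path
}

#' @rdname hierarchy_depth
#' @export
hierarchy_leaves <- function(h) {
  stopifnot(is_hierarchy(h))
  setdiff(h$nodes$path, h$nodes$parent)
}

hierarchy_children <- function(h, parent_path) {
  h$nodes$path[h$nodes$parent == parent_path]
}

#' Ancestor-augmented node set of a path
#'
#' The set of all nodes on the chain from level 1 to the path's terminal node,
#' including the terminal node and excluding the root sentinel. This is the
#' label set over which hierarchical precision/recall are computed.
#'
#' @param h A `class_hierarchy`.
#' @param path A single `/`-joined path that exists in `h`.
#' @return Character vector of full-path node keys.
#' @export
ancestors <- function(h, path) {
  stopifnot(is_hierarchy(h), length(path) == 1L)
  if (!path %in% h$nodes$path) {
    abort(sprintf("path '%s' is not a node of the hierarchy", path))
  }
  path_prefixes(path)
}

#' Nodes at a hierarchy level
#'
#' @param h A `class_hierarchy`.
#' @param level Level index, 1-based (the root sentinel sits at level 0 and is
#'   never returned).
#' @return Character vector of full-path keys in lexicographic (radix) order.
#' @export
level_nodes <- function(h, level) {
  stopifnot(is_hierarchy(h))
  if (length(level) != 1L || level < 1L || level > h$depth) {
    abort(sprintf("level must be in [1, %d], got %s", h$depth, toString(level)))
  }
  h$nodes$path[h$nodes$level == as.integer(level)]
}

#' Structural validation report for a hierarchy
#'
#' Checks the tree invariants: every non-root node's parent exists one level
#' up, sibling labels are unique under a common parent, and levels are
#' contiguous from 1. Returns a zero-row tibble for a valid tree.
#'
#' @param h A `class_hierarchy`.
#' @return A tibble with columns `check`, `node`, `detail`; one row per
#'   violation.
#' @export
validate_hierarchy <- function(h) {
  stopifnot(is_hierarchy(h))
  nd <- h$nodes
  out <- list()
  non_root <- nd[nd$level > 1L, , drop = FALSE]
  missing_parent <- non_root$path[!non_root$parent %in% nd$path]
  if (length(missing_parent)) {
    out[[length(out) + 1L]] <- tibble(check = "orphan", node = missing_parent,
                                      detail = "parent node not present")
  }
  idx <- match(non_root$parent, nd$path)
  bad_level <- non_root$path[!is.na(idx) & nd$level[idx] != non_root$level - 1L]
  if (length(bad_level)) {
    out[[length(out) + 1L]] <- tibble(check = "level", node = bad_level,
                                      detail = "level(child) != level(parent) + 1")
  }
  dup <- nd$path[duplicated(nd$path)]
  if (length(dup)) {
    out[[length(out) + 1L]] <- tibble(check = "duplicate", node = unique(dup),
                                      detail = "duplicate sibling label")
  }
  if (!setequal(unique(nd$level), seq_len(h$depth))) {
    out[[length(out) + 1L]] <- tibble(check = "depth", node = NA_character_,
                                      detail = "levels are not contiguous from 1")
  }
  if (length(out)) dplyr::bind_rows(out) else {
    tibble(check = character(), node = character(), detail = character())
  }
}

#' Newick export of a hierarchy
#'
#' A plain Newick string (labels are the node tokens; inner-node labels kept)
#' for visualisation in standard tree viewers.
#'
#' @param h A `class_hierarchy`.
#' @return A single Newick string ending in `";"`.
#' @export
hierarchy_newick <- function(h) {
  stopifnot(is_hierarchy(h))
  rec <- function(path, label) {
    kids <- hierarchy_children(h, path)
    lab <- gsub("[(),:;\\s]", "_", label)
    if (length(kids) == 0L) return(lab)
    kid_lab <- h$nodes$label[match(kids, h$nodes$path)]
    inner <- paste(mapply(rec, kids, kid_lab), collapse = ",")
    sprintf("(%s)%s", inner, lab)
  }
  paste0(rec("", "root"), ";")
}

#' Read or write a hierarchy as newline-delimited full paths
#'
#' @param h A `class_hierarchy`.
#' @param file Path to a text file, one full-path key per line.
#' @return `read_hierarchy()` returns a `class_hierarchy`;
#'   `write_hierarchy()` returns `file` invisibly.
#' @export
write_hierarchy <- function(h, file) {
  writeLines(hierarchy_paths(h), file)
  invisible(file)
}

#' @rdname write_hierarchy
#' @export
read_hierarchy <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(lines)]
  build_hierarchy(lines)
}

#' @rdname build_hierarchy
#' @param object A `class_hierarchy`.
#' @param ... Unused.
#' @export
autoplot.class_hierarchy <- function(object, ...) {
  nd <- object$nodes
  leaves <- hierarchy_leaves(object)
  xpos <- stats::setNames(rep(NA_real_, nrow(nd)), nd$path)
  xpos[leaves] <- seq_along(leaves)
  for (lv in rev(seq_len(object$depth - 1L))) {
    for (p in nd$path[nd$level == lv]) {
      kids <- nd$path[nd$parent == p]
      if (length(kids)) xpos[[p]] <- mean(xpos[kids])
    }
  }
  pts <- tibble(path = nd$path, label = nd$label, level = nd$level,
                x = unname(xpos[nd$path]))
  seg <- pts[pts$level > 1L, , drop = FALSE]
  seg$parent <- nd$parent[match(seg$path, nd$path)]
  seg$xend <- xpos[seg$parent]
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$x, y = -.data$level)) +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(xend = .data$xend, yend = -(.data$level - 1L))) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.8, size = 3) +
    ggplot2::scale_y_continuous(breaks = -seq_len(object$depth),
                                labels = seq_len(object$depth)) +
    ggplot2::labs(x = NULL, y = "level", title = "Class hierarchy") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
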