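# Synthetic hierarchical datasets. The generator makes the classification
# challenges of real tree-structured databases controllable: depth (up to 4
# levels, like CATH codes or EC numbers), number of classes via branching,
# class imbalance via the leaf-count distribution (targetable Variation
# coefficient), partial-depth labelling, and class separability. Class means
# follow the tree — each child's mean is its parent's plus an isotropic
# offset of norm separation * noise_sd — so nearby classes share ancestry and
# deeper levels are progressively harder.

#' Specification for a synthetic hierarchical dataset
#'
#' @param depth Number of hierarchy levels L (1..4 typical).
#' @param branching Children per node: a scalar, a length-L vector (entry 1 =
#'   number of level-1 nodes), or a list of `c(lo, hi)` ranges sampled per
#'   node.
#' @param leaf_counts Distribution of per-leaf sample counts: `"equal"`,
#'   `"lognormal"` (spread `sigma`), or `"powerlaw"` (exponent `alpha`).
#'   Counts are rounded up and floored at 1 so every class has a sample.
#' @param n0 Base count: the target mean samples per leaf class.
#' @param sigma Log-scale SD for `"lognormal"` counts.
#' @param alpha Exponent for `"powerlaw"` counts.
#' @param target_v Optional target Variation coefficient of leaf counts;
#'   implies `leaf_counts = "lognormal"` and sets
#'   `sigma = calibrate_sigma(target_v)`. An error with `"equal"` counts.
#' @param partial_depth_fraction Fraction of instances whose label is
#'   truncated at a uniformly chosen internal level (partial-depth
#'   labelling). Requires `depth >= 2` when positive.
#' @param feature_dim Number of Gaussian feature columns.
#' @param separation Distance between a child's and its parent's class mean,
#'   in units of `noise_sd`. Around 4, sibling clusters barely overlap; 0
#'   removes all signal.
#' @param noise_sd Within-class feature SD (spherical).
#' @param seed Integer seed; generation is deterministic given the spec.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(depth = 3, branching = 3,
                       leaf_counts = c("equal", "lognormal", "powerlaw"),
                       n0 = 20, sigma = 1, alpha = 1.5, target_v = NULL,
                       partial_depth_fraction = 0, feature_dim = 10,
                       separation = 3, noise_sd = 1, seed = 1L) {
  leaf_counts_stated <- !missing(leaf_counts)
  leaf_counts <- match.arg(leaf_counts)
  if (depth < 1L) abort("`depth` must be >= 1")
  if (!is.null(target_v)) {
    if (leaf_counts_stated && !identical(leaf_counts, "lognormal")) {
      abort("`target_v` calibration requires leaf_counts = \"lognormal\"")
    }
    leaf_counts <- "lognormal"
    sigma <- calibrate_sigma(target_v)
  }
  if (partial_depth_fraction < 0 || partial_depth_fraction > 1) {
    abort("`partial_depth_fraction` must be in [0, 1]")
  }
  if (partial_depth_fraction > 0 && depth < 2L) {
    abort("partial-depth labelling needs depth >= 2")
  }
  if (is.list(branching)) {
    stopifnot(length(branching) == depth)
  } else {
    branching <- rep_len(as.integer(branching), depth)
    if (any(branching < 1L)) abort("`branching` must be >= 1")
  }
  if (n0 < 1) abort("`n0` must be >= 1")
  if (noise_sd <= 0) abort("`noise_sd` must be > 0")
  if (separation < 0) abort("`separation` must be >= 0")
  structure(
    list(depth = as.integer(depth), branching = branching,
         leaf_counts = leaf_counts, n0 = n0, sigma = sigma, alpha = alpha,
         target_v = target_v,
         partial_depth_fraction = partial_depth_fraction,
         feature_dim = as.integer(feature_dim), separation = separation,
         noise_sd = noise_sd, seed = as.integer(seed)),
    class = "synth_spec")
}

#' Lognormal spread for a target Variation coefficient
#'
#' The coefficient of variation of a lognormal distribution with log-scale SD
#' sigma is `sqrt(exp(sigma^2) - 1)`; inverting gives
#' `sigma = sqrt(log(1 + v^2))`.
#'
#' @param target_v Target Variation coefficient, > 0.
#' @return The log-scale SD sigma.
#' @examples
#' calibrate_sigma(sqrt(exp(1) - 1))  # 1
#' @export
calibrate_sigma <- function(target_v) {
  if (length(target_v) != 1L || !is.finite(target_v) || target_v <= 0) {
    abort("`target_v` must be a single finite value > 0")
  }
  sqrt(log1p(target_v^2))
}

branch_count <- function(branching, level) {
  b <- branching[[level]]
  if (length(b) == 2L && is.numeric(b) && !is.list(b) && b[2] > b[1]) {
    sample(seq.int(b[1], b[2]), 1L)
  } else {
    as.integer(b[[1]])
  }
}

#' Generate a synthetic hierarchical dataset
#'
#' Builds the label tree from the spec's branching; draws per-leaf sample
#' counts from the chosen distribution (ceiling, floored at 1); assigns each
#' node a mean vector by recursive perturbation of its parent's mean (offset
#' direction uniform on the sphere, norm `separation * noise_sd`); samples
#' features from `N(leaf mean, noise_sd^2 I)`; and truncates a
#' `partial_depth_fraction` of labels at a uniformly chosen internal level.
#' Deterministic given the spec (including its seed).
#'
#' @param spec A `synth_spec`.
#' @return A hierarchical dataset tibble: `id`, `path`, and feature columns
#'   `f01`, `f02`, ...
#' @export
generate_hier_data <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  L <- spec$depth
  m <- spec$feature_dim
  # grow the tree and per-node means level by level
  nodes <- list(list(path = "", mean = rep(0, m), level = 0L))
  leaves <- list()
  frontier <- nodes
  for (lv in seq_len(L)) {
    nxt <- list()
    for (nd in frontier) {
      nb <- branch_count(spec$branching, lv)
      for (j in seq_len(nb)) {
        tok <- sprintf("n%02d", j)
        child_path <- if (nzchar(nd$path)) paste(nd$path, tok, sep = hc_delim) else tok
        off <- stats::rnorm(m)
        off <- off / sqrt(sum(off^2)) * spec$separation * spec$noise_sd
        nxt[[length(nxt) + 1L]] <- list(path = child_path,
                                        mean = nd$mean + off, level = lv)
      }
    }
    frontier <- nxt
  }
  leaves <- frontier
  nl <- length(leaves)
  counts <- switch(spec$leaf_counts,
    equal = rep(ceiling(spec$n0), nl),
    lognormal = pmax(1L, ceiling(stats::rlnorm(
      nl, meanlog = log(spec$n0) - spec$sigma^2 / 2, sdlog = spec$sigma))),
    powerlaw = {
      w <- sample(seq_len(nl))^(-spec$alpha)
      pmax(1L, ceiling(spec$n0 * w / mean(w)))
    })
  n <- sum(counts)
  leaf_idx <- rep.int(seq_len(nl), counts)
  mu <- do.call(rbind, lapply(leaves, `[[`, "mean"))
  x <- mu[leaf_idx, , drop = FALSE] +
    matrix(stats::rnorm(n * m, sd = spec$noise_sd), n, m)
  colnames(x) <- sprintf("f%02d", seq_len(m))
  path <- vapply(leaves, `[[`, character(1), "path")[leaf_idx]
  if (spec$partial_depth_fraction > 0 && L >= 2L) {
    cut <- stats::runif(n) < spec$partial_depth_fraction
    trunc_lv <- sample(seq_len(L - 1L), n, replace = TRUE)
    path[cut] <- path_at_level(path[cut], trunc_lv[cut])
  }
  out <- dplyr::bind_cols(
    tibble(id = sprintf("s%06d", seq_len(n)), path = path),
    as_tibble(x))
  out[sample(n), , drop = FALSE]
}

#' Preset generators echoing two well-known database shapes
#'
#' `make_cath_like()` emulates a CATH-style structural hierarchy: 4 levels,
#' full-depth labelling, and an extremely dispersed last level (target V
#' around 11). `make_biolip_like()` emulates an EC-number-style functional
#' hierarchy: 4 levels, about 30% partial-depth annotations, and a moderately
#' dispersed last level (target V around 3). Both are scaled down to run in
#' seconds.
#'
#' @param seed Integer seed.
#' @return A hierarchical dataset tibble.
#' @export
make_cath_like <- function(seed = 1L) {
  generate_hier_data(synth_spec(
    depth = 4, branching = c(4, 6, 4, 2), target_v = 11.07, n0 = 10,
    partial_depth_fraction = 0, feature_dim = 10, separation = 3,
    seed = seed))
}

#' @rdname make_cath_like
#' @export
make_biolip_like <- function(seed = 1L) {
  generate_hier_data(synth_spec(
    depth = 4, branching = c(6, 4, 3, 3), target_v = 3.01, n0 = 12,
    partial_depth_fraction = 0.3, feature_dim = 10, separation = 3,
    seed = seed))
}
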