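# A hierarchical dataset is an ordinary tibble: numeric feature columns plus
# one character column of "/"-joined label paths (default name "path") and an
# optional "id" column. Paths may stop above the tree's maximum depth
# (partial-depth labelling, as when an EC number is only annotated to two
# digits); every prefix of a path is a valid class.

feature_cols <- function(data, path_col = "path") {
  cand <- setdiff(names(data), c(path_col, "id"))
  cand[vapply(data[cand], is.numeric, logical(1))]
}

check_hier_data <- function(data, path_col = "path") {
  if (!is.data.frame(data)) abort("`data` must be a data frame")
  if (!path_col %in% names(data)) {
    abort(sprintf("label column '%s' not found in `data`", path_col))
  }
  if (nrow(data) == 0L) abort("`data` has no rows")
  normalize_paths(data[[path_col]])
  fc <- feature_cols(data, path_col)
  if (length(fc)) {
    bad <- fc[!vapply(data[fc], function(x) all(is.finite(x)), logical(1))]
    if (length(bad)) {
      abort(sprintf("non-finite values in feature column(s): %s", toString(bad)))
    }
  }
  invisible(data)
}

#' Read a hierarchical dataset from delimited text
#'
#' Expects a header row, numeric feature columns, and a label column holding
#' `/`-joined class paths (possibly partial depth). Row order is preserved.
#'
#' @param file Path to a delimited text file.
#' @param label_column Name of the label-path column. Default `"path"`.
#' @param delimiter Field delimiter; default `","` (use `"\t"` for TSV).
#' @return A tibble with the label column as character and all other columns
#'   numeric (an `id` column, if present, is kept as is).
#' @export
read_hier_dataset <- function(file, label_column = "path", delimiter = ",") {
  if (!file.exists(file)) abort(sprintf("file not found: %s", file))
  raw <- utils::read.delim(file, sep = delimiter, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) abort(sprintf("empty dataset file: %s", file))
  if (!label_column %in% names(raw)) {
    abort(sprintf("label column '%s' not found in %s", label_column, file))
  }
  raw[[label_column]] <- as.character(raw[[label_column]])
  for (col in setdiff(names(raw), c(label_column, "id"))) {
    if (!is.numeric(raw[[col]])) {
      coerced <- suppressWarnings(as.numeric(raw[[col]]))
      if (anyNA(coerced)) {
        abort(sprintf("non-numeric value in feature column '%s'", col))
      }
      raw[[col]] <- coerced
    }
  }
  out <- as_tibble(raw)
  check_hier_data(out, label_column)
  out
}

#' @rdname read_hier_dataset
#' @param data A hierarchical dataset tibble.
#' @export
write_hier_dataset <- function(data, file, delimiter = ",") {
  utils::write.table(data, file, sep = delimiter, row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' Variation coefficient
#'
#' The ratio SD / mean of per-class sample counts, the dispersion measure used
#' to characterise class imbalance level by level. Values above 1 (the V of an
#' exponential distribution, whose SD equals its mean) mark high dispersion.
#'
#' @param mean Mean class size(s); must be strictly positive.
#' @param sd Standard deviation(s) of class sizes; must be non-negative.
#' @return `sd / mean`, vectorised. Summaries report it rounded to 2 decimals.
#' @examples
#' variation_coefficient(46, 509)    # 11.07 after rounding
#' variation_coefficient(177.31, 532.99)
#' @export
variation_coefficient <- function(mean, sd) {
  if (any(!is.finite(mean)) || any(mean <= 0)) {
    abort("`mean` must be finite and > 0")
  }
  if (any(!is.finite(sd)) || any(sd < 0)) {
    abort("`sd` must be finite and >= 0")
  }
  sd / mean
}

#' Per-level class and sample statistics
#'
#' For each hierarchy level: the number of distinct classes, the mean number
#' of children per parent node (rounded to integer for reporting; `NA` at
#' level 1, whose only parent is the root sentinel), and the mean, sample SD
#' and Variation coefficient of per-class sample counts. Instances labelled
#' shallower than a level do not contribute to that level.
#'
#' @param data A hierarchical dataset tibble.
#' @param path_col Name of the label-path column.
#' @return A `hc_level_summary` tibble: one row per level with columns
#'   `level`, `n_classes`, `labels_per_node`, `mean`, `sd`, `v`.
#' @export
summarize_levels <- function(data, path_col = "path") {
  check_hier_data(data, path_col)
  paths <- data[[path_col]]
  depth <- max(path_depth(paths))
  rows <- lapply(seq_len(depth), function(lv) {
    reach <- paths[path_depth(paths) >= lv]
    cls <- path_at_level(reach, lv)
    counts <- as.integer(table(cls))
    n_cls <- length(counts)
    if (lv == 1L) {
      lpn <- NA_real_
    } else {
      parents <- unique(path_at_level(reach, lv - 1L))
      lpn <- round(n_cls / length(parents))
    }
    mu <- mean(counts)
    sdv <- if (n_cls > 1L) stats::sd(counts) else 0
    tibble(level = lv, n_classes = n_cls, labels_per_node = lpn,
           mean = mu, sd = sdv, v = variation_coefficient(mu, sdv))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("hc_level_summary", class(out))
  out
}

#' @export
print.hc_level_summary <- function(x, ...) {
  cat("# Per-level class-size characterisation\n")
  shown <- as_tibble(x)
  shown$mean <- round(shown$mean, 2)
  shown$sd <- round(shown$sd, 2)
  shown$v <- round(shown$v, 2)
  print(shown, ...)
  invisible(x)
}

#' Drop classes with too few samples
#'
#' Removes every instance whose class at `reference_level` (or at its deepest
#' available level, for partial-depth instances labelled shallower) has fewer
#' than `min_n` members. With `min_n` at least the number of CV folds this
#' guarantees one sample per class per fold.
#'
#' @param data A hierarchical dataset tibble.
#' @param min_n Minimum class size to keep. Default 10.
#' @param reference_level Level whose classes are counted; default the deepest
#'   observed level.
#' @param path_col Name of the label-path column.
#' @return The filtered tibble (row order preserved).
#' @export
filter_min_samples <- function(data, min_n = 10, reference_level = NULL,
                               path_col = "path") {
  check_hier_data(data, path_col)
  paths <- data[[path_col]]
  depth <- max(path_depth(paths))
  if (is.null(reference_level)) reference_level <- depth
  if (reference_level < 1L || reference_level > depth) {
    abort(sprintf("reference_level must be in [1, %d]", depth))
  }
  key <- path_at_level(paths, reference_level)
  counts <- table(key)
  keep <- counts[key] >= min_n
  if (!any(keep)) {
    abort(sprintf(
      "no class reaches min_n = %d at level %d (largest class has %d samples)",
      min_n, reference_level, max(counts)))
  }
  data[as.vector(keep), , drop = FALSE]
}

nearmiss_rank <- function(x_pos, x_neg, k = 3, version = 2) {
  # mean distance from each majority sample to its k farthest (version 2)
  # or k nearest (version 1) samples of the other classes
  k <- min(k, nrow(x_neg))
  cross <- outer(rowSums(x_pos^2), rep(1, nrow(x_neg))) +
    outer(rep(1, nrow(x_pos)), rowSums(x_neg^2)) -
    2 * tcrossprod(x_pos, x_neg)
  cross[cross < 0] <- 0
  cross <- sqrt(cross)
  apply(cross, 1L, function(d) {
    d <- sort(d, decreasing = (version == 2))
    mean(d[seq_len(k)])
  })
}

#' NearMiss semi-balancing by under-sampling majority classes
#'
#' Caps every class (deepest available label per instance) larger than `cap`
#' to exactly `cap` members. Following the NearMiss heuristic, the retained
#' majority samples are those with the shortest average distance to the `k`
#' farthest samples of the other classes (version 2, the default) or to the
#' `k` nearest (version 1). Classes at or below `cap` are untouched; this
#' semi-balances rather than equalising, so small classes are never
#' sub-sampled.
#'
#' @param data A hierarchical dataset tibble.
#' @param cap Maximum class size after balancing.
#' @param k Number of reference neighbours. Default 3.
#' @param version NearMiss variant, 1 or 2 (default 2).
#' @param seed Optional integer; ties in the distance ranking are broken by
#'   original row order, so the result is deterministic with or without it.
#' @param path_col Name of the label-path column.
#' @return The balanced tibble; surviving rows keep their original order.
#' @export
semi_balance <- function(data, cap, k = 3, version = 2, seed = NULL,
                         path_col = "path") {
  check_hier_data(data, path_col)
  if (length(cap) != 1L || cap < 1L) abort("`cap` must be a single integer >= 1")
  if (!version %in% c(1, 2)) abort("`version` must be 1 or 2")
  if (!is.null(seed)) set.seed(seed)
  fc <- feature_cols(data, path_col)
  if (length(fc) == 0L) abort("no numeric feature columns to compute distances on")
  x <- as.matrix(data[fc])
  cls <- data[[path_col]]
  counts <- table(cls)
  keep <- rep(TRUE, nrow(data))
  for (cl in names(counts)[counts > cap]) {
    pos_idx <- which(cls == cl)
    neg_idx <- which(cls != cl)
    if (length(neg_idx) == 0L) {
      warn(sprintf("class '%s' has no other classes to compare against; left uncapped", cl))
      next
    }
    score <- nearmiss_rank(x[pos_idx, , drop = FALSE],
                           x[neg_idx, , drop = FALSE], k = k, version = version)
    ord <- order(score, seq_along(score))  # stable tie-break by row order
    keep[pos_idx[ord[-seq_len(cap)]]] <- FALSE
  }
  out <- data[keep, , drop = FALSE]
  small <- table(out[[path_col]])
  if (min(small) < 2L) {
    warn("some classes have fewer than 2 samples after balancing; cross-validation may fail")
  }
  out
}

aa_letters <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Amino-acid composition features
#'
#' One row per sequence, one column per standard amino acid, holding the
#' relative frequency of that residue; rows sum to 1.
#'
#' @param x Protein sequences: a character vector (optionally named), a
#'   `Biostrings::AAStringSet`, or the path to a FASTA file (read with
#'   `Biostrings::readAAStringSet()`).
#' @param skip_nonstandard If `FALSE` (default), any letter outside the 20
#'   standard amino acids is an error; if `TRUE`, non-standard letters are
#'   dropped before computing frequencies.
#' @return A tibble with a leading `id` column and 20 frequency columns named
#'   by amino-acid letter.
#' @export
aac_features <- function(x, skip_nonstandard = FALSE) {
  if (inherits(x, "AAStringSet")) {
    seqs <- as.character(x)
  } else if (is.character(x) && length(x) == 1L && file.exists(x) &&
             !grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      abort("reading FASTA requires the Biostrings package")
    }
    seqs <- as.character(Biostrings::readAAStringSet(x))
  } else if (is.character(x)) {
    seqs <- x
  } else {
    abort("`x` must be sequences (character / AAStringSet) or a FASTA file path")
  }
  if (length(seqs) == 0L) abort("no sequences provided")
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  seqs <- toupper(seqs)
  rows <- lapply(seq_along(seqs), function(i) {
    letters_i <- strsplit(seqs[[i]], "", fixed = TRUE)[[1]]
    if (length(letters_i) == 0L) {
      abort(sprintf("sequence '%s' is empty", ids[[i]]))
    }
    nonstd <- setdiff(letters_i, aa_letters)
    if (length(nonstd)) {
      if (!skip_nonstandard) {
        abort(sprintf("sequence '%s' contains non-standard letter(s): %s",
                      ids[[i]], toString(nonstd)))
      }
      letters_i <- letters_i[letters_i %in% aa_letters]
      if (length(letters_i) == 0L) {
        abort(sprintf("sequence '%s' has no standard amino acids", ids[[i]]))
      }
    }
    counts <- table(factor(letters_i, levels = aa_letters))
    as.numeric(counts) / length(letters_i)
  })
  mat <- do.call(rbind, rows)
  colnames(mat) <- aa_letters
  dplyr::bind_cols(tibble(id = ids), as_tibble(mat))
}

#' @rdname summarize_levels
#' @param object A `hc_level_summary`.
#' @param ... Unused.
#' @export
autoplot.hc_level_summary <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("level", "n_classes", "mean", "v")],
    cols = c("n_classes", "mean", "v"),
    names_to = "statistic", values_to = "value")
  long$statistic <- factor(long$statistic, levels = c("n_classes", "mean", "v"),
                           labels = c("classes per level", "mean class size",
                                      "Variation coefficient"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$level, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "hierarchy level", y = NULL,
                  title = "Per-level class structure") +
    ggplot2::theme_minimal()
}
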