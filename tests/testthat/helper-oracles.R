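# Independent oracles used across the suite. They deliberately avoid the
# package's fast paths: ancestor sets are materialised node by node and
# intersected with set operations, and the metric sums follow the defining
# formulas directly.

# ancestor set of one path by repeatedly stripping the last token
oracle_ancestor_set <- function(path) {
  out <- character(0)
  tok <- strsplit(path, "/", fixed = TRUE)[[1]]
  while (length(tok) > 0L) {
    out <- c(out, paste(tok, collapse = "/"))
    tok <- tok[-length(tok)]
  }
  out
}

oracle_hier_prf <- function(truth, estimate) {
  inter <- 0; nz <- 0; nc <- 0
  for (i in seq_along(truth)) {
    Ci <- oracle_ancestor_set(truth[[i]])
    Zi <- oracle_ancestor_set(estimate[[i]])
    inter <- inter + length(intersect(Zi, Ci))
    nz <- nz + length(Zi)
    nc <- nc + length(Ci)
  }
  hp <- inter / nz
  hr <- inter / nc
  list(hP = hp, hR = hr, hF = if (hp + hr == 0) 0 else 2 * hp * hr / (hp + hr))
}

# random full-depth path over a fixed branching-b, depth-L universe
random_paths <- function(n, depth = 4, b = 3) {
  replicate(n, paste(sprintf("n%02d", sample.int(b, depth, replace = TRUE)),
                     collapse = "/"))
}

# a learner factory with scripted behaviour: predicts, for every row, the
# class chosen by `pick` from the sorted training classes
scripted_learner <- function(pick) {
  structure(list(
    make = function(seed) {
      list(
        fit = function(x, y) sort(unique(as.character(y)), method = "radix"),
        predict = function(fit, x) rep(pick(fit), nrow(x)),
        predict_confidences = NULL)
    },
    name = "scripted"), class = "base_learner")
}

# Fig-2-style toy: two level-1 classes, two children each, separable features
toy_fig2_data <- function(n_per = 6) {
  paths <- c("n1/n1a", "n1/n1b", "n2/n2a", "n2/n2b")
  centers <- rbind(c(0, 0), c(0, 8), c(8, 0), c(8, 8))
  rows <- lapply(seq_along(paths), function(i) {
    tibble::tibble(path = paths[[i]],
                   f01 = centers[i, 1] + seq_len(n_per) * 1e-3,
                   f02 = centers[i, 2] + seq_len(n_per) * 1e-3)
  })
  dplyr::bind_rows(rows)
}
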