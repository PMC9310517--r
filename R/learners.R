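# Base learners are injected: each hierarchical approach routes instances and
# delegates the flat multiclass work to whatever learner the user supplies.
# A factory is a function(seed) returning a learner, i.e. a list with
#   $fit(x, y)                -> fitted object (x: numeric matrix, y: character)
#   $predict(fit, x)          -> character vector of class labels
#   $predict_confidences(fit, x) -> numeric matrix (cols = classes) or NULL
# Repeated make() with the same seed must give identical predictions on
# identical data. Class predictions break probability ties by taking the
# lexicographically smallest class, so results are deterministic.

new_base_learner <- function(make, name) {
  structure(list(make = make, name = name), class = "base_learner")
}

#' @export
print.base_learner <- function(x, ...) {
  cat(sprintf("<base_learner> %s\n", x$name))
  invisible(x)
}

as_base_learner <- function(x) {
  if (inherits(x, "base_learner")) return(x)
  if (is.function(x)) return(new_base_learner(x, "custom"))
  abort("`learner` must be a base_learner or a function(seed) returning one learner")
}

argmax_class <- function(prob) {
  cls <- colnames(prob)
  ord <- order(cls, method = "radix")
  prob <- prob[, ord, drop = FALSE]
  cls <- cls[ord]
  cls[apply(prob, 1L, which.max)]
}

single_class_learner <- function(cls) {
  list(
    fit = NULL, single_class = cls,
    predict = function(fit, x) rep(cls, nrow(x)),
    predict_confidences = function(fit, x) {
      m <- matrix(1, nrow(x), 1L, dimnames = list(NULL, cls))
      m
    }
  )
}

#' Random-forest base learner (ranger)
#'
#' A probability forest; class predictions take the highest-probability class
#' with lexicographic tie-breaking. Single-threaded and seeded, so repeated
#' fits are identical.
#'
#' @param num.trees Number of trees. Default 100.
#' @param ... Further arguments passed to `ranger::ranger()`.
#' @return A `base_learner` factory.
#' @export
learner_ranger <- function(num.trees = 100, ...) {
  dots <- list(...)
  new_base_learner(function(seed) {
    list(
      fit = function(x, y) {
        y <- as.character(y)
        if (length(unique(y)) == 1L) return(single_class_learner(y[[1]]))
        df <- as.data.frame(x)
        df$.y <- factor(y)
        do.call(ranger::ranger, c(list(
          formula = .y ~ ., data = df, probability = TRUE,
          num.trees = num.trees, seed = seed, num.threads = 1L), dots))
      },
      predict = function(fit, x) {
        if (!is.null(fit$single_class)) return(rep(fit$single_class, nrow(x)))
        prob <- stats::predict(fit, data = as.data.frame(x),
                               num.threads = 1L)$predictions
        argmax_class(prob)
      },
      predict_confidences = function(fit, x) {
        if (!is.null(fit$single_class)) {
          return(matrix(1, nrow(x), 1L, dimnames = list(NULL, fit$single_class)))
        }
        stats::predict(fit, data = as.data.frame(x), num.threads = 1L)$predictions
      }
    )
  }, sprintf("ranger(num.trees=%d)", num.trees))
}

#' Decision-tree base learner (rpart)
#'
#' @param ... Arguments passed to `rpart::rpart.control()` (e.g. `cp`,
#'   `minsplit`).
#' @return A `base_learner` factory.
#' @export
learner_rpart <- function(...) {
  control <- rpart::rpart.control(...)
  new_base_learner(function(seed) {
    list(
      fit = function(x, y) {
        y <- as.character(y)
        if (length(unique(y)) == 1L) return(single_class_learner(y[[1]]))
        df <- as.data.frame(x)
        df$.y <- factor(y)
        rpart::rpart(.y ~ ., data = df, method = "class", control = control)
      },
      predict = function(fit, x) {
        if (!is.null(fit$single_class)) return(rep(fit$single_class, nrow(x)))
        prob <- stats::predict(fit, newdata = as.data.frame(x), type = "prob")
        argmax_class(prob)
      },
      predict_confidences = function(fit, x) {
        if (!is.null(fit$single_class)) {
          return(matrix(1, nrow(x), 1L, dimnames = list(NULL, fit$single_class)))
        }
        stats::predict(fit, newdata = as.data.frame(x), type = "prob")
      }
    )
  }, "rpart")
}

#' Memorizing base learner
#'
#' Stores the training set and predicts by exact feature match, falling back
#' to the nearest training point (Euclidean). On its own training set it
#' reproduces the training labels exactly, which makes it the reference
#' learner for self-consistency checks of the hierarchical approaches.
#'
#' @return A `base_learner` factory.
#' @export
learner_memorize <- function() {
  new_base_learner(function(seed) {
    list(
      fit = function(x, y) {
        list(x = as.matrix(x), y = as.character(y),
             key = apply(as.matrix(x), 1L, paste, collapse = "\r"))
      },
      predict = function(fit, x) {
        x <- as.matrix(x)
        key <- apply(x, 1L, paste, collapse = "\r")
        hit <- match(key, fit$key)
        out <- fit$y[hit]
        miss <- which(is.na(hit))
        for (i in miss) {
          d2 <- colSums((t(fit$x) - x[i, ])^2)
          out[[i]] <- fit$y[which.min(d2)]
        }
        out
      },
      predict_confidences = NULL
    )
  }, "memorize")
}

#' Majority-class base learner
#'
#' Always predicts the most frequent training class (lexicographic
#' tie-break). A floor baseline.
#'
#' @return A `base_learner` factory.
#' @export
learner_majority <- function() {
  new_base_learner(function(seed) {
    list(
      fit = function(x, y) {
        tab <- table(as.character(y))
        names(tab)[order(-as.vector(tab), names(tab), method = "radix")][1L]
      },
      predict = function(fit, x) rep(fit, nrow(x)),
      predict_confidences = NULL
    )
  }, "majority")
}

#' Look up a built-in base learner by name
#'
#' @param name One of `"ranger"`, `"rpart"`, `"memorize"`, `"majority"`.
#' @param ... Passed to the matching constructor.
#' @return A `base_learner` factory.
#' @export
base_learner <- function(name = c("ranger", "rpart", "memorize", "majority"), ...) {
  name <- match.arg(name)
  switch(name,
    ranger = learner_ranger(...),
    rpart = learner_rpart(...),
    memorize = learner_memorize(),
    majority = learner_majority())
}
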