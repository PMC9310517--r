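test_that("model counts follow the approach structure on the two-branch toy", {
  d <- toy_fig2_data()
  g <- train_global(d, learner_memorize())
  l <- train_local_per_level(d, learner_memorize())
  n <- train_local_per_node(d, learner_memorize())
  expect_equal(count_models(g), 1L)
  expect_equal(count_models(l), 2L)
  expect_equal(count_models(n), 3L)   # root + two level-1 parents
})

test_that("global training uses full observed paths as joint classes", {
  d <- tibble::tibble(path = rep(c("A/A1", "A/A2", "B/B1"), each = 4),
                      f01 = rnorm(12))
  m <- train_global(d, learner_memorize())
  expect_equal(m$meta$n_classes, 3L)
  # partial-depth paths form their own joint classes
  d2 <- tibble::tibble(path = rep(c("A/A1", "A"), each = 4), f01 = rnorm(8))
  m2 <- train_global(d2, learner_memorize())
  expect_equal(m2$meta$n_classes, 2L)
  expect_setequal(unique(predict(m2, d2)$.pred_path), c("A/A1", "A"))

  d3 <- tibble::tibble(path = rep("A/A1", 5), f01 = rnorm(5))
  expect_error(train_global(d3, learner_memorize()), "2 distinct")
  expect_error(predict(m, d["f01" != names(d)]), "feature column")
})

test_that("per-level training excludes partial-depth instances from deep levels", {
  withr::with_seed(4, {
    d <- generate_hier_data(synth_spec(depth = 3, branching = 2, n0 = 10,
                                       partial_depth_fraction = 0.4,
                                       feature_dim = 3, seed = 4))
  })
  m <- train_local_per_level(d, learner_rpart())
  depths <- nchar(gsub("[^/]", "", d$path)) + 1L
  meta <- tidy(m)
  for (lv in 1:3) {
    expect_equal(meta$n_train[meta$scope == sprintf("level_%d", lv)],
                 sum(depths >= lv))
  }
})

test_that("per-level reconciliation accepts children and truncates conflicts", {
  d <- tibble::tibble(path = rep(c("A/A1", "B/B1"), each = 5),
                      f01 = c(rnorm(5), rnorm(5) + 10))
  # scripted learners: level 1 predicts the first class (A), level 2 the last
  # (B/B1) — inconsistent on purpose
  inconsistent <- scripted_learner(function(classes) {
    if (max(nchar(gsub("[^/]", "", classes))) == 0) classes[[1]]
    else classes[[length(classes)]]
  })
  m <- train_local_per_level(d, inconsistent)
  raw <- predict(m, d, mode = "raw")
  expect_equal(unique(raw$.pred_level_1), "A")
  expect_equal(unique(raw$.pred_level_2), "B/B1")
  constrained <- predict(m, d, mode = "path_constrained")
  expect_equal(unique(constrained$.pred_path), "A")

  # consistent per-level outputs assemble to the full path
  consistent <- scripted_learner(function(classes) classes[[1]])
  m2 <- train_local_per_level(d, consistent)
  expect_equal(unique(predict(m2, d)$.pred_path), "A/A1")
})

test_that("per-node models train on exactly the parent's subtree (siblings policy)", {
  d <- toy_fig2_data(n_per = 5)
  m <- train_local_per_node(d, learner_memorize())
  meta <- tidy(m)
  expect_equal(meta$n_train[meta$scope == "<root>"], 20L)
  expect_equal(meta$n_train[meta$scope == "n1"], 10L)
  expect_equal(meta$n_train[meta$scope == "n2"], 10L)

  # single-child parents become pass-throughs, not fitted models
  d2 <- tibble::tibble(path = rep(c("A/A1", "B/B1"), each = 5), f01 = rnorm(10))
  m2 <- train_local_per_node(d2, learner_memorize())
  expect_equal(count_models(m2), 1L)  # only the root chooses
  expect_equal(sum(tidy(m2)$type == "passthrough"), 2L)
  expect_setequal(predict(m2, d2)$.pred_path, c("A/A1", "B/B1"))
})

test_that("memorizing learner reaches training hF = 1 for global and per-node", {
  withr::with_seed(8, {
    d <- generate_hier_data(synth_spec(depth = 3, branching = 2, n0 = 8,
                                       feature_dim = 4, seed = 8))
  })
  for (ap in c("global", "per_node")) {
    m <- train_hier(d, learner_memorize(), approach = ap)
    pred <- predict(m, d, leaf_policy = "mandatory")$.pred_path
    expect_equal(hier_metrics(d$path, pred)$hF, 1)
  }
})

test_that("every predicted path is a valid chain of the training hierarchy", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      spec <- synth_spec(depth = sample(2:4, 1), branching = 2,
                         n0 = 8, partial_depth_fraction = 0.2,
                         feature_dim = 3, separation = 1.5,
                         seed = 300 + rep)
      d <- generate_hier_data(spec)
      h <- build_hierarchy(d$path)
      for (ap in c("global", "per_level", "per_node")) {
        m <- train_hier(d, learner_rpart(), approach = ap)
        pred <- predict(m, d)$.pred_path
        pred <- pred[!is.na(pred)]
        expect_true(all(pred %in% hierarchy_paths(h)),
                    info = sprintf("approach %s rep %d", ap, rep))
      }
    }
  })
})

test_that("non-mandatory routing stops below a confidence threshold", {
  withr::with_seed(77, {
    # no signal: rpart class probabilities stay below 1
    d <- generate_hier_data(synth_spec(depth = 3, branching = 2, n0 = 20,
                                       separation = 0, feature_dim = 3,
                                       seed = 77))
  })
  m <- train_local_per_node(d, learner_rpart())
  full <- predict(m, d, leaf_policy = "mandatory")$.pred_path
  stopped <- predict(m, d, leaf_policy = "non_mandatory",
                     confidence_threshold = 1)$.pred_path
  depth_of <- function(p) ifelse(is.na(p), 0L, nchar(gsub("[^/]", "", p)) + 1L)
  expect_true(all(depth_of(full) == 3L))
  expect_true(any(depth_of(stopped) < 3L))
  # threshold 0 never stops early
  never <- predict(m, d, leaf_policy = "non_mandatory",
                   confidence_threshold = 0)$.pred_path
  expect_equal(never, full)
})

test_that("model-count law holds: per_node >= per_level >= global", {
  withr::with_seed(55, {
    for (rep in 1:5) {
      d <- generate_hier_data(synth_spec(depth = sample(2:4, 1),
                                         branching = sample(2:3, 1),
                                         n0 = 5, feature_dim = 2,
                                         seed = 550 + rep))
      counts <- vapply(c("global", "per_level", "per_node"), function(ap) {
        count_models(train_hier(d, learner_memorize(), approach = ap))
      }, integer(1))
      expect_equal(counts[["global"]], 1L)
      expect_gte(counts[["per_level"]], counts[["global"]])
      expect_gte(counts[["per_node"]], counts[["per_level"]])
    }
  })
})

test_that("training and prediction are deterministic given the seed", {
  withr::with_seed(12, {
    d <- generate_hier_data(synth_spec(depth = 2, branching = 3, n0 = 12,
                                       feature_dim = 4, seed = 12))
  })
  skip_if_not_installed("ranger")
  m1 <- train_hier(d, learner_ranger(num.trees = 30), seed = 9, approach = "per_node")
  m2 <- train_hier(d, learner_ranger(num.trees = 30), seed = 9, approach = "per_node")
  expect_identical(predict(m1, d)$.pred_path, predict(m2, d)$.pred_path)
})

test_that("tidy and glance summarise a trained model", {
  d <- toy_fig2_data()
  m <- train_local_per_node(d, learner_memorize())
  expect_s3_class(tidy(m), "tbl_df")
  g <- glance(m)
  expect_equal(g$n_models, 3L)
  expect_equal(g$approach, "per_node")
  expect_equal(g$depth, 2L)
})
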