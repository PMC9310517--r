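test_that("hierarchical metrics match the defining set arithmetic", {
  # perfect prediction
  expect_equal(hierarchical_precision("A/A1", "A/A1"), 1)
  expect_equal(hierarchical_recall("A/A1", "A/A1"), 1)
  expect_equal(hierarchical_f("A/A1", "A/A1"), 1)

  # sibling confusion at level 2: |Z ∩ C| = 1, |Z| = |C| = 2
  expect_equal(hierarchical_precision("A/A1", "A/A2"), 0.5)

  # micro aggregation: (1 + 1) / (2 + 1)
  expect_equal(hierarchical_precision(c("A/A1", "B"), c("A/A2", "B")), 2 / 3)

  # truncated prediction: hP stays 1, hR halves
  expect_equal(hierarchical_precision("A/A1", "A"), 1)
  expect_equal(hierarchical_recall("A/A1", "A"), 0.5)
  expect_equal(hierarchical_f("A/A1", "A"), 2 / 3)  # hF(1, 0.5)

  # over-deep prediction: hR = 1, hP < 1
  expect_equal(hierarchical_recall("A", "A/A1/A1a"), 1)
  expect_lt(hierarchical_precision("A", "A/A1/A1a"), 1)

  # harmonic-mean identities
  expect_equal(hier_metrics("A/A1", "A/A2")$hF, 0.5)  # hP = hR = 0.5
  m <- hier_metrics(c("A/A1", "B/B2"), c("A/A2", "B/B2"))
  expect_lte(m$hF, (m$hP + m$hR) / 2)
  expect_gte(m$hF, 0)
})

test_that("hierarchical metrics handle degenerate input per convention", {
  # totally disjoint paths: hP = hR = 0, hF defined as 0
  expect_equal(hier_metrics("A/A1", "B/B1")$hF, 0)
  expect_error(hierarchical_precision(character(0), character(0)), "empty")
  expect_error(hierarchical_precision("A", ""), "non-empty")
  expect_error(hierarchical_precision(c("A", "B"), "A"), "equal length")
})

test_that("fast prefix computation equals the brute-force ancestor-set oracle", {
  withr::with_seed(13, {
    for (rep in 1:4) {
      truth <- random_paths(250, depth = 4, b = 3)
      # mix of sibling errors, truncations, and unrelated predictions
      est <- truth
      i <- sample(250, 100)
      est[i] <- random_paths(100, depth = 4, b = 3)
      j <- sample(250, 50)
      est[j] <- path_at_level(est[j], sample(1:3, 50, replace = TRUE))
      want <- oracle_hier_prf(truth, est)
      got <- hier_metrics(truth, est)
      expect_equal(got$hP, want$hP)
      expect_equal(got$hR, want$hR)
      expect_equal(got$hF, want$hF)
    }
  })
})

test_that("predicting only correct level-1 classes on depth-4 truth gives hR = 1/4", {
  withr::with_seed(21, {
    truth <- random_paths(200, depth = 4, b = 3)
    est <- path_at_level(truth, 1)
    expect_equal(hierarchical_recall(truth, est), 0.25)
    expect_equal(hierarchical_precision(truth, est), 1)
  })
})

test_that("flat metrics agree with hand computation from the confusion table", {
  expect_equal(flat_level_metrics(c("a", "a", "b", "b"),
                                  c("a", "a", "b", "b"))$balanced_accuracy, 1)
  expect_equal(flat_level_metrics(c("a", "a", "b", "b"),
                                  c("a", "a", "b", "b"))$mcc, 1)
  expect_equal(flat_level_metrics(c("a", "b", "a", "b"),
                                  c("b", "a", "b", "a"))$mcc, -1)

  # 3-class toy; expectations computed from the printed contingency table:
  #          pred a  b  c
  #  true a       2  1  0     recall 2/3
  #  true b       1  1  1     recall 1/3
  #  true c       0  0  3     recall 1
  truth <- c("a", "a", "a", "b", "b", "b", "c", "c", "c")
  est <- c("a", "a", "b", "a", "b", "c", "c", "c", "c")
  fm <- flat_level_metrics(truth, est)
  expect_equal(fm$balanced_accuracy, (2 / 3 + 1 / 3 + 1) / 3)
  # MCC by the multiclass formula: c*s - sum(t*p) over sqrt terms
  cm <- table(truth, est)
  s <- sum(cm); cc <- sum(diag(cm))
  tk <- rowSums(cm); pk <- colSums(cm)
  mcc_hand <- (cc * s - sum(tk * pk)) /
    (sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2)))
  expect_equal(fm$mcc, mcc_hand)
  # macro F1 by hand: per-class F1 of (p, r) pairs
  f1 <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)
  expect_equal(fm$macro_f1,
               mean(c(f1(2 / 3, 2 / 3), f1(1 / 2, 1 / 3), f1(3 / 4, 1))))

  expect_warning(out <- flat_level_metrics(c("a", "a"), c("a", "b")), "MCC")
  expect_true(is.na(out$mcc))
})

test_that("macro one-vs-rest AUC is computed when scores are given", {
  skip_if_not_installed("pROC")
  truth <- c("a", "a", "b", "b")
  scores <- cbind(a = c(0.9, 0.8, 0.2, 0.1), b = c(0.1, 0.2, 0.8, 0.9))
  fm <- flat_level_metrics(truth, c("a", "a", "b", "b"), scores = scores)
  expect_equal(fm$auc, 1)
  scores2 <- cbind(a = c(0.1, 0.2, 0.8, 0.9), b = c(0.9, 0.8, 0.2, 0.1))
  fm2 <- flat_level_metrics(truth, c("b", "b", "a", "a"), scores = scores2)
  expect_equal(fm2$auc, 0)
})
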