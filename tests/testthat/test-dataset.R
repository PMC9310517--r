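test_that("dataset read/write round-trips and accepts partial-depth paths", {
  d <- tibble::tibble(id = c("a", "b", "c"),
                      path = c("A/A1", "A/A1", "A"),
                      f01 = c(1, 2, 3), f02 = c(0.5, -1, 2))
  f <- withr::local_tempfile(fileext = ".csv")
  write_hier_dataset(d, f)
  d2 <- read_hier_dataset(f)
  expect_equal(nrow(d2), 3L)
  expect_equal(d2$path, d$path)
  expect_equal(d2$f01, d$f01)
  expect_equal(max(nchar(gsub("[^/]", "", d2$path))), 1L)  # depth-1 path kept

  expect_error(read_hier_dataset(f, label_column = "missing"), "not found")
  writeLines(c("path,f01", "A,x"), f)
  expect_error(read_hier_dataset(f), "non-numeric")
  writeLines("path,f01", f)
  expect_error(read_hier_dataset(f), "empty")
})

test_that("summarize_levels computes per-level class-size statistics", {
  d <- tibble::tibble(path = rep(c("A", "B", "C"), each = 10), f01 = rnorm(30))
  s <- summarize_levels(d)
  expect_equal(s$mean, 10)
  expect_equal(s$sd, 0)
  expect_equal(s$v, 0)

  d2 <- tibble::tibble(path = rep(c("A", "B"), times = c(1, 99)), f01 = rnorm(100))
  s2 <- summarize_levels(d2)
  expect_equal(s2$mean, 50)
  expect_equal(round(s2$sd, 2), 69.3)       # sample SD of {1, 99}
  expect_equal(round(s2$v, 3), 1.386)

  # partial-depth instances do not reach deeper levels
  d3 <- tibble::tibble(path = c("A/A1", "A/A1", "A/A2", "A"), f01 = 1:4)
  s3 <- summarize_levels(d3)
  expect_equal(s3$n_classes, c(1L, 2L))
  expect_equal(s3$mean, c(4, 1.5))
})

test_that("variation_coefficient reproduces printed characterisation cells", {
  # the two hand-checked cells kept out of the headline set
  expect_equal(round(variation_coefficient(59, 291), 2), 4.93)
  expect_equal(round(variation_coefficient(1578.52, 2351.38), 2), 1.49)
  expect_equal(variation_coefficient(123.4, 0), 0)
  expect_error(variation_coefficient(0, 1), "> 0")
  expect_error(variation_coefficient(-2, 1), "> 0")
  expect_error(variation_coefficient(1, -1), ">= 0")
})

test_that("filter_min_samples keeps only classes with enough members", {
  d <- tibble::tibble(path = rep(c("A", "B"), times = c(12, 9)), f01 = rnorm(21))
  kept <- filter_min_samples(d, min_n = 10)
  expect_equal(nrow(kept), 12L)
  expect_true(all(kept$path == "A"))

  # identity when all classes pass
  d2 <- tibble::tibble(path = rep(c("A", "B"), each = 10), f01 = rnorm(20))
  expect_identical(filter_min_samples(d2, min_n = 10), d2)

  expect_error(filter_min_samples(d, min_n = 100), "no class reaches")

  # property: every surviving class has >= min_n members
  withr::with_seed(5, {
    d3 <- generate_hier_data(synth_spec(depth = 3, branching = 2,
                                        target_v = 1.5, n0 = 8,
                                        feature_dim = 2, seed = 5))
    kept3 <- filter_min_samples(d3, min_n = 5)
    expect_true(all(table(kept3$path) >= 5))
  })

  # PD instances shallower than the reference level group by deepest class
  d4 <- tibble::tibble(path = c(rep("A/A1", 10), rep("A", 3)), f01 = rnorm(13))
  kept4 <- filter_min_samples(d4, min_n = 10, reference_level = 2)
  expect_equal(sort(unique(kept4$path)), "A/A1")
})

test_that("semi_balance caps majority classes with NearMiss ranking", {
  # cap arithmetic on a large class
  withr::with_seed(2, {
    d <- tibble::tibble(path = rep(c("A", "B"), times = c(2000, 50)),
                        f01 = rnorm(2050), f02 = rnorm(2050))
    b <- semi_balance(d, cap = 1000, seed = 1)
    expect_equal(as.vector(table(b$path)[c("A", "B")]), c(1000L, 50L))
  })

  # 1-D toy against an exhaustive ranking oracle (NearMiss-2, k = 2 here
  # because only 2 negatives exist)
  toy <- tibble::tibble(path = c(rep("A", 5), rep("B", 2)),
                        f01 = c(0, 1, 2, 3, 10, 6, 7))
  sel <- semi_balance(toy, cap = 2, k = 3)
  score <- sapply(c(0, 1, 2, 3, 10), function(x) mean(abs(x - c(6, 7))))
  expected <- c(0, 1, 2, 3, 10)[order(score)[1:2]]
  expect_setequal(sel$f01[sel$path == "A"], expected)
  expect_equal(sum(sel$path == "B"), 2L)

  # already-balanced data is untouched
  d2 <- tibble::tibble(path = rep(c("A", "B"), each = 5), f01 = rnorm(10))
  expect_identical(semi_balance(d2, cap = 5), d2)

  # never increases any class and never touches classes <= cap
  withr::with_seed(9, {
    d3 <- generate_hier_data(synth_spec(depth = 2, branching = 3,
                                        target_v = 2, n0 = 15,
                                        feature_dim = 3, seed = 9))
    before <- table(d3$path)
    balanced <- suppressWarnings(semi_balance(d3, cap = 12))
    after <- table(factor(balanced$path, levels = names(before)))
    expect_true(all(after <= pmax(before, 0)))
    expect_true(all(after <= 12 | before <= 12))
    small <- names(before)[before <= 12]
    expect_equal(as.vector(after[small]), as.vector(before[small]))
  })
})

test_that("amino-acid composition rows are frequencies summing to 1", {
  a <- aac_features("AAAA")
  expect_equal(a$A, 1)
  expect_equal(sum(a[, -1]), 1)

  b <- aac_features("ACDE")
  expect_equal(unlist(b[, c("A", "C", "D", "E")], use.names = FALSE),
               rep(0.25, 4))

  withr::with_seed(3, {
    seqs <- replicate(10, paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                       sample(5:50, 1), replace = TRUE),
                                collapse = ""))
    m <- aac_features(seqs)
    expect_equal(rowSums(m[, -1]), rep(1, 10), tolerance = 1e-12)
  })

  expect_error(aac_features(""), "empty")
  expect_error(aac_features("ACDX"), "non-standard")
  sk <- aac_features("ACDX", skip_nonstandard = TRUE)
  expect_equal(sum(sk[, -1]), 1)
  expect_equal(sk$A, 1 / 3)
})

test_that("aac_features reads FASTA files", {
  skip_if_not_installed("Biostrings")
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "AAAA", ">p2", "ACDE"), f)
  m <- aac_features(f)
  expect_equal(m$id, c("p1", "p2"))
  expect_equal(m$A, c(1, 0.25))
})
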