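# helper: oracle node models via a classifier-free injected tree -- we
# build real trees on cluster-coded features where every node SVM is
# effectively perfect
coded_data <- function(counts) {
  labels <- rep(names(counts), counts)
  set.seed(51)
  x <- cbind(10 * as.integer(factor(labels)) + rnorm(length(labels), sd = 0.1),
             rnorm(length(labels), sd = 0.1))
  list(x = x, labels = labels)
}

test_that("build_tree trains one SVM per internal node", {
  d <- coded_data(c(C1 = 8, C3 = 6, C10 = 7))
  tr <- suppressWarnings(
    build_tree(list(list("C1", "C3"), "C10"), d$x, d$labels))
  expect_s3_class(tr, "classification_tree")
  expect_false(tr$root$leaf)
  expect_false(tr$root$left$leaf)     # (C1 vs C3) node
  expect_true(tr$root$right$leaf)     # C10 leaf
  expect_setequal(tr$leaves, c("C1", "C3", "C10"))
  # three-level nesting over four clusters: 3 internal nodes
  d4 <- coded_data(c(C1 = 8, C2 = 6, C3 = 6, C10 = 7))
  tr4 <- suppressWarnings(
    build_tree(list(list(list("C1", "C2"), "C3"), "C10"), d4$x, d4$labels))
  n_internal <- function(nd) if (nd$leaf) 0L else
    1L + n_internal(nd$left) + n_internal(nd$right)
  expect_equal(n_internal(tr4$root), 3L)
})

test_that("single-leaf trees and guards", {
  d <- coded_data(c(C1 = 5))
  tr <- build_tree("C1", d$x, d$labels)
  expect_equal(tree_classify(tr, d$x), rep("C1", 5))
  expect_equal(tree_classify(tr, matrix(rnorm(4), 2, 2)), rep("C1", 2))
  d2 <- coded_data(c(C1 = 5, C3 = 5))
  expect_error(build_tree(list("C1", "C9"), d2$x, d2$labels), "missing")
  expect_error(build_tree(list("C1", list("C3", "C1")), d2$x, d2$labels),
               "repeats")
  expect_error(build_tree(list("C1"), d2$x, d2$labels), "binary")
})

test_that("tree classification recovers well-separated clusters", {
  d <- coded_data(c(C1 = 10, C3 = 8, C10 = 9))
  for (spec in enumerate_structures(c("C1", "C3", "C10"))) {
    # high cost: the construction is noiseless, node SVMs should be exact
    tr <- suppressWarnings(build_tree(spec, d$x, d$labels,
                                      config = svm_config(cost = 100)))
    pred <- tree_classify(tr, d$x)
    expect_equal(success_rate(pred, d$labels), 1.0)  # structure-independent
    expect_true(all(pred %in% tr$leaves))
  }
  # imbalanced grouping warns
  d2 <- coded_data(c(C1 = 10, C3 = 3, C10 = 9))
  expect_warning(build_tree(list("C3", list("C1", "C10")), d2$x, d2$labels),
                 "imbalanced")
})

test_that("enumerate_structures counts match the enumeration oracle", {
  # oracle: number of distinct full binary nestings of k labels is
  # (2k-3)!! -- computed independently by the double factorial
  dfact <- function(k) prod(seq(2 * k - 3, 1, by = -2))
  for (k in 2:5) {
    got <- enumerate_structures(paste0("C", 1:k))
    expect_length(got, dfact(k))
    keys <- vapply(got, rtcamoa:::structure_key, character(1))
    expect_false(anyDuplicated(keys) > 0)
  }
  expect_length(enumerate_structures(c("A", "B")), 1)
  # named shallow family for 4 labels: 3 pair-vs-pair + 4 one-vs-rest
  two <- enumerate_structures(paste0("C", 1:4), family = "two_level")
  expect_length(two, 7)
  expect_error(enumerate_structures(paste0("C", 1:6)), "2 to 5")
})

test_that("multi-cluster SR on synthetic separated dynamics", {
  cfg <- preset_config("separable")
  cfg$counts <- c(10L, 1L, 6L, 1L, 1L, 1L, 8L)  # C1, C3, C10 in play
  ds <- generate_dataset(cfg, seed = 13)
  keep <- ds$labels %in% c("C1", "C3", "C10")
  ft <- featurize_sets(ds$sets[keep], n = 11, include_nc = TRUE,
                       level = 5, m = 4)
  spec <- list(list("C1", "C3"), "C10")
  clf <- list(
    train = function(x, y) suppressWarnings(build_tree(spec, x, y)),
    predict = function(model, x) tree_classify(model, x))
  res <- repeated_split_evaluation(ft$x, ft$labels, classifier = clf,
                                   reps = 30, seed = 17, task = "3-cluster")
  expect_gte(res$mean_sr, 0.85)
})

test_that("pairing the tiny cluster against the rest is never the better tree", {
  # regression guard for the balanced-grouping preference: with C3 at 4
  # compounds, [C3 vs (C1+C10)] trains a 3-vs-23 node
  ds <- generate_dataset(preset_config("separable"), seed = 29)
  keep <- ds$labels %in% c("C1", "C3", "C10")
  ft <- featurize_sets(ds$sets[keep], n = 11, include_nc = TRUE,
                       level = 5, m = 4)
  eval_spec <- function(spec) {
    clf <- list(
      train = function(x, y) suppressWarnings(build_tree(spec, x, y)),
      predict = function(model, x) tree_classify(model, x))
    repeated_split_evaluation(ft$x, ft$labels, classifier = clf,
                              reps = 30, seed = 19)$sr
  }
  imbalanced <- eval_spec(list("C3", list("C1", "C10")))
  balanced <- eval_spec(list(list("C1", "C3"), "C10"))
  # paired Monte-Carlo comparison (same splits): the lopsided grouping
  # must not be significantly better than the balanced one
  diffs <- imbalanced - balanced
  se <- stats::sd(diffs) / sqrt(length(diffs))
  expect_lte(mean(diffs), 2 * se)
})
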