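test_that("success_rate counts exact matches", {
  expect_equal(success_rate(c(rep("a", 9), "b"), rep("a", 10)), 0.9)
  expect_equal(success_rate(letters[1:5], letters[1:5]), 1.0)
  expect_equal(success_rate(rep("x", 4), rep("y", 4)), 0.0)
  expect_error(success_rate(character(0), character(0)), "empty")
  expect_error(success_rate("a", c("a", "b")), "mismatch")
})

test_that("average_error reproduces the worked two-cluster examples", {
  svm_best <- c(0.879, 1.000, 0.845, 0.941, 0.720, 0.964)
  svm11 <- c(0.742, 0.995, 0.845, 0.779, 0.720, 0.964)
  svm1 <- c(0.879, 1.000, 0.694, 0.941, 0.657, 0.901)
  expect_equal(round(average_error(svm11), 4), 0.1592)
  expect_equal(round(average_error(svm1), 4), 0.1547)
  expect_equal(round(average_error(combine_best(svm11, svm1)), 4), 0.1085)
  expect_equal(combine_best(svm11, svm1), svm_best)
  expect_equal(average_error(rep(1, 5)), 0)
  expect_error(average_error(numeric(0)), "empty")
})

test_that("combine_best is an elementwise max", {
  set.seed(41)
  for (i in 1:10) {
    a <- runif(6); b <- runif(6)
    cb <- combine_best(a, b)
    expect_true(all(cb >= a & cb >= b))
    expect_true(all(cb == pmax(a, b)))
    # combining never increases the average error
    expect_lte(average_error(cb), min(average_error(a), average_error(b)))
  }
  expect_equal(combine_best(c(0.5, 0.6), c(0.5, 0.6)), c(0.5, 0.6))
  expect_error(combine_best(1, c(1, 1)), "mismatch")
})

test_that("split plans stratify with round-half-up 70 % counts", {
  labels <- c(rep("C1", 20), rep("C10", 13))
  plan <- split_plan(labels, reps = 25, seed = 3)
  expect_equal(unname(plan$n_train[c("C1", "C10")]), c(14, 9))
  for (sp in plan$splits) {
    expect_length(sp$train, 23)
    expect_length(sp$test, 10)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_setequal(c(sp$train, sp$test), seq_along(labels))
    # per-cluster counts constant across repetitions
    expect_equal(sum(labels[sp$train] == "C1"), 14)
    expect_equal(sum(labels[sp$test] == "C10"), 4)
  }
  # reproducibility: same seed, identical plan
  plan2 <- split_plan(labels, reps = 25, seed = 3)
  expect_identical(plan, plan2)
  expect_error(split_plan(c("A", "B", "B"), reps = 2), "at least 2")
})

test_that("repeated_split_evaluation with stub classifiers", {
  labels <- c(rep("C1", 20), rep("C10", 13))
  # cluster-coded feature: nearest training row always shares the label
  x <- matrix(10 * as.integer(factor(labels)) + 0.01 * seq_along(labels),
              ncol = 1)
  res <- repeated_split_evaluation(x, labels, classifier = oracle_classifier(),
                                   reps = 20, seed = 5, task = "oracle")
  expect_equal(res$sr, rep(1, 20))
  expect_equal(res$mean_sr, 1)
  # constant-majority stub on the fixed 6-vs-4 stratified test composition
  resm <- repeated_split_evaluation(x, labels, classifier = majority_classifier(),
                                    reps = 20, seed = 5)
  expect_equal(resm$sr, rep(0.6, 20))
  res100 <- repeated_split_evaluation(x, labels, classifier = oracle_classifier(),
                                      reps = 100, seed = 5)
  expect_length(res100$sr, 100)
  # determinism end to end
  bl <- make_blobs(n_per = 10)
  r1 <- repeated_split_evaluation(bl$x, bl$labels, "svm", reps = 5, seed = 2)
  r2 <- repeated_split_evaluation(bl$x, bl$labels, "svm", reps = 5, seed = 2)
  expect_identical(r1$sr, r2$sr)
  expect_error(repeated_split_evaluation(x, rep("C1", 33), reps = 2),
               "two clusters")
})

test_that("evaluation results serialize to delimited text", {
  labels <- rep(c("A", "B"), each = 6)
  x <- matrix(10 * as.integer(factor(labels)) + 0.01 * seq_along(labels),
              ncol = 1)
  res <- repeated_split_evaluation(x, labels, classifier = oracle_classifier(),
                                   reps = 7, seed = 1, task = "t")
  td <- withr::local_tempdir()
  p <- file.path(td, "res.csv")
  write_evaluation(res, p)
  d <- read.csv(p)
  expect_equal(nrow(d), 7)
  expect_named(d, c("task", "rep", "sr"))
  s <- read.csv(paste0(p, ".summary"))
  expect_equal(s$mean_sr, 1)
  expect_equal(s$avg_error, 0)
})
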