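test_that("accuracy matches the counting oracle including the extremes", {
  expect_equal(accuracy(c("a", "b", "b", "b"), c("a", "b", "a", "b")), 75)
  expect_equal(accuracy(1:5, 1:5), 100)
  expect_equal(accuracy(rep("x", 4), rep("y", 4)), 0)
  set.seed(6)
  for (n in c(3, 100, 1000)) {
    p <- sample(1:4, n, replace = TRUE)
    t <- sample(1:4, n, replace = TRUE)
    expect_equal(accuracy(p, t), oracle_accuracy(p, t))
  }
  expect_error(accuracy(integer(), integer()), "non-empty")
  expect_error(accuracy(1:3, 1:4), "equal length")
})

test_that("crossvalidate runs k folds with exact counts and seeded determinism", {
  co <- simulate_cohort(4, seed = 3)
  r <- crossvalidate(co, "M1", "REC", train_cfg = train_config(epochs = 1, seed = 5),
                     k = 2)
  expect_equal(nrow(r$per_fold), 2)
  expect_equal(r$n_classes, 4)
  expect_true(all(r$per_fold$test_accuracy >= 0 & r$per_fold$test_accuracy <= 100))
  expect_equal(r$validation_accuracy, mean(r$per_fold$val_accuracy))
  expect_equal(r$test_accuracy, mean(r$per_fold$test_accuracy))

  r2 <- crossvalidate(co, "M1", "REC", train_cfg = train_config(epochs = 1, seed = 5),
                      k = 2)
  expect_identical(glance(r), glance(r2))
  expect_named(tidy(r), c("fold", "val_accuracy", "test_accuracy",
                          "arrangement", "dataset", "batchnorm"))

  rec_only <- Filter(function(x) x$condition == "REC", co)
  expect_error(crossvalidate(rec_only, "M1", "REC+REO",
                             train_cfg = train_config(epochs = 1)), "lacks")
  expect_error(crossvalidate(co, "M1", "REC", k = 1), ">= 2")
})

test_that("label permutation stays near the chance floor", {
  co <- simulate_cohort(4, seed = 3)
  null <- crossvalidate(co, "M1", "REC", train_cfg = train_config(epochs = 2, seed = 5),
                        k = 2, shuffle_labels = TRUE)
  expect_lt(abs(null$test_accuracy - chance_floor(4)), 20)
  expect_equal(chance_floor(10), 10)
})

test_that("the comparison grid covers every cell and flags a best per dataset", {
  co <- simulate_cohort(4, seed = 3)
  cmp <- compare_arrangements(co, arrangements = c("M1", "I1"),
                              datasets = "REC",
                              train_cfg = train_config(epochs = 1, seed = 2),
                              k = 2)
  expect_equal(nrow(cmp), 2)
  expect_setequal(cmp$arrangement, c("M1", "I1"))
  best <- attr(cmp, "best_by_dataset")
  expect_equal(nrow(best), 1)
  expect_equal(best$test_accuracy, max(cmp$test_accuracy))
  expect_s3_class(autoplot(cmp), "ggplot")
  expect_error(compare_arrangements(co, arrangements = character()), "non-empty")
})
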