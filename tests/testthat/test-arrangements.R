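test_that("segmentation yields consecutive non-overlapping windows", {
  co <- simulate_cohort(2, seed = 1, duration_s = 60)
  segs <- segment_recording(co[[1]])
  expect_length(segs, 60)
  expect_equal(vapply(segs, `[[`, integer(1), "index"), 0:59)
  expect_equal(segs[[1]]$data, co[[1]]$data[, 1:160], ignore_attr = TRUE)
  expect_equal(segs[[60]]$data, co[[1]]$data[, 9441:9600], ignore_attr = TRUE)

  whole <- segment_recording(co[[1]], window_s = 60)
  expect_length(whole, 1)
  expect_equal(whole[[1]]$data, co[[1]]$data)

  p <- make_profile(0, seed = 1)
  frac <- simulate_recording(p, "REO", duration_s = 61.5)
  expect_equal(ncol(frac$data), 9840)
  segs <- segment_recording(frac)
  expect_length(segs, 61)   # 80 trailing samples dropped

  expect_error(segment_recording(co[[1]], window_s = 61), "longer")
})

test_that("the rotated split gives exact counts and is a partition per fold", {
  co <- simulate_cohort(2, seed = 1, duration_s = 60)
  segs <- unlist(lapply(co, segment_recording), recursive = FALSE)
  key <- function(s) sprintf("%d|%s|%d", s$subject_id, s$condition, s$index)
  train_keys <- list()
  for (f in 0:2) {
    sp <- split_segments(segs, fold_id = f)
    expect_equal(lengths(sp[c("train", "validation", "test")]),
                 c(train = 100L, validation = 20L, test = 120L))
    all_keys <- c(vapply(sp$train, key, ""), vapply(sp$validation, key, ""),
                  vapply(sp$test, key, ""))
    expect_false(any(duplicated(all_keys)))      # disjoint within the fold
    expect_setequal(all_keys, vapply(segs, key, ""))  # and exhaustive
    train_keys[[f + 1]] <- sort(vapply(sp$train, key, ""))
  }
  expect_false(identical(train_keys[[1]], train_keys[[2]]))
  expect_false(identical(train_keys[[1]], train_keys[[3]]))
  expect_false(identical(train_keys[[2]], train_keys[[3]]))

  short <- segment_recording(co[[1]])[1:10]
  expect_error(split_segments(short), "at least")
})

test_that("amplitude matrix is the identity arrangement", {
  co <- simulate_cohort(2, seed = 1, duration_s = 1)
  seg <- segment_recording(co[[1]])[[1]]
  m1 <- amplitude_matrix(seg)
  expect_identical(m1$values, seg$data)
  expect_identical(m1$kind, "M1")
  seg$data[4, 18] <- 5.5      # x_3(17) in 0-based indexing
  expect_equal(unname(amplitude_matrix(seg)$values[4, 18]), 5.5)
  seg$data[] <- 0
  expect_true(all(amplitude_matrix(seg)$values == 0))
})

test_that("pearson_correlation matches the sum-formula oracle and handles edges", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, c(1, 2, 3, 5)), 0.9827, tolerance = 1e-4)
  expect_equal(pearson_correlation(x, x), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  set.seed(3)
  for (i in 1:10) {
    a <- rnorm(50); b <- rnorm(50)
    expect_equal(pearson_correlation(a, b), oracle_pearson(a, b))
  }
  expect_warning(r <- pearson_correlation(rep(1, 5), 1:5), "constant")
  expect_true(is.na(r))
  expect_error(pearson_correlation(1:3, 1:4), "equal length")
})

test_that("correlation matrix is symmetric, unit-diagonal and matches pairwise", {
  set.seed(5)
  x <- matrix(rnorm(4 * 300), 4)
  x[3, ] <- x[1, ]           # duplicated channel
  cm <- correlation_matrix(x)
  expect_equal(cm, t(cm))
  expect_equal(diag(cm), rep(1, 4), ignore_attr = TRUE)
  expect_equal(cm[1, 3], 1)
  expect_true(all(cm >= -1 & cm <= 1))
  expect_equal(cm[1, 2], pearson_correlation(x[1, ], x[2, ]))
  expect_error(correlation_matrix(list()), "empty")
  # concatenation across recordings
  co <- simulate_cohort(2, seed = 1, duration_s = 1)
  joint <- correlation_matrix(co)
  pooled <- do.call(cbind, lapply(co, `[[`, "data"))
  expect_equal(joint[2, 7], pearson_correlation(pooled[2, ], pooled[7, ]))
})

test_that("greedy reordering follows the chain rule, ties and permutation contract", {
  cm <- diag(3)
  cm[1, 2] <- cm[2, 1] <- 0.9
  cm[1, 3] <- cm[3, 1] <- 0.1
  cm[2, 3] <- cm[3, 2] <- 0.8
  expect_equal(reorder_channels(cm)$permutation, c(1L, 2L, 3L))

  expect_equal(reorder_channels(diag(64))$permutation, 1:64)

  set.seed(9)
  a <- matrix(rnorm(64 * 64), 64)
  s <- cov2cor(crossprod(a))
  perm <- reorder_channels(s)$permutation
  expect_setequal(perm, 1:64)

  bad <- diag(3); bad[1, 2] <- 0.5
  expect_error(reorder_channels(bad), "symmetric")
})

test_that("reordered matrix permutes rows and conserves their multiset", {
  co <- simulate_cohort(2, seed = 1, duration_s = 1)
  seg <- segment_recording(co[[1]])[[1]]
  id <- structure(list(permutation = 1:64, source_stat = diag(64)),
                  class = "channel_order")
  expect_equal(reordered_matrix(seg, id)$values, amplitude_matrix(seg)$values)

  rev_ord <- structure(list(permutation = 64:1, source_stat = diag(64)),
                       class = "channel_order")
  m3 <- reordered_matrix(seg, rev_ord)
  expect_equal(m3$values, seg$data[64:1, ])
  expect_equal(sort(rowSums(m3$values)), sort(rowSums(seg$data)))

  bad <- id; bad$permutation[2] <- 1L
  expect_error(reordered_matrix(seg, bad), "permutation")
})

test_that("min-max imaging quantizes to [0,255], hits both ends, ignores affine maps", {
  m <- matrix(c(1, 3, 2, 5), 2)
  expect_equal(matrix_to_image(m), matrix(c(0L, 128L, 64L, 255L), 2))

  b <- matrix(c(0, 1, 1, 0), 2)
  expect_equal(matrix_to_image(b), matrix(c(0L, 255L, 255L, 0L), 2))

  set.seed(2)
  r <- matrix(rnorm(64 * 160), 64)
  img <- matrix_to_image(r)
  expect_true(all(img == round(img)))
  expect_equal(range(img), c(0L, 255L))
  expect_identical(matrix_to_image(3 * r + 7), img)

  # idempotent (after rounding) on an already-quantized image
  expect_identical(matrix_to_image(img * 1.0), img)

  expect_warning(z <- matrix_to_image(matrix(4, 3, 3)), "constant")
  expect_true(all(z == 0))

  co <- simulate_cohort(2, seed = 1, duration_s = 1)
  seg <- segment_recording(co[[1]])[[1]]
  i2 <- matrix_to_image(energy_matrix(seg))
  expect_identical(i2$kind, "I2")
})

test_that("arrange_segment dispatches all six kinds with consistent metadata", {
  co <- simulate_cohort(2, seed = 1, duration_s = 1)
  seg <- segment_recording(co[[1]])[[1]]
  ord <- reorder_channels(correlation_matrix(co))
  for (k in arrangement_kinds()) {
    ai <- arrange_segment(seg, k, order = ord)
    expect_identical(ai$kind, k)
    expect_equal(dim(ai$values), c(64, 160))
    expect_identical(ai$subject_id, seg$subject_id)
  }
  expect_error(arrange_segment(seg, "M3"), "channel_order")
  expect_identical(arrange_segment(seg, "M3", order = ord)$channel_order, ord)
})
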