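test_that("profiles are deterministic, subject-distinct and valid", {
  expect_identical(make_profile(0, seed = 1), make_profile(0, seed = 1))
  p0 <- make_profile(0, seed = 1)
  p1 <- make_profile(1, seed = 1)
  expect_false(identical(p0$band_gains, p1$band_gains))
  expect_true(all(p0$band_gains >= 0))
  expect_gte(p0$alpha_rec_boost, 1.5)
  expect_lte(p0$alpha_rec_boost, 3)

  profiles <- lapply(0:108, make_profile, seed = 1)
  alpha <- vapply(profiles, function(p) p$band_gains[, "alpha"], numeric(64))
  # every pair of subjects differs in its alpha gain vector
  expect_equal(nrow(unique(t(alpha))), 109)
})

test_that("recordings have the requested geometry and validate inputs", {
  p <- make_profile(0, seed = 1)
  rec <- simulate_recording(p, "REO", duration_s = 60)
  expect_equal(dim(rec$data), c(64, 9600))
  expect_equal(rec$fs, 160L)
  expect_identical(rownames(rec$data), default_channel_names())
  expect_error(simulate_recording(p, "REO", duration_s = 0), "positive")
  expect_error(simulate_recording(p, "REO", fs = -1), "positive")
})

test_that("eyes-closed recordings carry more alpha mass on every channel", {
  p <- make_profile(4, seed = 11)
  rec <- simulate_recording(p, "REC", duration_s = 10)
  reo <- simulate_recording(p, "REO", duration_s = 10)
  # identical oscillators and noise; only the alpha weight differs
  for (i in c(1, 17, 33, 64)) {
    expect_gt(oracle_band_power(rec$data[i, ], 160, 8, 13),
              oracle_band_power(reo$data[i, ], 160, 8, 13))
  }
  diffs <- vapply(1:64, function(i) {
    oracle_band_power(rec$data[i, ], 160, 8, 13) -
      oracle_band_power(reo$data[i, ], 160, 8, 13)
  }, numeric(1))
  expect_true(all(diffs > 0))
})

test_that("a noise-free alpha-only profile peaks inside the alpha band", {
  p <- make_profile(0, seed = 3, noise_sd = 0)
  p$band_gains[, c("delta", "theta", "beta")] <- 0
  p$baseline_offsets[] <- 0
  rec <- simulate_recording(p, "REO", duration_s = 4)
  for (i in c(1, 32)) {
    X <- Mod(fft(rec$data[i, ]))^2
    n <- length(X)
    f <- (0:(n - 1)) * 160 / n
    peak <- f[f <= 80][which.max(X[f <= 80])]
    expect_gte(peak, 8)
    expect_lte(peak, 13)
  }
})

test_that("cohorts are reproducible and sized two recordings per subject", {
  expect_error(simulate_cohort(1), ">= 2")
  co <- simulate_cohort(3, seed = 7, duration_s = 2)
  expect_length(co, 6)
  expect_identical(co, simulate_cohort(3, seed = 7, duration_s = 2))
  tb <- as_tibble(co)
  expect_equal(sort(unique(tb$subject_id)), 0:2)
  expect_equal(unname(table(tb$condition)), c(3L, 3L), ignore_attr = TRUE)
  # per-subject streams: subject 0 unchanged when the cohort grows
  co2 <- simulate_cohort(4, seed = 7, duration_s = 2)
  expect_identical(co[[1]], co2[[1]])
})

test_that("band-power profiles separate subjects above chance (sanity floor)", {
  co <- simulate_cohort(6, seed = 2, duration_s = 10)
  bands <- eeg_bands()
  feats <- t(vapply(co, function(r) {
    unlist(lapply(seq_len(nrow(bands)), function(b) {
      vapply(1:64, function(i) {
        oracle_band_power(r$data[i, ], 160, bands$lo[b], bands$hi[b])
      }, numeric(1))
    }))
  }, numeric(256)))
  labs <- vapply(co, `[[`, integer(1), "subject_id")
  pred <- vapply(seq_along(labs), function(i) {
    cents <- t(vapply(unique(labs), function(s) {
      colMeans(feats[labs == s & seq_along(labs) != i, , drop = FALSE])
    }, numeric(ncol(feats))))
    unique(labs)[which.min(rowSums((t(t(cents) - feats[i, ]))^2))]
  }, integer(1))
  expect_gt(mean(pred == labs), 1 / 6)
})
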