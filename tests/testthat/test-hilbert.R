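test_that("Hilbert transform matches closed forms and the direct-kernel oracle", {
  expect_error(hilbert_transform(1), "length >= 2")
  expect_equal(hilbert_transform(rep(3.2, 50)), rep(0, 50))

  t <- (0:159) / 160
  expect_lt(max(abs(hilbert_transform(cos(2 * pi * 10 * t)) -
                      sin(2 * pi * 10 * t))), 1e-6)

  set.seed(42)
  for (i in 1:20) {
    x <- rnorm(160)
    expect_lt(max(abs(hilbert_transform(x) - oracle_hilbert_direct(x))), 1e-9)
  }
})

test_that("applying the transform twice negates a zero-mean band-limited series", {
  set.seed(7)
  n <- 160
  X <- complex(real = rnorm(n), imaginary = rnorm(n))
  X[1] <- 0                     # no DC
  X[n / 2 + 1] <- 0             # no Nyquist component
  X[seq(n, n / 2 + 2)] <- Conj(X[2:(n / 2)])  # Hermitian -> real series
  x <- Re(fft(X, inverse = TRUE) / n)
  expect_equal(hilbert_transform(hilbert_transform(x)), -x, tolerance = 1e-9)
})

test_that("analytic signal keeps the input as its exact real part", {
  set.seed(1)
  x <- rnorm(200)
  z <- analytic_signal(x)
  expect_identical(Re(z), x)
  t <- (0:159) / 160
  zc <- analytic_signal(cos(2 * pi * 10 * t))
  expect_equal(zc, exp(2i * pi * 10 * t), tolerance = 1e-9)
  zk <- analytic_signal(rep(2.5, 10))
  expect_equal(zk, rep(complex(real = 2.5, imaginary = 0), 10))
})

test_that("energy matrix is the squared quadrature and matches the oracle", {
  co <- simulate_cohort(2, seed = 1, duration_s = 2)
  seg <- segment_recording(co[[1]])[[1]]
  m2 <- energy_matrix(seg)
  expect_identical(m2$kind, "M2")
  expect_true(all(m2$values >= 0))
  for (i in c(1, 40)) {
    expect_equal(m2$values[i, ], oracle_hilbert_direct(seg$data[i, ])^2,
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
  # cos -> sin^2 closed form, peak 1
  seg$data[1, ] <- cos(2 * pi * 10 * (0:159) / 160)
  row <- energy_matrix(seg)$values[1, ]
  expect_equal(row, sin(2 * pi * 10 * (0:159) / 160)^2,
               tolerance = 1e-9, ignore_attr = TRUE)

  # conventional instantaneous-power alternative
  m2a <- energy_matrix(seg, energy = "analytic_magnitude")
  expect_equal(m2a$values, seg$data^2 + hilbert_transform_rows(seg$data)^2,
               tolerance = 1e-12, ignore_attr = TRUE)

  zero <- seg
  zero$data[] <- 0
  expect_true(all(energy_matrix(zero)$values == 0))
})
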