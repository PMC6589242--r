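# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the Hilbert oracle is an O(n^2) circular
# convolution with the closed-form discrete kernel, the correlation and
# accuracy oracles are literal sum formulas, and band power is integrated
# straight off the raw periodogram.

# Discrete Hilbert transform by direct circular convolution with the
# closed-form kernel for even length n: h[k] = (2/n) * cot(pi k / n) for odd
# k, 0 for even k.
oracle_hilbert_direct <- function(x) {
  n <- length(x)
  stopifnot(n %% 2 == 0)
  k <- 0:(n - 1)
  h <- ifelse(k %% 2 == 1, (2 / n) / tan(pi * k / n), 0)
  vapply(0:(n - 1), function(m) {
    sum(h * x[((m - k) %% n) + 1])
  }, numeric(1))
}

# Literal Pearson sum formula.
oracle_pearson <- function(x, y) {
  xb <- sum(x) / length(x)
  yb <- sum(y) / length(y)
  sum((x - xb) * (y - yb)) / sqrt(sum((x - xb)^2) * sum((y - yb)^2))
}

# Loop-and-count accuracy in percent.
oracle_accuracy <- function(pred, truth) {
  hits <- 0
  for (i in seq_along(pred)) if (pred[i] == truth[i]) hits <- hits + 1
  100 * hits / length(pred)
}

# Spectral mass of a series in [lo, hi] Hz from the raw periodogram.
oracle_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  X <- fft(x)
  f <- (0:(n - 1)) * fs / n
  keep <- f >= lo & f <= hi & f <= fs / 2
  sum(Mod(X[keep])^2) / n
}

# Small arranged M1 training/validation/test split from a simulated cohort;
# short recordings keep unit tests fast.
tiny_m1_split <- function(n_subjects = 2, seed = 1, duration_s = 10,
                          n_train = 6, n_val = 2, n_test = 2) {
  cohort <- simulate_cohort(n_subjects, seed = seed, duration_s = duration_s)
  segs <- unlist(lapply(cohort, segment_recording), recursive = FALSE)
  sp <- split_segments(segs, n_train = n_train, n_val = n_val, n_test = n_test)
  for (set in c("train", "validation", "test")) {
    sp[[set]] <- lapply(sp[[set]], amplitude_matrix)
  }
  sp
}

segment_ids <- function(set) {
  vapply(set, `[[`, integer(1), "subject_id")
}
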