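# Synthetic resting-state EEG cohorts.
#
# Each subject gets a spectral "fingerprint": per-channel amplitude weights for
# the four classical frequency bands, drawn once per subject. Recordings are a
# sum of band-limited sinusoids (random frequency and phase per channel per
# band) plus broadband white noise. Eyes-closed (REC) recordings multiply the
# alpha-band weight by a per-subject boost > 1, emulating the well-known
# posterior alpha increase when the eyes close.

.bci2000_channels <- c(
  "Fc5", "Fc3", "Fc1", "Fcz", "Fc2", "Fc4", "Fc6",
  "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
  "Cp5", "Cp3", "Cp1", "Cpz", "Cp2", "Cp4", "Cp6",
  "Fp1", "Fpz", "Fp2",
  "Af7", "Af3", "Afz", "Af4", "Af8",
  "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
  "Ft7", "Ft8",
  "T7", "T8", "T9", "T10",
  "Tp7", "Tp8",
  "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
  "Po7", "Po3", "Poz", "Po4", "Po8",
  "O1", "Oz", "O2", "Iz"
)

#' Default 64-channel montage labels
#'
#' The stored default channel order of the 64-electrode BCI2000 10-10 montage.
#' Row `i` of every matrix in this package corresponds to
#' `default_channel_names()[i]` unless a [channel_order] permutation has been
#' applied. The pipeline only uses these as labels; no physical electrode
#' positions are consulted.
#'
#' @param n Number of channels requested (default 64). For `n < 64` the first
#'   `n` labels are returned; for `n > 64` synthetic `ch<i>` labels are
#'   appended.
#' @return Character vector of length `n`.
#' @export
#' @examples
#' head(default_channel_names())
default_channel_names <- function(n = 64L) {
  if (!is_count(n, min = 1L)) stop_invalid("`n` must be a positive integer")
  if (n <= length(.bci2000_channels)) {
    .bci2000_channels[seq_len(n)]
  } else {
    c(.bci2000_channels, paste0("ch", seq(length(.bci2000_channels) + 1L, n)))
  }
}

#' Frequency band definitions
#'
#' The four classical EEG bands used by the synthetic generator: delta
#' (1--4 Hz), theta (4--8 Hz), alpha (8--13 Hz), beta (13--30 Hz).
#'
#' @return A tibble with columns `band`, `lo`, `hi` (Hz).
#' @export
eeg_bands <- function() {
  tibble::tibble(
    band = c("delta", "theta", "alpha", "beta"),
    lo = c(1, 4, 8, 13),
    hi = c(4, 8, 13, 30)
  )
}

# Base band amplitudes (arbitrary units); the resting-state spectrum falls off
# with frequency, with a visible alpha bump.
.base_band_amplitude <- c(delta = 1.0, theta = 0.6, alpha = 0.8, beta = 0.4)

#' Draw a subject's spectral profile
#'
#' Creates the per-subject parameters of the synthetic generator: a
#' channels-by-bands matrix of amplitude weights (lognormal variation around
#' fixed base amplitudes), the eyes-closed alpha boost, per-channel baseline
#' (DC) offsets, and the broadband noise standard deviation. The baseline
#' offsets emulate the electrode/amplifier offsets of raw unreferenced EEG —
#' the pipeline applies no detrending or re-referencing, so they reach the
#' classifier just as they do in unpreprocessed recordings. Deterministic
#' given `(subject_id, seed)`: the per-subject stream is seeded with
#' `seed + subject_id`, so enlarging a cohort never changes existing
#' subjects.
#'
#' @param subject_id Integer label, 0-based.
#' @param seed Integer base seed for the cohort.
#' @param n_channels Number of channels (default 64).
#' @param gain_sd Standard deviation of the lognormal gain variation
#'   (default 0.35).
#' @param alpha_boost_range Range the eyes-closed alpha multiplier is drawn
#'   from, uniformly (default `c(1.5, 3)`).
#' @param offset_sd Standard deviation of the per-channel baseline offsets,
#'   in signal units (default 2).
#' @param noise_sd Standard deviation of additive white noise, in signal
#'   units (default 0.5).
#' @return A `subject_profile` object.
#' @export
#' @examples
#' p <- make_profile(0, seed = 1)
#' dim(p$band_gains)
make_profile <- function(subject_id, seed, n_channels = 64L, gain_sd = 0.35,
                         alpha_boost_range = c(1.5, 3), offset_sd = 2,
                         noise_sd = 0.5) {
  if (!is_count(subject_id)) stop_invalid("`subject_id` must be a non-negative integer")
  if (!is_count(seed, min = -.Machine$integer.max)) stop_invalid("`seed` must be an integer")
  bands <- eeg_bands()$band
  prof <- with_seed(seed + subject_id, {
    gains <- matrix(
      rep(.base_band_amplitude[bands], each = n_channels) *
        exp(rnorm(n_channels * length(bands), 0, gain_sd)),
      nrow = n_channels, ncol = length(bands),
      dimnames = list(default_channel_names(n_channels), bands)
    )
    list(gains = gains,
         boost = runif(1, alpha_boost_range[1], alpha_boost_range[2]),
         offsets = rnorm(n_channels, 0, offset_sd))
  })
  structure(
    list(
      subject_id = as.integer(subject_id),
      band_gains = prof$gains,
      alpha_rec_boost = prof$boost,
      baseline_offsets = prof$offsets,
      noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "subject_profile"
  )
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "<subject_profile> id=%d, %d channels, alpha REC boost %.2f, noise sd %.2f\n",
    x$subject_id, nrow(x$band_gains), x$alpha_rec_boost, x$noise_sd
  ))
  invisible(x)
}

new_eeg_recording <- function(subject_id, condition, data, fs, channel_names) {
  stopifnot(is.matrix(data), !anyNA(data))
  rownames(data) <- channel_names
  structure(
    list(subject_id = as.integer(subject_id), condition = condition,
         data = data, fs = as.integer(fs), channel_names = channel_names),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> subject %d, %s, %d channels x %d samples @ %d Hz (%.1f s)\n",
    x$subject_id, x$condition, nrow(x$data), ncol(x$data), x$fs,
    ncol(x$data) / x$fs
  ))
  invisible(x)
}

# Oscillators per channel per band. Two sparse spectral lines per band are
# enough to carry a subject's band-weight fingerprint while keeping 60 s x 64
# channel synthesis cheap.
.n_oscillators <- 2L

#' Simulate one resting-state recording
#'
#' Synthesizes a multichannel recording for one subject under one condition as
#' the subject's per-channel baseline offset plus a sum of band-limited
#' sinusoids plus white noise. Oscillator frequencies
#' and phases, and the noise, are drawn from a stream seeded with
#' `seed + subject_id` and are identical between conditions: REC differs from
#' REO only through the alpha-band weight, which is multiplied by the
#' profile's `alpha_rec_boost` under REC.
#'
#' @param profile A [make_profile()] object.
#' @param condition `"REC"` (eyes closed) or `"REO"` (eyes open).
#' @param duration_s Recording length in seconds (default 60).
#' @param fs Sampling frequency in Hz (default 160).
#' @param seed Integer base seed (default the profile's seed).
#' @return An `eeg_recording` with a channels-by-samples data matrix.
#' @export
#' @examples
#' rec <- simulate_recording(make_profile(0, 1), "REO", duration_s = 2)
#' dim(rec$data)
simulate_recording <- function(profile, condition = c("REC", "REO"),
                               duration_s = 60, fs = 160L,
                               seed = profile$seed) {
  condition <- match.arg(condition)
  if (!inherits(profile, "subject_profile")) {
    stop_invalid("`profile` must be a subject_profile")
  }
  if (!is.numeric(duration_s) || length(duration_s) != 1L || duration_s <= 0) {
    stop_invalid("`duration_s` must be a positive number")
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop_invalid("`fs` must be a positive sampling frequency")
  }
  n_channels <- nrow(profile$band_gains)
  n <- round(duration_s * fs)
  bands <- eeg_bands()
  nb <- nrow(bands)
  draws <- with_seed(seed + profile$subject_id, {
    freqs <- array(0, c(n_channels, .n_oscillators, nb))
    phases <- array(0, c(n_channels, .n_oscillators, nb))
    for (b in seq_len(nb)) {
      freqs[, , b] <- runif(n_channels * .n_oscillators, bands$lo[b], bands$hi[b])
      phases[, , b] <- runif(n_channels * .n_oscillators, 0, 2 * pi)
    }
    noise <- matrix(rnorm(n_channels * n, 0, profile$noise_sd), n_channels, n)
    list(freqs = freqs, phases = phases, noise = noise)
  })
  gains <- profile$band_gains
  if (condition == "REC") {
    gains[, "alpha"] <- gains[, "alpha"] * profile$alpha_rec_boost
  }
  tt <- (seq_len(n) - 1) / fs
  x <- draws$noise + profile$baseline_offsets
  for (b in seq_len(nb)) {
    g <- gains[, b] / sqrt(.n_oscillators)
    for (k in seq_len(.n_oscillators)) {
      ang <- 2 * pi * outer(draws$freqs[, k, b], tt) + draws$phases[, k, b]
      x <- x + g * sin(ang)
    }
  }
  new_eeg_recording(profile$subject_id, condition, x, fs,
                    default_channel_names(n_channels))
}

#' Simulate a two-condition cohort
#'
#' One 60 s eyes-closed (REC) and one 60 s eyes-open (REO) recording per
#' subject, 64 channels at 160 Hz by default, mirroring the structure of the
#' public motor-movement/imagery baseline runs. Fully deterministic given
#' `(n_subjects, seed)`; subject `i` is unaffected by the presence of other
#' subjects.
#'
#' @param n_subjects Number of subjects (>= 2); subject ids are `0:(n-1)`.
#' @param seed Integer base seed.
#' @param duration_s,fs Recording length (s) and sampling rate (Hz).
#' @param n_channels Number of channels (default 64).
#' @param noise_sd Broadband noise standard deviation passed to the profiles.
#' @return An `eeg_cohort`: a list of `2 * n_subjects` recordings (REC then
#'   REO per subject) with the generation parameters attached.
#' @export
#' @examples
#' cohort <- simulate_cohort(2, seed = 1, duration_s = 2)
#' length(cohort)
simulate_cohort <- function(n_subjects, seed = 1L, duration_s = 60, fs = 160L,
                            n_channels = 64L, noise_sd = 0.5) {
  if (!is_count(n_subjects, min = 2L)) {
    stop_invalid("`n_subjects` must be an integer >= 2")
  }
  recs <- vector("list", 2L * n_subjects)
  for (i in seq_len(n_subjects)) {
    profile <- make_profile(i - 1L, seed, n_channels = n_channels,
                            noise_sd = noise_sd)
    recs[[2L * i - 1L]] <- simulate_recording(profile, "REC", duration_s, fs)
    recs[[2L * i]] <- simulate_recording(profile, "REO", duration_s, fs)
  }
  structure(recs, class = "eeg_cohort",
            n_subjects = as.integer(n_subjects), seed = as.integer(seed))
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat(sprintf("<eeg_cohort> %d subjects, %d recordings (seed %d)\n",
              attr(x, "n_subjects"), length(x), attr(x, "seed")))
  invisible(x)
}

#' Summarize a cohort as a tibble
#'
#' @param x An `eeg_cohort`.
#' @param ... Unused.
#' @return One row per recording: subject, condition, channels, samples, fs.
#' @method as_tibble eeg_cohort
#' @export
as_tibble.eeg_cohort <- function(x, ...) {
  purrr::map_dfr(unclass(x), function(r) {
    tibble::tibble(subject_id = r$subject_id, condition = r$condition,
                   n_channels = nrow(r$data), n_samples = ncol(r$data),
                   fs = r$fs)
  })
}
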