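# Segmentation, the train/validation/test split, and the six input
# arrangements: amplitude matrix M1, instantaneous-energy matrix M2,
# correlation-reordered amplitude matrix M3, and their 0-255 min-max image
# encodings I1/I2/I3.

new_segment <- function(subject_id, condition, index, data) {
  structure(
    list(subject_id = as.integer(subject_id), condition = condition,
         index = as.integer(index), data = data),
    class = "eeg_segment"
  )
}

#' @export
print.eeg_segment <- function(x, ...) {
  cat(sprintf("<eeg_segment> subject %d, %s, index %d, %d x %d\n",
              x$subject_id, x$condition, x$index, nrow(x$data), ncol(x$data)))
  invisible(x)
}

new_arranged_input <- function(kind, values, subject_id, condition, index,
                               channel_order = NULL) {
  structure(
    list(kind = kind, values = values, subject_id = as.integer(subject_id),
         condition = condition, index = as.integer(index),
         channel_order = channel_order),
    class = "arranged_input"
  )
}

#' @export
print.arranged_input <- function(x, ...) {
  cat(sprintf("<arranged_input> %s, subject %d, %s, index %d, %d x %d\n",
              x$kind, x$subject_id, x$condition, x$index,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Arrangement kinds
#' @return Character vector of the six arrangement tags.
#' @export
arrangement_kinds <- function() c("M1", "M2", "M3", "I1", "I2", "I3")

#' Cut a recording into fixed-length segments
#'
#' Splits a recording into consecutive, non-overlapping windows of
#' `window_s` seconds (1 s, i.e. 64 x 160 samples, by default). A trailing
#' remainder shorter than one window is dropped.
#'
#' @param rec An `eeg_recording`.
#' @param window_s Window length in seconds; `window_s * fs` must be an
#'   integer number of samples and no longer than the recording.
#' @return List of `eeg_segment`s, `index` running from 0 in temporal order.
#' @export
#' @examples
#' rec <- simulate_recording(make_profile(0, 1), "REO", duration_s = 3)
#' length(segment_recording(rec))
segment_recording <- function(rec, window_s = 1) {
  if (!inherits(rec, "eeg_recording")) stop_invalid("`rec` must be an eeg_recording")
  wlen <- window_s * rec$fs
  if (abs(wlen - round(wlen)) > 1e-9) {
    stop_invalid("`window_s` * fs must be an integer number of samples")
  }
  wlen <- as.integer(round(wlen))
  if (wlen < 1L || wlen > ncol(rec$data)) {
    stop_invalid("window (", wlen, " samples) must be positive and no longer ",
                 "than the recording (", ncol(rec$data), " samples)")
  }
  n_seg <- ncol(rec$data) %/% wlen
  lapply(seq_len(n_seg) - 1L, function(i) {
    new_segment(rec$subject_id, rec$condition, i,
                rec$data[, (i * wlen + 1L):((i + 1L) * wlen), drop = FALSE])
  })
}

#' Deterministic per-subject train/validation/test split
#'
#' Assigns each subject-condition's segments (ordered by temporal index) to
#' train/validation/test in the fixed proportions 25/5/30 (per 60 one-second
#' segments). Fold `f` rotates the index sequence by `f * rotation` positions
#' before taking the first `n_train` as training, the next `n_val` as
#' validation, and the last `n_test` as test, which gives the threefold
#' protocol a concrete, leakage-free meaning: within a fold the three sets
#' never share a (subject, condition, index) triple.
#'
#' @param segments List of `eeg_segment`s (or `arranged_input`s).
#' @param n_train,n_val,n_test Per subject-condition counts (default 25/5/30).
#' @param fold_id Integer fold index (0-based).
#' @param rotation Positions the index sequence is rotated per fold
#'   (default 20, one third of 60).
#' @return A `dataset_split` with elements `train`, `validation`, `test`
#'   (lists) and `fold_id`.
#' @export
split_segments <- function(segments, n_train = 25L, n_val = 5L, n_test = 30L,
                           fold_id = 0L, rotation = 20L) {
  if (length(segments) == 0L) stop_invalid("`segments` is empty")
  if (!is_count(fold_id)) stop_invalid("`fold_id` must be a non-negative integer")
  key <- vapply(segments, function(s) paste(s$subject_id, s$condition),
                character(1))
  groups <- split(seq_along(segments), key)
  take <- function(which) {
    idx <- unlist(lapply(groups, function(g) {
      g <- g[order(vapply(segments[g], `[[`, integer(1), "index"))]
      n_seg <- length(g)
      if (n_train + n_val + n_test > n_seg) {
        stop_invalid("subject-condition group has ", n_seg,
                     " segments; need at least ", n_train + n_val + n_test)
      }
      rot <- (fold_id * rotation) %% n_seg
      pos <- ((seq_len(n_seg) - 1L + rot) %% n_seg) + 1L
      g <- g[pos]
      switch(which,
             train = g[seq_len(n_train)],
             validation = g[n_train + seq_len(n_val)],
             test = g[n_train + n_val + seq_len(n_test)])
    }), use.names = FALSE)
    segments[idx]
  }
  structure(
    list(train = take("train"), validation = take("validation"),
         test = take("test"), fold_id = as.integer(fold_id)),
    class = "dataset_split"
  )
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> fold %d: %d train / %d validation / %d test\n",
              x$fold_id, length(x$train), length(x$validation),
              length(x$test)))
  invisible(x)
}

#' Amplitude-versus-time matrix (M1)
#'
#' The identity arrangement: the raw segment, channels as rows in the default
#' montage order, time as columns.
#'
#' @param seg An `eeg_segment`.
#' @return An `arranged_input` of kind `"M1"`.
#' @export
amplitude_matrix <- function(seg) {
  stopifnot(inherits(seg, "eeg_segment"))
  new_arranged_input("M1", seg$data, seg$subject_id, seg$condition, seg$index)
}

#' Instantaneous-energy matrix (M2)
#'
#' Per channel, the squared discrete Hilbert transform of the segment:
#' `E(i, t) = H(x_i(t))^2`. The conventional alternative, the squared modulus
#' of the analytic signal `|x + iH(x)|^2` (instantaneous power), is available
#' via `energy = "analytic_magnitude"`; the squared-quadrature form is the
#' default.
#'
#' @param seg An `eeg_segment`.
#' @param energy `"hilbert"` (default) or `"analytic_magnitude"`.
#' @return An `arranged_input` of kind `"M2"` with non-negative entries.
#' @export
energy_matrix <- function(seg, energy = c("hilbert", "analytic_magnitude")) {
  stopifnot(inherits(seg, "eeg_segment"))
  energy <- match.arg(energy)
  h <- hilbert_transform_rows(seg$data)
  e <- if (energy == "hilbert") h^2 else seg$data^2 + h^2
  dimnames(e) <- dimnames(seg$data)
  new_arranged_input("M2", e, seg$subject_id, seg$condition, seg$index)
}

#' Pearson correlation coefficient
#'
#' Linear correlation between two equal-length series. Thin wrapper over
#' [stats::cor()] with the degenerate constant-series case signalled
#' explicitly: a constant input has no defined correlation and yields `NA`
#' with a warning, leaving the decision to the caller.
#'
#' @param x,y Numeric vectors of equal length >= 2.
#' @return A number in `[-1, 1]`, or `NA` for a constant input.
#' @export
#' @examples
#' pearson_correlation(1:4, c(1, 2, 3, 5))
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop_invalid("`x` and `y` must have equal length")
  if (length(x) < 2L) stop_invalid("need at least 2 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("correlation undefined for a constant series; returning NA")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Pairwise channel correlation matrix
#'
#' Pearson correlations between all channel pairs, computed on the
#' channel-wise concatenation of the supplied recordings or segments. For the
#' reordered arrangements this is computed once on the pooled training-split
#' samples of all subjects, yielding a single global channel order.
#'
#' @param recordings Non-empty list of `eeg_recording`s / `eeg_segment`s, or
#'   a single channels-by-samples matrix.
#' @return Symmetric matrix with unit diagonal, entries in `[-1, 1]`.
#'   Undefined entries (constant channels) are set to 0 with a warning.
#' @export
correlation_matrix <- function(recordings) {
  if (is.matrix(recordings)) recordings <- list(list(data = recordings))
  if (length(recordings) == 0L) stop_invalid("`recordings` is empty")
  mats <- lapply(recordings, function(r) r$data)
  nch <- vapply(mats, nrow, integer(1))
  if (length(unique(nch)) != 1L) stop_invalid("all inputs must share a channel count")
  x <- do.call(cbind, mats)
  cm <- suppressWarnings(stats::cor(t(x)))
  if (anyNA(cm)) {
    warning("constant channel(s): undefined correlations set to 0")
    cm[is.na(cm)] <- 0
  }
  diag(cm) <- 1
  cm
}

#' Greedy correlation-based channel reordering
#'
#' Builds the channel permutation used by the M3/I3 arrangements: start from
#' the first channel of the default order, then repeatedly append the
#' not-yet-placed channel with the highest (signed) correlation to the most
#' recently placed one, concatenating correlated channels next to each other.
#' Ties break toward the lowest channel index.
#'
#' @param corr Symmetric correlation matrix with unit diagonal.
#' @return A `channel_order`: `permutation` (1-based channel indices) and
#'   `source_stat` (the matrix it was derived from).
#' @export
#' @examples
#' cm <- diag(3); cm[1, 2] <- cm[2, 1] <- 0.9
#' cm[1, 3] <- cm[3, 1] <- 0.1; cm[2, 3] <- cm[3, 2] <- 0.8
#' reorder_channels(cm)$permutation
reorder_channels <- function(corr) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr)) {
    stop_invalid("`corr` must be a square matrix")
  }
  if (max(abs(corr - t(corr))) > 1e-8) {
    stop_invalid("`corr` must be symmetric")
  }
  n <- nrow(corr)
  placed <- integer(n)
  placed[1] <- 1L
  remaining <- setdiff(seq_len(n), 1L)
  for (k in seq_len(n - 1L)) {
    last <- placed[k]
    best <- remaining[which.max(corr[last, remaining])]
    placed[k + 1L] <- best
    remaining <- setdiff(remaining, best)
  }
  structure(list(permutation = placed, source_stat = corr),
            class = "channel_order")
}

#' @export
print.channel_order <- function(x, ...) {
  cat(sprintf("<channel_order> %d channels: %s ...\n", length(x$permutation),
              paste(head(x$permutation, 8), collapse = " ")))
  invisible(x)
}

#' Channel-reordered amplitude matrix (M3)
#'
#' The amplitude matrix with rows permuted by a correlation-derived
#' [channel order][reorder_channels]: row `r` of M3 is channel
#' `permutation[r]` of the segment. The multiset of rows is preserved.
#'
#' @param seg An `eeg_segment`.
#' @param order A `channel_order` whose permutation covers the segment's
#'   channels exactly once.
#' @return An `arranged_input` of kind `"M3"` carrying the order used.
#' @export
reordered_matrix <- function(seg, order) {
  stopifnot(inherits(seg, "eeg_segment"))
  if (!inherits(order, "channel_order")) stop_invalid("`order` must be a channel_order")
  p <- order$permutation
  if (length(p) != nrow(seg$data) || !setequal(p, seq_len(nrow(seg$data)))) {
    stop_invalid("`order` is not a permutation of the segment's channels")
  }
  new_arranged_input("M3", seg$data[p, , drop = FALSE], seg$subject_id,
                     seg$condition, seg$index, channel_order = order)
}

#' Min-max image encoding (I1/I2/I3)
#'
#' Affinely rescales a single matrix to integers 0--255 (8-bit grayscale):
#' `I(i,t) = round((m(i,t) - min) / (max - min) * 255)` with min/max taken
#' over that one matrix and rounding half away from zero. A non-constant
#' input therefore always attains both 0 and 255, and the encoding is
#' invariant to affine transforms of the input. A constant matrix is
#' degenerate: an all-zero image is returned with a warning.
#'
#' @param m An `arranged_input` of kind M1/M2/M3, or a plain numeric matrix.
#' @param .kind Image tag used when `m` is a plain matrix (default `"I1"`).
#' @return An `arranged_input` of kind I1/I2/I3 (or an integer matrix when
#'   the input was a plain matrix).
#' @export
#' @examples
#' matrix_to_image(matrix(c(1, 3, 2, 5), 2))
matrix_to_image <- function(m, .kind = "I1") {
  plain <- !inherits(m, "arranged_input")
  v <- if (plain) m else m$values
  if (!is.numeric(v) || !is.matrix(v)) stop_invalid("input must be a numeric matrix")
  rng <- range(v)
  if (rng[1] == rng[2]) {
    warning("constant matrix: min-max scaling degenerate, emitting all-zero image")
    img <- matrix(0L, nrow(v), ncol(v))
  } else {
    img <- matrix(as.integer(round_half_away((v - rng[1]) / (rng[2] - rng[1]) * 255)),
                  nrow(v), ncol(v))
  }
  dimnames(img) <- dimnames(v)
  if (plain) return(img)
  kind <- sub("^M", "I", m$kind)
  if (!kind %in% c("I1", "I2", "I3")) kind <- .kind
  new_arranged_input(kind, img, m$subject_id, m$condition, m$index,
                     channel_order = m$channel_order)
}

#' Apply one of the six arrangements to a segment
#'
#' Dispatcher used by the cross-validation harness: M1/M2/M3 produce real
#' matrices, I1/I2/I3 the corresponding 0--255 images. M3/I3 require a
#' global [channel_order][reorder_channels].
#'
#' @param seg An `eeg_segment`.
#' @param kind One of [arrangement_kinds()].
#' @param order A `channel_order` (required for M3/I3).
#' @param energy Energy definition passed to [energy_matrix()].
#' @return An `arranged_input`.
#' @export
arrange_segment <- function(seg, kind, order = NULL,
                            energy = c("hilbert", "analytic_magnitude")) {
  kind <- match.arg(kind, arrangement_kinds())
  energy <- match.arg(energy)
  base <- switch(substr(kind, 2, 2),
    "1" = amplitude_matrix(seg),
    "2" = energy_matrix(seg, energy = energy),
    "3" = {
      if (is.null(order)) stop_invalid(kind, " requires a channel_order")
      reordered_matrix(seg, order)
    }
  )
  if (startsWith(kind, "I")) matrix_to_image(base) else base
}
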