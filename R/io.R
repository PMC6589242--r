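# On-disk artifacts: 8-bit grayscale PNG for the image arrangements, a raw
# little-endian double container with a JSON sidecar for recordings and real
# matrices, plain text for channel orders, and a minimal EDF reader/writer
# for interoperability with the public recordings (optional; nothing else in
# the package depends on it).

arranged_basename <- function(ai) {
  sprintf("S%03d_%s_seg%02d_%s", ai$subject_id, ai$condition, ai$index, ai$kind)
}

parse_arranged_basename <- function(path) {
  b <- sub("\\.[A-Za-z0-9]+$", "", basename(path))
  m <- regmatches(b, regexec("^S(\\d+)_(REC|REO)_seg(\\d+)_([MI][123])$", b))[[1]]
  if (length(m) == 0L) return(NULL)
  list(subject_id = as.integer(m[2]), condition = m[3],
       index = as.integer(m[4]), kind = m[5])
}

#' Write an image arrangement as 8-bit grayscale PNG
#'
#' Lossless: integer pixel values 0--255 round-trip bit-exactly through
#' [read_png()]. The image is 64 px tall by 160 px wide at the default
#' segment size; row `i` is channel `i`. The filename (when derived) encodes
#' subject, condition, segment index and arrangement kind.
#'
#' @param img An `arranged_input` of kind I1/I2/I3, or an integer matrix with
#'   entries in 0--255.
#' @param path Output path; for an `arranged_input` a directory may be given,
#'   in which case the encoded filename is used.
#' @return The path written, invisibly.
#' @export
write_png <- function(img, path) {
  v <- if (inherits(img, "arranged_input")) {
    if (!img$kind %in% c("I1", "I2", "I3")) {
      stop_invalid("only image arrangements (I1/I2/I3) can be written as PNG")
    }
    img$values
  } else {
    img
  }
  if (any(v < 0 | v > 255) || any(v != round(v))) {
    stop_invalid("image values must be integers in [0, 255]")
  }
  if (dir.exists(path)) {
    if (!inherits(img, "arranged_input")) {
      stop_invalid("`path` is a directory; pass an arranged_input or a file path")
    }
    path <- file.path(path, paste0(arranged_basename(img), ".png"))
  }
  png::writePNG(v / 255, path)
  invisible(path)
}

#' Read an 8-bit grayscale PNG arrangement
#'
#' Inverse of [write_png()]. If the filename follows the package's encoding
#' the result is an `arranged_input`; otherwise a plain integer matrix.
#'
#' @param path PNG file path.
#' @return An `arranged_input` or integer matrix with entries in 0--255.
#' @export
read_png <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  v <- m * 255
  if (max(abs(v - round(v))) > 1e-6) {
    stop_invalid("file is not an 8-bit grayscale image: ", path)
  }
  img <- matrix(as.integer(round(v)), nrow(m), ncol(m))
  meta <- parse_arranged_basename(path)
  if (is.null(meta)) return(img)
  new_arranged_input(meta$kind, img, meta$subject_id, meta$condition, meta$index)
}

#' Write / read a recording in the raw-double container
#'
#' A recording is stored as little-endian doubles (column-major,
#' channels x samples) in `<base>.dat` with a JSON sidecar `<base>.json`
#' holding subject id, condition, sampling rate, dimensions and channel
#' names. The pair is self-contained and reloads bit-exactly.
#'
#' @param rec An `eeg_recording`.
#' @param dir Output directory (created if needed).
#' @return `write_recording()` the sidecar path, invisibly;
#'   `read_recording()` an `eeg_recording`.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "eeg_recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  base <- file.path(dir, sprintf("S%03d_%s", rec$subject_id, rec$condition))
  con <- file(paste0(base, ".dat"), "wb")
  writeBin(as.vector(rec$data), con, size = 8, endian = "little")
  close(con)
  meta <- list(subject_id = rec$subject_id, condition = rec$condition,
               fs = rec$fs, n_channels = nrow(rec$data),
               n_samples = ncol(rec$data), channel_names = rec$channel_names)
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paste0(base, ".json"))
}

#' @rdname write_recording
#' @param path The `.json` sidecar path (or the `.dat` path).
#' @export
read_recording <- function(path) {
  base <- sub("\\.(json|dat)$", "", path)
  meta <- jsonlite::read_json(paste0(base, ".json"), simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  con <- file(paste0(base, ".dat"), "rb")
  x <- readBin(con, "double", n = n, size = 8, endian = "little")
  close(con)
  if (length(x) != n) stop_invalid("truncated data file: ", base, ".dat")
  new_eeg_recording(meta$subject_id, meta$condition,
                    matrix(x, meta$n_channels, meta$n_samples),
                    meta$fs, meta$channel_names)
}

#' Serialize a channel order as plain text
#'
#' One line per output row: `rank index name`, auditable with any text tool.
#'
#' @param order A `channel_order`.
#' @param path Output file.
#' @param channel_names Labels to annotate with (default the stored montage).
#' @return The path, invisibly; `read_channel_order()` the integer
#'   permutation.
#' @export
write_channel_order <- function(order, path,
                                channel_names = default_channel_names(length(order$permutation))) {
  stopifnot(inherits(order, "channel_order"))
  lines <- sprintf("%d\t%d\t%s", seq_along(order$permutation),
                   order$permutation, channel_names[order$permutation])
  writeLines(c("# rank\tchannel_index\tchannel_name", lines), path)
  invisible(path)
}

#' @rdname write_channel_order
#' @export
read_channel_order <- function(path) {
  lines <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  as.integer(vapply(strsplit(lines, "\t"), `[[`, character(1), 2))
}

# ---- minimal EDF support ----------------------------------------------------

edf_num <- function(x, width = 8L) {
  s <- formatC(x, format = "g", digits = 7)
  if (nchar(s) > width) s <- formatC(x, format = "g", digits = 4)
  if (nchar(s) > width) stop_invalid("cannot format ", x, " in ", width, " bytes")
  s
}

edf_pad <- function(s, width) {
  s <- substr(s, 1, width)
  formatC(s, width = -width, flag = " ")
}

#' Write a recording as EDF
#'
#' Minimal European Data Format writer: 1 s data records, 16-bit samples.
#' Each channel uses a power-of-ten quantization step (the smallest with
#' `max(|x|) <= 32767 * step`), so the stored physical range is exactly
#' representable in the 8-character header fields and reading inverts
#' writing: values are quantized to `round(x / step) * step`, and data
#' already on that grid round-trip exactly. Used for interoperability; the
#' core pipeline uses [write_recording()].
#'
#' @param rec An `eeg_recording` whose duration is a whole number of seconds
#'   (a trailing fraction is dropped with a warning).
#' @param path Output `.edf` path.
#' @return The path, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  ns <- nrow(rec$data)
  n_rec <- ncol(rec$data) %/% fs
  if (n_rec * fs != ncol(rec$data)) {
    warning("recording is not a whole number of seconds; trailing samples dropped")
  }
  x <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  amax <- pmax(apply(abs(x), 1, max), .Machine$double.eps)
  step <- 10^pmin(pmax(ceiling(log10(amax / 32767)), -5L), 3L)
  pmin <- -32768 * step
  pmax <- 32767 * step
  pmin_s <- vapply(pmin, edf_num, character(1))
  pmax_s <- vapply(pmax, edf_num, character(1))
  con <- file(path, "wb")
  on.exit(close(con))
  put <- function(s, w) writeChar(edf_pad(s, w), con, nchars = w, eos = NULL)
  put("0", 8)
  put(sprintf("S%03d subject", rec$subject_id), 80)
  put(sprintf("condition %s", rec$condition), 80)
  put("01.01.00", 8); put("00.00.00", 8)
  put(as.character(256L * (ns + 1L)), 8)
  put("", 44)
  put(as.character(n_rec), 8)
  put("1", 8)
  put(as.character(ns), 4)
  for (s in rec$channel_names[seq_len(ns)]) put(s, 16)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put("uV", 8)
  for (i in seq_len(ns)) put(pmin_s[i], 8)
  for (i in seq_len(ns)) put(pmax_s[i], 8)
  for (i in seq_len(ns)) put("-32768", 8)
  for (i in seq_len(ns)) put("32767", 8)
  for (i in seq_len(ns)) put("", 80)
  for (i in seq_len(ns)) put(as.character(fs), 8)
  for (i in seq_len(ns)) put("", 32)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * fs + 1L):(r * fs)
    for (i in seq_len(ns)) {
      d <- round(x[i, cols] / step[i])
      writeBin(as.integer(base::pmin(base::pmax(d, -32768), 32767)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' Minimal EDF parser for the 64-channel, 160 Hz baseline-run layout. The
#' subject and condition are taken from the `SxxxRyy` file-naming convention
#' of the public dataset (run 1 = eyes-open REO, run 2 = eyes-closed REC)
#' when the filename matches, else from the arguments.
#'
#' @param path `.edf` file.
#' @param expect_channels Required minimum signal count (default 64; `NULL`
#'   disables the check).
#' @param expect_fs Required sampling rate in Hz (default 160; `NULL`
#'   disables the check).
#' @param subject_id,condition Fallback metadata when the filename does not
#'   follow the convention.
#' @return An `eeg_recording` (first `expect_channels` signals).
#' @export
read_edf <- function(path, expect_channels = 64L, expect_fs = 160L,
                     subject_id = NULL, condition = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  get <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  ver <- get(8)
  if (!identical(ver, "0")) stop_invalid("malformed EDF: version field is '", ver, "'")
  get(80); get(80); get(8); get(8)
  header_bytes <- as.integer(get(8))
  get(44)
  n_rec <- as.integer(get(8))
  rec_dur <- as.numeric(get(8))
  ns <- as.integer(get(4))
  if (is.na(ns) || ns < 1L) stop_invalid("malformed EDF: signal count field")
  if (!is.null(expect_channels) && ns < expect_channels) {
    stop_invalid("channel count: EDF has ", ns, " signals, need >= ",
                 expect_channels)
  }
  labels <- vapply(seq_len(ns), function(i) get(16), character(1))
  for (i in seq_len(ns)) get(80)
  for (i in seq_len(ns)) get(8)
  pmin <- as.numeric(vapply(seq_len(ns), function(i) get(8), character(1)))
  pmax <- as.numeric(vapply(seq_len(ns), function(i) get(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(ns), function(i) get(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(ns), function(i) get(8), character(1)))
  for (i in seq_len(ns)) get(80)
  spr <- as.integer(vapply(seq_len(ns), function(i) get(8), character(1)))
  for (i in seq_len(ns)) get(32)
  if (any(is.na(c(pmin, pmax, dmin, dmax, spr)))) {
    stop_invalid("malformed EDF: unparseable signal header field")
  }
  fs <- spr[1] / rec_dur
  if (!is.null(expect_fs) && abs(fs - expect_fs) > 1e-9) {
    stop_invalid("sampling rate: EDF is ", fs, " Hz, need ", expect_fs, " Hz")
  }
  nch <- if (is.null(expect_channels)) ns else expect_channels
  x <- matrix(0, nch, n_rec * spr[1])
  seek(con, header_bytes)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", n = spr[i], size = 2, endian = "little")
      if (length(d) != spr[i]) stop_invalid("malformed EDF: truncated data record")
      if (i <= nch) {
        cols <- ((r - 1L) * spr[1] + 1L):(r * spr[1])
        x[i, cols] <- (d - dmin[i]) / (dmax[i] - dmin[i]) * (pmax[i] - pmin[i]) + pmin[i]
      }
    }
  }
  m <- regmatches(basename(path), regexec("^S(\\d+)R(\\d+)", basename(path)))[[1]]
  if (length(m) == 3L) {
    subject_id <- as.integer(m[2]) - 1L
    condition <- if (as.integer(m[3]) == 2L) "REC" else "REO"
  }
  new_eeg_recording(subject_id %||% 0L, condition %||% "REO", x,
                    as.integer(round(fs)), labels[seq_len(nch)])
}
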