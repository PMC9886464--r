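# RIFF/WAVE container read/write. Hand-written on readBin/writeBin: the
# toolkit needs PCM and IEEE-float WAV only, multi-channel averaged to mono.

#' Read a WAV file
#'
#' Reads a RIFF/WAVE audio file into a [pcg_signal]. PCM 8/16/24/32-bit and
#' IEEE float 32/64-bit encodings are supported; multi-channel recordings
#' are averaged to mono (clinical recorders occasionally emit stereo). The
#' original sample rate is preserved; use [resample_to()] afterwards.
#'
#' @param path Path to a readable WAV file.
#' @param label Optional class tag attached to the returned signal.
#' @return A mono [pcg_signal] with samples scaled to `[-1, 1]`.
#' @seealso [write_wav()], [resample_to()]
#' @export
read_wav <- function(path, label = NULL) {
  if (!is.character(path) || length(path) != 1L)
    abort_validation("path must be a single file path")
  if (!file.exists(path))
    abort_io("WAV file does not exist: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))

  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF"))
    abort_io("not a RIFF file (bad magic): %s", path)
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size, unused
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE"))
    abort_io("not a WAVE file: %s", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        code       = readBin(body[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        channels   = readBin(body[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        rate       = readBin(body[5:8], "integer", 1, 4, endian = "little"),
        bits       = readBin(body[15:16], "integer", 1, 2, signed = FALSE, endian = "little")
      )
      if (fmt$code == 65534L && size >= 40L)  # WAVE_FORMAT_EXTENSIBLE: subformat GUID
        fmt$code <- readBin(body[25:26], "integer", 1, 2, signed = FALSE, endian = "little")
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      seek(con, size + size %% 2, origin = "current")
      next
    }
    if (size %% 2 == 1) readBin(con, "raw", 1)
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt)) abort_io("corrupt WAV (no fmt chunk): %s", path)
  if (is.null(data_raw) || length(data_raw) == 0L)
    abort_validation("zero-length audio in %s", path)

  x <- decode_wav_samples(data_raw, fmt, path)
  if (fmt$channels > 1L) {
    n <- floor(length(x) / fmt$channels)
    x <- rowMeans(matrix(x[seq_len(n * fmt$channels)], ncol = fmt$channels, byrow = TRUE))
  }
  if (length(x) == 0L) abort_validation("zero-length audio in %s", path)
  pcg_signal(x, fmt$rate, label)
}

decode_wav_samples <- function(raw, fmt, path) {
  n <- length(raw)
  if (fmt$code == 1L) {            # integer PCM
    if (fmt$bits == 16L) {
      readBin(raw, "integer", n / 2, 2, signed = TRUE, endian = "little") / 32768
    } else if (fmt$bits == 8L) {   # 8-bit PCM is unsigned
      (readBin(raw, "integer", n, 1, signed = FALSE) - 128) / 128
    } else if (fmt$bits == 24L) {
      b <- as.integer(raw)
      i <- seq(1, n - 2, by = 3)
      v <- b[i] + 256 * b[i + 1] + 65536 * b[i + 2]
      v <- ifelse(v >= 8388608, v - 16777216, v)
      v / 8388608
    } else if (fmt$bits == 32L) {
      readBin(raw, "integer", n / 4, 4, endian = "little") / 2147483648
    } else {
      abort_io("unsupported PCM bit depth %d in %s", fmt$bits, path)
    }
  } else if (fmt$code == 3L) {     # IEEE float
    if (fmt$bits == 32L) {
      readBin(raw, "double", n / 4, 4, endian = "little")
    } else if (fmt$bits == 64L) {
      readBin(raw, "double", n / 8, 8, endian = "little")
    } else {
      abort_io("unsupported float bit depth %d in %s", fmt$bits, path)
    }
  } else {
    abort_io("unsupported WAV format code %d in %s", fmt$code, path)
  }
}

#' Write a WAV file
#'
#' Writes a mono [pcg_signal] as a canonical RIFF/WAVE file. `pcm16` output
#' clamps to `[-1, 32767/32768]` and rounds to the nearest 16-bit level;
#' a signal read from a PCM16 file round-trips sample-identically.
#'
#' @param signal A [pcg_signal].
#' @param path Output file path (parent directory must exist or be creatable).
#' @param bit_depth `"pcm16"` (default) or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, bit_depth = c("pcm16", "float32")) {
  stopifnot(inherits(signal, "pcg_signal"))
  bit_depth <- match.arg(bit_depth)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) abort_io("cannot open for writing: %s", path))
  on.exit(close(con))

  x <- signal$samples
  n <- length(x)
  rate <- as.integer(round(signal$rate))
  if (bit_depth == "pcm16") {
    code <- 1L; bits <- 16L
    pcm <- as.integer(pmin(pmax(round(x * 32768), -32768), 32767))
    data_size <- 2L * n
  } else {
    code <- 3L; bits <- 32L
    data_size <- 4L * n
  }
  block <- as.integer(bits / 8)

  writeChar("RIFF", con, 4, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, 4, eos = NULL)
  writeChar("fmt ", con, 4, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  writeBin(code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little")                  # channels
  writeBin(rate, con, 4, endian = "little")
  writeBin(as.integer(rate * block), con, 4, endian = "little")
  writeBin(block, con, 2, endian = "little")
  writeBin(bits, con, 2, endian = "little")
  writeChar("data", con, 4, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bit_depth == "pcm16") {
    writeBin(pcm, con, 2, endian = "little")
  } else {
    writeBin(as.double(x), con, 4, endian = "little")
  }
  invisible(path)
}

#' Read or write a labeled-dataset manifest
#'
#' The sidecar manifest is a CSV with columns `filename`, `label`, `rate`,
#' `duration` describing a folder of labeled recordings.
#'
#' @param path Manifest CSV path.
#' @return `read_manifest()` returns a data.frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort_io("manifest does not exist: %s", path)
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("filename", "label", "rate", "duration")
  if (!all(need %in% names(m)))
    abort_validation("manifest must have columns %s", paste(need, collapse = ", "))
  m
}

#' @rdname read_manifest
#' @param manifest Data.frame with the manifest columns.
#' @export
write_manifest <- function(manifest, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
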