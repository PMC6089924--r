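# Minimal RIFF/WAVE reader and writer. Supports the encodings used for
# acoustic-emission recordings: PCM 16-bit, PCM 24-bit and IEEE float32,
# mono or stereo (stereo is averaged to mono on read).

#' Read a WAV recording
#'
#' Reads a RIFF/WAVE file (PCM16, PCM24 or float32; 1 or 2 channels) into an
#' [audio_recording()]. Stereo files are averaged to mono (a single proximal
#' microphone makes channel identity irrelevant); integer samples are scaled
#' to `[-1, 1]` by the format's full-scale value.
#'
#' @param path WAV file path.
#' @param label optional ground-truth label stored on the recording.
#' @param annotations optional path to a sidecar annotations CSV
#'   (columns `event_type`, `time_s`) or a named numeric vector of times.
#' @return an [audio_recording()].
#' @export
read_wav <- function(path, label = "unknown", annotations = NULL) {
  if (!file.exists(path)) stop("WAV file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 4, useBytes = TRUE)
  if (!identical(hdr, "RIFF")) stop("not a RIFF file: ", path, call. = FALSE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a WAVE file: ", path, call. = FALSE)

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", sz)
      fmt <- list(
        audio_format = readBin(raw[1:2], "integer", 1, 2, signed = FALSE, endian = "little"),
        n_channels   = readBin(raw[3:4], "integer", 1, 2, signed = FALSE, endian = "little"),
        sample_rate  = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits         = readBin(raw[15:16], "integer", 1, 2, signed = FALSE, endian = "little"))
    } else if (id == "data") {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1))  # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw))
    stop("malformed WAV: missing fmt or data chunk in ", path, call. = FALSE)
  if (!fmt$audio_format %in% c(1L, 3L))
    stop("unsupported WAV encoding (format tag ", fmt$audio_format,
         "); only PCM and IEEE float are supported", call. = FALSE)

  if (fmt$audio_format == 3L) {
    if (fmt$bits != 32L) stop("unsupported float WAV bit depth: ", fmt$bits, call. = FALSE)
    x <- readBin(data_raw, "double", length(data_raw) / 4, size = 4, endian = "little")
  } else if (fmt$bits == 16L) {
    x <- readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
                 signed = TRUE, endian = "little") / 32767
  } else if (fmt$bits == 24L) {
    n <- length(data_raw) / 3
    b <- matrix(as.integer(data_raw), nrow = 3)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v <- ifelse(v >= 2^23, v - 2^24, v)
    x <- v / (2^23 - 1)
  } else {
    stop("unsupported PCM bit depth: ", fmt$bits, call. = FALSE)
  }

  if (fmt$n_channels > 1L) {
    x <- matrix(x, nrow = fmt$n_channels)
    x <- colMeans(x)
  }
  ann <- NULL
  if (!is.null(annotations)) {
    ann <- if (is.character(annotations)) read_annotations(annotations) else annotations
  }
  audio_recording(x, fmt$sample_rate, label = label, annotations = ann)
}

#' Write a WAV recording
#'
#' @param rec an [audio_recording()].
#' @param path output file path.
#' @param bits `16` (PCM) or `32` (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(rec, path, bits = 16) {
  stopifnot(inherits(rec, "audio_recording"))
  x <- rec$samples
  con <- file(path, "wb")
  on.exit(close(con))
  if (bits == 16) {
    fmt_tag <- 1L; bps <- 2L
    pcm <- as.integer(round(pmin(pmax(x, -1), 1) * 32767))
    data_size <- 2L * length(pcm)
  } else if (bits == 32) {
    fmt_tag <- 3L; bps <- 4L
    data_size <- 4L * length(x)
  } else stop("`bits` must be 16 or 32", call. = FALSE)

  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(fmt_tag, con, size = 2, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")                    # mono
  writeBin(as.integer(rec$fs), con, size = 4, endian = "little")
  writeBin(as.integer(rec$fs * bps), con, size = 4, endian = "little")
  writeBin(bps, con, size = 2, endian = "little")                   # block align
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, size = 4, endian = "little")
  if (bits == 16) writeBin(pcm, con, size = 2, endian = "little")
  else writeBin(x, con, size = 4, endian = "little")
  invisible(path)
}
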