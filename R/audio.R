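#' Audio recording container
#'
#' Holds a mono acoustic-emission waveform together with its sampling
#' frequency, an optional ground-truth label and optional event-time
#' annotations. All downstream operations (`decimate_audio()`,
#' [bandpass_butterworth()], [fit_tvar()], ...) consume and return this class.
#'
#' @param samples numeric vector of finite amplitudes, nominally in `[-1, 1]`.
#' @param fs sampling frequency in Hz (positive scalar).
#' @param label optional character tag, one of `"perforation"`, `"friction"`,
#'   `"bump"`, `"needle"`, `"unknown"`.
#' @param annotations optional named numeric vector of ground-truth event
#'   times in seconds (e.g. `c(t_in = 3, t_out = 8)`); must lie within the
#'   recording duration.
#' @return an object of class `audio_recording` with fields `samples`, `fs`,
#'   `label`, `annotations`.
#' @examples
#' rec <- audio_recording(sin(2 * pi * 440 * seq(0, 1, by = 1 / 8000)), fs = 8000)
#' duration(rec)
#' @export
audio_recording <- function(samples, fs, label = "unknown", annotations = NULL) {
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a positive finite scalar (Hz)", call. = FALSE)
  if (anyNA(samples) || !all(is.finite(samples)))
    stop("`samples` must be finite and free of NA", call. = FALSE)
  dur <- length(samples) / fs
  if (!is.null(annotations)) {
    annotations <- unlist(annotations)
    if (any(annotations < 0 | annotations > dur))
      stop("annotations must lie within [0, duration]", call. = FALSE)
  }
  structure(list(samples = samples, fs = fs, label = label,
                 annotations = annotations),
            class = "audio_recording")
}

#' @rdname audio_recording
#' @param rec an `audio_recording`.
#' @export
duration <- function(rec) length(rec$samples) / rec$fs

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording> %d samples @ %g Hz (%.3f s), label '%s'\n",
              length(x$samples), x$fs, duration(x), x$label))
  if (!is.null(x$annotations))
    cat("  annotations:", paste(sprintf("%s=%.3fs", names(x$annotations),
                                        x$annotations), collapse = ", "), "\n")
  invisible(x)
}

#' Decimate a recording
#'
#' Anti-alias filtered downsampling by an integer factor: a zero-phase
#' (forward-backward) order-8 Chebyshev type-I low-pass with cutoff at 80% of
#' the new Nyquist frequency, followed by subsampling. Zero-phase filtering
#' keeps event times unbiased.
#'
#' @param rec an [audio_recording()].
#' @param factor integer downsampling factor, `>= 1`.
#' @return an `audio_recording` with `fs = rec$fs / factor` and
#'   `ceiling(n / factor)` samples; annotations carried through unchanged.
#' @export
decimate_audio <- function(rec, factor) {
  stopifnot(inherits(rec, "audio_recording"))
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor))
    stop("`factor` must be an integer >= 1", call. = FALSE)
  factor <- as.integer(factor)
  if (factor == 1L) return(rec)
  fil <- signal::cheby1(8, 0.05, 0.8 / factor)
  y <- cpp_filtfilt(fil$b, fil$a, rec$samples)
  y <- y[seq(1L, length(y), by = factor)]
  audio_recording(y, rec$fs / factor, label = rec$label,
                  annotations = rec$annotations)
}

#' Read or write event annotations as a sidecar CSV
#'
#' The sidecar format has columns `event_type` and `time_s`.
#'
#' @param path CSV file path.
#' @return `read_annotations()` returns a named numeric vector of event times.
#' @export
read_annotations <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("event_type", "time_s") %in% names(d)))
  stats::setNames(as.numeric(d$time_s), d$event_type)
}

#' @rdname read_annotations
#' @param annotations named numeric vector of event times in seconds.
#' @export
write_annotations <- function(annotations, path) {
  write.csv(data.frame(event_type = names(annotations),
                       time_s = as.numeric(annotations)),
            path, row.names = FALSE)
  invisible(path)
}
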