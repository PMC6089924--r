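#' TV-AR analysis configuration
#'
#' Sliding-window settings for the time-varying autoregressive fit. Two
#' presets reproduce the published settings: `"needle"` (window 110 ms,
#' overlap 50%, order 30) and `"guidewire"` (window 50 ms, overlap 95%,
#' order 20).
#'
#' @param preset `"needle"`, `"guidewire"`, or `NULL` to set fields manually.
#' @param window_ms window width in milliseconds.
#' @param overlap overlap fraction in `[0, 1)`.
#' @param order AR model order `p`.
#' @return an object of class `tvar_config`.
#' @examples
#' tvar_config("needle")
#' @export
tvar_config <- function(preset = NULL, window_ms = NULL, overlap = NULL,
                        order = NULL) {
  def <- switch(preset %||% "none",
    needle    = list(window_ms = 110, overlap = 0.50, order = 30),
    guidewire = list(window_ms = 50,  overlap = 0.95, order = 20),
    none      = list(window_ms = window_ms, overlap = overlap, order = order),
    stop("unknown preset: ", preset, call. = FALSE))
  cfg <- list(window_ms = window_ms %||% def$window_ms,
              overlap   = overlap   %||% def$overlap,
              order     = order     %||% def$order,
              preset    = preset %||% "custom")
  if (is.null(cfg$window_ms) || is.null(cfg$overlap) || is.null(cfg$order))
    stop("window_ms, overlap and order must all be set", call. = FALSE)
  if (cfg$overlap < 0 || cfg$overlap >= 1)
    stop("overlap must be in [0, 1)", call. = FALSE)
  structure(cfg, class = "tvar_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tvar_config <- function(x, ...) {
  cat(sprintf("<tvar_config> %s: window %g ms, overlap %g%%, order %d\n",
              x$preset, x$window_ms, 100 * x$overlap, x$order))
  invisible(x)
}

#' Fit a sliding-window time-varying AR model
#'
#' Estimates, for each window, AR coefficients `a_k(n)` of the time-dependent
#' all-pole transfer function `H(z, n) = 1 / (1 + sum_k a_k(n) z^-k)` and the
#' innovation variance `sigma^2(n)`, using the Yule-Walker method with the
#' biased autocovariance estimator (which guarantees all poles strictly
#' inside the unit circle). Each window is demeaned before fitting; window
#' timestamps are at window centers and the hop is `window * (1 - overlap)`
#' rounded to integer samples.
#'
#' @param rec an [audio_recording()].
#' @param cfg a [tvar_config()].
#' @return an object of class `tvar_model` with fields `coeffs` (`p x W`
#'   matrix), `sigma2`, `times` (window centers, s), `fs`, `window_s`,
#'   `hop_s`, `ok` (logical per-window fit flag).
#' @export
fit_tvar <- function(rec, cfg) {
  stopifnot(inherits(rec, "audio_recording"), inherits(cfg, "tvar_config"))
  nw <- round(cfg$window_ms * rec$fs / 1000)
  hop <- max(1L, round(nw * (1 - cfg$overlap)))
  n <- length(rec$samples)
  if (n < nw) stop("recording shorter than one analysis window", call. = FALSE)
  if (cfg$order >= nw)
    stop("AR order must be smaller than the window sample count", call. = FALSE)
  starts <- seq(0L, n - nw, by = hop)              # 0-based for the C++ core
  fit <- cpp_sliding_yw(rec$samples, starts, as.integer(nw),
                        as.integer(cfg$order))
  structure(list(coeffs = fit$coeffs, sigma2 = as.numeric(fit$sigma2),
                 times = (starts + (nw - 1) / 2) / rec$fs,
                 fs = rec$fs, window_s = nw / rec$fs, hop_s = hop / rec$fs,
                 ok = as.logical(fit$ok), order = as.integer(cfg$order)),
            class = "tvar_model")
}

#' @export
print.tvar_model <- function(x, ...) {
  cat(sprintf("<tvar_model> order %d, %d windows (%.1f ms window, %.1f ms hop) @ %g Hz\n",
              x$order, length(x$times), 1000 * x$window_s, 1000 * x$hop_s, x$fs))
  invisible(x)
}

#' Time-varying AR spectrum
#'
#' Evaluates the per-window parametric power spectral density
#' `S_AR(f, n) = sigma^2(n) / |1 + sum_k a_k(n) exp(-i 2 pi f k / fs)|^2`
#' on `n_freq` equispaced bins spanning `[0, fs/2]`.
#'
#' @param model a [fit_tvar()] result.
#' @param n_freq number of frequency bins (`>= 2`).
#' @return an object of class `tv_spectrum`: `S` (`n_freq x W`, strictly
#'   positive for non-degenerate windows), `freqs`, `times`, and
#'   `mean_over_f` (the frequency-averaged spectrum per window).
#' @export
tvar_spectrum <- function(model, n_freq = 128) {
  stopifnot(inherits(model, "tvar_model"))
  if (n_freq < 2) stop("n_freq must be >= 2", call. = FALSE)
  freqs <- seq(0, model$fs / 2, length.out = n_freq)
  p <- nrow(model$coeffs)
  if (p == 0L) {
    S <- matrix(rep(model$sigma2, each = n_freq), nrow = n_freq)
  } else {
    E <- exp(-2i * pi * outer(freqs, seq_len(p)) / model$fs)
    denom <- 1 + E %*% model$coeffs
    S <- sweep(1 / (Mod(denom)^2), 2, model$sigma2, `*`)
  }
  structure(list(S = S, freqs = freqs, times = model$times,
                 mean_over_f = colMeans(S)),
            class = "tv_spectrum")
}

#' @export
print.tv_spectrum <- function(x, ...) {
  cat(sprintf("<tv_spectrum> %d frequency bins x %d windows, %g-%g Hz\n",
              nrow(x$S), ncol(x$S), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Per-window AR poles
#'
#' Finds the `p` roots of the AR characteristic polynomial
#' `1 + sum_k a_k(n) z^-k` for every window. Real signals yield root sets
#' closed under complex conjugation.
#'
#' @param model a [fit_tvar()] result.
#' @return an object of class `pole_track` with `poles` (`p x W` complex
#'   matrix), plus slots filled by [resonant_frequencies()] and
#'   [pole_powers()].
#' @export
tvar_poles <- function(model) {
  stopifnot(inherits(model, "tvar_model"))
  z <- cpp_ar_roots(model$coeffs)
  flagged <- colSums(is.na(Re(z))) > 0
  structure(list(poles = z, angles = Arg(z), res_freqs = NULL,
                 residues = NULL, powers = NULL,
                 times = model$times, fs = model$fs, hop_s = model$hop_s,
                 flagged = flagged | !model$ok),
            class = "pole_track")
}

#' @export
print.pole_track <- function(x, ...) {
  cat(sprintf("<pole_track> %d poles x %d windows @ %g Hz%s\n",
              nrow(x$poles), ncol(x$poles), x$fs,
              if (!is.null(x$powers)) " (residue powers computed)" else ""))
  invisible(x)
}

#' Resonant frequencies from pole phase angles
#'
#' Each pole with strictly positive imaginary part maps to a resonant
#' frequency `f_k(n) = theta_k(n) * fs / (2 pi)`. Real-axis poles model
#' trends, not resonances, and are excluded (their `res_freqs` entry is NA).
#'
#' @param track a [tvar_poles()] result.
#' @param fs sampling frequency in Hz; defaults to the track's own.
#' @return the `pole_track` with `res_freqs` filled (`p x W`, NA for
#'   lower-half-plane and real poles).
#' @export
resonant_frequencies <- function(track, fs = track$fs) {
  stopifnot(inherits(track, "pole_track"))
  f <- Arg(track$poles) * fs / (2 * pi)
  f[!(Im(track$poles) > 1e-12)] <- NA_real_
  track$res_freqs <- f
  track
}

#' Residue-based pole powers
#'
#' Computes, per window, the residue of the factored transfer function at
#' each pole, `r_k = 1 / prod_{j != k} (1 - z_j / z_k)`, and the spectral
#' power `P_k(n) = 2 sigma^2(n) Re(r_k(n))`. Powers are used only to rank
#' poles when selecting the maximal-energy pole. Near-coincident poles are
#' perturbed by 1e-8 before the residue product.
#'
#' @param model the [fit_tvar()] result the poles came from.
#' @param track a [resonant_frequencies()] result.
#' @return the `pole_track` with `residues` and `powers` filled.
#' @export
pole_powers <- function(model, track) {
  stopifnot(inherits(model, "tvar_model"), inherits(track, "pole_track"))
  if (is.null(track$res_freqs))
    track <- resonant_frequencies(track)
  res <- cpp_residues(track$poles)
  track$residues <- res
  track$powers <- sweep(2 * Re(res), 2, model$sigma2, `*`)
  track$flagged <- track$flagged | colSums(is.na(Re(res))) > 0
  track
}

#' Track the time-varying maximal energy pole (TV-MEP)
#'
#' For each window, the TV-MEP is the resonant frequency of the
#' upper-half-plane pole with the maximal residue power; ties are broken
#' toward the lower frequency. Windows without any upper-half-plane pole
#' carry the previous value forward and are flagged.
#'
#' @param model a [fit_tvar()] result (poles, resonant frequencies and
#'   powers are computed internally).
#' @return an object of class `mep_track`: `values` (Hz), `times` (s),
#'   `hop_s`, `window_s`, `fs`, `flagged`.
#' @export
mep_track <- function(model) {
  stopifnot(inherits(model, "tvar_model"))
  track <- pole_powers(model, resonant_frequencies(tvar_poles(model)))
  sel <- cpp_mep_select(track$res_freqs, track$powers)
  vals <- as.numeric(sel$values)
  flag <- as.logical(sel$flagged)
  # windows flagged before any valid value: backfill with first valid
  if (anyNA(vals)) {
    first_ok <- which(!is.na(vals))[1]
    if (is.na(first_ok)) stop("no window produced a resonant pole", call. = FALSE)
    vals[seq_len(first_ok - 1)] <- vals[first_ok]
  }
  new_mep_track(vals, model$times, hop_s = model$hop_s,
                window_s = model$window_s, fs = model$fs,
                flagged = flag | track$flagged)
}

new_mep_track <- function(values, times, hop_s = NULL, window_s = NULL,
                          fs = NULL, flagged = NULL) {
  if (is.null(hop_s)) hop_s <- if (length(times) > 1) median(diff(times)) else 1
  structure(list(values = as.numeric(values), times = as.numeric(times),
                 hop_s = hop_s, window_s = window_s, fs = fs,
                 flagged = flagged %||% logical(length(values))),
            class = "mep_track")
}

#' Build a TV-MEP track from raw values
#'
#' Constructor for externally computed or simulated maximal-energy-pole
#' tracks (e.g. imported from CSV); mainly useful for testing detectors in
#' isolation.
#'
#' @param values MEP values in Hz.
#' @param times window-center times in seconds (equispaced).
#' @return an object of class `mep_track`.
#' @export
as_mep_track <- function(values, times) new_mep_track(values, times)

#' @export
print.mep_track <- function(x, ...) {
  cat(sprintf("<mep_track> %d windows, hop %.1f ms, median %.0f Hz\n",
              length(x$values), 1000 * x$hop_s, median(x$values)))
  invisible(x)
}

#' @export
as.data.frame.mep_track <- function(x, ...) {
  data.frame(time_s = x$times, value = x$values)
}

#' Export a TV-MEP track as CSV
#'
#' @param mep an `mep_track`.
#' @param path output CSV path (columns `time_s`, `value`).
#' @export
write_mep_csv <- function(mep, path) {
  write.csv(as.data.frame(mep), path, row.names = FALSE)
  invisible(path)
}

#' Export a TV-AR spectrum as dense matrix text
#'
#' Writes a tab-separated table: first column the frequency grid in Hz,
#' remaining columns one spectrum per window, headed by the window-center
#' times in seconds.
#'
#' @param spec a [tvar_spectrum()] result.
#' @param path output file path.
#' @export
write_spectrum_txt <- function(spec, path) {
  stopifnot(inherits(spec, "tv_spectrum"))
  m <- cbind(freq_hz = spec$freqs, spec$S)
  colnames(m) <- c("freq_hz", sprintf("t%.6f", spec$times))
  utils::write.table(m, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
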