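#' Band-limiting filter specification
#'
#' Describes either a Butterworth band-pass (used for the needle pipeline)
#' or a Daubechies wavelet-scale reconstruction (used for the guide-wire
#' pipeline, whose events are more transient).
#'
#' @param kind `"butterworth"` or `"dwt"`.
#' @param low_hz,high_hz band edges in Hz (Butterworth).
#' @param order Butterworth prototype order per pass (applied
#'   forward-backward, so the effective attenuation is doubled).
#' @param wavelet_family wavelet name; only the Daubechies family is
#'   provided, `"db4"` by default.
#' @param n_levels decomposition depth (DWT).
#' @param keep_levels integer detail levels retained on reconstruction;
#'   all other detail bands and the final approximation are zeroed.
#' @param keep_approx logical; retain the level-`n_levels` approximation
#'   (default `FALSE`: the approximation carries baseline drift).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(kind = c("butterworth", "dwt"),
                        low_hz = NULL, high_hz = NULL, order = 7,
                        wavelet_family = "db4", n_levels = 10,
                        keep_levels = 2:6, keep_approx = FALSE) {
  kind <- match.arg(kind)
  if (kind == "butterworth") {
    if (is.null(low_hz) || is.null(high_hz) || !(0 < low_hz && low_hz < high_hz))
      stop("butterworth spec needs 0 < low_hz < high_hz", call. = FALSE)
  } else {
    if (!all(keep_levels %in% seq_len(n_levels)))
      stop("keep_levels must be a subset of 1..n_levels", call. = FALSE)
  }
  structure(list(kind = kind, low_hz = low_hz, high_hz = high_hz,
                 order = order, wavelet_family = wavelet_family,
                 n_levels = n_levels, keep_levels = keep_levels,
                 keep_approx = keep_approx),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  if (x$kind == "butterworth")
    cat(sprintf("<filter_spec> Butterworth order %d, band %g-%g Hz (zero-phase)\n",
                x$order, x$low_hz, x$high_hz))
  else
    cat(sprintf("<filter_spec> %s DWT, %d levels, keep details {%s}%s\n",
                x$wavelet_family, x$n_levels,
                paste(x$keep_levels, collapse = ","),
                if (x$keep_approx) " + approximation" else ""))
  invisible(x)
}

#' Zero-phase Butterworth band-pass
#'
#' Applies the band-pass forward and backward (`signal::filtfilt`) so that
#' detected event times are not biased by group delay.
#'
#' @param rec an [audio_recording()].
#' @param spec a [filter_spec()] with `kind = "butterworth"`.
#' @return a filtered `audio_recording` with unchanged length and `fs`.
#' @export
bandpass_butterworth <- function(rec, spec) {
  stopifnot(inherits(rec, "audio_recording"), inherits(spec, "filter_spec"))
  if (spec$kind != "butterworth") stop("spec$kind must be 'butterworth'", call. = FALSE)
  nyq <- rec$fs / 2
  if (spec$high_hz >= nyq)
    stop(sprintf("band edge %g Hz >= Nyquist %g Hz", spec$high_hz, nyq), call. = FALSE)
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / nyq, type = "pass")
  y <- cpp_filtfilt(bf$b, bf$a, rec$samples)
  audio_recording(y, rec$fs, label = rec$label, annotations = rec$annotations)
}

# ---- periodized orthogonal DWT (Daubechies family, hardcoded db filters) ----

db_filters <- function(family) {
  # analysis low-pass coefficients (orthonormal); high-pass by QMF relation
  dec_lo <- switch(family,
    db2 = c(-0.12940952255092145, 0.22414386804185735,
            0.836516303737469, 0.48296291314469025),
    db4 = c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
            -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
            0.7148465705529157, 0.2303778133088965),
    db8 = c(-0.00011747678400228192, 0.0006754494059985568, -0.0003917403729959771,
            -0.00487035299301066, 0.008746094047015655, 0.013981027917015516,
            -0.04408825393106472, -0.01736930100202211, 0.128747426620186,
            0.00047248457399797254, -0.2840155429624281, -0.015829105256023893,
            0.5853546836548691, 0.6756307362980128, 0.3128715909144659,
            0.05441584224308161),
    stop("unsupported wavelet family: ", family, call. = FALSE))
  L <- length(dec_lo)
  dec_hi <- rev(dec_lo) * (-1)^(seq_len(L) - 1)
  list(lo = dec_lo, hi = dec_hi, L = L)
}

# One analysis step with periodic extension. Returns list(a, d), each of
# length N/2 (N even). Row k of the analysis operator is the filter placed
# at circular offset 2k; orthonormality of the Daubechies filters makes the
# adjoint an exact inverse.
dwt_step <- function(x, fil) {
  N <- length(x)
  # circular access handled by extending the signal by the filter length
  xe <- c(x, x[seq_len(fil$L)])
  half <- N / 2
  idx <- 2 * (seq_len(half) - 1L) + 1L
  a <- numeric(half); d <- numeric(half)
  for (m in seq_len(fil$L)) {
    xi <- xe[idx + (m - 1L)]
    a <- a + fil$lo[m] * xi
    d <- d + fil$hi[m] * xi
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d, fil) {
  half <- length(a)
  N <- 2L * half
  xe <- numeric(N + fil$L)
  idx <- 2 * (seq_len(half) - 1L) + 1L
  for (m in seq_len(fil$L)) {
    pos <- idx + (m - 1L)
    xe[pos] <- xe[pos] + fil$lo[m] * a + fil$hi[m] * d
  }
  # fold the overhang back onto the periodic start
  x <- xe[seq_len(N)]
  x[seq_len(fil$L)] <- x[seq_len(fil$L)] + xe[N + seq_len(fil$L)]
  x
}

# Multi-level periodized DWT. Pads with zeros to a multiple of 2^n_levels;
# the original length is stored so reconstruction can trim exactly.
dwt_forward <- function(x, family, n_levels) {
  fil <- db_filters(family)
  n0 <- length(x)
  block <- 2^n_levels
  if (n0 < block) stop("signal too short for ", n_levels, " DWT levels", call. = FALSE)
  npad <- ceiling(n0 / block) * block
  if (npad > n0) x <- c(x, numeric(npad - n0))
  details <- vector("list", n_levels)
  a <- x
  for (j in seq_len(n_levels)) {
    st <- dwt_step(a, fil)
    details[[j]] <- st$d
    a <- st$a
  }
  list(approx = a, details = details, n0 = n0, family = family)
}

dwt_inverse <- function(dec) {
  fil <- db_filters(dec$family)
  a <- dec$approx
  for (j in rev(seq_along(dec$details))) {
    a <- idwt_step(a, dec$details[[j]], fil)
  }
  a[seq_len(dec$n0)]
}

#' Wavelet-scale band reconstruction
#'
#' Decomposes the signal into `n_levels` Daubechies wavelet scales
#' (periodized orthogonal DWT) and reconstructs using only the detail levels
#' in `keep_levels`; every other coefficient set (including the approximation
#' unless `keep_approx`) is zeroed. Detail level `j` covers roughly
#' `fs/2^(j+1)` to `fs/2^j` Hz, so keeping mid levels removes both
#' high-frequency noise and baseline drift.
#'
#' @param rec an [audio_recording()].
#' @param spec a [filter_spec()] with `kind = "dwt"`.
#' @return a filtered `audio_recording` of identical length and `fs`.
#' @export
dwt_band_reconstruct <- function(rec, spec) {
  stopifnot(inherits(rec, "audio_recording"), inherits(spec, "filter_spec"))
  if (spec$kind != "dwt") stop("spec$kind must be 'dwt'", call. = FALSE)
  dec <- dwt_forward(rec$samples, spec$wavelet_family, spec$n_levels)
  for (j in seq_len(spec$n_levels)) {
    if (!(j %in% spec$keep_levels)) dec$details[[j]][] <- 0
  }
  if (!spec$keep_approx) dec$approx[] <- 0
  audio_recording(dwt_inverse(dec), rec$fs, label = rec$label,
                  annotations = rec$annotations)
}
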