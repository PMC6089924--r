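# Shared fixtures. Expensive corpus-level computations are cached per
# session so several test files can reuse the same runs.

.aemid_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .aemid_cache)) {
    assign(key, force(expr), envir = .aemid_cache)
  }
  get(key, envir = .aemid_cache)
}

tone_recording <- function(freq_hz, fs = 44100, dur_s = 1, noise_sd = 0) {
  t <- seq(0, dur_s - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * freq_hz * t)
  if (noise_sd > 0) x <- x + rnorm(length(x), sd = noise_sd)
  audio_recording(x / max(abs(x)), fs)
}

fft_peak_hz <- function(rec) {
  n <- length(rec$samples)
  sp <- Mod(stats::fft(rec$samples))[seq_len(floor(n / 2))]
  (which.max(sp) - 1) * rec$fs / n
}

# polynomial product in ascending powers (complex-safe)
polymul <- function(p, q) {
  r <- rep(0i, length(p) + length(q) - 1)
  for (i in seq_along(p)) {
    idx <- i:(i + length(q) - 1)
    r[idx] <- r[idx] + p[i] * q
  }
  r
}

poly_from_roots <- function(zs) {
  p <- 1 + 0i
  for (zk in zs) p <- polymul(p, c(1, -zk))
  p
}

# a tvar_model built directly from known coefficients (single window)
manual_model <- function(a, sigma2 = 1, fs = 1000) {
  structure(list(coeffs = matrix(a, ncol = 1), sigma2 = sigma2,
                 times = 0, fs = fs, window_s = 0.1, hop_s = 0.05,
                 ok = TRUE, order = length(a)),
            class = "tvar_model")
}

# full guide-wire benchmark, cached by seed (used by acceptance and
# pipeline tests)
benchmark_cached <- function(seed) {
  cached(paste0("benchmark_", seed), guidewire_benchmark(seed = seed))
}
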