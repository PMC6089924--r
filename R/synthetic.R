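# Synthetic acoustic-emission generators. Events are modelled as white noise
# driven through time-varying two-pole resonators, so the dominant pole of
# every generated recording is analytically known and TV-AR recovery can be
# checked against ground truth.

#' Needle insertion simulation spec
#'
#' Describes a synthetic needle recording: broadband background noise plus a
#' noise-driven single resonance whose center frequency switches from
#' `base_resonance_hz` to `tissue_resonance_hz` at `t_in` and back at
#' `t_out`, emulating the dominant-resonance shift the TV-MEP tracks during
#' tissue passage.
#'
#' @param duration_s recording length in seconds.
#' @param fs sampling frequency in Hz (44100, the acquisition rate).
#' @param t_in,t_out true tissue entry/exit times in seconds.
#' @param base_resonance_hz,tissue_resonance_hz dominant resonance outside /
#'   inside the tissue, in Hz (defaults 3500 and 5000, inside the 3-6 kHz
#'   analysis band).
#' @param snr_db event-to-background power ratio in dB (default 10).
#' @param seed integer RNG seed; generation is deterministic given the seed.
#' @return an object of class `needle_sim_spec`.
#' @export
needle_sim_spec <- function(duration_s = 10, fs = 44100, t_in = 3, t_out = 8,
                            base_resonance_hz = 3500,
                            tissue_resonance_hz = 5000,
                            snr_db = 10, seed = 1L) {
  if (!(0 < t_in && t_in < t_out && t_out < duration_s))
    stop("need 0 < t_in < t_out < duration_s", call. = FALSE)
  if (max(base_resonance_hz, tissue_resonance_hz) >= fs / 2)
    stop("resonances must lie below Nyquist", call. = FALSE)
  structure(as.list(environment()), class = "needle_sim_spec")
}

#' Guide-wire event simulation spec
#'
#' Describes a synthetic guide-wire recording containing one event on a
#' broadband background:
#' * `perforation`: a resonator whose center frequency rises by
#'   `overshoot_height_hz` over `overshoot_width_s` (trapezoidal pulse) and
#'   then settles on a stable plateau at `plateau_freq_hz` with small jitter;
#' * `friction`: the resonance follows a bounded random walk
#'   (time-dispersed frequencies, no overshoot);
#' * `bump`: a brief broadband burst (50-200 ms).
#'
#' @param duration_s recording length in seconds (default 15: several
#'   seconds of idle background, a few-second event, an idle tail).
#' @param fs sampling frequency in Hz.
#' @param event_kind `"perforation"`, `"friction"` or `"bump"`.
#' @param t_on,t_off event start/end in seconds (bump requires
#'   `t_off - t_on <= 0.2`).
#' @param overshoot_height_hz,overshoot_width_s perforation overshoot height
#'   and width.
#' @param plateau_freq_hz post-overshoot plateau frequency.
#' @param plateau_jitter_hz plateau jitter standard deviation.
#' @param snr_db event-to-background power ratio in dB.
#' @param seed integer RNG seed.
#' @return an object of class `guidewire_sim_spec`.
#' @export
guidewire_sim_spec <- function(duration_s = 15, fs = 44100,
                               event_kind = c("perforation", "friction", "bump"),
                               t_on = 7, t_off = 10.5,
                               overshoot_height_hz = 1500,
                               overshoot_width_s = 0.3,
                               plateau_freq_hz = 800,
                               plateau_jitter_hz = 20,
                               snr_db = 10, seed = 1L) {
  event_kind <- match.arg(event_kind)
  if (!(0 < t_on && t_on < t_off && t_off <= duration_s))
    stop("need 0 < t_on < t_off <= duration_s", call. = FALSE)
  if (event_kind == "bump" && t_off - t_on > 0.2)
    stop("bump events must last at most 0.2 s", call. = FALSE)
  if (event_kind == "perforation" && overshoot_height_hz <= 0)
    stop("perforation requires overshoot_height_hz > 0", call. = FALSE)
  if (plateau_freq_hz + overshoot_height_hz >= fs / 2)
    stop("resonance excursion must stay below Nyquist", call. = FALSE)
  structure(as.list(environment()), class = "guidewire_sim_spec")
}

# amplitude envelope with linear attack/release ramps, in samples
event_envelope <- function(n_event, fs, attack_s = 0.05, release_s = 0.3) {
  env <- rep(1, n_event)
  na <- min(n_event, max(1L, round(attack_s * fs)))
  nr <- min(n_event - na, max(1L, round(release_s * fs)))
  env[seq_len(na)] <- seq(0, 1, length.out = na)
  if (nr > 0) env[seq(n_event - nr + 1L, n_event)] <- seq(1, 0, length.out = nr)
  env
}

# mix an event waveform into unit-variance background noise at snr_db,
# normalizing the result into [-1, 1]
mix_event <- function(y, noise, event_idx, snr_db) {
  amp <- 10^(snr_db / 20)
  ey <- rms(y[event_idx])
  s <- if (is.finite(amp) && ey > 0) y * (amp / ey) else numeric(length(y))
  x <- s + noise
  x / max(abs(x), 1e-12) * 0.95
}

#' Generate a synthetic needle recording
#'
#' @param spec a [needle_sim_spec()].
#' @return an [audio_recording()] with `label = "needle"` and annotations
#'   `t_in`, `t_out`.
#' @export
gen_needle_signal <- function(spec) {
  stopifnot(inherits(spec, "needle_sim_spec"))
  with_seed(spec$seed, {
    n <- round(spec$duration_s * spec$fs)
    tt <- (seq_len(n) - 1) / spec$fs
    f0 <- ifelse(tt >= spec$t_in & tt < spec$t_out,
                 spec$tissue_resonance_hz, spec$base_resonance_hz)
    y <- cpp_tv_resonator(rnorm(n), f0, rep(0.99, n), spec$fs)
    x <- mix_event(y, rnorm(n), seq_len(n), spec$snr_db)
    audio_recording(x, spec$fs, label = "needle",
                    annotations = c(t_in = spec$t_in, t_out = spec$t_out))
  })
}

#' Generate a synthetic guide-wire recording
#'
#' @param spec a [guidewire_sim_spec()].
#' @return an [audio_recording()] labelled with the event kind and
#'   annotations `t_on`, `t_off`.
#' @export
gen_guidewire_signal <- function(spec) {
  stopifnot(inherits(spec, "guidewire_sim_spec"))
  with_seed(spec$seed, {
    n <- round(spec$duration_s * spec$fs)
    fs <- spec$fs
    i_on <- round(spec$t_on * fs) + 1L
    i_off <- min(n, round(spec$t_off * fs))
    ev <- seq(i_on, i_off)
    ne <- length(ev)
    noise <- rnorm(n)
    y <- numeric(n)

    if (spec$event_kind == "bump") {
      env <- event_envelope(ne, fs, attack_s = 0.01, release_s = 0.02)
      y[ev] <- rnorm(ne) * env
    } else {
      if (spec$event_kind == "perforation") {
        te <- (seq_len(ne) - 1) / fs
        W <- spec$overshoot_width_s
        # trapezoidal overshoot pulse: 25% rise, 50% flat top, 25% fall
        pulse <- ifelse(te < 0.25 * W, te / (0.25 * W),
                 ifelse(te < 0.75 * W, 1,
                 ifelse(te < W, (W - te) / (0.25 * W), 0)))
        a <- exp(-1 / (0.2 * fs))        # jitter autocorrelation ~0.2 s
        jit <- spec$plateau_jitter_hz * sqrt(1 - a^2) *
          as.numeric(stats::filter(rnorm(ne), a, method = "recursive"))
        f0e <- spec$plateau_freq_hz + spec$overshoot_height_hz * pulse + jit
        radius <- 0.99                   # pure, stable plateau resonance
      } else {
        # friction: time-dispersed resonance = slow sweep + bounded random
        # walk (the sweep guarantees dispersion; the walk decorrelates runs)
        te <- (seq_len(ne) - 1) / fs
        sweep <- 350 * sin(2 * pi * 0.5 * te + runif(1, 0, 2 * pi))
        walk <- cumsum(rnorm(ne, sd = 300 / sqrt(fs)))
        lo <- 400; hi <- 2200
        start <- runif(1, 800, 1500)
        z <- (start + sweep + walk - lo) %% (2 * (hi - lo))
        f0e <- lo + ifelse(z > (hi - lo), 2 * (hi - lo) - z, z)  # reflect
        radius <- 0.97
      }
      f0 <- rep(spec$plateau_freq_hz, n)
      f0[ev] <- pmax(50, pmin(f0e, fs / 2 - 50))
      e <- numeric(n)
      e[ev] <- rnorm(ne) * event_envelope(ne, fs)
      y <- cpp_tv_resonator(e, f0, rep(radius, n), fs)
    }
    x <- mix_event(y, noise, ev, spec$snr_db)
    audio_recording(x, fs, label = spec$event_kind,
                    annotations = c(t_on = spec$t_on, t_off = spec$t_off))
  })
}

#' Generate a labelled synthetic corpus
#'
#' Builds a reproducible set of simulation specs (per-recording seeds derived
#' from the master seed) plus a manifest. Event parameters are jittered
#' between recordings so the corpus spans realistic variability. With
#' `out_dir` set, WAV files and a `manifest.csv` are written; otherwise
#' recordings are materialized on demand with [dataset_recording()].
#'
#' @param kind `"needle"` or `"guidewire"`.
#' @param counts for `"needle"`, a single count; for `"guidewire"`, a named
#'   vector `c(perforation = ..., friction = ..., bump = ...)`.
#' @param seed master seed.
#' @param out_dir optional directory to write WAV files and the manifest to.
#' @return an object of class `aemid_dataset`: `manifest` (data.frame with
#'   label, seed, reference times, and `wav_path` when written) and `specs`
#'   (list of simulation specs).
#' @export
gen_dataset <- function(kind = c("needle", "guidewire"), counts, seed = 1L,
                        out_dir = NULL) {
  kind <- match.arg(kind)
  specs <- list()
  rows <- list()
  if (kind == "needle") {
    n <- sum(counts)
    for (i in seq_len(n)) {
      si <- derive_seed(seed, i)
      jit <- with_seed(si, list(t_in = runif(1, 2.5, 3.5),
                                t_out = runif(1, 7, 8.5),
                                base = runif(1, 3300, 3700),
                                tissue = runif(1, 4800, 5200)))
      specs[[i]] <- needle_sim_spec(t_in = jit$t_in, t_out = jit$t_out,
                                    base_resonance_hz = jit$base,
                                    tissue_resonance_hz = jit$tissue,
                                    seed = derive_seed(si, 1))
      rows[[i]] <- data.frame(id = i, label = "needle", seed = si,
                              t_in_ref = jit$t_in, t_out_ref = jit$t_out)
    }
  } else {
    if (is.null(names(counts)))
      names(counts) <- c("perforation", "friction", "bump")[seq_along(counts)]
    if (any(counts < 1)) stop("each requested class needs a count >= 1", call. = FALSE)
    labels <- rep(names(counts), counts)
    for (i in seq_along(labels)) {
      si <- derive_seed(seed, i)
      lab <- labels[i]
      jit <- with_seed(si, {
        t_on <- runif(1, 5.5, 7.5)
        dur <- if (lab == "bump") runif(1, 0.05, 0.2) else runif(1, 3, 4.5)
        list(t_on = t_on, t_off = t_on + dur,
             os_h = runif(1, 1200, 1800), os_w = runif(1, 0.2, 0.4),
             plat = runif(1, 600, 1000), jitf = runif(1, 10, 30))
      })
      specs[[i]] <- guidewire_sim_spec(event_kind = lab,
                                       t_on = jit$t_on, t_off = jit$t_off,
                                       overshoot_height_hz = jit$os_h,
                                       overshoot_width_s = jit$os_w,
                                       plateau_freq_hz = jit$plat,
                                       plateau_jitter_hz = jit$jitf,
                                       seed = derive_seed(si, 1))
      rows[[i]] <- data.frame(id = i, label = lab, seed = si,
                              t_on_ref = jit$t_on, t_off_ref = jit$t_off)
    }
  }
  manifest <- do.call(rbind, rows)
  ds <- structure(list(manifest = manifest, specs = specs, kind = kind,
                       seed = seed),
                  class = "aemid_dataset")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(nrow(manifest))
    for (i in seq_len(nrow(manifest))) {
      paths[i] <- file.path(out_dir, sprintf("%s_%03d.wav", kind, i))
      write_wav(dataset_recording(ds, i), paths[i])
    }
    ds$manifest$wav_path <- paths
    write.csv(ds$manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
  }
  ds
}

#' Materialize one recording of a synthetic dataset
#'
#' @param ds an [gen_dataset()] result.
#' @param i recording index.
#' @return an [audio_recording()].
#' @export
dataset_recording <- function(ds, i) {
  stopifnot(inherits(ds, "aemid_dataset"))
  sp <- ds$specs[[i]]
  if (ds$kind == "needle") gen_needle_signal(sp) else gen_guidewire_signal(sp)
}

#' @export
print.aemid_dataset <- function(x, ...) {
  cat(sprintf("<aemid_dataset> %s, %d recordings (seed %d)\n",
              x$kind, nrow(x$manifest), x$seed))
  print(table(x$manifest$label))
  invisible(x)
}
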