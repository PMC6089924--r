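#' CUSUM detection of needle tissue entry and exit
#'
#' Two-sided tabular CUSUM on the standardized TV-MEP. The baseline mean and
#' standard deviation are estimated from the initial `baseline_s` seconds of
#' the track (which must precede the insertion). The first alarm gives the
#' entry time `t_in`; the statistic is then re-baselined on the
#' post-transition level and reset, and the next alarm sustained for at least
#' `sustain` consecutive windows gives the exit time `t_out`.
#'
#' The default reference value of one baseline standard deviation per window
#' deliberately desensitizes the detector to the slow wander the
#' maximal-energy-pole estimate shows on stationary audio; a tissue
#' transition shifts the MEP by tens of baseline standard deviations, so
#' detection delay is still about two windows.
#'
#' @param mep an [mep_track()].
#' @param drift_k CUSUM reference (drift) value in multiples of the baseline
#'   standard deviation (default 1).
#' @param threshold_h decision threshold in multiples of the baseline
#'   standard deviation (default 5).
#' @param baseline_s length in seconds of the baseline segment (default 2).
#' @param sustain number of consecutive alarm windows required for `t_out`
#'   (default 2; rejects single-window glitches).
#' @param clip_z winsorizing limit for the standardized MEP (default 4):
#'   single-window outlier spikes, which the maximal-energy-pole rule
#'   occasionally produces when a noise pole briefly dominates, cannot then
#'   trip the detector on their own, while a sustained shift still alarms
#'   within two windows.
#' @return an object of class `detection_result` with `t_in`, `t_out`
#'   (NA when absent, with `flagged = TRUE`), and `alarms` (all alarm times).
#' @export
cusum_detect <- function(mep, drift_k = 1.0, threshold_h = 5,
                         baseline_s = 2.0, sustain = 2L, clip_z = 4) {
  stopifnot(inherits(mep, "mep_track"))
  v <- mep$values; tt <- mep$times
  nb <- sum(tt < tt[1] + baseline_s)
  if (nb < 3 || nb >= length(v))
    stop("baseline segment must cover >= 3 windows and precede the series end",
         call. = FALSE)
  mu <- mean(v[seq_len(nb)])
  s <- sd(v[seq_len(nb)])
  s <- max(s, 1e-6 * max(abs(mu), 1))

  run <- function(idx, mu0, s0) {
    z <- pmin(pmax((v[idx] - mu0) / s0, -clip_z), clip_z)
    sp <- 0; sm <- 0
    hits <- integer(0)
    for (i in seq_along(z)) {
      sp <- max(0, sp + z[i] - drift_k)
      sm <- max(0, sm - z[i] - drift_k)
      if (sp > threshold_h || sm > threshold_h) {
        hits <- c(hits, idx[i])
        sp <- 0; sm <- 0                      # reset after each alarm
      }
    }
    hits
  }

  phase1 <- run(seq(nb + 1L, length(v)), mu, s)
  alarms <- tt[phase1]
  if (length(phase1) == 0L)
    return(new_detection_result(NA_real_, NA_real_, numeric(0), flagged = TRUE))
  i_in <- phase1[1]
  t_in <- tt[i_in]

  # re-baseline on the post-entry level: skip a short settling interval,
  # then estimate mean/sd over the next baseline_s worth of windows
  settle <- 3L
  nb2 <- max(3L, nb)
  b2 <- seq(i_in + settle, min(i_in + settle + nb2 - 1L, length(v)))
  t_out <- NA_real_
  flagged <- FALSE
  if (length(b2) >= 3 && max(b2) < length(v)) {
    mu2 <- mean(v[b2]); s2 <- max(sd(v[b2]), 1e-6 * max(abs(mu2), 1))
    phase2 <- run(seq(max(b2) + 1L, length(v)), mu2, s2)
    alarms <- c(alarms, tt[phase2])
    if (length(phase2) > 0L) {
      # sustained rule: the alarm (or its immediate neighbourhood) must stay
      # out of control for `sustain` consecutive windows
      for (a in phase2) {
        seg <- seq(a, min(a + sustain - 1L, length(v)))
        z2 <- abs(v[seg] - mu2) / s2
        if (length(seg) >= sustain && all(z2 > drift_k)) { t_out <- tt[a]; break }
      }
    }
  }
  if (is.na(t_out)) flagged <- TRUE
  new_detection_result(t_in, t_out, sort(unique(alarms)), flagged = flagged)
}

new_detection_result <- function(t_in, t_out, alarms, flagged = FALSE) {
  if (!is.na(t_in) && !is.na(t_out) && t_in >= t_out)
    stop("t_in must precede t_out", call. = FALSE)
  structure(list(t_in = t_in, t_out = t_out, alarms = alarms,
                 flagged = flagged),
            class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat(sprintf("<detection_result> t_in = %s s, t_out = %s s (%d alarms%s)\n",
              format(x$t_in, digits = 4), format(x$t_out, digits = 4),
              length(x$alarms), if (x$flagged) ", flagged" else ""))
  invisible(x)
}

#' Detection error statistics in seconds and millimetres
#'
#' Compares automatic entry/exit detections with reference annotations.
#' Signed and absolute error statistics are both reported; millimetre
#' figures follow by multiplying seconds with the insertion velocity.
#'
#' @param detected list of [cusum_detect()] results (or a data.frame with
#'   columns `t_in`, `t_out`).
#' @param reference data.frame with columns `t_in`, `t_out` (reference
#'   annotations, same order and length).
#' @param velocity_mm_s insertion velocity in mm/s (study values: 3, 5, 8).
#' @return an object of class `error_stats`: per-event (`entry`, `exit`)
#'   rows with `mean_s`, `std_s`, `mean_abs_s`, `std_abs_s` and their
#'   millimetre equivalents.
#' @export
detection_error_stats <- function(detected, reference, velocity_mm_s = 3) {
  if (is.data.frame(detected)) {
    det <- detected
  } else {
    if (length(detected) == 0L) stop("empty detection list", call. = FALSE)
    det <- data.frame(t_in = vapply(detected, function(d) d$t_in, 0),
                      t_out = vapply(detected, function(d) d$t_out, 0))
  }
  if (nrow(det) == 0L || nrow(det) != nrow(reference))
    stop("detected and reference must be non-empty and of equal length",
         call. = FALSE)
  stats_for <- function(err) {
    c(mean_s = mean(err), std_s = sd0(err),
      mean_abs_s = mean(abs(err)), std_abs_s = sd0(abs(err)))
  }
  e_in <- det$t_in - reference$t_in
  e_out <- det$t_out - reference$t_out
  tab <- rbind(entry = stats_for(e_in), exit = stats_for(e_out))
  mm <- tab * velocity_mm_s
  colnames(mm) <- sub("_s$", "_mm", colnames(tab))
  structure(list(seconds = as.data.frame(tab), mm = as.data.frame(mm),
                 velocity_mm_s = velocity_mm_s,
                 errors = data.frame(entry_s = e_in, exit_s = e_out)),
            class = "error_stats")
}

sd0 <- function(x) if (length(x) < 2) 0 else sd(x)

#' Convert timing error statistics to millimetres
#'
#' Worked-example helper: millimetre error = seconds error x insertion
#' velocity.
#'
#' @param mean_s,std_s error mean and standard deviation in seconds.
#' @param velocity_mm_s insertion velocity in mm/s.
#' @return named numeric vector `c(mean_mm, std_mm)`.
#' @examples
#' seconds_to_mm(0.59, 0.32, 3)  # 1.77, 0.96
#' @export
seconds_to_mm <- function(mean_s, std_s, velocity_mm_s) {
  c(mean_mm = mean_s * velocity_mm_s, std_mm = std_s * velocity_mm_s)
}

#' @export
print.error_stats <- function(x, ...) {
  cat(sprintf("<error_stats> velocity %g mm/s\n", x$velocity_mm_s))
  cat("  seconds:\n"); print(round(x$seconds, 3))
  cat("  millimetres:\n"); print(round(x$mm, 3))
  invisible(x)
}
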