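#' Detect guide-wire event bounds from the energy envelope
#'
#' Computes a short-time-energy envelope of the (filtered) recording on the
#' same window grid as the TV-MEP, thresholds it at the envelope median plus
#' `3 * MAD`, merges supra-threshold runs separated by less than 100 ms
#' (hysteresis), and keeps the run with the largest total energy. The
#' maximal-energy sub-interval length is `delta = delta_frac * (t_off - t_on)`.
#'
#' @param rec the band-limited [audio_recording()] the MEP was computed from.
#' @param mep the corresponding [mep_track()].
#' @param delta_frac fraction of the event duration used for the
#'   maximal-energy sub-interval (default 0.2).
#' @param min_dur_s minimum event duration retained (default 0.05 s; bump
#'   transients are as short as 50 ms).
#' @return an object of class `event_segment` with `t_on`, `t_off`, `delta`,
#'   or `NULL` if no supra-threshold interval exists.
#' @export
detect_event_bounds <- function(rec, mep, delta_frac = 0.2, min_dur_s = 0.05) {
  stopifnot(inherits(rec, "audio_recording"), inherits(mep, "mep_track"))
  nw <- round((mep$window_s %||% (2 * mep$hop_s)) * rec$fs)
  hop <- round(mep$hop_s * rec$fs)
  starts <- round((mep$times - (mep$window_s %||% 0) / 2) * rec$fs) + 1L
  starts <- pmax(1L, pmin(starts, length(rec$samples) - nw + 1L))
  # short-time energy per analysis window (vectorized via cumulative sums)
  cs <- c(0, cumsum(rec$samples^2))
  env <- (cs[starts + nw] - cs[starts]) / nw

  thr <- median(env) + 3 * mad(env)
  above <- env > thr
  if (!any(above)) return(NULL)

  r <- rle(above)
  ends <- cumsum(r$lengths)
  begs <- ends - r$lengths + 1L
  runs <- data.frame(beg = begs[r$values], end = ends[r$values])
  # hysteresis: merge runs separated by < 100 ms
  gap_w <- ceiling(0.1 / mep$hop_s)
  if (nrow(runs) > 1) {
    keep <- list(runs[1, ])
    for (i in 2:nrow(runs)) {
      last <- keep[[length(keep)]]
      if (runs$beg[i] - last$end <= gap_w) {
        keep[[length(keep)]]$end <- runs$end[i]
      } else keep[[length(keep) + 1]] <- runs[i, ]
    }
    runs <- do.call(rbind, keep)
  }
  min_w <- max(1L, floor(min_dur_s / mep$hop_s))
  runs <- runs[runs$end - runs$beg + 1L >= min_w, , drop = FALSE]
  if (nrow(runs) == 0L) return(NULL)
  energy <- vapply(seq_len(nrow(runs)),
                   function(i) sum(env[runs$beg[i]:runs$end[i]]), 0)
  best <- runs[which.max(energy), ]
  t_on <- mep$times[best$beg]
  t_off <- mep$times[best$end]
  event_segment(t_on, t_off, delta = delta_frac * (t_off - t_on))
}

#' Guide-wire event segment
#'
#' @param t_on,t_off event start/end in seconds (`t_on < t_off`).
#' @param delta maximal-energy sub-interval length in seconds
#'   (`<= t_off - t_on`).
#' @return an object of class `event_segment`.
#' @export
event_segment <- function(t_on, t_off, delta = 0.2 * (t_off - t_on)) {
  if (!(t_on < t_off)) stop("t_on must precede t_off", call. = FALSE)
  if (delta > t_off - t_on + 1e-12)
    stop("delta cannot exceed the event duration", call. = FALSE)
  structure(list(t_on = t_on, t_off = t_off, delta = delta),
            class = "event_segment")
}

#' @export
print.event_segment <- function(x, ...) {
  cat(sprintf("<event_segment> %.3f-%.3f s (delta %.3f s)\n",
              x$t_on, x$t_off, x$delta))
  invisible(x)
}

# peak prominence of a local maximum at index i in v: height above the
# higher of the two minima separating it from taller terrain (or the ends)
peak_prominence <- function(v, i) {
  n <- length(v)
  left <- if (i > 1) {
    j <- which(v[seq_len(i - 1)] > v[i])
    lo <- if (length(j)) (max(j) + 1) else 1
    min(v[lo:(i - 1)])
  } else v[i]
  right <- if (i < n) {
    j <- which(v[(i + 1):n] > v[i])
    hi <- if (length(j)) (i + min(j) - 1) else n
    min(v[(i + 1):hi])
  } else v[i]
  v[i] - max(left, right)
}

local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer(0))
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

#' Detect the perforation overshoot in the TV-MEP
#'
#' A vessel-wall perforation shows a fast, short rise of the dominant pole
#' frequency at event onset. The MEP inside `[t_on, t_on + delta]` is first
#' smoothed with a 5-window running median (single-window pole-tracking
#' glitches are not overshoots); the highest-prominence local maximum of the
#' smoothed track is taken as the overshoot peak and its start and end are
#' the half-prominence crossings. The overshoot is declared present only if
#' its prominence is positive and exceeds twice the pre-event MAD of the MEP.
#'
#' @param mep an [mep_track()].
#' @param seg an [event_segment()].
#' @return an object of class `overshoot_descriptor`: `present`, `OS_on`,
#'   `OS_off` (s), `OS_H` (Hz, the peak prominence), `OS_W` (s).
#' @export
detect_overshoot <- function(mep, seg) {
  stopifnot(inherits(mep, "mep_track"), inherits(seg, "event_segment"))
  idx <- which(mep$times >= seg$t_on & mep$times <= seg$t_on + seg$delta)
  pre <- mep$values[mep$times < seg$t_on]
  noise <- if (length(pre) >= 5) mad(pre) else mad(mep$values)
  none <- structure(list(present = FALSE, OS_on = NA_real_, OS_off = NA_real_,
                         OS_H = 0, OS_W = NA_real_),
                    class = "overshoot_descriptor")
  if (length(idx) < 3) return(none)
  v <- mep$values[idx]
  if (length(v) >= 5) v <- as.numeric(stats::runmed(v, 5))
  peaks <- local_maxima(v)
  if (length(peaks) == 0L) peaks <- which.max(v)
  proms <- vapply(peaks, function(i) peak_prominence(v, i), 0)
  k <- peaks[which.max(proms)]
  prom <- max(proms)
  if (prom <= 0 || prom < 2 * noise) return(none)
  half <- v[k] - prom / 2
  lo <- k; while (lo > 1 && v[lo - 1] > half) lo <- lo - 1
  hi <- k; while (hi < length(v) && v[hi + 1] > half) hi <- hi + 1
  structure(list(present = TRUE,
                 OS_on = mep$times[idx[lo]], OS_off = mep$times[idx[hi]],
                 OS_H = prom,
                 OS_W = max(mep$times[idx[hi]] - mep$times[idx[lo]], mep$hop_s)),
            class = "overshoot_descriptor")
}

#' @export
print.overshoot_descriptor <- function(x, ...) {
  if (x$present)
    cat(sprintf("<overshoot> %.3f-%.3f s, height %.0f Hz, width %.3f s\n",
                x$OS_on, x$OS_off, x$OS_H, x$OS_W))
  else cat("<overshoot> absent\n")
  invisible(x)
}

#' Detect TV-MEP plateaus at three derivative thresholds
#'
#' A plateau is an interval, after the overshoot, over which the per-hop
#' derivative of the MEP stays continuously below a threshold. Three nested
#' intervals `PL1 <= PL2 <= PL3` are produced for three increasing
#' thresholds: `PL1` is the longest sub-threshold run (minimum 3 windows);
#' each subsequent interval is the run at the larger threshold containing
#' the previous one, which guarantees the nesting `PL1` within `PL2` within
#' `PL3` as well as monotone lengths.
#'
#' @param mep an [mep_track()].
#' @param seg an [event_segment()].
#' @param thresholds three increasing per-hop derivative thresholds in Hz;
#'   default: 2%, 5% and 10% of the event's MEP range.
#' @param os optional [detect_overshoot()] result; the search starts after
#'   `OS_off` when the overshoot is present, else at `t_on`.
#' @return an object of class `plateau_set`: list of index vectors `PL1`,
#'   `PL2`, `PL3` (into `mep$values`; possibly empty), plus `thresholds`.
#' @export
detect_plateaus <- function(mep, seg, thresholds = NULL, os = NULL) {
  stopifnot(inherits(mep, "mep_track"), inherits(seg, "event_segment"))
  start_t <- if (!is.null(os) && isTRUE(os$present)) os$OS_off else seg$t_on
  idx <- which(mep$times >= start_t & mep$times <= seg$t_off)
  ev_idx <- which(mep$times >= seg$t_on & mep$times <= seg$t_off)
  if (is.null(thresholds)) {
    rng <- diff(range(mep$values[ev_idx]))
    thresholds <- c(0.02, 0.05, 0.10) * max(rng, 1)
  }
  if (length(thresholds) != 3 || is.unsorted(thresholds))
    stop("`thresholds` must be three increasing values", call. = FALSE)
  empty <- structure(list(PL1 = integer(0), PL2 = integer(0),
                          PL3 = integer(0), thresholds = thresholds),
                     class = "plateau_set")
  if (length(idx) < 4) return(empty)
  dv <- abs(diff(mep$values[idx]))

  runs_below <- function(thr) {
    ok <- dv < thr
    if (!any(ok)) return(data.frame(beg = integer(0), end = integer(0)))
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    begs <- ends - r$lengths + 1L
    # a run of m consecutive small derivatives spans m+1 samples
    data.frame(beg = begs[r$values], end = ends[r$values] + 1L)
  }
  pick <- function(thr, inner) {
    rr <- runs_below(thr)
    rr <- rr[rr$end - rr$beg + 1L >= 3L, , drop = FALSE]
    if (nrow(rr) == 0L) return(integer(0))
    if (length(inner) > 0L) {
      hit <- which(rr$beg <= min(inner) & rr$end >= max(inner))
      if (length(hit)) {
        i <- hit[which.max(rr$end[hit] - rr$beg[hit])]
        return(seq(rr$beg[i], rr$end[i]))
      }
    }
    i <- which.max(rr$end - rr$beg)
    seq(rr$beg[i], rr$end[i])
  }
  # local run indices refer to positions within idx; PL1 chosen first,
  # larger-threshold intervals grow around it
  p1 <- pick(thresholds[1], integer(0))
  p2 <- pick(thresholds[2], p1)
  p3 <- pick(thresholds[3], p2)
  structure(list(PL1 = idx[p1], PL2 = idx[p2], PL3 = idx[p3],
                 thresholds = thresholds),
            class = "plateau_set")
}

#' @export
print.plateau_set <- function(x, ...) {
  cat(sprintf("<plateau_set> lengths %d / %d / %d windows (thresholds %s Hz/hop)\n",
              length(x$PL1), length(x$PL2), length(x$PL3),
              paste(signif(x$thresholds, 3), collapse = ", ")))
  invisible(x)
}
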