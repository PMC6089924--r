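# one cached full-pipeline run per event kind (spec times chosen so the
# event sits mid-recording with ample idle background on both sides)
perf_out <- function() cached("perf_out", {
  rec <- gen_guidewire_signal(guidewire_sim_spec(
    duration_s = 20, t_on = 10, t_off = 14, seed = 101))
  aemid:::guidewire_features_one(rec, pipeline_config("guidewire"))
})
bump_out <- function() cached("bump_out", {
  rec <- gen_guidewire_signal(guidewire_sim_spec(
    event_kind = "bump", t_on = 7, t_off = 7.12, seed = 102))
  aemid:::guidewire_features_one(rec, pipeline_config("guidewire"))
})
fric_out <- function() cached("fric_out", {
  rec <- gen_guidewire_signal(guidewire_sim_spec(
    event_kind = "friction", seed = 103))
  aemid:::guidewire_features_one(rec, pipeline_config("guidewire"))
})

# mep + overshoot only (no spectrum/features), for ensembles
overshoot_of <- function(rec, cfg = pipeline_config("guidewire")) {
  rec <- dwt_band_reconstruct(decimate_audio(rec, cfg$decimation), cfg$filter)
  mep <- mep_track(fit_tvar(rec, cfg$tvar))
  seg <- detect_event_bounds(rec, mep, delta_frac = cfg$delta_frac)
  if (is.null(seg)) return(NULL)
  detect_overshoot(mep, seg)
}

test_that("event bounds recover the injected perforation interval", {
  seg <- perf_out()$segment
  expect_lt(abs(seg$t_on - 10), 0.3)
  expect_lt(abs(seg$t_off - 14), 0.5)
  expect_equal(seg$delta, 0.2 * (seg$t_off - seg$t_on))
})

test_that("pure background noise yields no event", {
  rec <- gen_guidewire_signal(guidewire_sim_spec(snr_db = -Inf, seed = 104))
  cfg <- pipeline_config("guidewire")
  r2 <- dwt_band_reconstruct(decimate_audio(rec, 4), cfg$filter)
  mep <- mep_track(fit_tvar(r2, cfg$tvar))
  expect_null(detect_event_bounds(r2, mep))
})

test_that("of two disjoint events the higher-energy one is selected", {
  # strong event at 7-9 s, weak one at 12-13 s
  strong <- gen_guidewire_signal(guidewire_sim_spec(
    t_on = 7, t_off = 9, snr_db = 12, seed = 105))
  weak <- gen_guidewire_signal(guidewire_sim_spec(
    t_on = 12, t_off = 13, snr_db = 3, seed = 106))
  mix <- audio_recording(
    (strong$samples + weak$samples) / 2, strong$fs)
  cfg <- pipeline_config("guidewire")
  r2 <- dwt_band_reconstruct(decimate_audio(mix, 4), cfg$filter)
  mep <- mep_track(fit_tvar(r2, cfg$tvar))
  seg <- detect_event_bounds(r2, mep)
  expect_false(is.null(seg))
  expect_lt(abs(seg$t_on - 7), 0.5)
  expect_lt(seg$t_off, 11)
})

test_that("the perforation overshoot is recovered near its generated height and width", {
  os <- perf_out()$overshoot
  expect_true(os$present)
  expect_lt(abs(os$OS_H - 1500) / 1500, 0.2)
  expect_lt(abs(os$OS_W - 0.3) / 0.3, 0.5)
  expect_gte(os$OS_on, 10 - 0.1)
  expect_lte(os$OS_off, 14)
})

test_that("a flat MEP has no overshoot", {
  mep <- as_mep_track(rep(1000, 200), (0:199) * 0.01)
  seg <- event_segment(0.5, 1.5)
  expect_false(detect_overshoot(mep, seg)$present)
})

test_that("friction artefacts rarely show an overshoot", {
  hits <- vapply(1:50, function(s) {
    rec <- gen_guidewire_signal(guidewire_sim_spec(event_kind = "friction",
                                                   seed = 200 + s))
    os <- overshoot_of(rec)
    !is.null(os) && os$present
  }, logical(1))
  expect_lte(mean(hits), 0.10)
})

test_that("plateaus span constant regions, vanish under noise, and nest", {
  # exactly constant MEP after the overshoot
  v <- c(rnorm(50, 900, 80), rep(1500, 10), rep(900, 140))
  mep <- as_mep_track(v, (seq_along(v) - 1) * 0.01)
  seg <- event_segment(0.5, 1.99)
  os <- list(present = TRUE, OS_off = 0.6)
  pl <- detect_plateaus(mep, seg, thresholds = c(1, 2, 4), os = os)
  post <- which(mep$times >= 0.6 & mep$times <= 1.99)
  expect_equal(pl$PL1, post)
  expect_equal(pl$PL3, post)

  # fluctuations far above threshold: empty PL1
  set.seed(41)
  v2 <- rnorm(200, 1000, 200)
  pl2 <- detect_plateaus(as_mep_track(v2, (0:199) * 0.01),
                         event_segment(0.2, 1.9),
                         thresholds = c(0.5, 1, 2))
  expect_length(pl2$PL1, 0)

  # nesting and length monotonicity over random MEPs
  set.seed(42)
  for (i in 1:100) {
    vr <- cumsum(rnorm(150, sd = runif(1, 1, 60)))
    plr <- detect_plateaus(as_mep_track(vr, (0:149) * 0.01),
                           event_segment(0.1, 1.4),
                           thresholds = c(5, 15, 45))
    expect_lte(length(plr$PL1), length(plr$PL2))
    expect_lte(length(plr$PL2), length(plr$PL3))
    if (length(plr$PL1)) expect_true(all(plr$PL1 %in% plr$PL2))
    if (length(plr$PL2)) expect_true(all(plr$PL2 %in% plr$PL3))
  }
})

test_that("feature edge cases follow their closed forms", {
  # time-constant spectrum over the event -> F15 = F16 = 1; flat plateau
  # spanning the event -> F10 = 1
  nw <- 101
  times <- (0:(nw - 1)) * 0.01
  v <- rep(1200, nw)
  mep <- as_mep_track(v, times)
  shape <- exp(-(1:32) / 8)
  spec <- structure(list(S = matrix(shape, 32, nw),
                         freqs = seq(0, 500, length.out = 32),
                         times = times,
                         mean_over_f = rep(mean(shape), nw)),
                    class = "tv_spectrum")
  seg <- event_segment(0.10, 0.90)
  os <- structure(list(present = FALSE, OS_on = NA, OS_off = NA,
                       OS_H = 0, OS_W = NA),
                  class = "overshoot_descriptor")
  ev_idx <- which(times >= 0.10 & times <= 0.90)
  pl <- structure(list(PL1 = ev_idx, PL2 = ev_idx, PL3 = ev_idx,
                       thresholds = c(1, 2, 3)), class = "plateau_set")
  fv <- compute_features(mep, spec, seg, os, pl)
  expect_equal(unname(fv["F15"]), 1)
  expect_equal(unname(fv["F16"]), 1)
  expect_equal(unname(fv["F10"]), 1)
  expect_equal(unname(fv["F1"]), 0)        # no overshoot
  expect_equal(unname(fv["F2"]), 1200)
  expect_equal(unname(fv["F6"]), unname(fv["F5"]) * 0.8)   # duration link
  expect_equal(unname(fv["F11"]), 0.8 / 1e-9)   # zero-variance plateau guard

  expect_error(compute_features(mep, spec, event_segment(0.10, 0.105), os, pl),
               "degenerate")
})

test_that("F15/F16 are invariant to global spectrum rescaling", {
  out <- perf_out()
  rec <- gen_guidewire_signal(guidewire_sim_spec(
    duration_s = 20, t_on = 10, t_off = 14, seed = 101))
  cfg <- pipeline_config("guidewire")
  r2 <- dwt_band_reconstruct(decimate_audio(rec, 4), cfg$filter)
  model <- fit_tvar(r2, cfg$tvar)
  sp <- tvar_spectrum(model, 64)
  sp2 <- sp
  sp2$S <- sp$S * 37.5
  sp2$mean_over_f <- sp$mean_over_f * 37.5
  f1 <- compute_features(out$mep, sp, out$segment, out$overshoot, out$plateaus)
  f2 <- compute_features(out$mep, sp2, out$segment, out$overshoot, out$plateaus)
  expect_equal(f1["F15"], f2["F15"], tolerance = 1e-12)
  expect_equal(f1["F16"], f2["F16"], tolerance = 1e-12)
})

test_that("generated event kinds contrast in the expected features", {
  expect_gt(perf_out()$features["F1"], bump_out()$features["F1"])
  expect_gt(perf_out()$features["F15"], fric_out()$features["F15"])
})

test_that("the SVM separates separable clouds and is honest under label permutation", {
  set.seed(43)
  n <- 60
  Xa <- matrix(rnorm(n * 16), n, 16)
  Xb <- matrix(rnorm(n * 16), n, 16); Xb[, 1] <- Xb[, 1] + 8
  X <- rbind(Xa, Xb)
  y <- rep(c("artefact", "perforation"), each = n)
  model <- train_classifier(X, y)
  expect_equal(mean(classify_event(model, X) == y), 1)

  # deep-inside training point and determinism
  probe <- Xb[1, , drop = FALSE]
  expect_equal(classify_event(model, probe), "perforation")
  expect_identical(classify_event(model, probe), classify_event(model, probe))

  expect_error(train_classifier(Xa, rep("artefact", n)), "both classes")

  # permuted labels: held-out accuracy compatible with chance
  accs <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    Xr <- matrix(rnorm(120 * 16), 120, 16)
    Xr[1:60, 2] <- Xr[1:60, 2] + 5
    yr <- sample(rep(c("artefact", "perforation"), 60))
    tr <- c(1:45, 61:105)
    mr <- train_classifier(Xr[tr, ], yr[tr], cost_grid = 1, gamma_grid = 1 / 16)
    mean(classify_event(mr, Xr[-tr, ]) == yr[-tr])
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.10)
})

test_that("confusion metrics reproduce their defining ratios", {
  cm <- confusion_metrics(TP = 418, FN = 42, FP = 10, TN = 205)
  expect_equal(cm$sensitivity, 418 / 460)
  expect_equal(cm$specificity, 205 / 215)

  pred <- c("perforation", "perforation", "artefact", "artefact")
  cm2 <- confusion_metrics(pred, pred)
  expect_equal(cm2$sensitivity, 1)
  expect_equal(cm2$specificity, 1)
  expect_error(confusion_metrics(character(0), character(0)), "equal length|non-empty")
})
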