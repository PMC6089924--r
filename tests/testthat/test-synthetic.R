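test_that("generators are deterministic given the seed", {
  a <- gen_needle_signal(needle_sim_spec(seed = 51))
  b <- gen_needle_signal(needle_sim_spec(seed = 51))
  expect_identical(a$samples, b$samples)
  c1 <- gen_guidewire_signal(guidewire_sim_spec(seed = 52))
  c2 <- gen_guidewire_signal(guidewire_sim_spec(seed = 52))
  expect_identical(c1$samples, c2$samples)
  expect_false(identical(a$samples,
                         gen_needle_signal(needle_sim_spec(seed = 53))$samples))
})

test_that("needle recordings shift their dominant resonance at t_in/t_out", {
  spec <- needle_sim_spec(seed = 54)
  rec <- gen_needle_signal(spec)
  seg_peak <- function(t0, t1) {
    idx <- seq(round(t0 * rec$fs) + 1, round(t1 * rec$fs))
    sp <- Mod(stats::fft(rec$samples[idx]))[seq_len(length(idx) / 2)]
    (which.max(sp) - 1) * rec$fs / length(idx)
  }
  expect_lt(abs(seg_peak(0.2, 2.8) - spec$base_resonance_hz), 150)
  expect_lt(abs(seg_peak(3.2, 7.8) - spec$tissue_resonance_hz), 150)
  expect_lt(abs(seg_peak(8.2, 9.8) - spec$base_resonance_hz), 150)
  expect_equal(unname(rec$annotations), c(3, 8))
})

test_that("a generator with no event energy produces no CUSUM alarms", {
  rec <- gen_needle_signal(needle_sim_spec(snr_db = -Inf, seed = 55))
  run <- run_needle_pipeline(rec)
  expect_true(is.na(run$results$t_in))
  expect_true(run$results$flagged)
})

test_that("spec validation rejects inconsistent simulation parameters", {
  expect_error(needle_sim_spec(t_in = 5, t_out = 3), "t_in")
  expect_error(needle_sim_spec(tissue_resonance_hz = 30000), "Nyquist")
  expect_error(guidewire_sim_spec(event_kind = "bump", t_on = 5, t_off = 6),
               "0.2")
  expect_error(guidewire_sim_spec(event_kind = "perforation",
                                  overshoot_height_hz = 0), "overshoot")
})

test_that("datasets are reproducible and mirror the requested composition", {
  d1 <- gen_dataset("guidewire", c(perforation = 10, friction = 5, bump = 5),
                    seed = 7)
  d2 <- gen_dataset("guidewire", c(perforation = 10, friction = 5, bump = 5),
                    seed = 7)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(dataset_recording(d1, 3)$samples,
                   dataset_recording(d2, 3)$samples)

  # composition scaled from 560/165/150 stays proportional within rounding
  comp <- round(c(560, 165, 150) / 5)
  expect_equal(comp, c(112, 33, 30))
  d3 <- gen_dataset("guidewire", c(perforation = 112, friction = 33,
                                   bump = 30), seed = 8)
  expect_equal(unname(table(d3$manifest$label)[c("perforation", "friction",
                                                 "bump")]),
               c(112, 33, 30), ignore_attr = TRUE)
})

test_that("writing a needle corpus produces one WAV and one manifest row each", {
  out <- withr::local_tempdir()
  ds <- gen_dataset("needle", 3, seed = 9, out_dir = out)
  expect_length(list.files(out, pattern = "\\.wav$"), 3)
  man <- utils::read.csv(file.path(out, "manifest.csv"))
  expect_equal(nrow(man), 3)
  expect_true(all(c("t_in_ref", "t_out_ref", "wav_path") %in% names(man)))
  back <- read_wav(man$wav_path[1])
  expect_equal(back$fs, 44100)
  expect_lt(max(abs(back$samples - dataset_recording(ds, 1)$samples)),
            1 / 32767)
})
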