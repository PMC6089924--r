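test_that("Yule-Walker on white noise gives small coefficients and matches ar.yw", {
  set.seed(21)
  x <- rnorm(20000)
  rec <- audio_recording(x / max(abs(x)), 1000)
  m <- fit_tvar(rec, tvar_config(window_ms = 20000, overlap = 0, order = 10))
  expect_true(all(abs(m$coeffs) <= 0.15))
  expect_equal(m$sigma2[1], var(rec$samples), tolerance = 0.1)

  # cross-check the sliding fit against stats::ar.yw on the same window
  ref <- stats::ar.yw(rec$samples, aic = FALSE, order.max = 10, demean = TRUE)
  expect_equal(-m$coeffs[, 1], unname(ref$ar), tolerance = 1e-10)
})

test_that("refitting a simulated stationary AR(2) recovers the pole within 2%", {
  set.seed(22)
  mod <- 0.95; ang <- 0.3 * pi
  phi <- c(2 * mod * cos(ang), -mod^2)
  x <- as.numeric(stats::arima.sim(list(ar = phi), 5000))
  rec <- audio_recording(x / max(abs(x)), 1000)
  m <- fit_tvar(rec, tvar_config(window_ms = 500, overlap = 0.5, order = 2))
  z <- tvar_poles(m)$poles
  expect_lt(abs(mean(Mod(z)) - mod) / mod, 0.02)
  expect_lt(abs(mean(abs(Arg(z))) - ang) / ang, 0.02)
})

test_that("needle preset spaces windows 55 ms apart", {
  rec <- audio_recording(rnorm(3 * 14700) / 5, 14700)
  m <- fit_tvar(rec, tvar_config("needle"))
  expect_equal(unique(round(diff(m$times), 6)), 0.055, tolerance = 1e-3)
  expect_error(fit_tvar(audio_recording(rnorm(100) / 5, 14700),
                        tvar_config("needle")), "shorter")
})

test_that("the TV-AR spectrum is an AR PSD: flat at order 0, peaked at the pole angle", {
  set.seed(23)
  rec <- audio_recording(rnorm(2000) / 5, 1000)
  m0 <- fit_tvar(rec, tvar_config(window_ms = 2000, overlap = 0, order = 0))
  s0 <- tvar_spectrum(m0, n_freq = 64)
  expect_lt(diff(range(s0$S[, 1])), 1e-12)

  mod <- 0.95; ang <- 0.3 * pi
  m2 <- manual_model(-c(2 * mod * cos(ang), -mod^2), fs = 1000)
  s2 <- tvar_spectrum(m2, n_freq = 256)
  peak <- s2$freqs[which.max(s2$S[, 1])]
  expect_lt(abs(peak - 0.15 * 1000), diff(s2$freqs[1:2]) + 1e-9)
  expect_true(all(s2$S > 0))
  expect_equal(s2$mean_over_f[1], mean(s2$S[, 1]))
  expect_error(tvar_spectrum(m2, n_freq = 1), "n_freq")
})

test_that("pole decomposition inverts the coefficient polynomial", {
  # (1 - 0.5 z^-1)(1 - 0.8 z^-1) = 1 - 1.3 z^-1 + 0.4 z^-2
  m <- manual_model(c(-1.3, 0.4))
  z <- sort(Re(tvar_poles(m)$poles[, 1]))
  expect_equal(z, c(0.5, 0.8), tolerance = 1e-10)

  # random stable coefficients reconstruct within 1e-8
  set.seed(24)
  for (i in 1:10) {
    zr <- complex(modulus = runif(3, 0.3, 0.95), argument = runif(3, 0, pi))
    zs <- c(zr, Conj(zr))
    co <- Re(poly_from_roots(zs))
    a <- co[-1]
    roots <- tvar_poles(manual_model(a))$poles[, 1]
    p2 <- poly_from_roots(roots)
    expect_lt(max(Mod(p2 - co)), 1e-8)
  }
})

test_that("poles of real signals are closed under conjugation and stable", {
  set.seed(25)
  x <- as.numeric(stats::arima.sim(list(ar = c(0.4, -0.5, 0.2)), 4000))
  rec <- audio_recording(x / max(abs(x)), 1000)
  m <- fit_tvar(rec, tvar_config(window_ms = 400, overlap = 0.5, order = 8))
  z <- tvar_poles(m)$poles
  expect_true(all(Mod(z) < 1))
  for (wi in seq_len(ncol(z))) {
    zs <- z[, wi]
    cmplx <- zs[abs(Im(zs)) > 1e-9]
    # every complex pole's conjugate is present
    for (zk in cmplx)
      expect_lt(min(Mod(zs - Conj(zk))), 1e-6)
  }
})

test_that("resonant frequencies follow theta * fs / (2 pi); real poles excluded", {
  pt <- structure(list(
    poles = matrix(c(complex(modulus = 0.9, argument = pi / 2),
                     complex(modulus = 0.9, argument = -pi / 2),
                     0.8 + 0i), ncol = 1),
    res_freqs = NULL, residues = NULL, powers = NULL,
    times = 0, fs = 1000, hop_s = 0.05, flagged = FALSE),
    class = "pole_track")
  f <- resonant_frequencies(pt)$res_freqs[, 1]
  expect_equal(f[1], 250)
  expect_true(is.na(f[2]))      # lower half plane
  expect_true(is.na(f[3]))      # real axis

  mod <- 0.95; ang <- 0.3 * pi
  m <- manual_model(-c(2 * mod * cos(ang), -mod^2), fs = 10000)
  f2 <- resonant_frequencies(tvar_poles(m))$res_freqs[, 1]
  expect_equal(f2[!is.na(f2)], 1500, tolerance = 1e-6)
})

test_that("residues satisfy the partial-fraction identity", {
  # AR(1): single-pole residue is exactly 1
  m1 <- manual_model(-0.6)
  t1 <- pole_powers(m1, resonant_frequencies(tvar_poles(m1)))
  expect_equal(Re(t1$residues[1, 1]), 1, tolerance = 1e-12)

  # random stable AR(4): sum_k r_k / (1 - z_k z^-1) == H(z) at test points
  set.seed(26)
  for (rep in 1:5) {
    zr <- complex(modulus = runif(2, 0.4, 0.9), argument = runif(2, 0.2, 2.9))
    zs <- c(zr, Conj(zr))
    a <- Re(poly_from_roots(zs))[-1]
    m <- manual_model(a)
    tr <- pole_powers(m, resonant_frequencies(tvar_poles(m)))
    ztest <- complex(modulus = runif(10, 1.1, 3), argument = runif(10, 0, 2 * pi))
    for (zt in ztest) {
      H <- 1 / (1 + sum(a * zt^-(seq_along(a))))
      Hpf <- sum(tr$residues[, 1] / (1 - tr$poles[, 1] / zt))
      expect_lt(Mod(H - Hpf), 1e-6)
    }
  }
})

test_that("the dominant resonance carries more residue power than a weak one", {
  # strong pair at 0.3 pi (modulus 0.95) times weak pair at 0.7 pi (modulus 0.5)
  strong <- complex(modulus = 0.95, argument = 0.3 * pi)
  weak <- complex(modulus = 0.5, argument = 0.7 * pi)
  zs <- c(strong, Conj(strong), weak, Conj(weak))
  m <- manual_model(Re(poly_from_roots(zs))[-1])
  tr <- pole_powers(m, resonant_frequencies(tvar_poles(m)))
  P <- tr$powers[, 1]
  f <- tr$res_freqs[, 1]
  up <- which(!is.na(f))
  strongest <- up[which.max(P[up])]
  expect_equal(f[strongest], 0.15 * 1000, tolerance = 1)
})

test_that("the TV-MEP tracks a known tone and its step, and is stable when the signal is", {
  set.seed(27)
  fs <- 11025
  t <- seq(0, 3 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 2000 * t) + rnorm(length(t), sd = 10^(-0.5))
  rec <- audio_recording(x / max(abs(x)), fs)
  mep <- mep_track(fit_tvar(rec, tvar_config("guidewire")))
  expect_lt(abs(median(mep$values) - 2000), 50)

  # 2 kHz -> 4 kHz step at t = 2 s
  t2 <- seq(0, 4 - 1 / fs, by = 1 / fs)
  f0 <- ifelse(t2 < 2, 2000, 4000)
  x2 <- sin(2 * pi * cumsum(f0) / fs) + rnorm(length(t2), sd = 10^(-0.5))
  rec2 <- audio_recording(x2 / max(abs(x2)), fs)
  mep2 <- mep_track(fit_tvar(rec2, tvar_config("needle")))
  expect_lt(abs(median(mep2$values[mep2$times < 1.8]) - 2000), 50)
  expect_lt(abs(median(mep2$values[mep2$times > 2.2]) - 4000), 50)
  mid <- mep2$values[mep2$times >= 2 - 3 * mep2$hop_s &
                     mep2$times <= 2 + 3 * mep2$hop_s]
  crossed <- which(abs(mep2$values - 4000) < 300)
  expect_lte(abs(mep2$times[min(crossed)] - 2), 3 * mep2$hop_s + 1e-9)

  # stationary AR(2): MEP std at most 5% of its median
  set.seed(28)
  phi <- c(2 * 0.95 * cos(0.3 * pi), -0.95^2)
  x3 <- as.numeric(stats::arima.sim(list(ar = phi), 5 * 11025))
  rec3 <- audio_recording(x3 / max(abs(x3)), 11025)
  mep3 <- mep_track(fit_tvar(rec3, tvar_config("guidewire")))
  expect_lt(sd(mep3$values) / median(mep3$values), 0.05)
})

test_that("a linear resonance drift is recovered within 5% from the MEP", {
  set.seed(29)
  fs <- 11025
  dur <- 4
  n <- dur * fs
  f0 <- seq(1000, 3000, length.out = n)          # 500 Hz/s drift
  y <- aemid:::cpp_tv_resonator(rnorm(n), f0, rep(0.97, n), fs)
  rec <- audio_recording(y / max(abs(y)), fs)
  mep <- mep_track(fit_tvar(rec, tvar_config("guidewire")))
  keep <- mep$times > 0.2 & mep$times < dur - 0.2
  slope <- stats::coef(stats::lm(mep$values[keep] ~ mep$times[keep]))[2]
  expect_lt(abs(slope - 500) / 500, 0.05)
})

test_that("the spectral argmax of each window is near a pole resonant frequency", {
  set.seed(30)
  phi <- c(2 * 0.9 * cos(0.4 * pi), -0.9^2)
  x <- as.numeric(stats::arima.sim(list(ar = phi), 20000))
  rec <- audio_recording(x / max(abs(x)), 1000)
  m <- fit_tvar(rec, tvar_config(window_ms = 1000, overlap = 0.5, order = 6))
  sp <- tvar_spectrum(m, n_freq = 128)
  tr <- resonant_frequencies(tvar_poles(m))
  mep <- mep_track(m)
  bin <- diff(sp$freqs[1:2])
  for (wi in seq_along(m$times)) {
    peak_f <- sp$freqs[which.max(sp$S[, wi])]
    fk <- tr$res_freqs[, wi]
    expect_lt(min(abs(fk - peak_f), na.rm = TRUE), 2 * bin)
    # single dominant well-separated resonance: the MEP is that peak
    expect_lt(abs(mep$values[wi] - peak_f), 2 * bin)
  }
})
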