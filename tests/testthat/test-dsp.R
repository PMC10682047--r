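test_that("bandpass preserves in-band tones and rejects out-of-band content", {
  fs <- 333
  t <- (0:(10 * fs - 1)) / fs
  mid <- sin(2 * pi * 2 * t)
  out <- bandpass(mid, fs, 0.5, 5)
  expect_lt(abs(max(out[500:2500]) - 1), 0.05)

  dc <- rep(1, 2000) + 0.1 * sin(2 * pi * 10 * (1:2000) / fs)
  expect_lt(abs(mean(bandpass(dc, fs, 1, 20))), 0.02)

  comp <- sin(2 * pi * 1 * t) + sin(2 * pi * 50 * t)
  filt <- bandpass(comp, fs, 0.5, 5)
  core <- (fs + 1):(length(t) - fs)  # interior, clear of edge transients
  expect_gt(cor(filt[core], sin(2 * pi * 1 * t)[core]), 0.99)

  expect_error(bandpass(mid, fs, 5, 200), "Nyquist|fs/2")
  expect_error(bandpass(mid, fs, 10, 5), "fs/2")
})

test_that("Welch PSD localizes tones, satisfies Parseval, matches a periodogram", {
  fs <- 333
  t <- (0:(fs * 12 - 1)) / fs
  x <- sin(2 * pi * 10 * t)
  psd <- welch_psd(x, fs, segment_len = 512)
  expect_lt(abs(psd$freq[which.max(psd$power)] - 10), fs / 512 + 1e-9)

  set.seed(1)
  wn <- rnorm(fs * 30)
  p <- welch_psd(wn, fs, segment_len = 256)
  tot <- sum(diff(p$freq) * (head(p$power, -1) + tail(p$power, -1)) / 2)
  expect_lt(abs(tot - var(wn)) / var(wn), 0.05)
  # flatness: more averaging shrinks the coefficient of variation
  p2 <- welch_psd(wn, fs, segment_len = 1024)
  cv <- function(q) sd(q$power) / mean(q$power)
  expect_lt(cv(p), cv(p2))

  # single full-length segment equals a directly computed modified periodogram
  y <- wn[1:1024]
  p3 <- welch_psd(y, fs, segment_len = 1024, overlap = 0, detrend = FALSE)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(1024) / 1025)
  ref <- Mod(fft(y * w)[1:513])^2 / (fs * sum(w^2))
  ref[2:512] <- 2 * ref[2:512]
  expect_equal(p3$power, ref, tolerance = 1e-12)

  expect_error(welch_psd(numeric(0), fs), "Empty")
})

test_that("band SNR behaves like an integrated power ratio", {
  fs <- 333
  t <- (0:(fs * 20 - 1)) / fs
  set.seed(2)
  make <- function(nsd) sin(2 * pi * 30 * t) + rnorm(length(t), 0, nsd)
  snrs <- vapply(c(0.5, 0.2, 0.05), function(nsd) {
    snr_db(make(nsd), fs, c(25, 35), c(60, 120))
  }, numeric(1))
  expect_true(all(diff(snrs) > 0))

  # symmetric bands of a white signal: near 0 dB
  wn <- rnorm(fs * 30)
  expect_lt(abs(snr_db(wn, fs, c(20, 60), c(80, 120))), 1.5)

  silent <- numeric(4096)
  expect_warning(v <- snr_db(silent, fs, c(25, 35), c(150, 160),
                             segment_len = 1024), "infinite")
  expect_true(is.infinite(v))
  expect_error(snr_db(wn, fs, c(20, 60), c(20, 60)), "distinct")
})

test_that("STFT frames match direct windowed FFTs and track tone changes", {
  fs <- 333
  t <- (0:(fs * 4 - 1)) / fs
  x <- ifelse(t < 2, sin(2 * pi * 50 * t), sin(2 * pi * 150 * t))
  sp <- stft_spectrogram(x, fs, win_len = 128, hop = 64)
  ridge <- sp$freqs[apply(sp$magnitude, 2, which.max)]
  expect_lt(max(abs(ridge[sp$times < 1.7] - 50)), 3)
  expect_lt(max(abs(ridge[sp$times > 2.3] - 150)), 3)

  # oracle equivalence: column k = |FFT| of the Hann-windowed slice
  k <- 5
  start <- (k - 1) * 64 + 1
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(128) / 129)
  ref <- Mod(fft(x[start:(start + 127)] * w)[1:65])
  expect_equal(sp$magnitude[, k], ref, tolerance = 1e-12)

  # independent implementation cross-check on the ridge
  sg <- signal::specgram(x, n = 128, Fs = fs, overlap = 64)
  ridge2 <- sg$f[apply(Mod(sg$S), 2, which.max)]
  expect_lt(max(abs(sort(unique(round(ridge2))) - c(50, 150))), 4)

  expect_equal(max(stft_spectrogram(numeric(500), fs, 128, 64)$magnitude), 0)
  expect_error(stft_spectrogram(numeric(50), fs, 128, 64), "win_len")
  expect_error(stft_spectrogram(x, fs, 128, 0), "hop")
})

test_that("vitals are recovered from synthetic recordings and flag degenerate input", {
  rec <- synthesize_recording(hr_bpm = 72, rr_bpm = 16, duration = 30,
                              seed = 3)
  v <- estimate_vitals(rec)
  expect_lt(abs(v$hr_bpm - 72), 2)
  expect_lt(abs(v$rr_bpm - 16), 1)
  expect_true(all(diff(v$hr_peak_times[[1]]) > 0))

  # clean cardiac train at 60 bpm
  prof <- subject_profile(baseline_noise_sd = 1e-9)
  rec2 <- synthesize_recording(hr_bpm = 60, rr_bpm = 12, duration = 30,
                               profile = prof, seed = 4)
  v2 <- estimate_vitals(rec2)
  expect_lt(abs(v2$hr_bpm - 60), 0.5)

  flat <- as_recording(data.frame(ax = numeric(4000), ay = numeric(4000),
                                  az = numeric(4000), semg = numeric(4000)),
                       fs = 333)
  v3 <- estimate_vitals(flat)
  expect_equal(v3$quality_flag, "undefined")
  expect_error(estimate_vitals(synthesize_recording(duration = 5, seed = 1)),
               "10 s")
})

test_that("vitals degrade monotonically with baseline noise", {
  grid <- c(0.005, 0.05, 0.2)
  err <- vapply(grid, function(nsd) {
    e <- 0
    for (i in 1:4) {
      prof <- subject_profile(baseline_noise_sd = nsd)
      rec <- synthesize_recording(hr_bpm = 60 + 10 * i, rr_bpm = 14,
                                  duration = 30, profile = prof,
                                  seed = 50 + i)
      v <- estimate_vitals(rec)
      e <- e + if (is.na(v$hr_bpm)) 60 else abs(v$hr_bpm - (60 + 10 * i))
    }
    e / 4
  }, numeric(1))
  expect_true(all(diff(err) >= 0))
})

test_that("fundamental frequency finds tones and rejects flat spectra", {
  fs <- 333
  t <- (0:(fs * 2 - 1)) / fs
  expect_lt(abs(fundamental_frequency(sin(2 * pi * 120 * t), fs) - 120), 2)
  set.seed(6)
  expect_true(is.na(fundamental_frequency(rnorm(fs * 2), fs)))
  # a talk event sits higher than a swallow event
  talk <- synthesize_event("vowel3", fs, 2, seed = 7)
  sw <- synthesize_event("swallow", fs, 2, seed = 7)
  expect_gt(fundamental_frequency(talk$az, fs),
            fundamental_frequency(sw$az, fs))
  expect_error(fundamental_frequency(numeric(10), fs), "0.5 s")
})
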