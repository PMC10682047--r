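# Spectral characterization and vital-sign decoupling.

#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero-phase) filtering so peak latencies stay aligned with
#' ground truth. `f_lo = 0` degenerates to a low-pass.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param f_lo,f_hi Band edges in Hz, `0 <= f_lo < f_hi < fs/2`.
#' @param order Butterworth order (default 4).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass <- function(x, fs, f_lo, f_hi, order = 4) {
  check_scalar(fs, "fs", lower = 1e-9)
  if (!(f_lo >= 0 && f_lo < f_hi && f_hi < fs / 2)) {
    abort(sprintf("Band [%g, %g] Hz must satisfy 0 <= f_lo < f_hi < fs/2 = %g.",
                  f_lo, f_hi, fs / 2))
  }
  if (!length(x)) abort("Empty signal.")
  bf <- if (f_lo <= 0) {
    signal::butter(order, f_hi / (fs / 2), type = "low")
  } else {
    signal::butter(order, c(f_lo, f_hi) / (fs / 2), type = "pass")
  }
  # odd-reflection padding suppresses the forward-backward edge transients
  n <- length(x)
  pad <- min(n - 1L, as.integer(round(3 * fs / max(f_lo, 0.2))))
  if (pad > 1L) {
    head_pad <- 2 * x[1] - x[(pad + 1L):2L]
    tail_pad <- 2 * x[n] - x[(n - 1L):(n - pad)]
    y <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
    y[(pad + 1L):(pad + n)]
  } else {
    signal::filtfilt(bf, x)
  }
}

#' Welch power spectral density
#'
#' Averaged modified periodograms: the signal is cut into `segment_len`-sample
#' segments with fractional `overlap`, each segment is Hann-windowed and its
#' one-sided periodogram (density scaling, per Hz) accumulated. With one
#' full-length segment the estimate reduces to a single modified periodogram.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param segment_len Segment length in samples (default `min(256, length(x))`).
#' @param overlap Fractional overlap in `[0, 1)` (default 0.5).
#' @param detrend Subtract each segment's mean before windowing (default TRUE).
#' @return A `laryx_psd` tibble with columns `freq` (Hz) and `power`
#'   (signal^2 per Hz).
#' @export
welch_psd <- function(x, fs, segment_len = NULL, overlap = 0.5,
                      detrend = TRUE) {
  if (!length(x)) abort("Empty signal.")
  check_scalar(fs, "fs", lower = 1e-9)
  n <- length(x)
  if (is.null(segment_len)) segment_len <- min(256L, n)
  segment_len <- as.integer(segment_len)
  if (segment_len < 2L || segment_len > n) {
    abort("`segment_len` must be in [2, length(x)].")
  }
  if (overlap < 0 || overlap >= 1) abort("`overlap` must be in [0, 1).")
  hop <- max(1L, as.integer(round(segment_len * (1 - overlap))))
  starts <- seq(1L, n - segment_len + 1L, by = hop)
  w <- hann_window(segment_len)
  scale <- fs * sum(w^2)
  n_freq <- segment_len %/% 2L + 1L
  acc <- numeric(n_freq)
  for (s in starts) {
    seg <- x[s:(s + segment_len - 1L)]
    if (detrend) seg <- seg - mean(seg)
    X <- fft(seg * w)[seq_len(n_freq)]
    p <- (Mod(X)^2) / scale
    # one-sided: double everything except DC and (for even lengths) Nyquist
    dbl <- rep(2, n_freq)
    dbl[1] <- 1
    if (segment_len %% 2L == 0L) dbl[n_freq] <- 1
    acc <- acc + p * dbl
  }
  out <- tibble(freq = (seq_len(n_freq) - 1) * fs / segment_len,
                power = acc / length(starts))
  attr(out, "method") <- "welch"
  attr(out, "fs") <- fs
  attr(out, "segment_len") <- segment_len
  attr(out, "overlap") <- overlap
  class(out) <- c("laryx_psd", class(out))
  out
}

# Integrate PSD power over a frequency band (trapezoidal).
band_power <- function(psd, band) {
  sel <- psd$freq >= band[1] & psd$freq <= band[2]
  if (sum(sel) < 2L) return(0)
  f <- psd$freq[sel]
  p <- psd$power[sel]
  sum(diff(f) * (head(p, -1) + tail(p, -1)) / 2)
}

#' Band signal-to-noise ratio in dB
#'
#' `10 log10` of the ratio of Welch-PSD power integrated over the signal band
#' to that over the noise band. A zero noise-band power yields `Inf` with a
#' warning so callers can flag it distinctly.
#'
#' @inheritParams welch_psd
#' @param signal_band,noise_band Two-element `c(lo, hi)` bands in Hz, inside
#'   Nyquist.
#' @return SNR in dB (possibly `Inf`).
#' @export
snr_db <- function(x, fs, signal_band, noise_band, segment_len = NULL,
                   overlap = 0.5) {
  for (b in list(signal_band, noise_band)) {
    if (length(b) != 2L || b[1] < 0 || b[1] >= b[2] || b[2] > fs / 2) {
      abort("Bands must be c(lo, hi) with 0 <= lo < hi <= fs/2.")
    }
  }
  if (identical(signal_band, noise_band)) {
    abort("Signal and noise bands must be distinct.")
  }
  psd <- welch_psd(x, fs, segment_len, overlap)
  ps <- band_power(psd, signal_band)
  pn <- band_power(psd, noise_band)
  if (pn <= 0) {
    warn("Noise-band power is zero; SNR is infinite.")
    return(Inf)
  }
  10 * log10(ps / pn)
}

#' Short-time Fourier transform magnitude spectrogram
#'
#' Hann-windowed frames of `win_len` samples every `hop` samples; each column
#' of the magnitude matrix is the one-sided FFT magnitude of one frame.
#'
#' @inheritParams welch_psd
#' @param win_len Frame length in samples.
#' @param hop Hop between frame starts in samples, `0 < hop <= win_len`.
#' @return A `laryx_spectrogram` list with `times` (frame centers, s),
#'   `freqs` (Hz) and `magnitude` (`|freqs| x |times|`).
#' @export
stft_spectrogram <- function(x, fs, win_len = 256, hop = win_len %/% 2) {
  if (!length(x)) abort("Empty signal.")
  win_len <- as.integer(win_len)
  hop <- as.integer(hop)
  if (win_len > length(x)) abort("`win_len` exceeds the signal length.")
  if (hop < 1L || hop > win_len) abort("`hop` must satisfy 0 < hop <= win_len.")
  starts <- seq(1L, length(x) - win_len + 1L, by = hop)
  w <- hann_window(win_len)
  n_freq <- win_len %/% 2L + 1L
  mag <- vapply(starts, function(s) {
    Mod(fft(x[s:(s + win_len - 1L)] * w)[seq_len(n_freq)])
  }, numeric(n_freq))
  out <- list(times = (starts - 1 + win_len / 2) / fs,
              freqs = (seq_len(n_freq) - 1) * fs / win_len,
              magnitude = matrix(mag, nrow = n_freq))
  class(out) <- "laryx_spectrogram"
  out
}

#' @export
print.laryx_spectrogram <- function(x, ...) {
  cat(sprintf("<laryx_spectrogram> %d freqs x %d frames, %.1f-%.1f Hz, %.2f-%.2f s\n",
              length(x$freqs), length(x$times), min(x$freqs), max(x$freqs),
              min(x$times), max(x$times)))
  invisible(x)
}

# Peak detection: local maxima above mean + k*sd, with a refractory interval.
# Returns sample indices (1-based). Ties inside the refractory window keep the
# first-occurring peak.
detect_peaks <- function(x, fs, refractory, k = 0.5) {
  thr <- mean(x) + k * sd(x)
  if (!is.finite(thr)) return(integer())
  pk <- pracma::findpeaks(x, minpeakheight = thr,
                          minpeakdistance = max(1L, round(refractory * fs)))
  if (is.null(pk)) return(integer())
  sort(pk[, 2])
}

#' Decouple heart rate and respiration rate from a recording
#'
#' Heart rate comes from the z-axis acceleration band-passed to `hr_band`
#' followed by refractory peak detection (refractory 0.35 s); respiration rate
#' from the y-axis in `rr_band` (refractory 1.5 s, computed on a decimated
#' copy for numerical robustness of the very-low-frequency filter). Rates are
#' `60 / mean(inter-peak interval)`. With fewer than two peaks on either
#' channel the estimate is flagged `undefined`.
#'
#' @param recording A `laryx_recording` (>= 10 s).
#' @param hr_band,rr_band Analysis bands in Hz; defaults bracket physiological
#'   rates (0.6-20 Hz cardiac on z, 0.1-0.7 Hz respiratory on y).
#' @return A one-row `laryx_vitals` tibble: `hr_bpm`, `rr_bpm`,
#'   `quality_flag` (`ok`, `low_confidence`, `undefined`) and list-columns
#'   `hr_peak_times`, `rr_peak_times` (seconds).
#' @export
estimate_vitals <- function(recording, hr_band = c(0.6, 20),
                            rr_band = c(0.1, 0.7)) {
  fs <- recording_fs(recording)
  if (nrow(recording) < 10 * fs) {
    abort("Vitals estimation needs at least 10 s of signal.")
  }
  hr <- rr <- NA_real_
  hr_t <- rr_t <- numeric()

  az <- recording$az
  if (sd(az) > .Machine$double.eps) {
    azf <- bandpass(az, fs, hr_band[1], hr_band[2])
    idx <- detect_peaks(azf, fs, refractory = 0.35)
    if (length(idx) >= 2L) {
      hr_t <- (idx - 1) / fs
      hr <- 60 / mean(diff(hr_t))
    }
  }

  ay <- recording$ay
  if (sd(ay) > .Machine$double.eps) {
    # decimate to ~33 Hz so the 0.1-0.7 Hz Butterworth stays well conditioned
    dec <- max(1L, floor(fs / 33))
    ayl <- bandpass(ay, fs, 0, min(0.45 * fs / dec, fs / 2 * 0.9))
    ayd <- ayl[seq(1L, length(ayl), by = dec)]
    fsd <- fs / dec
    ayf <- bandpass(ayd, fsd, rr_band[1], rr_band[2])
    idx <- detect_peaks(ayf, fsd, refractory = 1.5, k = 0)
    if (length(idx) >= 2L) {
      rr_t <- (idx - 1) / fsd
      rr <- 60 / mean(diff(rr_t))
    }
  }

  flag <- if (is.na(hr) || is.na(rr)) {
    "undefined"
  } else if (length(hr_t) < 5L || length(rr_t) < 3L) {
    "low_confidence"
  } else {
    "ok"
  }
  out <- tibble(hr_bpm = hr, rr_bpm = rr, quality_flag = flag,
                hr_peak_times = list(hr_t), rr_peak_times = list(rr_t))
  class(out) <- c("laryx_vitals", class(out))
  out
}

#' Fundamental frequency of a signal
#'
#' The dominant Welch-spectrum peak above a noise floor (10x the median
#' spectral density). Returns `NA` when the spectrum is flat (no peak clears
#' the floor), e.g. for white noise.
#'
#' @inheritParams welch_psd
#' @param f_min Ignore spectral content below this frequency (default 1 Hz).
#' @return Fundamental frequency in Hz, or `NA_real_` when undefined.
#' @export
fundamental_frequency <- function(x, fs, f_min = 1) {
  if (length(x) < 0.5 * fs) abort("Need at least 0.5 s of signal.")
  # enough segment averaging that a flat spectrum stays below the peak floor
  seg <- 2^floor(log2(length(x) / 4))
  seg <- max(64L, min(1024L, seg))
  psd <- welch_psd(x, fs, segment_len = min(length(x), seg))
  sel <- psd$freq >= f_min
  p <- psd$power[sel]
  f <- psd$freq[sel]
  floor_p <- 10 * median(p)
  i <- which.max(p)
  if (p[i] <= floor_p) return(NA_real_)
  f[i]
}
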