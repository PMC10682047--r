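# Seeded simulator of neck-worn triaxial acceleration + sEMG recordings.
#
# Axis conventions follow the device: z is the skin-normal axis carrying
# cardiac micro-vibrations and laryngeal event energy, y carries respiration
# and whole-body locomotion, x is a weakly coupled lateral axis. Acceleration
# is in g, sEMG in arbitrary units, time in seconds.

#' Natural duration of an event kind
#'
#' Default event durations (seconds) used by the cohort generator.
#'
#' @param kind An event kind (see [laryx_event_kinds()]).
#' @return Duration in seconds.
#' @export
default_event_duration <- function(kind) kind_default_duration(kind)

# Default natural durations (s) per event kind, used by the cohort generator.
kind_default_duration <- function(kind) {
  switch(kind,
    swallow = 1.5, drink = 3, cough = 0.8,
    walk = 3, jump = 2.5, chew = 3, nod = 3, choke = 2, rest = 2,
    1.5 # acoustic classes
  )
}

#' Acoustic class spectral templates
#'
#' Each of the ten acoustic classes (five pinyin, five vowel surrogates) has a
#' fixed pair of "formant" band centers on an alias-free grid below the
#' 333 Hz Nyquist limit: class `i` (in canonical order) is centered at
#' `49 + 11 i` Hz with formants 6 Hz either side, so neighboring class
#' centroids are 11 Hz apart and all energy stays in the laryngeal band.
#'
#' @param kind An acoustic class name, e.g. `"pinyin3"` or `"vowel1"`.
#' @return A list with `f1`, `f2` (Hz) and `centroid` (their mean).
#' @export
acoustic_template <- function(kind) {
  acoustic <- laryx_classes()[1:10]
  i <- match(kind, acoustic)
  if (is.na(i)) abort(sprintf("`%s` is not an acoustic class.", kind))
  centroid <- 49 + 11 * i
  list(f1 = centroid - 6, f2 = centroid + 6, centroid = centroid)
}

is_acoustic <- function(kind) kind %in% laryx_classes()[1:10]
is_laryngeal <- function(kind) kind %in% laryx_classes()

# Band-limited Gaussian noise carrier, unit standard deviation.
noise_carrier <- function(n, fs, f_lo, f_hi) {
  x <- rnorm(n)
  f_hi <- min(f_hi, 0.45 * fs)
  bf <- signal::butter(4, c(f_lo, f_hi) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)
  s <- sd(y)
  if (s < .Machine$double.eps) return(numeric(n))
  y / s
}

# Normalize a waveform to unit peak magnitude (zero stays zero).
peak_norm <- function(x) {
  m <- max(abs(x))
  if (m < .Machine$double.eps) x else x / m
}

# Smooth multi-burst envelope: Gaussian bumps at fractional `centers` with
# fractional `widths`, peak-normalized to 1.
burst_envelope <- function(n, centers, widths) {
  u <- seq(0, 1, length.out = n)
  env <- rowSums(vapply(seq_along(centers), function(k) {
    exp(-0.5 * ((u - centers[k]) / widths[k])^2)
  }, numeric(n)))
  env / max(env)
}

#' Synthesize cardiac micro-vibrations on the z-axis
#'
#' Generates a quasi-periodic train of triphasic wavelets (an upward R-like
#' lobe, a downward S-like lobe and a smaller upward T-like lobe, each a
#' Gaussian window with latencies fixed as fractions of the cardiac cycle)
#' riding on a weak sinusoidal component at the cardiac fundamental. Cycle
#' lengths are perturbed by at most 2 percent.
#'
#' @param hr_bpm Heart rate in beats per minute, within `[30, 220]`.
#' @param fs Sampling rate in Hz.
#' @param duration Length of the generated vector in seconds; must contain at
#'   least two beats.
#' @param profile A [subject_profile()]; `cardiac_amp` sets the wavelet peak
#'   amplitude in g.
#' @param seed Integer seed; equal seeds give identical output.
#' @return Numeric vector of z-axis acceleration in g.
#' @export
synthesize_cardiac <- function(hr_bpm, fs, duration,
                               profile = subject_profile(), seed = 1) {
  check_scalar(hr_bpm, "hr_bpm", lower = 30, upper = 220)
  check_scalar(fs, "fs", lower = 1)
  check_scalar(duration, "duration", lower = 0)
  period <- 60 / hr_bpm
  if (duration < 2 * period) {
    abort("`duration` must contain at least two cardiac cycles.")
  }
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  with_seed(seed, {
    # beat times with <=2% cycle jitter
    n_beats <- ceiling(duration / period) + 2L
    jit <- pmin(pmax(rnorm(n_beats, 0, 0.008), -0.02), 0.02)
    beats <- cumsum(period * (1 + jit))
    beats <- beats - beats[1] + 0.4 * period
    z <- numeric(n)
    # Wide Gaussian lobes keep the train's fundamental dominant in the PSD
    # while only the R lobe rises above the peak-detection threshold.
    lobes <- list(
      list(lat = 0.00, sig = 0.050, amp = 1.0),    # R
      list(lat = 0.09, sig = 0.040, amp = -0.45),  # S
      list(lat = 0.30, sig = 0.120, amp = 0.18)    # T
    )
    for (tb in beats) {
      lo <- max(1L, floor((tb - 0.5 * period) * fs) + 1L)
      hi <- min(n, ceiling((tb + 0.6 * period) * fs) + 1L)
      if (lo > hi) next
      tt <- t[lo:hi] - tb
      w <- numeric(length(tt))
      for (lb in lobes) {
        w <- w + lb$amp * exp(-0.5 * ((tt - lb$lat * period) / (lb$sig * period))^2)
      }
      z[lo:hi] <- z[lo:hi] + w
    }
    # beat-locked baseline oscillation: keeps the PSD fundamental dominant
    # and its maxima coincide with the R lobes, so peak detection sees one
    # local maximum per cycle
    z <- z + 0.35 * cos(2 * pi * (hr_bpm / 60) * (t - beats[1]))
    profile$cardiac_amp * z
  })
}

#' Synthesize the respiratory oscillation on the y-axis
#'
#' A smooth low-frequency oscillation at the respiration fundamental with two
#' weak harmonics (relative amplitudes 0.2 and 0.05) and a random phase.
#'
#' @param rr_bpm Respiration rate in breaths per minute, within `[5, 60]`.
#' @inheritParams synthesize_cardiac
#' @return Numeric vector of y-axis acceleration in g.
#' @export
synthesize_respiration <- function(rr_bpm, fs, duration,
                                   profile = subject_profile(), seed = 1) {
  check_scalar(rr_bpm, "rr_bpm", lower = 5, upper = 60)
  check_scalar(fs, "fs", lower = 1)
  check_scalar(duration, "duration", lower = 1e-9)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  f0 <- rr_bpm / 60
  with_seed(seed, {
    phi <- runif(1, 0, 2 * pi)
    profile$resp_amp * (sin(2 * pi * f0 * t + phi) +
                          0.2 * sin(2 * pi * 2 * f0 * t + 2 * phi) +
                          0.05 * sin(2 * pi * 3 * f0 * t + 3 * phi))
  })
}

#' Synthesize one event's channel contributions
#'
#' Laryngeal events (the 13 feature states) concentrate band-limited energy on
#' the z-axis with peak amplitude below 0.4 g; locomotion (`walk`, `jump`)
#' puts large low-frequency motion (fundamental below 5 Hz) on the y-axis;
#' motion artifacts (`chew`, `nod`, `choke`) contaminate all axes at low
#' frequency. Acoustic classes use their fixed formant-pair templates (see
#' [acoustic_template()]) perturbed by the subject's `spectral_jitter`, and
#' swallowing/drinking/coughing events carry a co-timed sEMG activation
#' envelope.
#'
#' @param kind One of [laryx_event_kinds()].
#' @param intensity Dimensionless amplitude scale in `(0, 1]`.
#' @inheritParams synthesize_cardiac
#' @return A list of vectors `ax`, `ay`, `az` (g) and `semg_env` (a.u., all
#'   `>= 0`), each of length `round(duration * fs)`.
#' @export
synthesize_event <- function(kind, fs, duration, intensity = 1,
                             profile = subject_profile(), seed = 1) {
  if (!is.character(kind) || length(kind) != 1L ||
      !(kind %in% laryx_event_kinds())) {
    abort(sprintf("Unknown event kind `%s`.", paste(kind, collapse = "/")))
  }
  check_scalar(fs, "fs", lower = 1)
  check_scalar(duration, "duration", lower = 1e-9)
  check_scalar(intensity, "intensity", lower = 0, upper = 1)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  ax <- ay <- az <- semg_env <- numeric(n)
  with_seed(seed, {
    if (is_acoustic(kind)) {
      tmpl <- acoustic_template(kind)
      j <- profile$spectral_jitter
      f1 <- tmpl$f1 * (1 + j * runif(1, -1, 1))
      f2 <- tmpl$f2 * (1 + j * runif(1, -1, 1))
      env <- sin(pi * seq_len(n) / (n + 1))^2
      carrier <- 0.65 * sin(2 * pi * f1 * t + runif(1, 0, 2 * pi)) +
        0.45 * sin(2 * pi * f2 * t + runif(1, 0, 2 * pi))
      az <- 0.18 * intensity * env * carrier
      ax <- 0.08 * az
      ay <- 0.05 * az
      semg_env <- 0.5 * intensity * env
    } else if (kind == "swallow") {
      env <- burst_envelope(n, c(0.3, 0.65), c(0.10, 0.12))
      az <- 0.25 * intensity * peak_norm(env * noise_carrier(n, fs, 30, 90))
      ax <- 0.05 * az
      semg_env <- intensity * env
    } else if (kind == "drink") {
      env <- burst_envelope(n, c(0.2, 0.5, 0.8), c(0.07, 0.07, 0.07))
      az <- 0.20 * intensity * peak_norm(env * noise_carrier(n, fs, 20, 60))
      ax <- 0.05 * az
      semg_env <- 0.9 * intensity * env
    } else if (kind == "cough") {
      u <- seq(0, 1, length.out = n)
      env <- (u / 0.12) * exp(1 - u / 0.12)  # sharp attack, exponential decay
      env <- pmin(env, 1)
      az <- 0.32 * intensity * peak_norm(env * noise_carrier(n, fs, 40, 140))
      ay <- 0.10 * intensity * env * noise_carrier(n, fs, 1, 8)
      semg_env <- 0.7 * intensity * env
    } else if (kind %in% c("walk", "jump")) {
      f0 <- if (kind == "walk") 1.8 else 2.5
      f0 <- f0 * (0.9 + 0.2 * runif(1))
      amp <- if (kind == "walk") 0.8 else 1.2
      phi <- runif(1, 0, 2 * pi)
      env <- sin(pi * seq_len(n) / (n + 1))^0.5
      ay <- amp * intensity * env * (sin(2 * pi * f0 * t + phi) +
                                       0.3 * sin(2 * pi * 2 * f0 * t))
      az <- 0.25 * amp * intensity * env * sin(2 * pi * f0 * t + phi + 0.8)
      ax <- 0.15 * amp * intensity * env * sin(2 * pi * f0 * t + phi + 2.1)
    } else if (kind == "chew") {
      f0 <- 1.5 * (0.9 + 0.2 * runif(1))
      phi <- runif(1, 0, 2 * pi)
      rhythmic <- abs(sin(2 * pi * f0 / 2 * t + phi))
      broad <- noise_carrier(n, fs, 0.5, 8)
      ax <- 0.06 * intensity * (sin(2 * pi * f0 * t + phi) + 0.4 * broad)
      ay <- 0.05 * intensity * (sin(2 * pi * f0 * t + phi + 1.3) + 0.4 * broad)
      az <- 0.08 * intensity * (sin(2 * pi * f0 * t + phi + 0.6) + 0.4 * broad)
      semg_env <- 0.3 * intensity * rhythmic
    } else if (kind == "nod") {
      f0 <- 0.7 * (0.85 + 0.3 * runif(1))
      phi <- runif(1, 0, 2 * pi)
      ax <- 0.12 * intensity * sin(2 * pi * f0 * t + phi)
      ay <- 0.10 * intensity * sin(2 * pi * f0 * t + phi + 0.9)
      az <- 0.15 * intensity * sin(2 * pi * f0 * t + phi + 1.7)
    } else if (kind == "choke") {
      n_b <- sample(3:5, 1)
      env <- burst_envelope(n, sort(runif(n_b, 0.1, 0.9)),
                            rep(0.04, n_b))
      az <- 0.30 * intensity * peak_norm(env * noise_carrier(n, fs, 20, 100))
      ay <- 0.15 * intensity * env * noise_carrier(n, fs, 1, 10)
      ax <- 0.05 * az
      semg_env <- 0.8 * intensity * env
    } # rest: all zeros
    list(ax = ax, ay = ay, az = az, semg_env = pmax(semg_env, 0))
  })
}

#' Synthesize a surface-EMG trace from an activation envelope
#'
#' A zero-mean stochastic carrier band-limited to 20-150 Hz (or 0.45 fs if
#' lower) is amplitude-modulated by `envelope * semg_gain`; the subject's
#' noise floor is added on top. With an all-zero envelope the output is
#' baseline noise only.
#'
#' @param envelope Non-negative activation envelope, one value per sample.
#' @inheritParams synthesize_cardiac
#' @return Numeric vector of sEMG in arbitrary units.
#' @export
synthesize_semg <- function(envelope, fs, profile = subject_profile(),
                            seed = 1) {
  check_scalar(fs, "fs", lower = 1)
  if (any(envelope < 0)) abort("sEMG activation envelope must be >= 0.")
  n <- length(envelope)
  if (n == 0L) abort("Empty envelope.")
  with_seed(seed, {
    out <- rnorm(n, 0, profile$baseline_noise_sd)
    if (any(envelope > 0) && n > 24) {
      carrier <- noise_carrier(n, fs, 20, 150)
      out <- out + carrier * envelope * profile$semg_gain
    }
    out
  })
}

#' Synthesize a complete labeled recording
#'
#' Additively superposes cardiac micro-vibrations (z-axis), respiration
#' (y-axis), all scheduled events, white baseline noise, and an sEMG channel
#' driven by the summed activation envelopes. Annotations are preserved
#' verbatim; the same seed reproduces the recording bit for bit.
#'
#' @param schedule An [event_schedule()] tibble (may be empty, may overlap).
#' @param hr_bpm,rr_bpm Vital-sign ground truth for the cardiac and
#'   respiratory components.
#' @inheritParams synthesize_cardiac
#' @return A `laryx_recording` tibble with columns `t, ax, ay, az, semg` and
#'   metadata attributes `fs`, `profile`, `annotations`, `seed`.
#' @export
synthesize_recording <- function(schedule = event_schedule(),
                                 hr_bpm = 72, rr_bpm = 16,
                                 fs = 333, duration = 10,
                                 profile = subject_profile(), seed = 1) {
  check_scalar(duration, "duration", lower = 1e-9)
  if (nrow(schedule)) {
    if (any(schedule$onset + schedule$duration > duration + 1e-9)) {
      abort("Scheduled events must lie within the recording duration.")
    }
    dup <- duplicated(schedule[, c("kind", "onset")])
    if (any(dup)) {
      warn("Overlapping identical-kind events at identical onsets; generating anyway.")
    }
  }
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  az <- synthesize_cardiac(hr_bpm, fs, duration, profile, derive_seed(seed, 1))
  ay <- synthesize_respiration(rr_bpm, fs, duration, profile, derive_seed(seed, 2))
  ax <- numeric(n)
  env <- numeric(n)
  if (nrow(schedule)) {
    for (i in seq_len(nrow(schedule))) {
      ev <- synthesize_event(schedule$kind[i], fs, schedule$duration[i],
                             schedule$intensity[i], profile,
                             derive_seed(seed, 10 + i))
      i0 <- round(schedule$onset[i] * fs)
      idx <- seq_len(length(ev$az)) + i0
      keep <- idx <= n
      idx <- idx[keep]
      ax[idx] <- ax[idx] + ev$ax[keep]
      ay[idx] <- ay[idx] + ev$ay[keep]
      az[idx] <- az[idx] + ev$az[keep]
      env[idx] <- env[idx] + ev$semg_env[keep]
    }
  }
  noise <- with_seed(derive_seed(seed, 3),
                     matrix(rnorm(3 * n, 0, profile$baseline_noise_sd), ncol = 3))
  semg <- synthesize_semg(env, fs, profile, derive_seed(seed, 4))
  new_recording(t, ax + noise[, 1], ay + noise[, 2], az + noise[, 3], semg,
                fs, profile, schedule, seed)
}

#' Synthesize a multi-subject labeled cohort
#'
#' Each subject receives an independent seeded [subject_profile()] (log-normal
#' amplitude/gain variation around the defaults) and per-subject vitals; each
#' requested class is recorded `reps_per_class` times per subject as a short
#' recording containing one annotated event. The result supports
#' subject-disjoint train/test splits.
#'
#' @param n_subjects Number of subjects (`>= 2` so a holdout exists).
#' @param classes Event kinds to record; defaults to the 13 feature states.
#' @param reps_per_class Recordings per class per subject.
#' @param recording_duration Per-recording duration in seconds.
#' @param spectral_jitter,baseline_noise_sd Cohort-wide profile parameters.
#' @inheritParams synthesize_cardiac
#' @return A `laryx_cohort` tibble with columns `subject_id, kind, rep,
#'   hr_bpm, rr_bpm, recording` (list-column of `laryx_recording`).
#' @export
synthesize_cohort <- function(n_subjects, classes = laryx_classes(),
                              reps_per_class = 1, fs = 333, seed = 1,
                              recording_duration = 4,
                              spectral_jitter = 0.05,
                              baseline_noise_sd = 0.005) {
  if (!is.numeric(n_subjects) || n_subjects < 2) {
    abort("`n_subjects` must be >= 2 so a subject holdout is possible.")
  }
  bad <- setdiff(classes, laryx_event_kinds())
  if (length(bad)) abort(paste0("Unknown classes: ", paste(bad, collapse = ", ")))
  rows <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", s)
    prof_seed <- derive_seed(seed, s)
    prof <- with_seed(prof_seed, subject_profile(
      subject_id = sid,
      cardiac_amp = 0.02 * exp(rnorm(1, 0, 0.2)),
      resp_amp = 0.05 * exp(rnorm(1, 0, 0.2)),
      semg_gain = exp(rnorm(1, 0, 0.15)),
      spectral_jitter = spectral_jitter,
      baseline_noise_sd = baseline_noise_sd
    ))
    vit <- with_seed(derive_seed(seed, 1000 + s),
                     c(hr = runif(1, 60, 90), rr = runif(1, 12, 18)))
    for (ci in seq_along(classes)) {
      for (r in seq_len(reps_per_class)) {
        kind <- classes[ci]
        dur <- min(kind_default_duration(kind), recording_duration - 1)
        sched <- event_schedule(kind, onset = 0.5, duration = dur,
                                intensity = 1)
        rec_seed <- derive_seed(seed, s * 100000 + ci * 100 + r)
        rec <- synthesize_recording(sched, hr_bpm = vit[["hr"]],
                                    rr_bpm = vit[["rr"]], fs = fs,
                                    duration = recording_duration,
                                    profile = prof, seed = rec_seed)
        rows[[length(rows) + 1L]] <- tibble(
          subject_id = sid, kind = kind, rep = r,
          hr_bpm = vit[["hr"]], rr_bpm = vit[["rr"]],
          recording = list(rec)
        )
      }
    }
  }
  cohort <- dplyr::bind_rows(rows)
  attr(cohort, "seed") <- seed
  attr(cohort, "fs") <- fs
  class(cohort) <- c("laryx_cohort", class(cohort))
  cohort
}
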