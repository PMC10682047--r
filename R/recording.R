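#' Event kinds and classifier classes
#'
#' The simulator knows 15 event kinds. Thirteen of them are the classifier's
#' feature states: five pinyin and five vowel speech surrogates (acoustic
#' states) plus the swallowing, drinking-water and coughing behaviors.
#' Locomotion (`walk`, `jump`) and motion artifacts (`chew`, `nod`, `choke`)
#' are contamination sources, and `rest` is quiet baseline.
#'
#' @return `laryx_event_kinds()` returns all simulatable kinds;
#'   `laryx_classes()` returns the 13 classifier feature states in canonical
#'   order.
#' @export
laryx_event_kinds <- function() {
  c(laryx_classes(), "walk", "jump", "chew", "nod", "choke", "rest")
}

#' @rdname laryx_event_kinds
#' @export
laryx_classes <- function() {
  c(paste0("pinyin", 1:5), paste0("vowel", 1:5), "swallow", "drink", "cough")
}

#' Subject profile for the recording simulator
#'
#' Between-subject variation is captured by a small set of per-subject scales:
#' the cardiac and respiratory acceleration amplitudes on the z- and y-axes,
#' an sEMG gain, a fractional jitter applied to the acoustic-class formant
#' frequencies, and the white baseline noise level of the accelerometer.
#'
#' @param subject_id Character subject label.
#' @param cardiac_amp Peak amplitude of the cardiac micro-vibration wavelets
#'   on the z-axis, in g. Default 0.02 g.
#' @param resp_amp Amplitude of the respiratory oscillation on the y-axis, in
#'   g. Default 0.05 g.
#' @param semg_gain Dimensionless gain applied to sEMG activation envelopes.
#' @param spectral_jitter Fractional perturbation (in `[0, 0.5]`) applied to
#'   each acoustic class's formant center frequencies for this subject.
#' @param baseline_noise_sd Standard deviation of white accelerometer noise,
#'   in g (also used, in arbitrary units, as the sEMG noise floor).
#' @return A `laryx_profile` list.
#' @export
subject_profile <- function(subject_id = "S01",
                            cardiac_amp = 0.02,
                            resp_amp = 0.05,
                            semg_gain = 1,
                            spectral_jitter = 0.05,
                            baseline_noise_sd = 0.005) {
  check_scalar(cardiac_amp, "cardiac_amp", lower = 1e-9)
  check_scalar(resp_amp, "resp_amp", lower = 1e-9)
  check_scalar(semg_gain, "semg_gain", lower = 1e-9)
  check_scalar(spectral_jitter, "spectral_jitter", lower = 0, upper = 0.5)
  check_scalar(baseline_noise_sd, "baseline_noise_sd", lower = 0)
  structure(
    list(subject_id = as.character(subject_id),
         cardiac_amp = cardiac_amp,
         resp_amp = resp_amp,
         semg_gain = semg_gain,
         spectral_jitter = spectral_jitter,
         baseline_noise_sd = baseline_noise_sd),
    class = "laryx_profile"
  )
}

#' @export
print.laryx_profile <- function(x, ...) {
  cat("<laryx_profile>", x$subject_id,
      sprintf("cardiac %.3g g, resp %.3g g, sEMG gain %.3g, jitter %.3g, noise %.3g g\n",
              x$cardiac_amp, x$resp_amp, x$semg_gain, x$spectral_jitter,
              x$baseline_noise_sd))
  invisible(x)
}

#' Event annotation table
#'
#' @param kind Character vector of event kinds (see [laryx_event_kinds()]).
#' @param onset,duration Event onset and duration in seconds.
#' @param intensity Dimensionless scale in `(0, 1]` applied to event
#'   amplitudes.
#' @return A tibble with one row per event.
#' @export
event_schedule <- function(kind = character(), onset = numeric(),
                           duration = numeric(), intensity = 1) {
  kind <- as.character(kind)
  bad <- setdiff(kind, laryx_event_kinds())
  if (length(bad)) {
    abort(paste0("Unknown event kind(s): ", paste(bad, collapse = ", ")))
  }
  if (any(onset < 0)) abort("Event onsets must be >= 0 s.")
  if (any(duration <= 0)) abort("Event durations must be > 0 s.")
  tibble(kind = kind, onset = as.numeric(onset),
         duration = as.numeric(duration),
         intensity = rep_len(as.numeric(intensity), length(kind)))
}

# Recording constructor: a tibble of samples carrying acquisition metadata.
new_recording <- function(t, ax, ay, az, semg, fs, profile, annotations, seed) {
  n <- length(t)
  stopifnot(length(ax) == n, length(ay) == n, length(az) == n,
            length(semg) == n)
  rec <- tibble(t = t, ax = ax, ay = ay, az = az, semg = semg)
  attr(rec, "fs") <- fs
  attr(rec, "profile") <- profile
  attr(rec, "annotations") <- annotations
  attr(rec, "seed") <- seed
  class(rec) <- c("laryx_recording", class(rec))
  rec
}

#' Wrap tabular channel data as a recording
#'
#' Builds a `laryx_recording` from a data frame of samples, e.g. data imported
#' from a device export. Column `t` is derived from `fs` when absent.
#'
#' @param data A data frame with numeric columns `ax`, `ay`, `az`, `semg`
#'   (and optionally `t`).
#' @param fs Sampling rate in Hz.
#' @param profile A [subject_profile()] (metadata only).
#' @param annotations An [event_schedule()] tibble.
#' @param seed Optional provenance seed recorded as metadata.
#' @return A `laryx_recording`.
#' @export
as_recording <- function(data, fs, profile = subject_profile(),
                         annotations = event_schedule(), seed = NA_integer_) {
  check_scalar(fs, "fs", lower = 1e-9)
  need <- c("ax", "ay", "az", "semg")
  if (!all(need %in% names(data))) {
    abort("`data` needs numeric columns ax, ay, az, semg.")
  }
  n <- nrow(data)
  if (!n) abort("`data` has no rows.")
  t <- if ("t" %in% names(data)) data$t else (seq_len(n) - 1) / fs
  new_recording(t, data$ax, data$ay, data$az, data$semg, fs, profile,
                annotations, seed)
}

#' Recording accessors
#'
#' @param recording A `laryx_recording` tibble produced by
#'   [synthesize_recording()] or [read_recording()].
#' @return `recording_fs()` the sampling rate in Hz; `recording_annotations()`
#'   the event table; `recording_profile()` the subject profile;
#'   `recording_channels()` the numeric channel matrix (samples x 4).
#' @export
recording_fs <- function(recording) attr(recording, "fs")

#' @rdname recording_fs
#' @export
recording_annotations <- function(recording) attr(recording, "annotations")

#' @rdname recording_fs
#' @export
recording_profile <- function(recording) attr(recording, "profile")

#' @rdname recording_fs
#' @export
recording_channels <- function(recording) {
  as.matrix(recording[, c("ax", "ay", "az", "semg")])
}

#' @export
print.laryx_recording <- function(x, ...) {
  fs <- recording_fs(x)
  ann <- recording_annotations(x)
  cat(sprintf("<laryx_recording> %d samples @ %g Hz (%.2f s), subject %s, %d annotation(s)\n",
              nrow(x), fs, nrow(x) / fs,
              recording_profile(x)$subject_id,
              if (is.null(ann)) 0L else nrow(ann)))
  NextMethod()
}
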