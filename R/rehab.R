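# Clinical-style rehabilitation outputs: per-behavior normal/abnormal flags,
# the eight-level swallowing/drinking/talking (S/D/T) state, and the clinical
# swallow-timing safety rules (< 3 s to circumpharyngeal opening, < 15 s total
# ingestion; both strict).

rehab_behaviors <- c("swallowing", "drinking", "talking")

# Level table: abnormal-behavior count first, ties by severity priority
# S > D > T (abnormal swallowing is worst). I = all normal ... VIII = all
# abnormal.
rehab_level_table <- function() {
  tibble(
    level = 1:8,
    roman = as.character(utils::as.roman(1:8)),
    swallowing = c("normal", "normal", "normal", "abnormal",
                   "normal", "abnormal", "abnormal", "abnormal"),
    drinking = c("normal", "normal", "abnormal", "normal",
                 "abnormal", "normal", "abnormal", "abnormal"),
    talking = c("normal", "abnormal", "normal", "normal",
                "abnormal", "abnormal", "normal", "abnormal")
  )
}

#' Swallow timing against the clinical rhythm standard
#'
#' Detects activity bursts in a segmented swallow signal via a moving-RMS
#' envelope. The time from signal onset to the first burst peak proxies the
#' indicator-in-mouth to circumpharyngeal-opening interval and must be under
#' 3 s (safety); the time to the last burst offset is the total ingestion
#' duration and must be under 15 s (effectiveness). Both rules are strict
#' inequalities: boundary values fail.
#'
#' @param x Numeric signal containing the swallow event train (e.g. the
#'   z-axis acceleration of a swallow segment, measured from event onset).
#' @param fs Sampling rate in Hz.
#' @param rel_threshold Burst threshold as a fraction of the peak envelope
#'   (default 0.2).
#' @return A one-row tibble: `onset_to_opening`, `total_duration` (s),
#'   `safety_ok`, `effectiveness_ok`, `n_bursts`, `assessable`.
#' @export
swallow_timing <- function(x, fs, rel_threshold = 0.2) {
  check_scalar(fs, "fs", lower = 1e-9)
  if (!length(x)) abort("Empty signal.")
  win <- max(3L, round(0.15 * fs))
  if (win %% 2L == 0L) win <- win + 1L  # odd: envelope stays centered
  env <- sqrt(stats::filter(x^2, rep(1 / win, win), sides = 2))
  env[is.na(env)] <- 0
  env <- as.numeric(env)
  peak <- max(env)
  floor_env <- quantile(env, 0.1, names = FALSE)
  if (peak <= 0 || peak < 5 * (floor_env + .Machine$double.eps)) {
    return(tibble(onset_to_opening = NA_real_, total_duration = NA_real_,
                  safety_ok = NA, effectiveness_ok = NA,
                  n_bursts = 0L, assessable = FALSE))
  }
  above <- env > rel_threshold * peak
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bursts <- which(r$values)
  first_burst <- starts[bursts[1]]:ends[bursts[1]]
  first_peak_idx <- first_burst[which.max(env[first_burst])]
  last_off_idx <- ends[bursts[length(bursts)]]
  onset_to_opening <- first_peak_idx / fs
  total_duration <- last_off_idx / fs
  tibble(onset_to_opening = onset_to_opening,
         total_duration = total_duration,
         safety_ok = onset_to_opening < 3,
         effectiveness_ok = total_duration < 15,
         n_bursts = length(bursts), assessable = TRUE)
}

#' Per-behavior normal/abnormal flags
#'
#' A behavior is `abnormal` when its mean classifier confidence falls below
#' `conf_threshold` or any of its timing rules fails; a behavior absent from
#' the session is `not_assessable` (distinct from abnormal).
#'
#' @param predictions A tibble with columns `behavior` (values among
#'   `"swallowing"`, `"drinking"`, `"talking"`) and `confidence` (classifier
#'   probability assigned to the true behavior), one row per evaluated event
#'   or window.
#' @param timings Optional tibble with columns `behavior`, `safety_ok`,
#'   `effectiveness_ok` ([swallow_timing()] results for swallowing/drinking
#'   events).
#' @param conf_threshold Confidence below which a behavior is abnormal
#'   (default 0.5).
#' @return A `laryx_flags` tibble: `behavior`, `status` in
#'   `{normal, abnormal, not_assessable}`.
#' @export
behavior_flags <- function(predictions, timings = NULL,
                           conf_threshold = 0.5) {
  if (!all(c("behavior", "confidence") %in% names(predictions))) {
    abort("`predictions` needs columns `behavior` and `confidence`.")
  }
  status <- vapply(rehab_behaviors, function(b) {
    rows <- predictions[predictions$behavior == b, , drop = FALSE]
    if (!nrow(rows)) return("not_assessable")
    ok <- mean(rows$confidence) >= conf_threshold
    if (!is.null(timings)) {
      tr <- timings[timings$behavior == b, , drop = FALSE]
      if (nrow(tr) &&
          any(!tr$safety_ok | !tr$effectiveness_ok, na.rm = TRUE)) {
        ok <- FALSE
      }
    }
    if (ok) "normal" else "abnormal"
  }, character(1))
  out <- tibble(behavior = rehab_behaviors, status = unname(status))
  class(out) <- c("laryx_flags", class(out))
  out
}

#' Map behavior flags to the eight-level rehabilitation state
#'
#' The eight combinations of normal/abnormal over swallowing (S), drinking
#' (D) and talking (T) map bijectively onto ordinal levels I (all normal)
#' through VIII (all abnormal). Levels increase with the number of abnormal
#' behaviors; ties within a count are ordered by the severity priority
#' S > D > T.
#'
#' @param flags A `laryx_flags` tibble from [behavior_flags()] (all three
#'   behaviors assessable).
#' @return A list with `level` (integer 1-8), `roman` ("I".."VIII") and the
#'   input `flags`.
#' @export
rehab_level <- function(flags) {
  if (!all(rehab_behaviors %in% flags$behavior)) {
    abort("Flags must cover swallowing, drinking and talking.")
  }
  st <- setNames(flags$status, flags$behavior)[rehab_behaviors]
  if (any(st == "not_assessable")) {
    abort("All three behaviors must be assessable to assign a level.")
  }
  tab <- rehab_level_table()
  hit <- which(tab$swallowing == st[["swallowing"]] &
                 tab$drinking == st[["drinking"]] &
                 tab$talking == st[["talking"]])
  list(level = tab$level[hit], roman = tab$roman[hit], flags = flags)
}
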