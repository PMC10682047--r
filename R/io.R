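# On-disk formats: a columnar text interchange format for recordings (header
# comments carry metadata and annotations) and a native binary container
# (lossless round trip) for recordings, datasets and model checkpoints.

#' Write and read recordings
#'
#' The text format is a tab-separated table with columns
#' `t, ax, ay, az, semg`, preceded by `#`-comment lines carrying the sampling
#' rate, subject profile, seed and one line per annotation. It round-trips
#' losslessly up to the declared decimal precision (`digits`). The binary
#' container (`format = "rds"`, R serialization) round-trips exactly.
#'
#' @param recording A `laryx_recording`.
#' @param path Output/input file path.
#' @param format `"text"` or `"rds"`; `read_recording()` infers it from the
#'   file content.
#' @param digits Significant digits for the text format (default 10).
#' @return `write_recording()` returns `path` invisibly; `read_recording()`
#'   returns the `laryx_recording`.
#' @export
write_recording <- function(recording, path, format = c("text", "rds"),
                            digits = 10) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(recording, path)
    return(invisible(path))
  }
  prof <- recording_profile(recording)
  ann <- recording_annotations(recording)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# fs: %.10g", recording_fs(recording)),
    sprintf("# seed: %d", as.integer(attr(recording, "seed") %||% NA)),
    sprintf("# subject: %s %.10g %.10g %.10g %.10g %.10g",
            prof$subject_id, prof$cardiac_amp, prof$resp_amp,
            prof$semg_gain, prof$spectral_jitter, prof$baseline_noise_sd)
  ), con)
  if (!is.null(ann) && nrow(ann)) {
    for (i in seq_len(nrow(ann))) {
      writeLines(sprintf("# annotation: %s %.10g %.10g %.10g",
                         ann$kind[i], ann$onset[i], ann$duration[i],
                         ann$intensity[i]), con)
    }
  }
  writeLines(paste(c("t", "ax", "ay", "az", "semg"), collapse = "\t"), con)
  df <- as.data.frame(recording)[, c("t", "ax", "ay", "az", "semg")]
  utils::write.table(format(df, digits = digits, scientific = TRUE,
                            trim = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  first <- readBin(path, "raw", n = 5)
  if (length(first) >= 2 && first[1] == as.raw(0x1f) ||
      identical(rawToChar(first[1:2]), "X\n")) {
    rec <- readRDS(path)
    if (!inherits(rec, "laryx_recording")) {
      abort("The container does not hold a laryx_recording.")
    }
    return(rec)
  }
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  fs_line <- grep("^# fs:", hdr, value = TRUE)
  if (!length(fs_line)) abort("Malformed header: missing `# fs:` line.")
  fs <- as.numeric(sub("^# fs:\\s*", "", fs_line[1]))
  seed_line <- grep("^# seed:", hdr, value = TRUE)
  seed <- if (length(seed_line)) {
    suppressWarnings(as.integer(sub("^# seed:\\s*", "", seed_line[1])))
  }
  subj_line <- grep("^# subject:", hdr, value = TRUE)
  prof <- if (length(subj_line)) {
    f <- strsplit(sub("^# subject:\\s*", "", subj_line[1]), "\\s+")[[1]]
    subject_profile(f[1], as.numeric(f[2]), as.numeric(f[3]),
                    as.numeric(f[4]), as.numeric(f[5]), as.numeric(f[6]))
  } else {
    subject_profile()
  }
  ann_lines <- grep("^# annotation:", hdr, value = TRUE)
  ann <- if (length(ann_lines)) {
    parts <- lapply(ann_lines, function(l) {
      strsplit(sub("^# annotation:\\s*", "", l), "\\s+")[[1]]
    })
    event_schedule(kind = vapply(parts, `[[`, "", 1),
                   onset = as.numeric(vapply(parts, `[[`, "", 2)),
                   duration = as.numeric(vapply(parts, `[[`, "", 3)),
                   intensity = as.numeric(vapply(parts, `[[`, "", 4)))
  } else {
    event_schedule()
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (!length(body)) abort("Malformed file: no data rows.")
  cols <- strsplit(body[1], "\t")[[1]]
  expected <- c("t", "ax", "ay", "az", "semg")
  extra <- setdiff(cols, expected)
  if (length(extra)) {
    abort(paste0("Unknown column(s) in recording file: ",
                 paste(extra, collapse = ", ")))
  }
  if (!identical(cols, expected)) {
    abort("Recording header must name exactly: t, ax, ay, az, semg.")
  }
  fields <- strsplit(body[-1], "\t")
  nf <- lengths(fields)
  if (any(nf != 5L)) {
    abort(sprintf("Parse error at data row %d: expected 5 fields, found %d.",
                  which(nf != 5L)[1], nf[nf != 5L][1]))
  }
  m <- matrix(as.numeric(unlist(fields)), ncol = 5, byrow = TRUE)
  if (anyNA(m)) abort("Parse error: non-numeric value in data rows.")
  new_recording(m[, 1], m[, 2], m[, 3], m[, 4], m[, 5], fs, prof, ann, seed)
}

#' Save and load datasets and model checkpoints
#'
#' Native binary containers (R serialization). Checkpoints embed the model,
#' its configuration, the layer census, the training history and the seed.
#'
#' @param dataset,fit Objects to save.
#' @param path File path.
#' @return The loaded object, or `path` invisibly for writers.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "laryx_dataset"))
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "laryx_dataset")) abort("Not a laryx_dataset container.")
  x
}

#' @rdname write_dataset
#' @export
write_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "laryx_fit") || inherits(fit, "laryx_sfe"))
  obj <- if (inherits(fit, "laryx_fit")) fit else list(model = fit)
  obj$census <- layer_census(if (inherits(fit, "laryx_fit")) fit$model else fit)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!(inherits(x, "laryx_fit") ||
        (is.list(x) && inherits(x$model, "laryx_sfe")))) {
    abort("Not a laryx model checkpoint.")
  }
  x
}

#' Export a spectrogram as columnar text
#'
#' One row per (time, frequency) cell: `time`, `freq`, `magnitude`.
#'
#' @param spectrogram A `laryx_spectrogram`.
#' @param path Output path.
#' @export
write_spectrogram <- function(spectrogram, path) {
  df <- expand.grid(freq = spectrogram$freqs, time = spectrogram$times)
  df$magnitude <- as.vector(spectrogram$magnitude)
  utils::write.table(df[, c("time", "freq", "magnitude")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
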