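# End-to-end pipeline plumbing: a validated serializable configuration, staged
# artifact-producing runs, and a thin command-line dispatcher.

pipeline_defaults <- function() {
  list(
    seed = 1,
    synthesis = list(n_subjects = 4, classes = laryx_classes(),
                     reps_per_class = 1, fs = 333, recording_duration = 4,
                     spectral_jitter = 0.05, baseline_noise_sd = 0.005),
    vitals = list(enabled = TRUE, duration = 30,
                  hr_band = c(0.6, 20), rr_band = c(0.1, 0.7)),
    windowing = list(n_sequences = 6, length = 1000, holdout_frac = 0.2),
    split = list(n_test_subjects = 1),
    model = list(channels = c(8, 8, 12, 12, 16, 16, 16, 16), kernel_len = 7,
                 hidden_units = 32, triplet_margin = 1, loss_mix = 0.5,
                 batch_size = 16, epochs = 10),
    schedule = list(iLR = 0.01, mode = "cosine_annealing"),
    optimizer = list(beta1 = 0.9, beta2 = 0.999, eps = 1e-8),
    class_map = NULL,
    protocols = c("within_subject", "new_subject_zero_shot"),
    rehab = list(conf_threshold = 0.5)
  )
}

#' Pipeline configuration
#'
#' Builds the full nested configuration with every defaulted value explicit;
#' unknown keys are rejected. The configuration is YAML-serializable and its
#' hash is embedded in every artifact the pipeline writes.
#'
#' @param ... Named overrides of top-level sections (each a named list) or
#'   scalar fields, e.g. `synthesis = list(n_subjects = 6)`.
#' @return A validated `laryx_config` list.
#' @export
pipeline_config <- function(...) {
  defaults <- pipeline_defaults()
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) {
    abort(paste0("Unknown configuration key(s): ", paste(bad, collapse = ", ")))
  }
  cfg <- defaults
  for (nm in names(over)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      sub_bad <- setdiff(names(over[[nm]]), names(defaults[[nm]]))
      if (length(sub_bad)) {
        abort(paste0("Unknown configuration key(s) in `", nm, "`: ",
                     paste(sub_bad, collapse = ", ")))
      }
      cfg[[nm]] <- modifyList(defaults[[nm]], over[[nm]])
    } else {
      cfg[nm] <- list(over[[nm]])  # keep NULL-valued keys in place
    }
  }
  structure(cfg, class = "laryx_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file `%s` not found.", path))
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config A `laryx_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
config_hash <- function(config) {
  # canonicalize so a YAML round trip (integer vs double, list vs vector)
  # hashes identically
  canon <- rapply(unclass(config), function(x) {
    if (is.numeric(x)) as.numeric(x) else as.character(x)
  }, how = "replace")
  digest::digest(canon, algo = "sha1")
}

ensure_dir <- function(out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  out_dir
}

log_stage <- function(out_dir, stage, config, extra = "") {
  line <- sprintf("stage=%s seed=%d hash=%s pkg=%s %s",
                  stage, as.integer(config$seed), config_hash(config),
                  as.character(utils::packageVersion("laryx")), extra)
  cat(line, "\n", file = file.path(out_dir, "pipeline.log"), append = TRUE)
}

need_artifact <- function(path, what) {
  if (!file.exists(path)) {
    abort(sprintf("Missing artifact: %s (expected at %s). Run the earlier stage first.",
                  what, path), class = "laryx_missing_artifact")
  }
  path
}

#' Run pipeline stages
#'
#' `run_pipeline()` executes simulate, (optionally) vitals, preprocess, train,
#' evaluate and report in order, writing all artifacts under `out_dir`:
#' `cohort.rds` + `manifest.json`, `vitals.json`, `dataset.rds`,
#' `checkpoint.rds` + `train_log.tsv`, one `report_<protocol>.json` (+
#' confusion CSV) per protocol, and `rehab_session.json`. Every artifact
#' embeds the configuration hash and seed; identical configurations and seeds
#' reproduce the evaluation reports byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the trained fit and the evaluation reports.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "laryx_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage_simulate(config, out_dir)
  if (isTRUE(config$vitals$enabled)) stage_vitals(config, out_dir)
  stage_preprocess(config, out_dir)
  fit <- stage_train(config, out_dir)
  reports <- stage_evaluate(config, out_dir)
  session <- stage_report(config, out_dir)
  invisible(list(fit = fit, reports = reports, session = session))
}

#' @rdname run_pipeline
#' @export
stage_simulate <- function(config, out_dir) {
  ensure_dir(out_dir)
  syn <- config$synthesis
  cohort <- synthesize_cohort(syn$n_subjects, syn$classes, syn$reps_per_class,
                              fs = syn$fs, seed = config$seed,
                              recording_duration = syn$recording_duration,
                              spectral_jitter = syn$spectral_jitter,
                              baseline_noise_sd = syn$baseline_noise_sd)
  saveRDS(cohort, file.path(out_dir, "cohort.rds"))
  manifest <- list(hash = config_hash(config), seed = config$seed,
                   n_subjects = syn$n_subjects,
                   subjects = unique(cohort$subject_id),
                   classes = syn$classes,
                   n_recordings = nrow(cohort))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_stage(out_dir, "simulate", config,
            sprintf("recordings=%d", nrow(cohort)))
  invisible(cohort)
}

#' @rdname run_pipeline
#' @export
stage_vitals <- function(config, out_dir) {
  need_artifact(file.path(out_dir, "cohort.rds"), "simulated cohort")
  cohort <- readRDS(file.path(out_dir, "cohort.rds"))
  subj <- unique(cohort$subject_id)
  rows <- lapply(seq_along(subj), function(i) {
    sid <- subj[i]
    row1 <- cohort[cohort$subject_id == sid, ][1, ]
    prof <- recording_profile(row1$recording[[1]])
    rec <- synthesize_recording(event_schedule(),
                                hr_bpm = row1$hr_bpm, rr_bpm = row1$rr_bpm,
                                fs = config$synthesis$fs,
                                duration = config$vitals$duration,
                                profile = prof,
                                seed = derive_seed(config$seed, 5000 + i))
    v <- estimate_vitals(rec, config$vitals$hr_band, config$vitals$rr_band)
    list(subject = sid, hr_true = round(row1$hr_bpm, 6),
         rr_true = round(row1$rr_bpm, 6),
         hr_bpm = round(v$hr_bpm, 6), rr_bpm = round(v$rr_bpm, 6),
         quality = v$quality_flag)
  })
  jsonlite::write_json(list(hash = config_hash(config), vitals = rows),
                       file.path(out_dir, "vitals.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_stage(out_dir, "vitals", config, sprintf("subjects=%d", length(subj)))
  invisible(rows)
}

#' @rdname run_pipeline
#' @export
stage_preprocess <- function(config, out_dir) {
  need_artifact(file.path(out_dir, "cohort.rds"), "simulated cohort")
  cohort <- readRDS(file.path(out_dir, "cohort.rds"))
  subj <- unique(cohort$subject_id)
  n_test <- config$split$n_test_subjects
  test_subjects <- tail(subj, n_test)
  class_map <- if (!is.null(config$class_map)) {
    unlist(config$class_map)
  }
  ds <- assemble_dataset(cohort, test_subjects, class_map,
                         n_sequences = config$windowing$n_sequences,
                         length = config$windowing$length,
                         holdout_frac = config$windowing$holdout_frac,
                         seed = config$seed)
  ds$hash <- config_hash(config)
  write_dataset(ds, file.path(out_dir, "dataset.rds"))
  log_stage(out_dir, "preprocess", config,
            sprintf("windows=%d classes=%d", dim(ds$x)[3], ds$n_classes))
  invisible(ds)
}

#' @rdname run_pipeline
#' @export
stage_train <- function(config, out_dir) {
  need_artifact(file.path(out_dir, "dataset.rds"), "preprocessed dataset")
  ds <- read_dataset(file.path(out_dir, "dataset.rds"))
  m <- config$model
  mc <- sfe_config(n_classes = ds$n_classes,
                   input_length = config$windowing$length,
                   channels = m$channels, kernel_len = m$kernel_len,
                   hidden_units = m$hidden_units,
                   triplet_margin = m$triplet_margin, loss_mix = m$loss_mix,
                   batch_size = m$batch_size, epochs = m$epochs)
  model <- build_sfe(mc, seed = derive_seed(config$seed, 21))
  sched <- lr_schedule_config(iLR = config$schedule$iLR, epochs = m$epochs,
                              mode = config$schedule$mode)
  opt <- adam_config(config$optimizer$beta1, config$optimizer$beta2,
                     config$optimizer$eps)
  fit <- train_sfe(model, ds, schedule = sched, optimizer = opt,
                   epochs = m$epochs, seed = derive_seed(config$seed, 22))
  write_checkpoint(fit, file.path(out_dir, "checkpoint.rds"))
  utils::write.table(as.data.frame(fit$history),
                     file.path(out_dir, "train_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage(out_dir, "train", config,
            sprintf("best_epoch=%d best_test=%.4f", fit$best_epoch,
                    max(fit$history$test_acc)))
  invisible(fit)
}

#' @rdname run_pipeline
#' @export
stage_evaluate <- function(config, out_dir) {
  need_artifact(file.path(out_dir, "checkpoint.rds"), "trained checkpoint")
  need_artifact(file.path(out_dir, "dataset.rds"), "preprocessed dataset")
  fit <- read_checkpoint(file.path(out_dir, "checkpoint.rds"))
  if (!inherits(fit, "laryx_fit")) {
    abort("Incompatible checkpoint: no trained fit inside.",
          class = "laryx_bad_checkpoint")
  }
  ds <- read_dataset(file.path(out_dir, "dataset.rds"))
  reports <- list()
  for (p in config$protocols) {
    rep <- evaluate_protocol(fit, ds, p, seed = derive_seed(config$seed, 31))
    write_report(rep, file.path(out_dir, paste0("report_", p, ".json")))
    reports[[p]] <- rep
  }
  log_stage(out_dir, "evaluate", config,
            paste(vapply(reports, function(r) {
              sprintf("%s=%.4f", r$protocol, r$overall_accuracy)
            }, character(1)), collapse = " "))
  invisible(reports)
}

#' @rdname run_pipeline
#' @export
stage_report <- function(config, out_dir) {
  need_artifact(file.path(out_dir, "checkpoint.rds"), "trained checkpoint")
  need_artifact(file.path(out_dir, "dataset.rds"), "preprocessed dataset")
  need_artifact(file.path(out_dir, "cohort.rds"), "simulated cohort")
  fit <- read_checkpoint(file.path(out_dir, "checkpoint.rds"))
  ds <- read_dataset(file.path(out_dir, "dataset.rds"))
  cohort <- readRDS(file.path(out_dir, "cohort.rds"))
  session <- rehab_session(fit, ds, cohort,
                           conf_threshold = config$rehab$conf_threshold)
  body <- list(hash = config_hash(config), seed = config$seed,
               flags = lapply(seq_len(nrow(session$flags)), function(i) {
                 list(behavior = session$flags$behavior[i],
                      status = session$flags$status[i])
               }),
               level = session$level, roman = session$roman,
               timings = lapply(seq_len(nrow(session$timings)), function(i) {
                 as.list(session$timings[i, ])
               }))
  jsonlite::write_json(body, file.path(out_dir, "rehab_session.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = 8)
  log_stage(out_dir, "report", config, sprintf("level=%s", session$roman))
  invisible(session)
}

# Map the 13 feature classes onto the three rehabilitation behaviors.
behavior_of_class <- function(class_name) {
  dplyr::case_when(
    class_name %in% laryx_classes()[1:10] ~ "talking",
    class_name == "talk" ~ "talking",
    class_name == "swallow" ~ "swallowing",
    class_name == "drink" ~ "drinking",
    TRUE ~ NA_character_
  )
}

#' Assemble a rehabilitation session assessment
#'
#' Classifier confidences come from the dataset's held-out windows: for each
#' behavior the mean probability mass its windows receive on classes of the
#' same behavior. Swallow and drink timing rules are applied to the z-axis of
#' each test subject's swallow/drink recordings via [swallow_timing()].
#'
#' @param fit A trained `laryx_fit`.
#' @param dataset The `laryx_dataset`.
#' @param cohort The source `laryx_cohort`.
#' @param conf_threshold Confidence threshold for [behavior_flags()].
#' @return A list with `flags`, `level`, `roman`, `timings`, `confidences`.
#' @export
rehab_session <- function(fit, dataset, cohort, conf_threshold = 0.5) {
  meta <- dataset$meta
  idx <- which(meta$split %in% c("holdout", "test"))
  if (!length(idx)) abort("No evaluation windows available for a session report.")
  pred <- predict(fit, dataset$x[, , idx, drop = FALSE])
  behav_of <- behavior_of_class(dataset$classes)
  win_behav <- behav_of[meta$label[idx]]
  conf <- vapply(seq_along(idx), function(i) {
    b <- win_behav[i]
    if (is.na(b)) return(NA_real_)
    sum(pred$probs[i, which(behav_of == b)])
  }, numeric(1))
  predictions <- tibble(behavior = win_behav, confidence = conf) |>
    dplyr::filter(!is.na(.data$behavior))
  timing_rows <- list()
  test_rows <- which(cohort$subject_id %in% dataset$test_subjects &
                       cohort$kind %in% c("swallow", "drink"))
  for (i in test_rows) {
    rec <- cohort$recording[[i]]
    ann <- recording_annotations(rec)
    fs <- recording_fs(rec)
    i0 <- round(ann$onset[1] * fs) + 1L
    i1 <- min(nrow(rec), i0 + round((ann$duration[1] + 1) * fs))
    tm <- swallow_timing(rec$az[i0:i1] - mean(rec$az[i0:i1]), fs)
    tm$behavior <- if (cohort$kind[i] == "swallow") "swallowing" else "drinking"
    timing_rows[[length(timing_rows) + 1L]] <- tm
  }
  timings <- if (length(timing_rows)) {
    dplyr::bind_rows(timing_rows)
  } else {
    tibble(behavior = character(), safety_ok = logical(),
           effectiveness_ok = logical())
  }
  flags <- behavior_flags(predictions, timings, conf_threshold)
  lv <- rehab_level(flags)
  list(flags = flags, level = lv$level, roman = lv$roman,
       timings = timings,
       confidences = dplyr::summarise(
         dplyr::group_by(predictions, .data$behavior),
         confidence = mean(.data$confidence), n = dplyr::n()))
}

#' Command-line entry point
#'
#' Thin dispatcher over the pipeline stages. Subcommands: `simulate`,
#' `vitals`, `preprocess`, `train`, `evaluate`, `report`, `run` (all stages).
#' Flags: `--config <yaml>`, `--out <dir>`, `--seed <int>`.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status, invisibly: 0 success, 1 usage/other error,
#'   2 missing input artifact, 3 malformed configuration.
#' @export
laryx_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: laryx <simulate|vitals|preprocess|train|evaluate|report|run>",
    "[--config cfg.yaml] [--out dir] [--seed int]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  if (cmd %in% c("--help", "-h", "help")) { message(usage); return(invisible(0L)) }
  opts <- list(config = NULL, out = "laryx_out", seed = NULL)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opts) || i == length(args)) {
      message("Unknown or incomplete flag: ", args[i], "\n", usage)
      return(invisible(1L))
    }
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  status <- tryCatch({
    config <- if (!is.null(opts$config)) {
      read_config(opts$config)
    } else {
      pipeline_config()
    }
    if (!is.null(opts$seed)) config$seed <- as.integer(opts$seed)
    switch(cmd,
      simulate = stage_simulate(config, opts$out),
      vitals = stage_vitals(config, opts$out),
      preprocess = stage_preprocess(config, opts$out),
      train = stage_train(config, opts$out),
      evaluate = stage_evaluate(config, opts$out),
      report = stage_report(config, opts$out),
      run = run_pipeline(config, opts$out),
      {
        message("Unknown subcommand: ", cmd, "\n", usage)
        return(invisible(1L))
      })
    0L
  },
  laryx_missing_artifact = function(e) { message(conditionMessage(e)); 2L },
  laryx_bad_checkpoint = function(e) { message(conditionMessage(e)); 4L },
  error = function(e) {
    msg <- conditionMessage(e)
    message(msg)
    if (grepl("configuration|Config", msg)) 3L else 1L
  })
  invisible(status)
}
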