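#' Write a session recording to disk
#'
#' Streams go to one CSV (`channel`, `t_seconds`, `value_c`, full `write_csv`
#' precision so values round-trip exactly); session metadata (ids, setting,
#' lights-off, presence intervals, stream file path) to a JSON manifest.
#' The simulator's latent trajectories are not serialized.
#'
#' @param rec A `tss_session`.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest, invisibly.
#' @export
write_session <- function(rec, dir) {
  stopifnot(inherits(rec, "tss_session"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stem <- paste0(rec$subject_id, "_", rec$session_id)
  streams_file <- paste0(stem, "_streams.csv")
  readr::write_csv(rec$streams, file.path(dir, streams_file), na = "")
  manifest <- list(
    subject_id = rec$subject_id,
    session_id = rec$session_id,
    setting = rec$setting,
    lights_off = if (is.na(rec$lights_off)) NULL else rec$lights_off,
    duration_min = rec$duration_min,
    presence = list(start_s = rec$presence$start_s,
                    end_s = rec$presence$end_s),
    streams_file = streams_file
  )
  manifest_path <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest_path)
}

#' Load a session recording from a manifest
#'
#' Validates the stream file against the schema: known channels only and
#' strictly increasing timestamps within each channel. Violations raise
#' distinct error classes (`bedtherm_error_missing_file`,
#' `bedtherm_error_unknown_channel`, `bedtherm_error_bad_timestamps` — the
#' latter naming the offending row).
#'
#' @param manifest_path Path to a manifest written by [write_session()].
#' @return A `tss_session`.
#' @export
load_session <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    abort(paste0("manifest not found: ", manifest_path),
          class = "bedtherm_error_missing_file")
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  streams_path <- file.path(dirname(manifest_path), manifest$streams_file)
  if (!file.exists(streams_path)) {
    abort(paste0("stream file not found: ", streams_path),
          class = "bedtherm_error_missing_file")
  }
  streams <- readr::read_csv(
    streams_path,
    col_types = readr::cols(channel = readr::col_character(),
                            t_seconds = readr::col_double(),
                            value_c = readr::col_double())
  )
  bad <- setdiff(unique(streams$channel), known_channels())
  if (length(bad)) {
    abort(paste0("unknown channel(s): ", paste(bad, collapse = ", ")),
          class = "bedtherm_error_unknown_channel")
  }
  for (ch in unique(streams$channel)) {
    idx <- which(streams$channel == ch)
    t <- streams$t_seconds[idx]
    drop <- which(diff(t) <= 0)
    if (length(drop)) {
      abort(sprintf(
        "non-increasing timestamp in channel %s at stream row %d",
        ch, idx[drop[1] + 1]
      ), class = "bedtherm_error_bad_timestamps")
    }
  }
  presence <- tibble::tibble(
    start_s = as.numeric(manifest$presence$start_s),
    end_s = as.numeric(manifest$presence$end_s)
  )
  structure(
    list(
      subject_id = manifest$subject_id,
      session_id = manifest$session_id,
      setting = manifest$setting,
      lights_off = manifest$lights_off %||% NA_real_,
      duration_min = manifest$duration_min,
      streams = streams,
      presence = presence,
      latent = NULL
    ),
    class = "tss_session"
  )
}

#' Write cross-validation results as a fold-per-row table
#'
#' One row per fold (`fold`, `n_sessions`, `bias`, `lower_loa`, `upper_loa`,
#' `r2`) plus a final `mean` row holding the grand means.
#'
#' @param cv A `dst_cv` from [run_cv()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cv_results <- function(cv, path) {
  stopifnot(inherits(cv, "dst_cv"))
  folds <- dplyr::mutate(cv$fold_means, fold = as.character(.data$fold))
  mean_row <- dplyr::bind_cols(
    tibble::tibble(fold = "mean", n_sessions = sum(folds$n_sessions)),
    cv$grand
  )
  readr::write_csv(dplyr::bind_rows(folds, mean_row), path, na = "")
  invisible(path)
}

#' Run configuration for a reproducible pipeline run
#'
#' A serializable bundle of every knob of the pipeline; together with its
#' seed it fully determines all outputs.
#'
#' @param seed Integer master seed.
#' @param n_home_subjects,home_nights,n_lab_subjects,lab_nights,duration
#'   Study design passed to [simulate_study()].
#' @param params A [physio_params()].
#' @param artifacts An [artifact_spec()].
#' @param oscillation_threshold,gate_threshold Preprocessing thresholds.
#' @param config A [hyperparam_config()].
#' @param k Cross-validation folds.
#' @param fractions Learning-curve fractions.
#' @return A `run_config` (named list).
#' @export
run_config <- function(seed = 1L,
                       n_home_subjects = 20L, home_nights = 5L,
                       n_lab_subjects = 18L, lab_nights = 2L,
                       duration = 240L,
                       params = physio_params(),
                       artifacts = artifact_spec(),
                       oscillation_threshold = 2,
                       gate_threshold = 0.80,
                       config = default_config(),
                       k = 5L,
                       fractions = c(0.2, 0.4, 0.6, 0.8, 1)) {
  structure(
    list(seed = seed, n_home_subjects = n_home_subjects,
         home_nights = home_nights, n_lab_subjects = n_lab_subjects,
         lab_nights = lab_nights, duration = duration, params = params,
         artifacts = artifacts,
         oscillation_threshold = oscillation_threshold,
         gate_threshold = gate_threshold, config = config, k = k,
         fractions = fractions),
    class = "run_config"
  )
}

#' Read / write a run configuration as YAML
#' @param path YAML file path.
#' @param rc A [run_config()].
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  rc <- run_config()
  for (nm in intersect(names(raw), c("seed", "n_home_subjects", "home_nights",
                                     "n_lab_subjects", "lab_nights",
                                     "duration", "oscillation_threshold",
                                     "gate_threshold", "k", "fractions"))) {
    rc[[nm]] <- raw[[nm]]
  }
  if (!is.null(raw$params)) {
    rc$params <- do.call(physio_params, raw$params)
  }
  if (!is.null(raw$artifacts)) {
    rc$artifacts <- do.call(artifact_spec, raw$artifacts)
  }
  if (!is.null(raw$config)) {
    rc$config <- do.call(hyperparam_config, raw$config)
  }
  rc
}

#' @rdname read_run_config
#' @export
write_run_config <- function(rc, path) {
  stopifnot(inherits(rc, "run_config"))
  out <- unclass(rc)
  out$params <- unclass(out$params)
  out$artifacts <- unclass(out$artifacts)
  out$config <- unclass(out$config)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Run the full pipeline from a configuration
#'
#' Simulates the study, runs subject-blocked cross-validation on the home
#' arm, trains a final model on every gated home session, verifies it on the
#' lab arm, and writes results (`cv_results.csv`, `cv_results.json`,
#' `change_curves.csv`, `run_log.json`) under `out_dir`.
#'
#' @param rc A [run_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the `dst_cv`, the `dst_verification` and
#'   the study.
#' @export
run_pipeline <- function(rc, out_dir) {
  stopifnot(inherits(rc, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  study <- simulate_study(rc$n_home_subjects, rc$home_nights,
                          rc$n_lab_subjects, rc$lab_nights,
                          params = rc$params, spec = rc$artifacts,
                          seed = rc$seed, duration = rc$duration)
  prep <- preprocess_study(study,
                           oscillation_threshold = rc$oscillation_threshold,
                           gate_threshold = rc$gate_threshold)
  cv <- run_cv(prep, config = rc$config, k = rc$k, seed = rc$seed)
  write_cv_results(cv, file.path(out_dir, "cv_results.csv"))
  jsonlite::write_json(
    list(fold_means = cv$fold_means, grand = cv$grand,
         session_stats = cv$session_stats),
    file.path(out_dir, "cv_results.json"), digits = NA
  )
  model <- train_sequential(prep[prep$setting == "home" & prep$included, ],
                            rc$config, seed = rc$seed)
  verification <- verify_in_lab(study, model,
                                oscillation_threshold = rc$oscillation_threshold,
                                gate_threshold = rc$gate_threshold)
  curves <- dplyr::full_join(
    stats::setNames(verification$mean_a, c("minute", "estimated_dst")),
    stats::setNames(verification$mean_b, c("minute", "foot")),
    by = "minute"
  )
  readr::write_csv(curves, file.path(out_dir, "change_curves.csv"), na = "")
  jsonlite::write_json(
    list(seed = rc$seed, pearson_r = verification$r, p = verification$p,
         grand = cv$grand),
    file.path(out_dir, "run_log.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(list(cv = cv, verification = verification, study = study))
}
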