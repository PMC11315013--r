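#' Simulate one night of smart-bed thermodata for one subject
#'
#' Generates the latent thermoregulation trajectory of a sleeper and the raw
#' sensor streams observing it: the five-sensor temperature strip (~1 Hz,
#' 0.1 degC quantum, +/-5% sampling jitter), a wrist reference (4 Hz,
#' 0.02 degC), and foot/proximal channels (1 sample/30 s, 0.0625 degC).
#' The latent distal skin temperature is flat until sleep onset, then rises
#' by `params$distal_rise` as a saturating exponential; strip sensors read a
#' contact-weighted mixture of skin and bed-microclimate temperature, with
#' couplings that drift at random body-movement events.
#'
#' @param params A [physio_params()] object.
#' @param setting `"home"` (wrist reference worn) or `"lab"` (lights-off
#'   marker present, no wrist device).
#' @param duration Session length in minutes (>= 60).
#' @param seed Integer seed; identical `(params, seed)` reproduce identical
#'   streams.
#' @param subject_id,session_id Identifiers stored in the recording.
#' @param lights_off_min For lab sessions, lights-off time in minutes from
#'   session start. Sleep onset occurs `params$sleep_onset_latency` minutes
#'   after lights-off (lab) or after session start (home).
#' @param include_wrist,include_foot,include_proximal Channel toggles; the
#'   wrist default follows the setting.
#' @return A `tss_session`: list with `subject_id`, `session_id`, `setting`,
#'   `lights_off` (seconds, `NA` at home), `duration_min`, `streams` (tibble
#'   `channel`, `t_seconds`, `value_c`), `presence` (tibble `start_s`,
#'   `end_s`) and `latent` (per-minute noise-free trajectories).
#' @export
#' @examples
#' rec <- simulate_subject_night(physio_params(), "home", duration = 90,
#'                               seed = 1)
#' dplyr::count(rec$streams, channel)
simulate_subject_night <- function(params, setting = c("home", "lab"),
                                   duration = 240, seed,
                                   subject_id = "S01", session_id = "N01",
                                   lights_off_min = 10,
                                   include_wrist = NULL,
                                   include_foot = TRUE,
                                   include_proximal = TRUE) {
  stopifnot(inherits(params, "physio_params"))
  setting <- match.arg(setting)
  if (missing(seed)) abort("seed is required")
  if (duration < 60) abort("duration must be at least 60 minutes")
  include_wrist <- include_wrist %||% (setting == "home")

  dur_s <- duration * 60
  lights_off <- if (setting == "lab") lights_off_min * 60 else NA_real_
  onset_s <- (if (is.na(lights_off)) 0 else lights_off) +
    params$sleep_onset_latency * 60
  tau_s <- params$rise_timescale * 60 / 3   # 95% of the rise by onset + timescale

  shape <- function(t) ifelse(t < onset_s, 0, 1 - exp(-(t - onset_s) / tau_s))

  withr::with_seed(seed, {
    # Slow systemic vasomotor wander of the skin temperature after the rise
    # has completed; ramps in over ~10 min so the rise window stays monotone.
    wander_start <- onset_s + params$rise_timescale * 60
    w_amp <- params$wander_amp * runif(2, 0.4, 1)
    w_period <- runif(2, 40, 120) * 60
    w_phase <- runif(2, 0, 2 * pi)
    wander <- function(t) {
      env <- pmax(0, 1 - exp(-(t - wander_start) / 600)) * (t >= wander_start)
      env * (w_amp[1] * sin(2 * pi * t / w_period[1] + w_phase[1]) +
               w_amp[2] * sin(2 * pi * t / w_period[2] + w_phase[2]))
    }
    latent_dst <- function(t) {
      params$baseline_dst + params$distal_rise * shape(t) + wander(t)
    }
    latent_foot <- function(t) {
      params$baseline_dst - 0.3 + params$distal_rise * shape(t) + wander(t)
    }
    latent_prox <- function(t) {
      params$baseline_dst + 2 + params$proximal_rise * shape(t) +
        0.5 * wander(t)
    }
    # Bed microclimate: slow warm-up after bed entry plus a small
    # per-session sinusoidal drift.
    amb_amp <- runif(1, 0, 0.3)
    amb_period <- runif(1, 60, 120) * 60
    amb_phase <- runif(1, 0, 2 * pi)
    ambient <- function(t) {
      params$ambient_temp + 0.5 * (1 - exp(-t / 1800)) +
        amb_amp * sin(2 * pi * t / amb_period + amb_phase)
    }

    # Contact couplings drift at Poisson-distributed position changes.
    n_moves <- rpois(1, params$movement_rate * duration / 60)
    move_times <- sort(runif(n_moves, 0, dur_s))
    seg_bounds <- c(0, move_times, dur_s)
    n_seg <- length(seg_bounds) - 1
    couplings <- matrix(NA_real_, n_seg, 5)
    couplings[1, ] <- params$contact_coupling
    if (n_seg > 1) {
      for (s in 2:n_seg) {
        couplings[s, ] <- pmin(1, pmax(0, couplings[s - 1, ] +
          rnorm(5, 0, params$coupling_jitter)))
      }
    }
    coupling_at <- function(t, i) {
      couplings[findInterval(t, seg_bounds, rightmost.closed = TRUE), i]
    }

    streams <- list()
    for (i in 1:5) {
      # ~1 Hz with +/-5% uniform jitter on the sampling interval
      dt <- runif(ceiling(dur_s * 1.06) + 8, 0.95, 1.05)
      t <- cumsum(dt)
      t <- t[t < dur_s]
      ci <- coupling_at(t, i)
      v <- ci * latent_dst(t) + (1 - ci) * ambient(t) +
        rnorm(length(t), 0, params$noise_sd)
      streams[[paste0("T", i)]] <- tibble::tibble(
        channel = paste0("T", i), t_seconds = t,
        value_c = quantize(v, 0.1)
      )
    }
    if (include_wrist) {
      t <- seq(0, dur_s - 0.25, by = 0.25)
      v <- latent_dst(t) + rnorm(length(t), 0, params$noise_sd)
      streams$wrist <- tibble::tibble(channel = "wrist", t_seconds = t,
                                      value_c = quantize(v, 0.02))
    }
    if (include_foot) {
      t <- seq(0, dur_s - 30, by = 30)
      v <- latent_foot(t) + rnorm(length(t), 0, params$noise_sd)
      streams$foot <- tibble::tibble(channel = "foot", t_seconds = t,
                                     value_c = quantize(v, 0.0625))
    }
    if (include_proximal) {
      t <- seq(0, dur_s - 30, by = 30)
      v <- latent_prox(t) + rnorm(length(t), 0, params$noise_sd)
      streams$proximal <- tibble::tibble(channel = "proximal", t_seconds = t,
                                         value_c = quantize(v, 0.0625))
    }

    minute_mid <- (seq_len(duration) - 0.5) * 60
    latent <- tibble::tibble(
      n = seq_len(duration),
      dst = latent_dst(minute_mid),
      foot = latent_foot(minute_mid),
      proximal = latent_prox(minute_mid),
      ambient = ambient(minute_mid)
    )

    structure(
      list(
        subject_id = subject_id, session_id = session_id, setting = setting,
        lights_off = lights_off, duration_min = duration,
        onset_s = onset_s,
        streams = dplyr::bind_rows(streams),
        presence = tibble::tibble(start_s = 0, end_s = dur_s),
        latent = latent
      ),
      class = "tss_session"
    )
  })
}

#' Inject recording artifacts into a session
#'
#' Adds the invalid-data modes observed in the field: null samples, negative
#' readings, large intra-minute oscillations on the strip, and bed-absence
#' segments (carved out of the presence intervals; strip readings decay
#' towards the bed microclimate while the sleeper is away).
#'
#' @param rec A `tss_session`.
#' @param spec An [artifact_spec()].
#' @param seed Integer seed.
#' @param channels Channels receiving sample-level (null/negative) artifacts;
#'   defaults to the strip plus the wrist.
#' @return A modified copy of `rec` with an `artifact_counts` attribute
#'   (named list: `n_null`, `n_negative`, `n_oscillation_minutes`,
#'   `n_absence_segments`).
#' @export
inject_artifacts <- function(rec, spec, seed,
                             channels = c(strip_channels(), "wrist")) {
  stopifnot(inherits(rec, "tss_session"), inherits(spec, "artifact_spec"))
  if (missing(seed)) abort("seed is required")

  streams <- rec$streams
  counts <- list(n_null = 0L, n_negative = 0L, n_oscillation_minutes = 0L,
                 n_absence_segments = 0L)

  withr::with_seed(seed, {
    sel <- streams$channel %in% channels
    n_sel <- sum(sel)
    if (spec$p_null > 0 && n_sel > 0) {
      hit <- sel & runif(nrow(streams)) < spec$p_null
      streams$value_c[hit] <- NA_real_
      counts$n_null <- sum(hit)
    }
    if (spec$p_negative > 0 && n_sel > 0) {
      hit <- sel & !is.na(streams$value_c) & runif(nrow(streams)) < spec$p_negative
      streams$value_c[hit] <- -abs(streams$value_c[hit]) - 0.5
      counts$n_negative <- sum(hit)
    }
    if (spec$p_oscillation_minute > 0) {
      minutes <- which(runif(rec$duration_min) < spec$p_oscillation_minute)
      chans <- sample(strip_channels(), length(minutes), replace = TRUE)
      for (k in seq_along(minutes)) {
        m <- minutes[k]
        idx <- which(streams$channel == chans[k] &
                       streams$t_seconds >= (m - 1) * 60 &
                       streams$t_seconds < m * 60 &
                       !is.na(streams$value_c))
        if (length(idx)) {
          streams$value_c[idx] <- streams$value_c[idx] +
            spec$oscillation_amplitude * rep_len(c(1, -1), length(idx))
        }
      }
      counts$n_oscillation_minutes <- length(minutes)
    }
    if (spec$n_absence_segments > 0) {
      dur_s <- rec$duration_min * 60
      presence <- rec$presence
      for (k in seq_len(spec$n_absence_segments)) {
        len_s <- runif(1, spec$absence_duration[1], spec$absence_duration[2]) * 60
        start <- runif(1, 0, dur_s - len_s)
        presence <- interval_difference(presence, start, start + len_s)
        # strip sensors cool towards the microclimate while the bed is empty
        away <- streams$channel %in% strip_channels() &
          streams$t_seconds >= start & streams$t_seconds < start + len_s &
          !is.na(streams$value_c)
        dt <- streams$t_seconds[away] - start
        streams$value_c[away] <- streams$value_c[away] -
          4 * (1 - exp(-dt / 120))
      }
      rec$presence <- presence
      counts$n_absence_segments <- spec$n_absence_segments
    }
  })

  rec$streams <- streams
  attr(rec, "artifact_counts") <- counts
  rec
}

# Remove [start, end) from a set of non-overlapping presence intervals.
interval_difference <- function(presence, start, end) {
  out <- list()
  for (r in seq_len(nrow(presence))) {
    a <- presence$start_s[r]; b <- presence$end_s[r]
    if (end <= a || start >= b) {
      out[[length(out) + 1]] <- c(a, b)
    } else {
      if (start > a) out[[length(out) + 1]] <- c(a, start)
      if (end < b) out[[length(out) + 1]] <- c(end, b)
    }
  }
  if (!length(out)) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(start_s = m[, 1], end_s = m[, 2])
}

#' Simulate a multi-subject, multi-night study
#'
#' Emulates the two-arm design used to develop the estimator: a set of
#' subjects recording nights at home (strip + wrist reference) and a set
#' recording in-lab nights (strip + foot/proximal, lights-off marker, no
#' wrist device). Subjects vary in baseline distal temperature and contact
#' pattern; sleep-onset latency varies per session.
#'
#' @param n_home_subjects,home_nights Home arm size.
#' @param n_lab_subjects,lab_nights Lab arm size. The first
#'   `min(n_home_subjects, n_lab_subjects)` subjects participate in both
#'   arms.
#' @param params A [physio_params()].
#' @param spec An [artifact_spec()]; use [no_artifacts()] for clean data.
#' @param seed Integer seed.
#' @param duration Session length in minutes.
#' @param participants Optional participant roster (tibble with
#'   `subject_id`, `gender`, `age`, `height`, `weight`); generated when
#'   `NULL`.
#' @return A `tss_study`: list with `participants` (tibble) and `sessions`
#'   (tibble `subject_id`, `session_id`, `setting`, `recording` list-column)
#'   plus the `seed`.
#' @export
#' @examples
#' study <- simulate_study(2, 2, 1, 1, physio_params(), no_artifacts(),
#'                         seed = 1, duration = 60)
#' nrow(study$sessions)
simulate_study <- function(n_home_subjects, home_nights,
                           n_lab_subjects, lab_nights,
                           params = physio_params(),
                           spec = artifact_spec(),
                           seed, duration = 240,
                           participants = NULL) {
  if (n_home_subjects < 1 && n_lab_subjects < 1) {
    abort("at least one subject is required")
  }
  if ((n_home_subjects >= 1 && home_nights < 1) ||
      (n_lab_subjects >= 1 && lab_nights < 1)) {
    abort("night counts must be >= 1")
  }
  if (missing(seed)) abort("seed is required")
  n_total <- max(n_home_subjects, n_lab_subjects)

  withr::with_seed(child_seed(seed, 0), {
    if (is.null(participants)) {
      participants <- tibble::tibble(
        subject_id = sprintf("S%02d", seq_len(n_total)),
        gender = sample(c("Male", "Female"), n_total, replace = TRUE),
        age = round(runif(n_total, 31, 57)),
        height = round(runif(n_total, 1.55, 1.95), 2),
        weight = round(runif(n_total, 62, 118), 1)
      )
    } else {
      participants <- tibble::as_tibble(participants)
      if (nrow(participants) < n_total) {
        abort("participant roster smaller than the requested subject count")
      }
      participants <- participants[seq_len(n_total), ]
    }
    subject_baseline <- rnorm(n_total, params$baseline_dst,
                              params$between_subject_sd)
    subject_coupling <- lapply(seq_len(n_total), function(i) {
      pmin(1, pmax(0, params$contact_coupling + rnorm(5, 0, 0.02)))
    })
  })

  make_sessions <- function(subjects, nights, setting, tag) {
    rows <- list()
    for (si in subjects) {
      for (nt in seq_len(nights)) {
        sid <- participants$subject_id[si]
        ses <- sprintf("%s%02d", tag, nt)
        sseed <- child_seed(seed, si * 1000L + nt * 10L +
                              (if (setting == "lab") 5L else 0L))
        p <- params
        p$baseline_dst <- subject_baseline[si]
        p$contact_coupling <- subject_coupling[[si]]
        p$sleep_onset_latency <- withr::with_seed(
          child_seed(sseed, 1),
          max(5, rnorm(1, params$sleep_onset_latency, params$latency_sd))
        )
        rec <- simulate_subject_night(p, setting, duration, seed = sseed,
                                      subject_id = sid, session_id = ses)
        if (spec$p_null > 0 || spec$p_negative > 0 ||
            spec$p_oscillation_minute > 0 || spec$n_absence_segments > 0) {
          rec <- inject_artifacts(rec, spec, seed = child_seed(sseed, 2))
        }
        rows[[length(rows) + 1]] <- tibble::tibble(
          subject_id = sid, session_id = ses, setting = setting,
          recording = list(rec)
        )
      }
    }
    rows
  }

  sessions <- dplyr::bind_rows(c(
    if (n_home_subjects >= 1) {
      make_sessions(seq_len(n_home_subjects), home_nights, "home", "H")
    },
    if (n_lab_subjects >= 1) {
      make_sessions(seq_len(n_lab_subjects), lab_nights, "lab", "L")
    }
  ))

  structure(list(participants = participants, sessions = sessions,
                 seed = seed),
            class = "tss_study")
}

#' Summarize a participant roster
#'
#' @param participants Tibble with at least `age` and `gender`.
#' @return One-row tibble: `n`, `mean_age`, `sd_age` (n-1 denominator) and
#'   one `n_<gender>` column per gender level.
#' @export
#' @examples
#' summarize_demographics(example_participants())
summarize_demographics <- function(participants) {
  participants <- tibble::as_tibble(participants)
  if (nrow(participants) < 2) {
    abort("at least two participants are required")
  }
  counts <- table(participants$gender)
  out <- tibble::tibble(
    n = nrow(participants),
    mean_age = mean(participants$age),
    sd_age = sd(participants$age)
  )
  for (g in names(counts)) {
    out[[paste0("n_", tolower(g))]] <- as.integer(counts[[g]])
  }
  out
}

#' Participant roster of the original validation study
#'
#' The demographic table of the 18 adults whose in-home and in-lab nights
#' were used to develop and verify the smart-bed DST estimator.
#'
#' @return Tibble: `subject_id`, `gender`, `age` (years), `height` (m),
#'   `weight` (kg).
#' @export
example_participants <- function() {
  tibble::tibble(
    subject_id = sprintf("S%02d", 1:18),
    gender = c("Male", "Female", "Male", "Female", "Male", "Female", "Male",
               "Male", "Female", "Female", "Male", "Female", "Female",
               "Male", "Male", "Female", "Male", "Female"),
    age = c(41, 37, 45, 39, 42, 42, 43, 31, 49, 49, 51, 45, 57, 41, 57, 42,
            50, 40),
    height = c(1.75, 1.55, 1.83, 1.72, 1.95, 1.61, 1.76, 1.86, 1.57, 1.60,
               1.76, 1.60, 1.55, 1.75, 1.79, 1.59, 1.76, 1.73),
    weight = c(112.7, 68.7, 117.7, 68.2, 92.9, 61.9, 87.8, 99.6, 81.8, 79.0,
               85.5, 79.0, 81.8, 81.8, 102.7, 84.9, 91.7, 88.5)
  )
}

#' Published per-fold validation statistics of the original study
#'
#' Mean validation accuracy per cross-validation fold reported for the
#' in-home arm of the original study: Bland-Altman bias, limits of agreement
#' and coefficient of determination.
#'
#' @return Tibble: `fold`, `bias`, `lower_loa`, `upper_loa`, `r2`.
#' @export
reference_fold_stats <- function() {
  tibble::tibble(
    fold = 1:5,
    bias = c(-0.01, 0.01, -0.01, 0.00, 0.00),
    lower_loa = c(-0.76, -0.77, -0.96, -0.82, -0.65),
    upper_loa = c(0.73, 0.79, 0.94, 0.83, 0.65),
    r2 = c(0.88, 0.89, 0.83, 0.87, 0.90)
  )
}
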