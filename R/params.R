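#' Physiological and sensing parameters for the sleep-thermodata simulator
#'
#' Bundles the latent thermoregulation model and sensor-contact settings used
#' by [simulate_subject_night()] and [simulate_study()]. The latent distal
#' skin temperature (DST) is flat at `baseline_dst` until sleep onset and then
#' rises as a saturating exponential towards `baseline_dst + distal_rise`,
#' reaching 95% of the rise `rise_timescale` minutes after onset. Proximal
#' (trunk) and foot temperatures follow the same vasodilation latent scaled to
#' their own rise magnitudes.
#'
#' @param baseline_dst Pre-onset wrist DST, degrees C.
#' @param distal_rise Post-onset distal rise, degrees C (around 1 degC at the
#'   wrist and foot during the wake-sleep transition).
#' @param proximal_rise Post-onset proximal rise, degrees C (around 0.5 degC).
#' @param rise_timescale Minutes from sleep onset to 95% of the rise.
#' @param sleep_onset_latency Minutes from bed entry (or lights-off, when
#'   present) to sleep onset.
#' @param noise_sd Per-sample sensor noise standard deviation, degrees C.
#' @param ambient_temp Baseline bed-microclimate temperature seen by
#'   uncovered strip sensors, degrees C. The microclimate under an occupied,
#'   covered mattress sits only a few degrees below skin temperature.
#' @param wander_amp Amplitude scale of the slow post-onset vasomotor
#'   fluctuations of skin temperature, degrees C. The wander ramps in only
#'   after `sleep_onset + rise_timescale`, so the rise window itself stays
#'   monotone, and it is shared by the wrist, foot and strip skin signals
#'   (it is systemic vasomotor activity, not sensor noise).
#' @param contact_coupling Numeric vector of 5 weights in \[0, 1\]: sensor i
#'   reads `coupling[i] * skin + (1 - coupling[i]) * ambient`.
#' @param movement_rate Expected body-position changes per hour; each event
#'   perturbs the contact couplings.
#' @param coupling_jitter SD of the per-event coupling perturbation.
#' @param between_subject_sd SD of per-subject baseline DST around
#'   `baseline_dst` when simulating a study, degrees C.
#' @param latency_sd Per-session SD of the sleep-onset latency, minutes.
#' @return An object of class `physio_params` (a named list).
#' @export
#' @examples
#' physio_params(distal_rise = 1, sleep_onset_latency = 20)
physio_params <- function(baseline_dst = 33,
                          distal_rise = 1,
                          proximal_rise = 0.5,
                          rise_timescale = 30,
                          sleep_onset_latency = 20,
                          noise_sd = 0.1,
                          ambient_temp = 31,
                          contact_coupling = c(0.15, 0.55, 0.95, 0.90, 0.50),
                          movement_rate = 0.5,
                          coupling_jitter = 0.02,
                          wander_amp = 0.25,
                          between_subject_sd = 0.4,
                          latency_sd = 5) {
  if (distal_rise < 0) abort("distal_rise must be >= 0")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (length(contact_coupling) != 5 ||
      any(contact_coupling < 0 | contact_coupling > 1)) {
    abort("contact_coupling must have exactly 5 entries, each in [0, 1]")
  }
  if (rise_timescale <= 0) abort("rise_timescale must be positive")
  structure(
    list(
      baseline_dst = baseline_dst, distal_rise = distal_rise,
      proximal_rise = proximal_rise, rise_timescale = rise_timescale,
      sleep_onset_latency = sleep_onset_latency, noise_sd = noise_sd,
      ambient_temp = ambient_temp, contact_coupling = contact_coupling,
      movement_rate = movement_rate, coupling_jitter = coupling_jitter,
      wander_amp = wander_amp,
      between_subject_sd = between_subject_sd, latency_sd = latency_sd
    ),
    class = "physio_params"
  )
}

#' Artifact contamination settings
#'
#' Rates of the invalid-data modes seen in field recordings: null samples,
#' negative readings, large intra-minute oscillations (electronics issues),
#' and out-of-bed segments.
#'
#' @param p_null Per-sample probability that a strip/wrist sample is null.
#' @param p_negative Per-sample probability of a negative reading.
#' @param p_oscillation_minute Per-minute probability that a minute of strip
#'   data is contaminated by a large alternating oscillation.
#' @param oscillation_amplitude Peak amplitude of injected oscillations,
#'   degrees C.
#' @param n_absence_segments Number of bed-absence segments injected per
#'   session.
#' @param absence_duration Length-2 numeric, min/max absence duration in
#'   minutes.
#' @return An object of class `artifact_spec`.
#' @export
artifact_spec <- function(p_null = 5e-5,
                          p_negative = 2e-5,
                          p_oscillation_minute = 0.01,
                          oscillation_amplitude = 3,
                          n_absence_segments = 1,
                          absence_duration = c(2, 8)) {
  probs <- c(p_null, p_negative, p_oscillation_minute)
  if (any(probs < 0 | probs > 1)) {
    abort("artifact probabilities must lie in [0, 1]")
  }
  if (oscillation_amplitude <= 0) abort("oscillation_amplitude must be > 0")
  structure(
    list(
      p_null = p_null, p_negative = p_negative,
      p_oscillation_minute = p_oscillation_minute,
      oscillation_amplitude = oscillation_amplitude,
      n_absence_segments = n_absence_segments,
      absence_duration = absence_duration
    ),
    class = "artifact_spec"
  )
}

#' Silent artifact settings (no contamination)
#' @return An `artifact_spec` with all rates zero.
#' @export
no_artifacts <- function() {
  artifact_spec(p_null = 0, p_negative = 0, p_oscillation_minute = 0,
                n_absence_segments = 0)
}

#' Hyperparameter search space for the two-stage model
#'
#' The default space matches the published search: gradient boosted tree
#' (GBT) estimators in \{100, 200, 300\}, maximum depth in
#' \{3, 5, 7, 9, 15\}, learning rate uniform on (0, 1); random forest (RF)
#' estimators in \[10, 300\], maximum depth in \[1, 30\] or unbounded, and
#' minimum samples to split in \[2, 20\].
#'
#' @param gbt_n_estimators Integer choices for GBT boosting rounds.
#' @param gbt_max_depth Integer choices for GBT tree depth.
#' @param gbt_learning_rate Length-2 range for the GBT learning rate.
#' @param rf_n_estimators Length-2 integer range for RF tree count.
#' @param rf_max_depth Length-2 integer range for RF depth.
#' @param rf_allow_unbounded_depth Include an explicit unbounded-depth option
#'   alongside the bounded range.
#' @param rf_min_samples_split Length-2 integer range for the minimum node
#'   size that may still be split.
#' @return An object of class `hyperparam_space`.
#' @export
hyperparam_space <- function(gbt_n_estimators = c(100L, 200L, 300L),
                             gbt_max_depth = c(3L, 5L, 7L, 9L, 15L),
                             gbt_learning_rate = c(0, 1),
                             rf_n_estimators = c(10L, 300L),
                             rf_max_depth = c(1L, 30L),
                             rf_allow_unbounded_depth = TRUE,
                             rf_min_samples_split = c(2L, 20L)) {
  structure(
    list(
      gbt_n_estimators = as.integer(gbt_n_estimators),
      gbt_max_depth = as.integer(gbt_max_depth),
      gbt_learning_rate = as.numeric(gbt_learning_rate),
      rf_n_estimators = as.integer(rf_n_estimators),
      rf_max_depth = as.integer(rf_max_depth),
      rf_allow_unbounded_depth = isTRUE(rf_allow_unbounded_depth),
      rf_min_samples_split = as.integer(rf_min_samples_split)
    ),
    class = "hyperparam_space"
  )
}

#' A concrete hyperparameter configuration
#'
#' @param gbt_n_estimators,gbt_max_depth,gbt_learning_rate Stage-one GBT
#'   settings.
#' @param rf_n_estimators,rf_max_depth,rf_min_samples_split Stage-two RF
#'   settings; `rf_max_depth = 0` means unbounded.
#' @return An object of class `hyperparam_config`.
#' @export
hyperparam_config <- function(gbt_n_estimators = 300L,
                              gbt_max_depth = 3L,
                              gbt_learning_rate = 0.031,
                              rf_n_estimators = 300L,
                              rf_max_depth = 0L,
                              rf_min_samples_split = 2L) {
  structure(
    list(
      gbt_n_estimators = as.integer(gbt_n_estimators),
      gbt_max_depth = as.integer(gbt_max_depth),
      gbt_learning_rate = as.numeric(gbt_learning_rate),
      rf_n_estimators = as.integer(rf_n_estimators),
      rf_max_depth = as.integer(rf_max_depth),
      rf_min_samples_split = as.integer(rf_min_samples_split)
    ),
    class = "hyperparam_config"
  )
}

#' Default model configuration
#'
#' The optimum reported for the original in-home study: 300 GBT trees of
#' depth 3 with learning rate 0.031, and a 300-tree random forest with
#' unbounded depth and minimum split size 2. Used as the test-time default
#' without any claim of optimality on other data.
#'
#' @return A `hyperparam_config`.
#' @export
default_config <- function() hyperparam_config()

config_in_space <- function(config, space) {
  depth_ok <- if (config$rf_max_depth == 0L) {
    space$rf_allow_unbounded_depth
  } else {
    config$rf_max_depth >= space$rf_max_depth[1] &&
      config$rf_max_depth <= space$rf_max_depth[2]
  }
  config$gbt_n_estimators %in% space$gbt_n_estimators &&
    config$gbt_max_depth %in% space$gbt_max_depth &&
    config$gbt_learning_rate >= space$gbt_learning_rate[1] &&
    config$gbt_learning_rate <= space$gbt_learning_rate[2] &&
    config$rf_n_estimators >= space$rf_n_estimators[1] &&
    config$rf_n_estimators <= space$rf_n_estimators[2] &&
    depth_ok &&
    config$rf_min_samples_split >= space$rf_min_samples_split[1] &&
    config$rf_min_samples_split <= space$rf_min_samples_split[2]
}
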