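# Fixtures are generated in code; nothing is read from disk.

# A slow random-walk feature table where the reference is exactly V1 —
# the identity map the estimator should recover.
identity_features <- function(n_minutes = 300, subject = "S01",
                              session = "N01", seed = 1,
                              start = 32, step_sd = 0.03) {
  withr::with_seed(seed, {
    v1 <- start + cumsum(rnorm(n_minutes, 0, step_sd))
    v1 <- pmin(pmax(v1, 29), 36)
    out <- tibble::tibble(
      n = seq_len(n_minutes),
      V1 = v1, V2 = v1 - 0.5, V3 = v1 - 1,
      i1 = 3L, i2 = 4L, i3 = 2L,
      s = v1,
      tss_valid = TRUE, ref_valid = TRUE
    )
    attr(out, "meta") <- list(subject_id = subject, session_id = session,
                              setting = "home", lights_off = NA_real_)
    attr(out, "included") <- TRUE
    class(out) <- c("tss_features", class(out))
    out
  })
}

# Several identity-map sessions from distinct subjects.
identity_study_features <- function(n_subjects = 4, n_minutes = 300,
                                    seed = 1) {
  purrr::map(seq_len(n_subjects), function(i) {
    identity_features(n_minutes, subject = sprintf("S%02d", i),
                      seed = seed + i)
  })
}

# Minimal raw stream builder.
raw_stream <- function(t, v, channel = "T1") {
  tibble::tibble(channel = channel, t_seconds = t, value_c = v)
}

# Quality mask with a prescribed number of valid minutes out of n.
mask_with_fraction <- function(n, n_valid) {
  flags <- c(rep("valid", n_valid), rep("missing", n - n_valid))
  bedtherm:::new_quality_mask(seq_len(n), flags)
}

quick_session <- function(seed = 1, duration = 90, setting = "home",
                          params = physio_params()) {
  simulate_subject_night(params, setting, duration = duration, seed = seed)
}
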