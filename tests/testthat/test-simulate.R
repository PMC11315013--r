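test_that("latent distal temperature rises by about the configured magnitude", {
  p <- physio_params(distal_rise = 1, sleep_onset_latency = 20)
  rec <- simulate_subject_night(p, "home", duration = 90, seed = 7)
  rise <- mean(rec$latent$dst[50:60]) - mean(rec$latent$dst[1:10])
  expect_gte(rise, 0.8)
  expect_lte(rise, 1.2)
})

test_that("latent trajectory is non-decreasing through the rise window", {
  p <- physio_params(noise_sd = 0, sleep_onset_latency = 15,
                     rise_timescale = 30)
  rec <- simulate_subject_night(p, "home", duration = 90, seed = 3)
  window <- rec$latent$dst[15:45]
  expect_true(all(diff(window) >= -1e-12))
})

test_that("emitted samples are quantized to their channel resolution", {
  p <- physio_params(noise_sd = 0)
  rec <- simulate_subject_night(p, "home", duration = 60, seed = 5)
  for (row in seq_len(nrow(channel_spec()))) {
    ch <- channel_spec()$channel[row]
    res <- channel_spec()$resolution[row]
    v <- rec$streams$value_c[rec$streams$channel == ch]
    expect_true(all(abs(v / res - round(v / res)) < 1e-9),
                label = paste("channel", ch, "quantized"))
  }
})

test_that("identical parameters and seed reproduce identical sessions", {
  p <- physio_params()
  a <- simulate_subject_night(p, "lab", duration = 60, seed = 42)
  b <- simulate_subject_night(p, "lab", duration = 60, seed = 42)
  expect_identical(a$streams, b$streams)
  expect_identical(a$latent, b$latent)
  c <- simulate_subject_night(p, "lab", duration = 60, seed = 43)
  expect_false(identical(a$streams, c$streams))
})

test_that("simulator rejects invalid inputs", {
  expect_error(physio_params(contact_coupling = c(0.5, 0.5)), "5 entries")
  expect_error(physio_params(contact_coupling = c(0.5, 0.5, 0.5, 0.5, 1.2)),
               "5 entries")
  expect_error(physio_params(noise_sd = -1), "noise_sd")
  expect_error(simulate_subject_night(physio_params(), "home",
                                      duration = 30, seed = 1),
               "at least 60")
  expect_error(simulate_subject_night(physio_params(), "home",
                                      duration = 90),
               "seed")
})

test_that("setting controls the channel complement and lights-off", {
  home <- quick_session(seed = 1, setting = "home")
  lab <- quick_session(seed = 1, setting = "lab")
  expect_true("wrist" %in% home$streams$channel)
  expect_false("wrist" %in% lab$streams$channel)
  expect_true(is.na(home$lights_off))
  expect_equal(lab$lights_off, 600)
})

test_that("zero artifact rates leave the recording untouched", {
  rec <- quick_session(seed = 2)
  out <- inject_artifacts(rec, no_artifacts(), seed = 9)
  expect_identical(out$streams, rec$streams)
  expect_identical(out$presence, rec$presence)
  counts <- attr(out, "artifact_counts")
  expect_true(all(unlist(counts) == 0))
})

test_that("saturating null probability nulls every sample of the channel", {
  rec <- quick_session(seed = 2)
  out <- inject_artifacts(rec, artifact_spec(p_null = 1), seed = 9,
                          channels = "T1")
  t1 <- out$streams$value_c[out$streams$channel == "T1"]
  expect_true(all(is.na(t1)))
  others <- out$streams$value_c[out$streams$channel != "T1"]
  expect_false(anyNA(others))
})

test_that("artifact counts equal the modifications actually made", {
  rec <- quick_session(seed = 4)
  spec <- artifact_spec(p_null = 0.01, p_negative = 0.01,
                        p_oscillation_minute = 0.05,
                        n_absence_segments = 2)
  out <- inject_artifacts(rec, spec, seed = 11)
  counts <- attr(out, "artifact_counts")
  expect_equal(sum(is.na(out$streams$value_c)), counts$n_null)
  expect_equal(sum(out$streams$value_c < 0, na.rm = TRUE), counts$n_negative)
  expect_equal(counts$n_absence_segments, 2)
  lost <- sum(rec$presence$end_s - rec$presence$start_s) -
    sum(out$presence$end_s - out$presence$start_s)
  expect_gt(lost, 0)
})

test_that("minute-oscillation contamination matches its binomial expectation", {
  rec <- simulate_subject_night(
    physio_params(), "home", duration = 400, seed = 6,
    include_wrist = FALSE, include_foot = FALSE, include_proximal = FALSE
  )
  spec <- artifact_spec(p_null = 0, p_negative = 0,
                        p_oscillation_minute = 0.1, n_absence_segments = 0)
  n_rep <- 150
  hits <- vapply(seq_len(n_rep), function(i) {
    attr(inject_artifacts(rec, spec, seed = 1000 + i),
         "artifact_counts")$n_oscillation_minutes
  }, numeric(1))
  expected <- 400 * 0.1
  se <- sqrt(400 * 0.1 * 0.9 / n_rep)
  expect_lt(abs(mean(hits) - expected), 3 * se)
})

test_that("study layout produces the requested session grid", {
  st <- simulate_study(3, 2, 2, 1, physio_params(), no_artifacts(),
                       seed = 8, duration = 60)
  expect_equal(sum(st$sessions$setting == "home"), 6)
  expect_equal(sum(st$sessions$setting == "lab"), 2)
  expect_true(all(st$sessions$subject_id %in% st$participants$subject_id))
  one <- simulate_study(1, 1, 0, 0, physio_params(), no_artifacts(),
                        seed = 8, duration = 60)
  expect_equal(nrow(one$sessions), 1)
  expect_error(simulate_study(0, 1, 0, 1, seed = 1), "at least one subject")
  # lab recordings carry lights-off and foot but no wrist
  lab_rec <- st$sessions$recording[[which(st$sessions$setting == "lab")[1]]]
  expect_false(is.na(lab_rec$lights_off))
  expect_true("foot" %in% lab_rec$streams$channel)
  expect_false("wrist" %in% lab_rec$streams$channel)
})

test_that("study simulation is reproducible under its seed", {
  a <- simulate_study(2, 1, 1, 1, physio_params(), artifact_spec(),
                      seed = 21, duration = 60)
  b <- simulate_study(2, 1, 1, 1, physio_params(), artifact_spec(),
                      seed = 21, duration = 60)
  expect_identical(purrr::map(a$sessions$recording, "streams"),
                   purrr::map(b$sessions$recording, "streams"))
  expect_identical(a$participants, b$participants)
})

test_that("demographic summaries use the sample standard deviation", {
  roster <- example_participants()
  s <- summarize_demographics(roster)
  expect_equal(round(s$mean_age, 1), 44.5)
  expect_equal(round(s$sd_age, 1), 6.7)
  expect_equal(s$n_male, 9L)
  expect_equal(s$n_female, 9L)

  two <- tibble::tibble(subject_id = c("a", "b"), gender = c("Male", "Female"),
                        age = c(40, 50))
  s2 <- summarize_demographics(two)
  expect_equal(s2$mean_age, 45)
  expect_equal(s2$sd_age, sqrt(50), tolerance = 1e-12)

  same <- tibble::tibble(subject_id = c("a", "b"), gender = c("Male", "Male"),
                         age = c(44, 44))
  expect_equal(summarize_demographics(same)$sd_age, 0)
  expect_error(summarize_demographics(same[1, ]), "at least two")
})
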