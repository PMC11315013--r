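# independent windowed-mean oracle for minute aggregation
oracle_minute_mean <- function(t, v, duration_min) {
  vapply(seq_len(duration_min), function(n) {
    inwin <- t >= 60 * (n - 1) & t < 60 * n
    if (!any(inwin)) NA_real_ else mean(v[inwin])
  }, numeric(1))
}

test_that("minute aggregation equals the windowed mean", {
  s <- raw_stream(0:59 + 0.5, rep(30, 60))
  agg <- aggregate_minute(s, duration_min = 1)
  expect_equal(agg$value, 30)

  s2 <- raw_stream(0:59 + 0.5, rep(c(29.9, 30.1), 30))
  expect_equal(aggregate_minute(s2, duration_min = 1)$value, 30)

  withr::with_seed(10, {
    t <- sort(runif(600, 0, 600))
    v <- rnorm(600, 33, 1)
  })
  agg3 <- aggregate_minute(raw_stream(t, v), duration_min = 10)
  expect_equal(agg3$value, oracle_minute_mean(t, v, 10), tolerance = 1e-9)
})

test_that("aggregation is linear and empty streams give empty series", {
  withr::with_seed(2, {
    t <- sort(runif(180, 0, 180))
    v <- rnorm(180, 30, 0.5)
  })
  a1 <- aggregate_minute(raw_stream(t, v), duration_min = 3)
  a2 <- aggregate_minute(raw_stream(t, 2.5 * v), duration_min = 3)
  expect_equal(a2$value, 2.5 * a1$value, tolerance = 1e-12)

  empty <- aggregate_minute(raw_stream(numeric(), numeric()),
                            duration_min = 0, nominal_rate = 1)
  expect_equal(nrow(empty), 0)
})

test_that("invalid minutes are flagged by cause", {
  t <- 0:179 + 0.5
  v <- rep(30, 180)
  v[30] <- NA            # null in minute 1
  v[70] <- -1            # negative in minute 2
  v[130] <- 31.6         # 1.6 degC range in minute 3 (below threshold)
  s <- raw_stream(t, v)
  agg <- aggregate_minute(s, duration_min = 3)
  mask <- flag_invalid_minutes(agg, s, oscillation_threshold = 2)
  expect_equal(as.character(mask$flag),
               c("null_invalid", "negative_invalid", "valid"))

  v2 <- rep(30, 180); v2[130] <- 33  # 3 degC range in minute 3
  s2 <- raw_stream(t, v2)
  mask2 <- flag_invalid_minutes(aggregate_minute(s2, duration_min = 3), s2,
                                oscillation_threshold = 2)
  expect_equal(as.character(mask2$flag),
               c("valid", "valid", "oscillation_invalid"))

  # sparse minute -> missing (under 50% of nominal 60 samples/min)
  s3 <- raw_stream(c(0:59, 60:79) + 0.5, rep(30, 80))
  mask3 <- flag_invalid_minutes(aggregate_minute(s3, duration_min = 2), s3, 2)
  expect_equal(as.character(mask3$flag), c("valid", "missing"))
})

test_that("flag counts always account for every minute", {
  rec <- quick_session(seed = 12)
  rec <- inject_artifacts(rec, artifact_spec(p_null = 0.005,
                                             p_negative = 0.003,
                                             p_oscillation_minute = 0.1),
                          seed = 3)
  f <- preprocess_session(rec)
  mask <- attr(f, "tss_mask")
  expect_equal(sum(table(mask$flag)), rec$duration_min)
  expect_equal(good_fraction(mask), mean(mask$flag == "valid"))
})

test_that("bed absence overrides valid minutes by window overlap", {
  mask <- mask_with_fraction(30, 30)
  full <- mask_bed_absence(mask, tibble::tibble(start_s = 0, end_s = 1800))
  expect_equal(as.character(full$flag), rep("valid", 30))

  none <- mask_bed_absence(mask, tibble::tibble(start_s = numeric(),
                                                end_s = numeric()))
  expect_equal(as.character(none$flag), rep("bed_absent", 30))

  # presence exactly covering minutes 10..20
  part <- mask_bed_absence(mask, tibble::tibble(start_s = 540, end_s = 1200))
  expect_equal(which(part$flag == "valid"), 10:20)
  expect_true(all(part$flag[-(10:20)] == "bed_absent"))
})

test_that("the session gate is an inclusive conjunction at 80%", {
  expect_true(session_quality_gate(mask_with_fraction(100, 95),
                                   mask_with_fraction(100, 95)))
  expect_true(session_quality_gate(mask_with_fraction(100, 80),
                                   mask_with_fraction(100, 80)))
  expect_false(session_quality_gate(mask_with_fraction(100, 81),
                                    mask_with_fraction(100, 79)))
  expect_warning(
    expect_false(session_quality_gate(mask_with_fraction(0, 0),
                                      mask_with_fraction(100, 95))),
    class = "bedtherm_warning_empty_session"
  )
})

test_that("raising artifact rates never improves the good fraction", {
  rec <- quick_session(seed = 14, duration = 120)
  gf <- function(p_mult) {
    spec <- artifact_spec(p_null = 1e-3 * p_mult, p_negative = 5e-4 * p_mult,
                          p_oscillation_minute = 0.02 * p_mult,
                          n_absence_segments = 1)
    f <- preprocess_session(inject_artifacts(rec, spec, seed = 99))
    c(good_fraction(attr(f, "tss_mask")), good_fraction(attr(f, "ref_mask")))
  }
  low <- gf(1); high <- gf(5)
  expect_true(all(high <= low + 1e-12))
})

test_that("top-three selection sorts descending with stable ties", {
  one <- select_top3(tibble::tibble(n = 1, T1 = 20.1, T2 = 31.2, T3 = 30.0,
                                    T4 = 33.4, T5 = 29.5))
  expect_equal(c(one$V1, one$V2, one$V3), c(33.4, 31.2, 30.0))
  expect_equal(c(one$i1, one$i2, one$i3), c(4L, 2L, 3L))

  ties <- select_top3(tibble::tibble(n = 1, T1 = 30, T2 = 30, T3 = 30,
                                     T4 = 30, T5 = 30))
  expect_equal(c(ties$i1, ties$i2, ties$i3), c(1L, 2L, 3L))

  desc <- select_top3(tibble::tibble(n = 1, T1 = 35, T2 = 34, T3 = 33,
                                     T4 = 32, T5 = 31))
  expect_equal(c(desc$V1, desc$V2, desc$V3), c(35, 34, 33))

  # a minute with any missing sensor is excluded
  gap <- select_top3(tibble::tibble(n = 1:2, T1 = c(30, 30), T2 = c(31, NA),
                                    T3 = c(32, 32), T4 = c(33, 33),
                                    T5 = c(34, 34)))
  expect_equal(gap$n, 1L)
})

test_that("top-three values are invariant to channel relabeling", {
  withr::with_seed(5, {
    vals <- matrix(runif(50 * 5, 28, 35), 50, 5)
  })
  wide <- tibble::as_tibble(as.data.frame(vals))
  names(wide) <- paste0("T", 1:5)
  wide$n <- 1:50
  base <- select_top3(wide)
  perm <- wide
  names(perm)[1:5] <- paste0("T", c(3, 5, 1, 2, 4))
  permuted <- select_top3(perm[, c(paste0("T", 1:5), "n")])
  expect_equal(permuted[, c("V1", "V2", "V3")],
               base[, c("V1", "V2", "V3")])
})

test_that("reference smoothing preserves constants and trends, resists spikes", {
  t <- seq(0, 3600 - 0.25, by = 0.25)
  const <- smooth_reference(raw_stream(t, rep(33, length(t)), "wrist"))
  expect_equal(const$s, rep(33, 60), tolerance = 1e-9)

  ramp_v <- 32 + t / 3600
  ramp <- smooth_reference(raw_stream(t, ramp_v, "wrist"))
  mid <- 10:50
  expected <- 32 + ((mid - 0.5) * 60) / 3600
  expect_lt(max(abs(ramp$s[mid] - expected)), 0.01)

  spiked <- ramp_v
  spiked[t >= 1800 & t < 1802] <- spiked[t >= 1800 & t < 1802] + 3
  rob <- smooth_reference(raw_stream(t, spiked, "wrist"))
  expect_lt(max(abs(rob$s[mid] - expected)), 0.2)
})

test_that("smoothing does not inflate per-minute variance", {
  withr::with_seed(8, {
    t <- seq(0, 1200 - 0.25, by = 0.25)
    v <- 33 + 0.5 * sin(t / 300) + rnorm(length(t), 0, 0.2)
  })
  sm <- smooth_reference(raw_stream(t, v, "wrist"))
  raw_minutes <- aggregate_minute(raw_stream(t, v, "wrist"),
                                  duration_min = 20, nominal_rate = 4)
  expect_lte(var(sm$s), var(raw_minutes$value))
})

test_that("preprocessing a clean session yields a gated, fully valid table", {
  rec <- quick_session(seed = 16, duration = 60,
                       params = physio_params(noise_sd = 0.05))
  f <- preprocess_session(rec)
  expect_true(attr(f, "included"))
  expect_equal(nrow(f), 60)
  expect_true(all(f$V1 >= f$V2 & f$V2 >= f$V3, na.rm = TRUE))
  expect_true(sum(f$tss_valid) > 50)
  expect_true(all(!is.na(f$s[f$ref_valid])))
})
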