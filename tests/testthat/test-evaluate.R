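# single-pass reference implementations of the agreement statistics
oracle_bland_altman <- function(s, y) {
  d <- s - y
  m <- length(d)
  bias <- sum(d) / m
  sd_d <- sqrt(sum((d - bias)^2) / (m - 1))
  c(bias = bias, sd_d = sd_d,
    lower = bias - 1.96 * sd_d, upper = bias + 1.96 * sd_d)
}
oracle_r2 <- function(s, y) 1 - sum((s - y)^2) / sum((s - mean(s))^2)

test_that("Bland-Altman statistics match hand-computed values", {
  s <- c(30.2, 30.4, 30.6)
  y <- c(30.0, 30.0, 30.0)
  ba <- bland_altman(s, y, smooth = FALSE)
  expect_equal(ba$bias, 0.4, tolerance = 1e-12)
  expect_equal(ba$sd_d, 0.2, tolerance = 1e-12)
  expect_equal(ba$lower_loa, 0.008, tolerance = 1e-12)
  expect_equal(ba$upper_loa, 0.792, tolerance = 1e-12)
  expect_equal(ba$m, 3L)

  perfect <- bland_altman(s, s, smooth = FALSE)
  expect_equal(perfect$bias, 0)
  expect_equal(perfect$sd_d, 0)
  expect_equal(c(perfect$lower_loa, perfect$upper_loa), c(0, 0))

  expect_error(bland_altman(1, 1, smooth = FALSE),
               class = "bedtherm_error_insufficient_pairs")
})

test_that("agreement statistics equal an independent oracle on random data", {
  withr::with_seed(123, {
    for (i in 1:50) {
      m <- sample(10:300, 1)
      s <- rnorm(m, 33, 0.7)
      y <- s + rnorm(m, 0, 0.3)
      ba <- bland_altman(s, y, smooth = FALSE)
      o <- oracle_bland_altman(s, y)
      expect_equal(ba$bias, unname(o["bias"]), tolerance = 1e-10)
      expect_equal(ba$sd_d, unname(o["sd_d"]), tolerance = 1e-10)
      expect_equal(ba$lower_loa, unname(o["lower"]), tolerance = 1e-10)
      expect_equal(ba$upper_loa, unname(o["upper"]), tolerance = 1e-10)
      expect_equal(r_squared(s, y), oracle_r2(s, y), tolerance = 1e-12)
      expect_equal(ba$upper_loa - ba$lower_loa, 2 * 1.96 * ba$sd_d,
                   tolerance = 1e-12)
    }
  })
})

test_that("adding a constant to the estimate shifts only the bias", {
  withr::with_seed(9, {
    s <- rnorm(100, 33, 0.5)
    y <- s + rnorm(100, 0, 0.2)
  })
  a <- bland_altman(s, y, smooth = FALSE)
  b <- bland_altman(s, y + 0.3, smooth = FALSE)
  expect_equal(b$bias, a$bias - 0.3, tolerance = 1e-12)
  expect_equal(b$sd_d, a$sd_d, tolerance = 1e-12)
})

test_that("R-squared has its textbook fixed points", {
  withr::with_seed(4, s <- rnorm(50, 33, 0.5))
  expect_equal(r_squared(s, s), 1.0)
  expect_equal(r_squared(s, rep(mean(s), 50)), 0.0, tolerance = 1e-12)
  expect_error(r_squared(rep(33, 10), rnorm(10)),
               class = "bedtherm_error_constant_reference")
})

test_that("series pairing joins on the minute index", {
  s <- tibble::tibble(n = 1:10, s = 33 + (1:10) / 10)
  y <- tibble::tibble(n = 4:12, y = 33.2 + (4:12) / 10)
  ba <- bland_altman(s, y, smooth = FALSE)
  expect_equal(ba$m, 7L)
  expect_equal(ba$bias, -0.2, tolerance = 1e-12)
})

test_that("subject folds are balanced, disjoint and exhaustive", {
  ids <- sprintf("S%02d", 1:18)
  folds <- make_subject_folds(ids, k = 5, seed = 1)
  sizes <- sort(as.integer(table(folds$fold)), decreasing = TRUE)
  expect_equal(sizes, c(4L, 4L, 4L, 3L, 3L))
  expect_setequal(folds$subject_id, ids)
  expect_equal(anyDuplicated(folds$subject_id), 0)

  single <- make_subject_folds(ids, k = 1, seed = 2)
  expect_true(all(single$fold == 1))
  expect_error(make_subject_folds(ids[1:3], k = 5), "exceed")
  expect_identical(make_subject_folds(ids, 5, seed = 3),
                   make_subject_folds(ids, 5, seed = 3))
})

test_that("change curves are normalized to zero at lights-off", {
  const <- tibble::tibble(n = 1:120, value = 33)
  cc <- change_curve(const, lights_off = 600, horizon = 60)
  expect_equal(cc$delta, rep(0, 61))
  expect_equal(cc$minute, 0:60)

  lin <- tibble::tibble(n = 1:120, value = 30 + 0.02 * (1:120))
  cc2 <- change_curve(lin, lights_off = 600, horizon = 60)
  expect_equal(cc2$delta[1], 0)
  expect_equal(cc2$delta[61], 1.2, tolerance = 1e-12)

  expect_error(change_curve(const, lights_off = NA), "lights_off")
  gappy <- const
  gappy$value[20] <- NA
  cc3 <- change_curve(gappy, lights_off = 600, horizon = 60)
  expect_true(is.na(cc3$delta[cc3$minute == 9]))  # minute 20 = lights-off + 9
})

test_that("grand averages correlate as expected in degenerate cases", {
  base <- tibble::tibble(minute = 0:60, delta = seq(0, 1, length.out = 61))
  set_a <- list(base, dplyr::mutate(base, delta = delta * 1.1))
  same <- grand_average_and_correlate(set_a, set_a)
  expect_equal(same$r, 1.0, tolerance = 1e-12)

  negated <- purrr::map(set_a, ~ dplyr::mutate(.x, delta = -delta))
  anti <- grand_average_and_correlate(set_a, negated)
  expect_equal(anti$r, -1.0, tolerance = 1e-12)

  expect_error(grand_average_and_correlate(set_a[1], set_a), "at least two")
})

test_that("cross-validation is subject-blocked with faithful aggregation", {
  study <- simulate_study(6, 2, 0, 0, physio_params(), no_artifacts(),
                          seed = 77, duration = 60)
  prep <- preprocess_study(study)
  cv <- run_cv(prep, config = default_config(), k = 3, seed = 77)

  # no subject appears in two folds, and validation subjects own their fold
  expect_equal(anyDuplicated(cv$folds$subject_id), 0)
  joined <- dplyr::left_join(cv$session_stats, cv$folds, by = "subject_id")
  expect_true(all(joined$fold.x == joined$fold.y))

  # fold means are the unweighted means of their session stats
  manual <- cv$session_stats |>
    dplyr::group_by(fold) |>
    dplyr::summarise(bias = mean(bias), r2 = mean(r2), .groups = "drop")
  expect_equal(cv$fold_means$bias, manual$bias, tolerance = 1e-12)
  expect_equal(cv$fold_means$r2, manual$r2, tolerance = 1e-12)
  expect_equal(cv$grand$bias, mean(cv$fold_means$bias), tolerance = 1e-12)

  # tidy()/glance() expose the fold and grand summaries
  expect_identical(tidy(cv), cv$fold_means)
  expect_equal(glance(cv)$r2, cv$grand$r2)
})

test_that("the learning curve at full budget reproduces the CV grand mean", {
  study <- simulate_study(6, 2, 0, 0, physio_params(), no_artifacts(),
                          seed = 78, duration = 60)
  prep <- preprocess_study(study)
  cv <- run_cv(prep, k = 3, seed = 78)
  lc <- learning_curve(prep, fractions = 1, k = 3, seed = 78)
  expect_equal(lc$val_r2, cv$grand$r2, tolerance = 1e-12)
  expect_error(learning_curve(prep, fractions = c(0, 0.5)), "fractions")
})
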