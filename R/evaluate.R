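pair_series <- function(s, y) {
  if (is.data.frame(s) && is.data.frame(y)) {
    sv <- names(s)[names(s) != "n"][1]
    yv <- names(y)[names(y) != "n"][1]
    paired <- dplyr::inner_join(
      stats::setNames(s[, c("n", sv)], c("n", "s")),
      stats::setNames(y[, c("n", yv)], c("n", "y")),
      by = "n"
    )
  } else {
    if (length(s) != length(y)) abort("s and y must have equal length")
    paired <- tibble::tibble(n = seq_along(s), s = as.numeric(s),
                             y = as.numeric(y))
  }
  paired[!is.na(paired$s) & !is.na(paired$y), ]
}

# LOWESS smoothing of a minute-indexed series, same robust settings as the
# reference smoother; window covers at least 10 minutes.
smooth_minute_series <- function(n, v, lowess_frac = 0.05, lowess_iter = 3) {
  if (length(n) < 3) return(v)
  f <- min(1, max(lowess_frac, 10 / length(n)))
  sm <- lowess(n, v, f = f, iter = lowess_iter)
  sm$y[match(n, sm$x)]
}

#' Bland-Altman agreement between reference and estimated DST
#'
#' Over the `m` paired minutes, `bias = mean(s - y)`, `sd_d` is the sample
#' standard deviation of the differences (denominator `m - 1`), and the 95%
#' limits of agreement are `bias -/+ 1.96 * sd_d`. The estimate is
#' LOWESS-smoothed before comparison (disable with `smooth = FALSE`). The
#' coefficient of determination of the paired values is included.
#'
#' @param s Reference series: tibble `(n, s)` or numeric vector.
#' @param y Estimated series: tibble `(n, y)` or numeric vector aligned with
#'   `s`.
#' @param smooth Smooth the estimate before comparison.
#' @param lowess_frac,lowess_iter Smoother settings.
#' @return One-row tibble: `bias`, `sd_d`, `lower_loa`, `upper_loa`, `r2`,
#'   `m`.
#' @export
#' @examples
#' bland_altman(c(33.2, 33.4, 33.6), c(33.0, 33.0, 33.0), smooth = FALSE)
bland_altman <- function(s, y, smooth = TRUE, lowess_frac = 0.05,
                         lowess_iter = 3) {
  paired <- pair_series(s, y)
  if (nrow(paired) < 2) {
    abort("Bland-Altman statistics need at least 2 paired minutes",
          class = "bedtherm_error_insufficient_pairs")
  }
  if (smooth) {
    paired$y <- smooth_minute_series(paired$n, paired$y, lowess_frac,
                                     lowess_iter)
  }
  d <- paired$s - paired$y
  bias <- mean(d)
  sd_d <- sd(d)
  r2 <- if (sd(paired$s) > 0) {
    r_squared(paired$s, paired$y)
  } else {
    NA_real_
  }
  tibble::tibble(
    bias = bias, sd_d = sd_d,
    lower_loa = bias - 1.96 * sd_d,
    upper_loa = bias + 1.96 * sd_d,
    r2 = r2, m = nrow(paired)
  )
}

#' Coefficient of determination of an estimate against a reference
#'
#' `1 - SS_res / SS_tot` with `SS_tot` taken about the mean of the
#' reference: the proportion of the variation in the reference DST explained
#' by the estimate.
#'
#' @param s Reference values (numeric or tibble `(n, s)`).
#' @param y Estimates aligned with `s`.
#' @return A single number (<= 1, possibly negative).
#' @export
r_squared <- function(s, y) {
  paired <- pair_series(s, y)
  if (nrow(paired) < 2) {
    abort("R-squared needs at least 2 paired values",
          class = "bedtherm_error_insufficient_pairs")
  }
  ss_tot <- sum((paired$s - mean(paired$s))^2)
  if (ss_tot == 0) {
    abort("R-squared is undefined for a constant reference",
          class = "bedtherm_error_constant_reference")
  }
  1 - sum((paired$s - paired$y)^2) / ss_tot
}

#' Partition subjects into cross-validation folds
#'
#' Mutually exclusive, collectively exhaustive subject-level folds with sizes
#' differing by at most one, so that no participant contributes data to both
#' training and validation.
#'
#' @param subject_ids Character vector of unique subject ids.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Tibble `subject_id`, `fold`.
#' @export
make_subject_folds <- function(subject_ids, k = 5L, seed = 1L) {
  subject_ids <- unique(subject_ids)
  if (k < 1) abort("k must be >= 1")
  if (k > length(subject_ids)) {
    abort("k must not exceed the number of subjects")
  }
  shuffled <- withr::with_seed(seed, sample(subject_ids))
  tibble::tibble(
    subject_id = shuffled,
    fold = rep_len(seq_len(k), length(shuffled))
  ) |> dplyr::arrange(.data$subject_id)
}

session_meta <- function(f) {
  meta <- attr(f, "meta") %||% list()
  tibble::tibble(subject_id = meta$subject_id %||% NA_character_,
                 session_id = meta$session_id %||% NA_character_)
}

fit_and_score_fold <- function(feats, train_idx, val_idx, config, seed,
                               smooth = TRUE) {
  model <- train_sequential(feats[train_idx], config, seed = seed)
  stats <- purrr::map(val_idx, function(i) {
    f <- feats[[i]]
    y <- predict_session(model, f)
    ba <- bland_altman(f[, c("n", "s")], y, smooth = smooth)
    dplyr::bind_cols(session_meta(f), ba)
  })
  list(model = model, stats = dplyr::bind_rows(stats))
}

#' Subject-blocked cross-validation of the full pipeline
#'
#' Subjects are partitioned into `k` folds; for each fold the two-stage
#' model is trained sequentially on the other folds' sessions and every
#' held-out session is scored with [bland_altman()]. Accuracy is aggregated
#' session -> fold (unweighted mean over sessions) -> grand mean (unweighted
#' over folds).
#'
#' @param study A `tss_study` or a [preprocess_study()] tibble; only home
#'   sessions passing the quality gate participate.
#' @param config A [hyperparam_config()].
#' @param k Number of folds.
#' @param seed Integer seed (fold assignment and tree construction).
#' @param ... Passed to [preprocess_session()] when `study` is raw.
#' @return A `dst_cv` object: `session_stats`, `fold_means`, `grand`
#'   (one-row tibble), plus `folds`, `k`, `seed`, `config`.
#' @export
run_cv <- function(study, config = default_config(), k = 5L, seed = 1L, ...) {
  prep <- if (inherits(study, "tss_study")) {
    preprocess_study(study, ...)
  } else {
    study
  }
  prep <- prep[prep$setting == "home" & prep$included, ]
  if (!nrow(prep)) abort("no home sessions survive the quality gate")
  feats <- prep$features
  subjects <- unique(prep$subject_id)
  folds <- make_subject_folds(subjects, k = k, seed = seed)
  assignment <- folds$fold[match(prep$subject_id, folds$subject_id)]

  fold_rows <- list()
  for (i in seq_len(k)) {
    val_idx <- which(assignment == i)
    train_idx <- which(assignment != i)
    if (!length(val_idx)) {
      warn(sprintf("fold %d has no surviving validation sessions", i))
      next
    }
    res <- fit_and_score_fold(feats, train_idx, val_idx, config,
                              seed = child_seed(seed, 100 + i))
    res$stats$fold <- i
    fold_rows[[length(fold_rows) + 1]] <- res$stats
  }
  session_stats <- dplyr::bind_rows(fold_rows)
  fold_means <- session_stats |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(
      n_sessions = dplyr::n(),
      bias = mean(.data$bias), lower_loa = mean(.data$lower_loa),
      upper_loa = mean(.data$upper_loa), r2 = mean(.data$r2),
      .groups = "drop"
    )
  grand <- fold_means |>
    dplyr::summarise(
      bias = mean(.data$bias), lower_loa = mean(.data$lower_loa),
      upper_loa = mean(.data$upper_loa), r2 = mean(.data$r2)
    )
  structure(
    list(session_stats = session_stats, fold_means = fold_means,
         grand = grand, folds = folds, k = k, seed = seed, config = config),
    class = "dst_cv"
  )
}

#' @export
print.dst_cv <- function(x, ...) {
  cat(sprintf("Subject-blocked %d-fold cross-validation (%d sessions)\n",
              x$k, nrow(x$session_stats)))
  print(x$fold_means)
  cat(sprintf("grand means: bias %.3f degC, LoA [%.2f, %.2f] degC, R2 %.2f\n",
              x$grand$bias, x$grand$lower_loa, x$grand$upper_loa,
              x$grand$r2))
  invisible(x)
}

#' @method tidy dst_cv
#' @export
tidy.dst_cv <- function(x, ...) x$fold_means

#' @method glance dst_cv
#' @export
glance.dst_cv <- function(x, ...) {
  dplyr::bind_cols(x$grand,
                   tibble::tibble(k = x$k, n_sessions = nrow(x$session_stats)))
}

#' Learning curve over the training-subject budget
#'
#' For each fraction, the training subjects of every fold are subsampled at
#' the subject level, the pipeline retrained, and the mean per-session
#' R-squared reported for both the (subsampled) training sessions and the
#' validation sessions, averaged over folds. At fraction 1 the validation
#' value equals the [run_cv()] grand mean under the same seed.
#'
#' @param study A `tss_study` or [preprocess_study()] tibble.
#' @param fractions Fractions of training subjects to use, in (0, 1].
#' @param config A [hyperparam_config()].
#' @param k,seed As in [run_cv()].
#' @param ... Passed to [preprocess_session()] when `study` is raw.
#' @return Tibble (class `dst_learning_curve`): `fraction`, `train_r2`,
#'   `val_r2`, `gap`.
#' @export
learning_curve <- function(study, fractions = c(0.2, 0.4, 0.6, 0.8, 1),
                           config = default_config(), k = 5L, seed = 1L,
                           ...) {
  if (any(fractions <= 0 | fractions > 1)) {
    abort("fractions must lie in (0, 1]")
  }
  prep <- if (inherits(study, "tss_study")) {
    preprocess_study(study, ...)
  } else {
    study
  }
  prep <- prep[prep$setting == "home" & prep$included, ]
  feats <- prep$features
  subjects <- unique(prep$subject_id)
  folds <- make_subject_folds(subjects, k = k, seed = seed)
  assignment <- folds$fold[match(prep$subject_id, folds$subject_id)]

  rows <- list()
  for (f in fractions) {
    fold_train <- c(); fold_val <- c()
    for (i in seq_len(k)) {
      val_idx <- which(assignment == i)
      train_subjects <- folds$subject_id[folds$fold != i]
      n_take <- ceiling(f * length(train_subjects))
      if (n_take < 1) {
        warn(sprintf("fraction %.2f yields no training subjects; skipped", f))
        next
      }
      take <- withr::with_seed(
        child_seed(seed, 500 + i),
        sample(train_subjects, n_take)
      )
      train_idx <- which(prep$subject_id %in% take)
      if (!length(train_idx) || !length(val_idx)) next
      res <- fit_and_score_fold(feats, train_idx, val_idx, config,
                                seed = child_seed(seed, 100 + i))
      train_r2 <- purrr::map_dbl(train_idx, function(j) {
        fj <- feats[[j]]
        y <- predict_session(res$model, fj)
        bland_altman(fj[, c("n", "s")], y, smooth = TRUE)$r2
      })
      fold_train <- c(fold_train, mean(train_r2))
      fold_val <- c(fold_val, mean(res$stats$r2))
    }
    if (length(fold_val)) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        fraction = f,
        train_r2 = mean(fold_train),
        val_r2 = mean(fold_val)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$gap <- out$train_r2 - out$val_r2
  class(out) <- c("dst_learning_curve", class(out))
  out
}

#' Temperature change curve relative to lights-off
#'
#' Extracts minutes 0..`horizon` from lights-off and normalizes by
#' subtracting the value at lights-off, so the curve starts at exactly zero.
#' Missing minutes propagate as `NA`.
#'
#' @param series Tibble `(n, value)` at one sample per minute, `n` counted
#'   from session start.
#' @param lights_off Lights-off time in seconds from session start.
#' @param horizon Curve length in minutes.
#' @return Tibble `minute` (0..horizon), `delta` (degrees C).
#' @export
change_curve <- function(series, lights_off, horizon = 60) {
  if (is.null(lights_off) || is.na(lights_off)) {
    abort("lights_off is required for a change curve")
  }
  vcol <- names(series)[names(series) != "n"][1]
  m0 <- floor(lights_off / 60) + 1
  v <- series[[vcol]][match(m0 + 0:horizon, series$n)]
  if (is.na(v[1])) {
    abort("series does not cover the lights-off minute")
  }
  tibble::tibble(minute = 0:horizon, delta = v - v[1])
}

#' Grand-average two sets of change curves and correlate the means
#'
#' Pointwise unweighted means over each set (ignoring undefined points),
#' then the Pearson correlation between the two mean curves with its
#' two-sided p-value. Note the curve points are strongly autocorrelated, so
#' the p-value is optimistic; it is reported as-is for comparability.
#'
#' @param curves_a,curves_b Lists of [change_curve()] tibbles on the same
#'   minute grid.
#' @return A `curve_comparison`: `mean_a`, `mean_b` (tibbles `minute`,
#'   `delta`), `r`, `p`, `n_a`, `n_b`.
#' @export
grand_average_and_correlate <- function(curves_a, curves_b) {
  if (length(curves_a) < 2 || length(curves_b) < 2) {
    abort("at least two curves per group are required")
  }
  avg <- function(curves) {
    dplyr::bind_rows(curves) |>
      dplyr::group_by(.data$minute) |>
      dplyr::summarise(delta = mean(.data$delta, na.rm = TRUE),
                       .groups = "drop")
  }
  mean_a <- avg(curves_a)
  mean_b <- avg(curves_b)
  joined <- dplyr::inner_join(mean_a, mean_b, by = "minute",
                              suffix = c("_a", "_b"))
  joined <- joined[is.finite(joined$delta_a) & is.finite(joined$delta_b), ]
  if (nrow(joined) < 3) {
    abort("no overlapping defined minutes between the two groups")
  }
  ct <- cor.test(joined$delta_a, joined$delta_b, method = "pearson")
  structure(
    list(mean_a = mean_a, mean_b = mean_b,
         r = unname(ct$estimate), p = ct$p.value,
         n_a = length(curves_a), n_b = length(curves_b)),
    class = "curve_comparison"
  )
}

#' @export
print.curve_comparison <- function(x, ...) {
  cat(sprintf(
    "Grand-average change curves (%d vs %d sessions): Pearson r = %.3f, p = %.3g\n",
    x$n_a, x$n_b, x$r, x$p
  ))
  invisible(x)
}

#' Verify the estimator on in-lab sessions via change curves
#'
#' Estimates the DST of every lab session with a trained model, extracts the
#' estimated-DST and measured foot-temperature change curves from lights-off,
#' and correlates their grand averages — the falling-asleep process should
#' raise both distal temperatures in a strongly correlated way.
#'
#' @param study A `tss_study` containing lab sessions.
#' @param model A trained `dst_model`.
#' @param horizon Curve length in minutes.
#' @param ... Passed to [preprocess_session()].
#' @return A `dst_verification`: the `curve_comparison` plus the per-session
#'   curve lists (`est_curves`, `foot_curves`).
#' @export
verify_in_lab <- function(study, model, horizon = 60, ...) {
  stopifnot(inherits(study, "tss_study"))
  lab <- study$sessions[study$sessions$setting == "lab", ]
  if (!nrow(lab)) abort("study has no lab sessions")
  est_curves <- list(); foot_curves <- list()
  for (i in seq_len(nrow(lab))) {
    rec <- lab$recording[[i]]
    f <- preprocess_session(rec, ...)
    y <- predict_session(model, f)
    res <- tryCatch(
      list(
        est = change_curve(y, rec$lights_off, horizon),
        foot = change_curve(f[, c("n", "foot")], rec$lights_off, horizon)
      ),
      error = function(e) {
        warn(sprintf("session %s/%s skipped: %s", rec$subject_id,
                     rec$session_id, conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(res)) {
      est_curves[[length(est_curves) + 1]] <- res$est
      foot_curves[[length(foot_curves) + 1]] <- res$foot
    }
  }
  cmp <- grand_average_and_correlate(est_curves, foot_curves)
  structure(
    c(cmp, list(est_curves = est_curves, foot_curves = foot_curves)),
    class = c("dst_verification", "curve_comparison")
  )
}
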