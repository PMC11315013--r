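flag_levels <- function() {
  c("valid", "missing", "null_invalid", "negative_invalid",
    "oscillation_invalid", "bed_absent")
}

new_quality_mask <- function(n, flag) {
  out <- tibble::tibble(n = n, flag = factor(flag, levels = flag_levels()))
  attr(out, "good_fraction") <-
    if (nrow(out)) mean(out$flag == "valid") else NA_real_
  class(out) <- c("quality_mask", class(out))
  out
}

#' Fraction of valid minutes in a quality mask
#' @param mask A quality mask as returned by [flag_invalid_minutes()].
#' @return Proportion of minutes flagged `valid`.
#' @export
good_fraction <- function(mask) attr(mask, "good_fraction")

#' Aggregate a raw stream to one sample per minute
#'
#' Minute `n` covers seconds `[60(n-1), 60n)` from session start; the
#' aggregated value is the mean of the samples falling in that window.
#' Minutes holding fewer than 50% of the channel's nominal sample count are
#' reported with `n_samples` so that [flag_invalid_minutes()] can mark them
#' missing.
#'
#' @param stream Tibble with `t_seconds`, `value_c` and (optionally)
#'   `channel`; timestamps must be sorted.
#' @param duration_min Minutes in the session; inferred from the last sample
#'   when `NULL`.
#' @param nominal_rate Samples/s; looked up from `channel` when `NULL`.
#' @return Tibble `n`, `value`, `n_samples` — one row per minute, `value`
#'   `NA` where no samples fell in the window (null samples propagate `NA`).
#' @export
aggregate_minute <- function(stream, duration_min = NULL,
                             nominal_rate = NULL) {
  if (is.null(nominal_rate)) {
    ch <- unique(stream$channel)
    if (length(ch) != 1) abort("stream must hold exactly one channel")
    nominal_rate <- channel_info(ch)$nominal_rate
  }
  if (nrow(stream) && is.unsorted(stream$t_seconds)) {
    abort("stream timestamps must be sorted")
  }
  if (is.null(duration_min)) {
    duration_min <- if (nrow(stream)) ceiling(max(stream$t_seconds) / 60) else 0L
  }
  out <- tibble::tibble(n = seq_len(duration_min),
                        value = NA_real_, n_samples = 0L)
  if (!nrow(stream)) return(out)
  idx <- floor(stream$t_seconds / 60) + 1
  keep <- idx >= 1 & idx <= duration_min
  idx <- idx[keep]
  v <- stream$value_c[keep]
  cnt <- tabulate(idx, nbins = duration_min)
  sums <- rowsum(v, idx)            # NA null samples propagate
  out$n_samples <- cnt
  out$value[as.integer(rownames(sums))] <- as.numeric(sums) /
    cnt[as.integer(rownames(sums))]
  attr(out, "nominal_rate") <- nominal_rate
  out
}

#' Flag invalid minutes of a channel
#'
#' A minute is `null_invalid` if any of its raw samples is null,
#' `negative_invalid` if any sample is below 0 degC, `oscillation_invalid`
#' if the intra-minute range (max - min) exceeds `oscillation_threshold`
#' (an electronics signature), `missing` if fewer than 50% of the nominal
#' samples are present, and `valid` otherwise.
#'
#' @param series Minute series from [aggregate_minute()].
#' @param raw The raw stream the series was aggregated from.
#' @param oscillation_threshold Intra-minute range limit, degrees C.
#' @return A quality mask: tibble `n`, `flag` with a `good_fraction`
#'   attribute.
#' @export
flag_invalid_minutes <- function(series, raw, oscillation_threshold = 2) {
  nominal_rate <- attr(series, "nominal_rate") %||% {
    ch <- unique(raw$channel)
    channel_info(ch)$nominal_rate
  }
  need <- 0.5 * nominal_rate * 60
  nmin <- nrow(series)
  has_null <- logical(nmin); has_neg <- logical(nmin); rng <- numeric(nmin)
  if (nrow(raw)) {
    idx <- floor(raw$t_seconds / 60) + 1
    keep <- idx >= 1 & idx <= nmin
    idx <- idx[keep]; v <- raw$value_c[keep]
    has_null[unique(idx[is.na(v)])] <- TRUE
    has_neg[unique(idx[!is.na(v) & v < 0])] <- TRUE
    fin <- !is.na(v)
    if (any(fin)) {
      mx <- tapply(v[fin], idx[fin], max)
      mn <- tapply(v[fin], idx[fin], min)
      rng[as.integer(names(mx))] <- mx - mn
    }
  }
  flag <- rep("valid", nmin)
  flag[series$n_samples < need] <- "missing"
  flag[rng > oscillation_threshold] <- "oscillation_invalid"
  flag[has_neg] <- "negative_invalid"
  flag[has_null] <- "null_invalid"
  new_quality_mask(series$n, flag)
}

#' Discard minutes outside bed-presence intervals
#'
#' Minutes whose window overlaps the presence intervals for less than 50% of
#' their span are flagged `bed_absent` (overriding `valid`).
#'
#' @param mask A quality mask.
#' @param presence_intervals Tibble with `start_s`, `end_s` (half-open,
#'   non-overlapping).
#' @return The updated quality mask.
#' @export
mask_bed_absence <- function(mask, presence_intervals) {
  flag <- as.character(mask$flag)
  w0 <- (mask$n - 1) * 60
  w1 <- mask$n * 60
  overlap <- numeric(nrow(mask))
  for (r in seq_len(nrow(presence_intervals))) {
    overlap <- overlap + pmax(0, pmin(w1, presence_intervals$end_s[r]) -
                                 pmax(w0, presence_intervals$start_s[r]))
  }
  absent <- overlap < 30
  flag[absent & flag == "valid"] <- "bed_absent"
  new_quality_mask(mask$n, flag)
}

#' Session inclusion gate on data quality
#'
#' A session enters model training only if at least `threshold` of the strip
#' minutes and at least `threshold` of the reference minutes are valid
#' ("at least" read inclusively).
#'
#' @param tss_mask,ref_mask Quality masks over the same minute span.
#' @param threshold Minimum good fraction, default 0.80.
#' @return `TRUE`/`FALSE`; a zero-length session returns `FALSE` with a
#'   warning of class `bedtherm_warning_empty_session`.
#' @export
session_quality_gate <- function(tss_mask, ref_mask, threshold = 0.80) {
  if (nrow(tss_mask) == 0 || nrow(ref_mask) == 0) {
    warn("zero-length session excluded",
         class = "bedtherm_warning_empty_session")
    return(FALSE)
  }
  good_fraction(tss_mask) >= threshold && good_fraction(ref_mask) >= threshold
}

#' Select the top three strip values per minute
#'
#' The five strip values of each minute are sorted in descending order and
#' the three largest retained — the sensors most likely in contact with the
#' body. Ties break towards the smaller sensor index.
#'
#' @param minutes Tibble with columns `n` and `T1`..`T5`.
#' @return Tibble `n`, `V1 >= V2 >= V3`, `i1`, `i2`, `i3` — only minutes
#'   where all five values are finite.
#' @export
#' @examples
#' select_top3(tibble::tibble(n = 1, T1 = 20.1, T2 = 31.2, T3 = 30.0,
#'                            T4 = 33.4, T5 = 29.5))
select_top3 <- function(minutes) {
  cols <- strip_channels()
  m <- as.matrix(minutes[, cols])
  ok <- rowSums(is.finite(m)) == 5
  m <- m[ok, , drop = FALSE]
  n <- minutes$n[ok]
  if (!nrow(m)) {
    return(tibble::tibble(n = integer(), V1 = numeric(), V2 = numeric(),
                          V3 = numeric(), i1 = integer(), i2 = integer(),
                          i3 = integer()))
  }
  ord <- t(apply(m, 1, function(x) order(-x, seq_along(x))[1:3]))
  tibble::tibble(
    n = n,
    V1 = m[cbind(seq_len(nrow(m)), ord[, 1])],
    V2 = m[cbind(seq_len(nrow(m)), ord[, 2])],
    V3 = m[cbind(seq_len(nrow(m)), ord[, 3])],
    i1 = ord[, 1], i2 = ord[, 2], i3 = ord[, 3]
  )
}

#' Smooth the wrist reference and subsample to one value per minute
#'
#' Applies robust locally weighted regression (LOWESS) to the full-rate
#' wrist stream and then takes the per-minute mean of the smoothed values —
#' an anti-aliasing subsampling justified by the low intrinsic variability
#' of skin temperature.
#'
#' @param wrist Raw wrist stream (tibble `t_seconds`, `value_c`).
#' @param lowess_frac Smoother span as a fraction of the session; widened as
#'   needed so the local window covers at least 10 minutes of samples.
#' @param lowess_iter Robustifying iterations.
#' @param duration_min Session length in minutes; inferred when `NULL`.
#' @return Tibble `n`, `s` (degrees C); empty when the stream holds no valid
#'   samples.
#' @export
smooth_reference <- function(wrist, lowess_frac = 0.05, lowess_iter = 3,
                             duration_min = NULL) {
  ok <- !is.na(wrist$value_c) & wrist$value_c >= 0
  t <- wrist$t_seconds[ok]
  v <- wrist$value_c[ok]
  if (!length(t)) return(tibble::tibble(n = integer(), s = numeric()))
  span_s <- max(t) - min(t)
  if (span_s < 600) abort("wrist stream must span at least 10 minutes")
  f <- min(1, max(lowess_frac, 600 / span_s))
  sm <- lowess(t, v, f = f, iter = lowess_iter)
  if (is.null(duration_min)) duration_min <- ceiling(max(t) / 60)
  agg <- aggregate_minute(
    tibble::tibble(t_seconds = sm$x, value_c = sm$y),
    duration_min = duration_min, nominal_rate = 4
  )
  tibble::tibble(n = agg$n, s = agg$value)
}

combine_strip_flags <- function(masks) {
  # one mask per strip channel -> pooled mask: valid iff all five valid,
  # otherwise the highest-priority offending flag
  priority <- c("null_invalid", "negative_invalid", "oscillation_invalid",
                "missing", "bed_absent")
  flags <- vapply(masks, function(m) as.character(m$flag), character(nrow(masks[[1]])))
  if (is.null(dim(flags))) flags <- matrix(flags, nrow = 1)
  pooled <- apply(flags, 1, function(fl) {
    if (all(fl == "valid")) return("valid")
    for (p in priority) if (p %in% fl) return(p)
    "missing"
  })
  new_quality_mask(masks[[1]]$n, pooled)
}

#' Build the per-minute feature table of a session
#'
#' Runs the full preprocessing chain: minute aggregation of every channel,
#' invalidity flagging, bed-absence masking, pooled strip validity (a minute
#' is usable only when all five strip sensors are valid), top-three
#' selection, and — when a wrist reference is present — LOWESS smoothing of
#' the reference plus the 80% session quality gate.
#'
#' @param rec A `tss_session`.
#' @param oscillation_threshold Intra-minute range limit, degrees C.
#' @param gate_threshold Session inclusion threshold on the good fraction.
#' @param lowess_frac,lowess_iter Reference smoothing settings.
#' @return A tibble (class `tss_features`) with one row per minute:
#'   `n`, `V1`..`V3`, `i1`..`i3`, `s` (reference, `NA` without wrist),
#'   `foot` (minute-mean foot temperature when recorded), `tss_valid`,
#'   `ref_valid`. Attributes: `meta` (ids, setting, lights-off),
#'   `tss_mask`, `ref_mask`, `included` (`NA` when no reference).
#' @export
preprocess_session <- function(rec, oscillation_threshold = 2,
                               gate_threshold = 0.80,
                               lowess_frac = 0.05, lowess_iter = 3) {
  stopifnot(inherits(rec, "tss_session"))
  dur <- rec$duration_min
  streams <- rec$streams

  strip_masks <- list()
  minutes <- tibble::tibble(n = seq_len(dur))
  for (ch in strip_channels()) {
    raw <- streams[streams$channel == ch, ]
    agg <- aggregate_minute(raw, duration_min = dur, nominal_rate = 1)
    mask <- flag_invalid_minutes(agg, raw, oscillation_threshold)
    mask <- mask_bed_absence(mask, rec$presence)
    strip_masks[[ch]] <- mask
    minutes[[ch]] <- ifelse(as.character(mask$flag) == "valid",
                            agg$value, NA_real_)
  }
  tss_mask <- combine_strip_flags(strip_masks)
  top3 <- select_top3(minutes)

  has_wrist <- "wrist" %in% streams$channel
  ref <- tibble::tibble(n = seq_len(dur), s = NA_real_)
  ref_mask <- NULL
  included <- NA
  if (has_wrist) {
    wrist <- streams[streams$channel == "wrist", ]
    agg_w <- aggregate_minute(wrist, duration_min = dur, nominal_rate = 4)
    ref_mask <- flag_invalid_minutes(agg_w, wrist, oscillation_threshold)
    ref_mask <- mask_bed_absence(ref_mask, rec$presence)
    sm <- smooth_reference(wrist, lowess_frac, lowess_iter,
                           duration_min = dur)
    ref$s[sm$n] <- ifelse(as.character(ref_mask$flag)[sm$n] == "valid",
                          sm$s, NA_real_)
    included <- session_quality_gate(tss_mask, ref_mask, gate_threshold)
  }

  out <- tibble::tibble(n = seq_len(dur)) |>
    dplyr::left_join(top3, by = "n") |>
    dplyr::left_join(ref, by = "n")
  if ("foot" %in% streams$channel) {
    foot <- aggregate_minute(streams[streams$channel == "foot", ],
                             duration_min = dur, nominal_rate = 1 / 30)
    out$foot <- foot$value
  }
  out$tss_valid <- as.character(tss_mask$flag) == "valid"
  out$ref_valid <- if (has_wrist) as.character(ref_mask$flag) == "valid" else NA

  attr(out, "meta") <- list(subject_id = rec$subject_id,
                            session_id = rec$session_id,
                            setting = rec$setting,
                            lights_off = rec$lights_off)
  attr(out, "tss_mask") <- tss_mask
  attr(out, "ref_mask") <- ref_mask
  attr(out, "included") <- included
  class(out) <- c("tss_features", class(out))
  out
}

#' Preprocess every session of a study
#'
#' @param study A `tss_study`.
#' @param ... Passed to [preprocess_session()].
#' @return The study's session tibble with added list-column `features` and
#'   logical `included` (quality gate; `NA` for sessions without a wrist
#'   reference).
#' @export
preprocess_study <- function(study, ...) {
  stopifnot(inherits(study, "tss_study"))
  feats <- purrr::map(study$sessions$recording, preprocess_session, ...)
  dplyr::mutate(
    study$sessions,
    features = feats,
    included = purrr::map_lgl(feats, ~ isTRUE(attr(.x, "included")))
  )
}
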