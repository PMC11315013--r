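stage1_matrix <- function(features) {
  as.matrix(features[, c("V1", "V2", "V3")])
}

# Rows usable for stage-one training: a full sorted triple and a reference.
stage1_rows <- function(features) {
  !is.na(features$V1) & !is.na(features$V2) & !is.na(features$V3) &
    !is.na(features$s)
}

# Stage-one estimates X(n) aligned on the full minute grid (NA where the
# triple is unavailable).
stage1_predict_full <- function(stage1, features) {
  x <- rep(NA_real_, nrow(features))
  ok <- !is.na(features$V1) & !is.na(features$V2) & !is.na(features$V3)
  if (any(ok)) {
    dm <- xgboost::xgb.DMatrix(stage1_matrix(features[ok, ]))
    x[ok] <- predict(stage1, dm)
  }
  x
}

# Five-minute rolling windows (X(n), X(n-1), ..., X(n-4)) with the minute
# index of each complete window. A gap in X resets accumulation.
window_matrix <- function(x) {
  if (length(x) < 5) {
    return(list(n = integer(),
                m = matrix(numeric(), 0, 5,
                           dimnames = list(NULL, paste0("x", 0:4)))))
  }
  m <- stats::embed(x, 5)            # row j = x[j+4], x[j+3], ..., x[j]
  colnames(m) <- paste0("x", 0:4)
  ok <- complete.cases(m)
  list(n = which(ok) + 4L, m = m[ok, , drop = FALSE])
}

as_feature_list <- function(x) {
  if (inherits(x, "tss_features")) return(list(x))
  if (is.data.frame(x) && "features" %in% names(x)) return(x$features)
  if (is.list(x)) return(x)
  abort("expected a feature table, a list of them, or a preprocessed study")
}

#' Train the two-stage DST model sequentially
#'
#' Stage one (gradient boosted trees) maps the top-three strip values
#' `(V1, V2, V3)` of a minute to the reference DST, pooling minutes across
#' all training sessions. Its predictions `X(n)` on those same sessions are
#' then grouped into five-minute rolling windows `X(n), ..., X(n-4)` on
#' which stage two (a random forest) is fitted against the reference —
#' exploiting the strong correlation between consecutive DST values.
#'
#' @param train Feature tables: a list of [preprocess_session()] outputs or
#'   a [preprocess_study()] tibble.
#' @param config A [hyperparam_config()].
#' @param seed Integer seed (tree construction is seeded; single-threaded
#'   training keeps results reproducible).
#' @return A `dst_model`: list with `stage1` (xgb.Booster), `stage2`
#'   (ranger), `config`, `seed`, `subjects`, and `s_range` (reference range
#'   seen in training).
#' @export
train_sequential <- function(train, config = default_config(), seed = 1L) {
  stopifnot(inherits(config, "hyperparam_config"))
  feats <- as_feature_list(train)
  if (!length(feats)) abort("no training sessions supplied")

  rows1 <- purrr::map(feats, ~ .x[stage1_rows(.x), c("V1", "V2", "V3", "s")])
  pooled <- dplyr::bind_rows(rows1)
  if (nrow(pooled) < 5) {
    abort("not enough valid minutes with a reference to train stage one")
  }

  withr::with_seed(seed, {
    dtrain <- xgboost::xgb.DMatrix(
      as.matrix(pooled[, c("V1", "V2", "V3")]),
      label = pooled$s
    )
    stage1 <- xgboost::xgb.train(
      params = list(
        objective = "reg:squarederror",
        max_depth = config$gbt_max_depth,
        eta = config$gbt_learning_rate,
        base_score = mean(pooled$s),
        nthread = 1
      ),
      data = dtrain,
      nrounds = config$gbt_n_estimators,
      verbose = 0
    )
  })

  # stage-one estimates on the SAME sessions feed the stage-two windows
  win <- purrr::map(feats, function(f) {
    x <- stage1_predict_full(stage1, f)
    w <- window_matrix(x)
    keep <- !is.na(f$s[w$n])
    list(m = w$m[keep, , drop = FALSE], s = f$s[w$n][keep])
  })
  m2 <- do.call(rbind, purrr::map(win, "m"))
  s2 <- unlist(purrr::map(win, "s"))
  if (is.null(m2) || nrow(m2) < 2) {
    abort("no complete five-minute window in the training data")
  }
  df2 <- as.data.frame(m2)
  df2$.y <- s2
  stage2 <- ranger::ranger(
    dependent.variable.name = ".y",
    data = df2,
    num.trees = config$rf_n_estimators,
    max.depth = if (config$rf_max_depth == 0L) NULL else config$rf_max_depth,
    min.node.size = config$rf_min_samples_split,
    num.threads = 1,
    seed = child_seed(seed, 7)
  )

  structure(
    list(
      stage1 = stage1, stage2 = stage2, config = config, seed = seed,
      subjects = unique(purrr::map_chr(
        feats, ~ attr(.x, "meta")$subject_id %||% NA_character_
      )),
      s_range = range(pooled$s)
    ),
    class = "dst_model"
  )
}

#' Predict the final DST series of a session
#'
#' Emits `Y(n)` for every minute with a complete window of five consecutive
#' stage-one estimates; the earliest possible index is 5, and a gap in valid
#' minutes resets the window (the next estimate appears four minutes after
#' the gap ends).
#'
#' @param model A `dst_model`.
#' @param features A feature table from [preprocess_session()] (or any tibble
#'   with `V1`..`V3` columns indexed by `n`).
#' @return Tibble `n`, `y` — empty when no complete window exists.
#' @export
predict_session <- function(model, features) {
  stopifnot(inherits(model, "dst_model"))
  x <- stage1_predict_full(model$stage1, features)
  w <- window_matrix(x)
  if (!length(w$n)) return(tibble::tibble(n = integer(), y = numeric()))
  y <- predict(model$stage2, data = as.data.frame(w$m),
               num.threads = 1)$predictions
  tibble::tibble(n = features$n[w$n], y = y)
}

#' Save / load a fitted two-stage model
#'
#' The model directory holds the boosted-tree stage in xgboost's native
#' format, the forest stage as an RDS, and a JSON file with the
#' configuration and training metadata. A saved model reloads to identical
#' predictions.
#'
#' @param model A `dst_model`.
#' @param path Directory to create/use.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   `dst_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dst_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  xgboost::xgb.save(model$stage1, file.path(path, "stage1.ubj"))
  saveRDS(model$stage2, file.path(path, "stage2.rds"))
  jsonlite::write_json(
    list(config = unclass(model$config), seed = model$seed,
         subjects = model$subjects, s_range = model$s_range),
    file.path(path, "model.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "model.json"),
                              simplifyVector = TRUE)
  structure(
    list(
      stage1 = xgboost::xgb.load(file.path(path, "stage1.ubj")),
      stage2 = readRDS(file.path(path, "stage2.rds")),
      config = do.call(hyperparam_config, as.list(meta$config)),
      seed = meta$seed,
      subjects = meta$subjects,
      s_range = meta$s_range
    ),
    class = "dst_model"
  )
}

#' @export
print.dst_model <- function(x, ...) {
  cat("Two-stage DST model (GBT -> RF)\n")
  cat(sprintf("  stage 1: %d trees, depth %d, learning rate %.3g\n",
              x$config$gbt_n_estimators, x$config$gbt_max_depth,
              x$config$gbt_learning_rate))
  cat(sprintf("  stage 2: %d trees, depth %s, min split %d\n",
              x$config$rf_n_estimators,
              if (x$config$rf_max_depth == 0L) "unbounded"
              else as.character(x$config$rf_max_depth),
              x$config$rf_min_samples_split))
  cat(sprintf("  trained on %d subject(s); reference range [%.2f, %.2f] degC\n",
              length(x$subjects), x$s_range[1], x$s_range[2]))
  invisible(x)
}

#' @method glance dst_model
#' @export
glance.dst_model <- function(x, ...) {
  tibble::tibble(
    gbt_n_estimators = x$config$gbt_n_estimators,
    gbt_max_depth = x$config$gbt_max_depth,
    gbt_learning_rate = x$config$gbt_learning_rate,
    rf_n_estimators = x$config$rf_n_estimators,
    rf_max_depth = x$config$rf_max_depth,
    rf_min_samples_split = x$config$rf_min_samples_split,
    n_subjects = length(x$subjects),
    seed = x$seed
  )
}
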