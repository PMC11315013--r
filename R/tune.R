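# --- TPE-style sequential model-based search ---------------------------------
# Mixed-space sampler in the spirit of the tree-structured Parzen estimator:
# after a random warm-up, observed trials are split at the loss quantile
# `gamma` into "good" and "bad" sets; candidates are drawn per dimension from
# a density fitted to the good set and scored by the good/bad log-density
# ratio, and the best-scoring candidate is evaluated next.

tune_dims <- function(space) {
  list(
    gbt_n_estimators = list(type = "choice", values = space$gbt_n_estimators),
    gbt_max_depth = list(type = "choice", values = space$gbt_max_depth),
    gbt_learning_rate = list(type = "uniform",
                             range = space$gbt_learning_rate),
    rf_n_estimators = list(type = "int", range = space$rf_n_estimators),
    rf_unbounded = list(type = "choice",
                        values = if (space$rf_allow_unbounded_depth)
                          c(TRUE, FALSE) else FALSE),
    rf_max_depth = list(type = "int", range = space$rf_max_depth),
    rf_min_samples_split = list(type = "int",
                                range = space$rf_min_samples_split)
  )
}

sample_dim <- function(dim) {
  switch(dim$type,
    choice = dim$values[sample.int(length(dim$values), 1)],
    uniform = runif(1, dim$range[1], dim$range[2]),
    int = sample(seq(dim$range[1], dim$range[2]), 1)
  )
}

# density of `x` under a Parzen model of the observed values `obs`
parzen_logdens <- function(x, obs, dim) {
  if (dim$type == "choice") {
    k <- length(dim$values)
    w <- (sum(obs == x) + 1) / (length(obs) + k)
    return(log(w))
  }
  span <- diff(range(dim$range))
  s <- sd(obs)
  if (!is.finite(s)) s <- 0
  bw <- max(1.06 * s * length(obs)^(-0.2), span / 20, 1e-9)
  log(mean(dnorm(x, mean = obs, sd = bw)) + 1e-12)
}

sample_from_good <- function(dim, good_obs) {
  if (dim$type == "choice") {
    k <- length(dim$values)
    w <- vapply(dim$values, function(v) sum(good_obs == v) + 1, numeric(1))
    return(dim$values[sample.int(k, 1, prob = w)])
  }
  span <- diff(range(dim$range))
  s <- sd(good_obs)
  if (!is.finite(s)) s <- 0
  bw <- max(1.06 * s * length(good_obs)^(-0.2), span / 20, 1e-9)
  x <- rnorm(1, good_obs[sample.int(length(good_obs), 1)], bw)
  x <- min(max(x, dim$range[1]), dim$range[2])
  if (dim$type == "int") x <- as.integer(round(x)) else x
}

draw_to_config <- function(draw) {
  hyperparam_config(
    gbt_n_estimators = draw$gbt_n_estimators,
    gbt_max_depth = draw$gbt_max_depth,
    gbt_learning_rate = draw$gbt_learning_rate,
    rf_n_estimators = draw$rf_n_estimators,
    rf_max_depth = if (isTRUE(draw$rf_unbounded)) 0L else draw$rf_max_depth,
    rf_min_samples_split = draw$rf_min_samples_split
  )
}

#' Tune the two-stage model with a TPE-style Bayesian search
#'
#' Splits the tuning subjects 75/25, trains the full two-stage pipeline on
#' the larger part for each candidate configuration, and minimizes the mean
#' squared error of the final estimate against the reference on the held-out
#' part. Candidates are proposed by a tree-structured-Parzen-estimator-style
#' sampler over the declared space.
#'
#' @param tuning Feature tables of the tuning sessions (list or
#'   [preprocess_study()] tibble); sessions must carry a reference.
#' @param space A [hyperparam_space()].
#' @param budget Number of trials (>= 1).
#' @param seed Integer seed; the random warm-up trials form a common prefix
#'   across budgets under the same seed.
#' @param n_init Random warm-up trials before the Parzen model kicks in.
#' @param gamma Loss quantile separating good from bad trials.
#' @return The best `hyperparam_config`, with attribute `trials`: a tibble of
#'   every trial's parameters and validation loss.
#' @export
tune_hyperparams <- function(tuning, space = hyperparam_space(), budget = 20L,
                             seed = 1L, n_init = 5L, gamma = 0.25) {
  if (budget < 1) abort("budget must be at least 1")
  feats <- as_feature_list(tuning)
  subj <- purrr::map_chr(feats, ~ attr(.x, "meta")$subject_id %||% NA_character_)
  subjects <- unique(subj)
  if (length(subjects) < 2) {
    abort("tuning requires at least two subjects for a held-out split")
  }
  n_val <- max(1L, floor(length(subjects) * 0.25))
  val_subjects <- withr::with_seed(child_seed(seed, 3),
                                   sample(subjects, n_val))
  train_feats <- feats[!(subj %in% val_subjects)]
  val_feats <- feats[subj %in% val_subjects]

  objective <- function(config, trial) {
    model <- train_sequential(train_feats, config,
                              seed = child_seed(seed, 50 + trial))
    err <- purrr::map(val_feats, function(f) {
      y <- predict_session(model, f)
      paired <- dplyr::inner_join(y, f[, c("n", "s")], by = "n")
      paired <- paired[!is.na(paired$s), ]
      paired$s - paired$y
    })
    e <- unlist(err)
    if (!length(e)) return(Inf)
    mean(e^2)
  }

  dims <- tune_dims(space)
  history <- list()
  for (trial in seq_len(budget)) {
    draw <- withr::with_seed(child_seed(seed, 200 + trial), {
      if (trial <= n_init || length(history) < 2) {
        purrr::map(dims, sample_dim)
      } else {
        losses <- purrr::map_dbl(history, "loss")
        n_good <- max(1L, min(length(losses) - 1L,
                              ceiling(gamma * length(losses))))
        good <- order(losses)[seq_len(n_good)]
        best <- NULL; best_score <- -Inf
        for (cand in 1:24) {
          d <- purrr::imap(dims, function(dim, nm) {
            obs_good <- purrr::map_dbl(history[good], ~ as.numeric(.x$draw[[nm]]))
            sample_from_good(dim, obs_good)
          })
          score <- sum(purrr::imap_dbl(dims, function(dim, nm) {
            obs <- purrr::map_dbl(history, ~ as.numeric(.x$draw[[nm]]))
            parzen_logdens(as.numeric(d[[nm]]), obs[good], dim) -
              parzen_logdens(as.numeric(d[[nm]]), obs[-good], dim)
          }))
          if (score > best_score) { best <- d; best_score <- score }
        }
        best
      }
    })
    config <- draw_to_config(draw)
    loss <- objective(config, trial)
    history[[trial]] <- list(draw = draw, config = config, loss = loss)
  }

  losses <- purrr::map_dbl(history, "loss")
  best <- history[[which.min(losses)]]$config
  trials <- dplyr::bind_rows(purrr::imap(history, function(h, i) {
    tibble::tibble(
      trial = i,
      gbt_n_estimators = h$config$gbt_n_estimators,
      gbt_max_depth = h$config$gbt_max_depth,
      gbt_learning_rate = h$config$gbt_learning_rate,
      rf_n_estimators = h$config$rf_n_estimators,
      rf_max_depth = h$config$rf_max_depth,
      rf_min_samples_split = h$config$rf_min_samples_split,
      loss = h$loss
    )
  }))
  attr(best, "trials") <- trials
  best
}
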