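# Continuous grasp-force estimation: feed-forward network regression of
# window-mean %MVC force from time-domain EMG features, R^2 evaluation,
# window/step sweeps, channel-force correlation and channel selection.

#' Force regressor configuration
#'
#' A single-hidden-layer feed-forward network trained by
#' back-propagation (quasi-Newton in `nnet`), with a linear output unit.
#'
#' @param hidden Hidden layer width (default 20 units).
#' @param maxit Maximum training iterations.
#' @param decay Weight decay (L2) regularization.
#' @param seed Integer seed for weight initialization.
#' @return List of class `regressor_config`.
#' @export
regressor_config <- function(hidden = 20, maxit = 300, decay = 1e-3,
                             seed = 1) {
  stopifnot(hidden > 0, maxit > 0, decay >= 0)
  structure(list(hidden = hidden, maxit = maxit, decay = decay,
                 seed = seed), class = "regressor_config")
}

#' Train the force regressor
#'
#' Fits the network to map feature vectors to window-mean force (%MVC).
#' Features are z-scored and the target scaled to [0, 1] internally;
#' both transforms are stored in the returned model. Training is
#' deterministic given the config seed.
#'
#' @param X Numeric matrix, windows x features.
#' @param y Numeric vector, window-mean force in %MVC.
#' @param cfg A [regressor_config()].
#' @return Object of class `force_regressor`.
#' @export
train_regressor <- function(X, y, cfg = regressor_config()) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("non-finite values in features or target")
  }
  if (stats::sd(y) == 0) {
    warning("constant force target: training R^2 undefined (NaN)")
  }
  sc <- fit_scaler(X)
  Xs <- apply_scaler(X, sc)
  set.seed(cfg$seed)
  net <- nnet::nnet(Xs, y / 100, size = cfg$hidden, linout = TRUE,
                    maxit = cfg$maxit, decay = cfg$decay, trace = FALSE,
                    MaxNWts = 10000)
  structure(list(net = net, scaler = sc, cfg = cfg),
            class = "force_regressor")
}

#' Predict force from features
#'
#' @param object A `force_regressor`.
#' @param newdata Feature matrix.
#' @param clip Clip range for reported predictions, %MVC; `NULL` for
#'   raw output.
#' @param ... Unused.
#' @return Numeric vector of predicted force, %MVC.
#' @export
predict.force_regressor <- function(object, newdata, clip = c(0, 120),
                                    ...) {
  p <- 100 * as.numeric(stats::predict(object$net,
                                       apply_scaler(newdata,
                                                    object$scaler)))
  if (!is.null(clip)) p <- pmin(pmax(p, clip[1]), clip[2])
  p
}

#' Coefficient of determination
#'
#' R^2 = 1 - sum((ref - pred)^2) / sum((ref - mean(ref))^2). `NaN` with
#' a warning for a constant reference.
#'
#' @param reference,predictions Equal-length numeric vectors (n >= 2).
#' @return A single numeric value (<= 1).
#' @export
r_squared <- function(reference, predictions) {
  stopifnot(length(reference) == length(predictions),
            length(reference) >= 2)
  ss_tot <- sum((reference - mean(reference))^2)
  if (ss_tot == 0) {
    warning("constant reference: R^2 undefined")
    return(NaN)
  }
  1 - sum((reference - predictions)^2) / ss_tot
}

# internal: trial-wise train/test split
split_trials <- function(trial_ids, train_frac, seed) {
  ids <- unique(trial_ids)
  set.seed(seed)
  n_train <- max(1, round(train_frac * length(ids)))
  train_ids <- sample(ids, n_train)
  list(train = trial_ids %in% train_ids, test = !(trial_ids %in% train_ids))
}

#' Train/evaluate force regression with repeated trial-wise splits
#'
#' Repeats a trial-wise train/test split, trains the network on the
#' training windows and scores held-out R^2; mean and sd across repeats
#' mirror a per-subject mean +/- sd report.
#'
#' @param fm A `feature_matrix` with `y_force`.
#' @param cfg A [regressor_config()].
#' @param train_frac Fraction of trials used for training (default 0.75).
#' @param n_repeats Number of repeated splits (default 5).
#' @param seed Integer seed.
#' @param keep_predictions Keep reference/prediction vectors of the
#'   first split.
#' @return List with `r2_mean`, `r2_sd`, `r2` (per repeat), and
#'   optionally `reference` / `predictions`.
#' @export
evaluate_regression <- function(fm, cfg = regressor_config(),
                                train_frac = 0.75, n_repeats = 5,
                                seed = 1, keep_predictions = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"))
  r2 <- numeric(n_repeats)
  ref <- pred <- NULL
  for (r in seq_len(n_repeats)) {
    sp <- split_trials(fm$trial_id, train_frac, derive_seed(seed, r))
    cfg_r <- cfg; cfg_r$seed <- derive_seed(seed, 1000 + r)
    mod <- train_regressor(fm$X[sp$train, , drop = FALSE],
                           fm$y_force[sp$train], cfg_r)
    p <- predict(mod, fm$X[sp$test, , drop = FALSE])
    r2[r] <- r_squared(fm$y_force[sp$test], p)
    if (r == 1 && keep_predictions) {
      ref <- fm$y_force[sp$test]; pred <- p
    }
  }
  out <- list(r2_mean = mean(r2), r2_sd = stats::sd(r2), r2 = r2)
  if (keep_predictions) { out$reference <- ref; out$predictions <- pred }
  out
}

#' Two-stage sliding-window sweep for force regression
#'
#' Stage 1 fixes the window width (default 300 ms, roughly the human
#' feedback-perception delay) and sweeps the step size; stage 2 fixes
#' the best step from stage 1 and sweeps the window width. Reports
#' held-out R^2 per movement and the four-movement mean for every grid
#' point.
#'
#' @param trials Experiment-2 trials (one profile kind).
#' @param steps_ms Stage-1 step grid (default 20/40/80/160 ms).
#' @param widths_ms Stage-2 width grid (default 100--300 ms).
#' @param fixed_width_ms Stage-1 window width (default 300).
#' @param cfg,seed,n_repeats Passed to [evaluate_regression()].
#' @param channels Channel subset used throughout.
#' @return List with `table` (stage / width_ms / step_ms / movement /
#'   r2; movement "mean" rows aggregate the four grasps), `best_step_ms`,
#'   `best_width_ms`.
#' @export
sweep_windows <- function(trials, steps_ms = c(20, 40, 80, 160),
                          widths_ms = c(100, 150, 200, 250, 300),
                          fixed_width_ms = 300,
                          cfg = regressor_config(), seed = 1,
                          n_repeats = 2, channels = channel_names()) {
  eval_cell <- function(width, step) {
    if (width < step) {
      warning("width ", width, " < step ", step, " ms: skipped")
      return(NULL)
    }
    spec <- window_spec(width, step, trials[[1]]$fs)
    out <- list()
    for (mv in unique(vapply(trials, `[[`, "", "movement"))) {
      sub <- Filter(function(t) t$movement == mv, trials)
      fm <- featurize(sub, spec, channels = channels)
      ev <- evaluate_regression(fm, cfg, n_repeats = n_repeats,
                                seed = seed)
      out[[mv]] <- ev$r2_mean
    }
    out
  }
  rows <- list()
  add_rows <- function(stage, width, step, res) {
    for (mv in names(res)) {
      rows[[length(rows) + 1]] <<- data.frame(
        stage = stage, width_ms = width, step_ms = step,
        movement = mv, r2 = res[[mv]])
    }
    rows[[length(rows) + 1]] <<- data.frame(
      stage = stage, width_ms = width, step_ms = step,
      movement = "mean", r2 = mean(unlist(res)))
  }
  for (s in steps_ms) {
    res <- eval_cell(fixed_width_ms, s)
    if (!is.null(res)) add_rows(1, fixed_width_ms, s, res)
  }
  tab1 <- do.call(rbind, rows)
  means1 <- tab1[tab1$stage == 1 & tab1$movement == "mean", ]
  best_step <- means1$step_ms[which.max(means1$r2)]
  for (w in widths_ms) {
    res <- eval_cell(w, best_step)
    if (!is.null(res)) add_rows(2, w, best_step, res)
  }
  tab <- do.call(rbind, rows)
  means2 <- tab[tab$stage == 2 & tab$movement == "mean", ]
  best_width <- means2$width_ms[which.max(means2$r2)]
  list(table = tab, best_step_ms = best_step, best_width_ms = best_width)
}

#' Channel-force correlation table
#'
#' For each trial, correlates the windowed RMS envelope of every channel
#' with the window-mean force over the active phase; reports
#' |Pearson r| x 100 as mean +/- sd across trials, per movement x
#' channel. This is the statistic used to rank channels for force
#' estimation.
#'
#' @param trials List of `emg_trial` (>= 2 per movement).
#' @param spec A [window_spec()] (default 200/80 ms at the trials' fs).
#' @return List of class `correlation_table`: `mean` and `sd`
#'   (4 movements x 8 channels matrices, %), `n_trials`.
#' @export
channel_correlation <- function(trials, spec = NULL) {
  fs <- trials[[1]]$fs
  if (is.null(spec)) spec <- window_spec(200, 80, fs)
  mvs <- movement_names(); chs <- channel_names()
  acc <- array(NA_real_, c(length(mvs), length(chs), length(trials)),
               dimnames = list(mvs, chs, NULL))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    seg <- extract_phase(tr, active_window(tr$condition))
    win <- window_indices(length(seg$force), spec)
    fwin <- vapply(seq_len(nrow(win)), function(k)
      mean(seg$force[win$start[k]:win$end[k]]), numeric(1))
    for (ch in chs) {
      env <- vapply(seq_len(nrow(win)), function(k)
        rms(seg$emg[ch, win$start[k]:win$end[k]]), numeric(1))
      if (stats::sd(env) == 0 || stats::sd(fwin) == 0) next  # left NA
      acc[tr$movement, ch, i] <- 100 * abs(stats::cor(env, fwin))
    }
  }
  m <- apply(acc, c(1, 2), mean, na.rm = TRUE)
  s <- apply(acc, c(1, 2), stats::sd, na.rm = TRUE)
  n <- apply(acc, c(1, 2), function(x) sum(!is.na(x)))
  structure(list(mean = m, sd = s, n_trials = n),
            class = "correlation_table")
}

#' Select channels for force estimation of a movement
#'
#' `top_k` returns the k channels with the highest mean correlation for
#' the movement (ties broken toward the lower channel index);
#' `preset` returns the fixed per-movement four-channel subsets
#' established by the channel-selection analysis (pinch: C1 C2 C3 C5;
#' palmar: C2 C4 C5 C6; twist: C1 C2 C3 C4; plug: C2 C4 C5 C7).
#'
#' @param table A `correlation_table` (required for `top_k`).
#' @param movement One of [movement_names()].
#' @param k Number of channels (default 4, <= 8).
#' @param mode `"top_k"` or `"preset"`.
#' @return Character vector of channel names.
#' @export
select_channels <- function(table = NULL, movement, k = 4,
                            mode = c("top_k", "preset")) {
  mode <- match.arg(mode)
  stopifnot(movement %in% movement_names())
  if (k > 8) stop("at most 8 channels available")
  if (mode == "preset") {
    presets <- list(pinch = c("C1", "C2", "C3", "C5"),
                    palmar = c("C2", "C4", "C5", "C6"),
                    twist = c("C1", "C2", "C3", "C4"),
                    plug = c("C2", "C4", "C5", "C7"))
    return(presets[[movement]][seq_len(min(k, 4))])
  }
  stopifnot(inherits(table, "correlation_table"))
  v <- table$mean[movement, ]
  ord <- order(-v, seq_along(v))  # ties -> lower channel index
  channel_names()[sort(ord[seq_len(k)])]
}

#' Channel-subset scan for force regression
#'
#' For each subset size, evaluates held-out R^2 over all channel subsets
#' of that size (or a seeded sample of `budget` subsets), per movement.
#'
#' @param trials Experiment-2 trials (one profile kind).
#' @param sizes Subset sizes (default 1:8).
#' @param spec A [window_spec()] (default 200/80 ms).
#' @param cfg,seed As in [evaluate_regression()].
#' @param budget Max subsets per size; `NULL` = exhaustive.
#' @param n_repeats Repeated splits per subset.
#' @return List of class `regression_scan_result`: `per_subset`
#'   (movement / size / channels / r2), `per_size` (movement / size /
#'   mean, min, max R^2).
#' @export
regression_scan <- function(trials, sizes = 1:8, spec = NULL,
                            cfg = regressor_config(), seed = 1,
                            budget = NULL, n_repeats = 2) {
  fs <- trials[[1]]$fs
  if (is.null(spec)) spec <- window_spec(200, 80, fs)
  mvs <- unique(vapply(trials, `[[`, "", "movement"))
  fms <- lapply(stats::setNames(mvs, mvs), function(mv) {
    featurize(Filter(function(t) t$movement == mv, trials), spec)
  })
  rows <- list()
  for (n in sizes) {
    combs <- utils::combn(channel_names(), n, simplify = FALSE)
    if (!is.null(budget) && length(combs) > budget) {
      set.seed(derive_seed(seed, n))
      combs <- combs[sample(length(combs), budget)]
    }
    for (ch in combs) {
      for (mv in mvs) {
        ev <- evaluate_regression(subset_channels(fms[[mv]], ch), cfg,
                                  n_repeats = n_repeats, seed = seed)
        rows[[length(rows) + 1]] <- data.frame(
          movement = mv, size = n,
          channels = paste(ch, collapse = "+"), r2 = ev$r2_mean)
      }
    }
  }
  per_subset <- do.call(rbind, rows)
  per_size <- do.call(rbind, by(per_subset,
                                per_subset[c("movement", "size")],
                                function(d) data.frame(
                                  movement = d$movement[1],
                                  size = d$size[1],
                                  r2_mean = mean(d$r2),
                                  r2_min = min(d$r2),
                                  r2_max = max(d$r2))))
  rownames(per_size) <- NULL
  structure(list(per_subset = per_subset, per_size = per_size),
            class = "regression_scan_result")
}

#' Movement-by-profile R^2 summary table
#'
#' Evaluates force regression per movement x profile (each on its
#' selected channels) with repeated trial-wise splits and lays the
#' results out as a table of mean +/- sd R^2 (in %), with an AVE row per
#' movement averaging its four profiles.
#'
#' @param trials_by_profile Named list (profile kind -> trial list).
#' @param channels_by_movement Named list (movement -> channel subset).
#' @param spec A [window_spec()] (default 200/80 ms).
#' @param cfg,seed,n_repeats As in [evaluate_regression()].
#' @return Data frame: movement / profile / r2_mean_pct / r2_sd_pct,
#'   including per-movement "AVE" rows.
#' @export
profile_r2_table <- function(trials_by_profile, channels_by_movement,
                             spec = NULL, cfg = regressor_config(),
                             seed = 1, n_repeats = 5) {
  rows <- list()
  for (mv in names(channels_by_movement)) {
    r2s <- c()
    for (pf in names(trials_by_profile)) {
      sub <- Filter(function(t) t$movement == mv, trials_by_profile[[pf]])
      fs <- sub[[1]]$fs
      sp <- if (is.null(spec)) window_spec(200, 80, fs) else spec
      fm <- featurize(sub, sp, channels = channels_by_movement[[mv]])
      ev <- evaluate_regression(fm, cfg, n_repeats = n_repeats,
                                seed = derive_seed(seed,
                                  match(pf, names(trials_by_profile))))
      rows[[length(rows) + 1]] <- data.frame(
        movement = mv, profile = pf,
        r2_mean_pct = 100 * ev$r2_mean, r2_sd_pct = 100 * ev$r2_sd)
      r2s <- c(r2s, ev$r2_mean)
    }
    rows[[length(rows) + 1]] <- data.frame(
      movement = mv, profile = "AVE",
      r2_mean_pct = 100 * mean(r2s), r2_sd_pct = 100 * stats::sd(r2s))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
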