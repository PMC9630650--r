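# End-to-end orchestration: one reproducible run per experiment, CSV
# report bundles, and a structured run log.

#' Run configuration
#'
#' A single serializable object holding every parameter of an
#' end-to-end run; a run is reproducible from its config alone.
#' The default trial counts are deliberately below the full study
#' design (50 classification trials per movement x level, 20 tracking
#' trials per movement x profile): the simulator accepts the full
#' counts, and the defaults here keep a desk-scale run light while
#' preserving every structural property of the analysis.
#'
#' @param experiment 1 (classification) or 2 (force estimation).
#' @param seed Master seed.
#' @param gains_preset Gain-matrix preset for [make_gain_matrix()].
#' @param noise A [noise_config()].
#' @param trials_per_condition Trials per movement x condition.
#' @param movements Movements simulated.
#' @param schemes Classification schemes evaluated (experiment 1).
#' @param sizes Channel-subset sizes scanned.
#' @param scan_budget Max subsets per size (`NULL` = exhaustive).
#' @param class_window,class_step Classification window/step, ms.
#' @param reg_window,reg_step Regression window/step, ms.
#' @param folds Cross-validation folds.
#' @param channels Fixed channel subset for the classification
#'   accuracy report (default the four informative channels C2 C4 C5
#'   C7).
#' @param profiles Target profiles simulated (experiment 2).
#' @param sweep_steps,sweep_widths Step/width grids (ms) for the
#'   sliding-window sweep of experiment 2.
#' @param n_repeats Repeated trial-wise splits for regression scores.
#' @param phase Classification analysis window, s.
#' @return List of class `run_config`.
#' @export
run_config <- function(experiment = 1, seed = 1,
                       gains_preset = "paperlike",
                       noise = noise_config(),
                       trials_per_condition = if (experiment == 1) 6 else 10,
                       movements = movement_names(),
                       schemes = paste0("SCH", 1:5),
                       sizes = 1:8, scan_budget = 5,
                       class_window = 175, class_step = 20,
                       reg_window = 200, reg_step = 80,
                       folds = 5,
                       channels = c("C2", "C4", "C5", "C7"),
                       profiles = c("rectangular", "triangle",
                                    "step_climbing", "random"),
                       sweep_steps = c(40, 80, 160),
                       sweep_widths = c(150, 200, 300),
                       n_repeats = 5, phase = c(10, 13)) {
  structure(as.list(environment()), class = "run_config")
}

log_stage <- function(log, stage, seed, t0) {
  line <- sprintf("stage=%s seed=%s elapsed=%.1fs", stage, seed,
                  as.numeric(Sys.time()) - t0)
  message(line)
  c(log, line)
}

#' Run the classification experiment end to end
#'
#' Simulate -> preprocess -> featurize -> per-scheme channel scan ->
#' report. Writes `scheme_curves.csv`, `ir_table.csv`,
#' `per_subset.csv`, `accuracy_fixed_channels.csv` and `run_log.txt`
#' under `out_dir` when given.
#'
#' @param cfg A [run_config()] with `experiment = 1`.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return List with `scans`, `report`, `fixed_accuracy`, `config`.
#' @export
run_experiment_1 <- function(cfg = run_config(1), out_dir = NULL) {
  stopifnot(cfg$experiment == 1)
  t0 <- as.numeric(Sys.time()); log <- character(0)
  gains <- make_gain_matrix(cfg$gains_preset)
  design <- experiment_design(1, movements = cfg$movements,
                              trials_per_condition = cfg$trials_per_condition)
  session <- simulate_session(design, gains, seed = cfg$seed,
                              noise = cfg$noise)
  log <- log_stage(log, "simulate", cfg$seed, t0)
  trials <- preprocess_session(session)
  log <- log_stage(log, "preprocess", cfg$seed, t0)
  spec <- window_spec(cfg$class_window, cfg$class_step, session$fs)
  fm <- featurize(trials, spec, phase = cfg$phase)
  log <- log_stage(log, "featurize", cfg$seed, t0)
  scans <- list()
  fixed_rows <- list()
  for (s in cfg$schemes) {
    bl <- build_labels(fm, s)
    scans[[s]] <- channel_scan(bl$fm, bl$labels, sizes = cfg$sizes,
                               k = cfg$folds, seed = cfg$seed,
                               budget = cfg$scan_budget)
    cv <- crossval_accuracy(subset_channels(bl$fm, cfg$channels),
                            bl$labels, k = cfg$folds, seed = cfg$seed)
    fixed_rows[[s]] <- data.frame(scheme = s,
                                  channels = paste(cfg$channels,
                                                   collapse = "+"),
                                  mean_accuracy = cv$mean_accuracy,
                                  sd_accuracy = stats::sd(cv$fold_accuracy))
    log <- log_stage(log, paste0("scan_", s), cfg$seed, t0)
  }
  report <- scheme_report(scans)
  fixed <- do.call(rbind, fixed_rows)
  rownames(fixed) <- NULL
  out <- list(scans = scans, report = report, fixed_accuracy = fixed,
              config = cfg, log = log)
  if (!is.null(out_dir)) write_bundle_1(out, out_dir)
  out
}

write_bundle_1 <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$report$curves,
                   file.path(out_dir, "scheme_curves.csv"),
                   row.names = FALSE)
  utils::write.csv(res$report$ir_table,
                   file.path(out_dir, "ir_table.csv"), row.names = FALSE)
  per_subset <- do.call(rbind, lapply(names(res$scans), function(s)
    cbind(scheme = s, res$scans[[s]]$per_subset)))
  utils::write.csv(per_subset, file.path(out_dir, "per_subset.csv"),
                   row.names = FALSE)
  utils::write.csv(res$fixed_accuracy,
                   file.path(out_dir, "accuracy_fixed_channels.csv"),
                   row.names = FALSE)
  writeLines(res$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}

#' Run the force-estimation experiment end to end
#'
#' Simulate (per profile) -> preprocess -> window/step sweep on the
#' staircase profile -> channel-force correlation -> per-movement
#' channel selection -> per-movement x profile regression. Writes
#' `sweep.csv`, `correlation_table.csv`, `selected_channels.csv`,
#' `r2_table.csv`, per-condition `predictions_<movement>_<profile>.csv`
#' and `run_log.txt` under `out_dir` when given.
#'
#' @param cfg A [run_config()] with `experiment = 2`.
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return List with `sweep`, `correlation`, `channels`, `r2_table`,
#'   `predictions`, `config`.
#' @export
run_experiment_2 <- function(cfg = run_config(2), out_dir = NULL) {
  stopifnot(cfg$experiment == 2)
  t0 <- as.numeric(Sys.time()); log <- character(0)
  gains <- make_gain_matrix(cfg$gains_preset)
  trials_by_profile <- list()
  for (pf in cfg$profiles) {
    design <- experiment_design(2, movements = cfg$movements,
                                profiles = pf,
                                trials_per_condition = cfg$trials_per_condition)
    session <- simulate_session(design, gains,
                                seed = derive_seed(cfg$seed,
                                                   match(pf, cfg$profiles)),
                                noise = cfg$noise)
    trials_by_profile[[pf]] <- preprocess_session(session)
    log <- log_stage(log, paste0("simulate_", pf), cfg$seed, t0)
  }
  sweep <- if ("step_climbing" %in% names(trials_by_profile)) {
    sweep_windows(trials_by_profile$step_climbing,
                  steps_ms = cfg$sweep_steps,
                  widths_ms = cfg$sweep_widths,
                  cfg = regressor_config(seed = cfg$seed),
                  seed = cfg$seed)
  } else NULL
  log <- log_stage(log, "sweep", cfg$seed, t0)
  spec <- window_spec(cfg$reg_window, cfg$reg_step)
  all_trials <- do.call(c, unname(trials_by_profile))
  corr <- channel_correlation(all_trials, spec)
  log <- log_stage(log, "correlation", cfg$seed, t0)
  channels <- lapply(stats::setNames(nm = cfg$movements),
                     function(mv) select_channels(corr, mv, mode = "top_k"))
  r2_tab <- profile_r2_table(trials_by_profile, channels, spec,
                             cfg = regressor_config(seed = cfg$seed),
                             seed = cfg$seed, n_repeats = cfg$n_repeats)
  log <- log_stage(log, "regression", cfg$seed, t0)
  preds <- list()
  for (mv in cfg$movements) {
    for (pf in names(trials_by_profile)) {
      sub <- Filter(function(t) t$movement == mv,
                    trials_by_profile[[pf]])
      fm <- featurize(sub, spec, channels = channels[[mv]])
      ev <- evaluate_regression(fm,
                                regressor_config(seed = cfg$seed),
                                n_repeats = 1, seed = cfg$seed,
                                keep_predictions = TRUE)
      preds[[paste(mv, pf, sep = "_")]] <- data.frame(
        movement = mv, profile = pf,
        reference = ev$reference, predicted = ev$predictions)
    }
  }
  log <- log_stage(log, "predictions", cfg$seed, t0)
  out <- list(sweep = sweep, correlation = corr, channels = channels,
              r2_table = r2_tab, predictions = preds, config = cfg,
              log = log)
  if (!is.null(out_dir)) write_bundle_2(out, out_dir)
  out
}

write_bundle_2 <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(res$sweep)) {
    utils::write.csv(res$sweep$table, file.path(out_dir, "sweep.csv"),
                     row.names = FALSE)
  }
  ct <- data.frame(movement = rownames(res$correlation$mean),
                   round(res$correlation$mean, 2))
  utils::write.csv(ct, file.path(out_dir, "correlation_table.csv"),
                   row.names = FALSE)
  sel <- data.frame(movement = names(res$channels),
                    channels = vapply(res$channels, paste, "",
                                      collapse = "+"))
  utils::write.csv(sel, file.path(out_dir, "selected_channels.csv"),
                   row.names = FALSE)
  utils::write.csv(res$r2_table, file.path(out_dir, "r2_table.csv"),
                   row.names = FALSE)
  for (nm in names(res$predictions)) {
    utils::write.csv(res$predictions[[nm]],
                     file.path(out_dir, paste0("predictions_", nm, ".csv")),
                     row.names = FALSE)
  }
  writeLines(res$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
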