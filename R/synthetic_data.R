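# Synthetic EMG/force/trigger session generator.
#
# The generative model is the standard sEMG surrogate: band-limited,
# amplitude-modulated Gaussian noise. Channel c during movement m is
#
#   emg_c(t) = g[c, m] * (f(t)/100)^alpha * n_c(t) + b * e_c(t)
#
# where f(t) is the target force profile in %MVC, n_c and e_c are
# independent unit-variance Gaussian processes band-limited to
# [20, 450] Hz, g is the channel-by-movement gain matrix and b the
# baseline (rest) noise amplitude. The measured force is the profile
# scaled by the movement's MVC plus additive Gaussian sensor noise,
# lagging the EMG envelope by the electromechanical delay.

#' Channel-by-movement EMG gain matrix
#'
#' Builds the 8 x 4 nonnegative gain matrix coupling each electrode
#' channel to each grasping movement. The `"paperlike"` preset encodes
#' the ordinal structure observed in real recordings of these grasps:
#' C2--C5 are informative for all movements, C7/C8 are nearly silent for
#' pinch, C7 is strongly recruited by plug grasp, and C6 contributes
#' little to plug. The `"random"` preset draws gains with at least one
#' informative and at least one near-zero channel per movement.
#'
#' @param preset `"paperlike"` or `"random"`.
#' @param seed Integer seed, required for the random preset.
#' @return Numeric matrix, rows = channels C1..C8, columns = movements.
#' @export
make_gain_matrix <- function(preset = c("paperlike", "random"), seed = NULL) {
  preset <- match.arg(preset)
  mv <- movement_names()
  ch <- channel_names()
  if (preset == "paperlike") {
    g <- matrix(c(
      # pinch, palmar, twist, plug
      0.90, 0.50, 1.00, 0.30,  # C1
      0.80, 0.70, 0.80, 0.70,  # C2
      0.60, 0.50, 0.90, 0.60,  # C3
      0.40, 1.00, 1.10, 1.20,  # C4
      1.00, 0.90, 0.70, 0.90,  # C5
      0.50, 0.80, 0.70, 0.15,  # C6
      0.05, 0.15, 0.50, 1.10,  # C7
      0.10, 0.08, 0.25, 0.35   # C8
    ), nrow = 8, ncol = 4, byrow = TRUE)
  } else {
    if (is.null(seed)) stop("random gain preset requires a seed")
    set.seed(seed)
    g <- matrix(0, 8, 4)
    for (j in 1:4) {
      col <- stats::runif(8, 0.3, 1.2)
      silent <- sample(8, 2)          # >= 1 near-zero channel
      col[silent] <- stats::runif(2, 0, 0.03)
      g[, j] <- col
    }
  }
  dimnames(g) <- list(ch, mv)
  validate_gain_matrix(g)
  g
}

validate_gain_matrix <- function(g) {
  stopifnot(is.matrix(g), nrow(g) == 8, ncol(g) == 4, all(g >= 0))
  if (!all(apply(g, 2, max) > 0)) {
    stop("each movement column must have at least one positive gain")
  }
  invisible(g)
}

#' Noise configuration for the simulator
#'
#' @param baseline_amp Baseline (rest) EMG noise amplitude, same arbitrary
#'   amplitude units as the gain matrix. Default 0.02.
#' @param force_noise_pct Std. dev. of additive force sensor noise, in
#'   %MVC. Default 0.5.
#' @param alpha Amplitude--force exponent: EMG amplitude scales with
#'   (force/100)^alpha. Default 1 (linear amplitude--force coupling).
#' @param emd_s Electromechanical delay, s: measured force lags the
#'   EMG amplitude envelope by this much. Default 0.03 s.
#' @param overshoot Tracking-overshoot fraction: when the target jumps
#'   faster than `fast_slope`, the executed force overshoots by this
#'   fraction of the jump and rings down (decaying ~1.5 Hz
#'   oscillation). The ringing is a property of the subject's force
#'   response, not of the neural drive, so it is invisible in the EMG
#'   and degrades EMG--force regression for profiles with jumps
#'   (rectangular) but not for slow ramps (triangular). Default 0.3;
#'   0 disables.
#' @param fast_slope Slope threshold (%MVC per s) above which a target
#'   segment counts as a jump. Default 60 (the triangular ramp at
#'   32 %MVC/s stays below, the rectangular transitions far above).
#' @return List of class `noise_config`.
#' @export
noise_config <- function(baseline_amp = 0.02, force_noise_pct = 0.5,
                         alpha = 1, emd_s = 0.03, overshoot = 0.3,
                         fast_slope = 60) {
  stopifnot(baseline_amp >= 0, force_noise_pct >= 0, alpha > 0,
            emd_s >= 0, overshoot >= 0, fast_slope > 0)
  structure(list(baseline_amp = baseline_amp,
                 force_noise_pct = force_noise_pct,
                 alpha = alpha, emd_s = emd_s, overshoot = overshoot,
                 fast_slope = fast_slope), class = "noise_config")
}

#' Build a target force profile
#'
#' Constructs a piecewise-linear %MVC force trajectory of one of five
#' kinds: `rectangular` (three 2 s plateaus at 20/50/80 %MVC joined by
#' short ramps), `triangle` (0 to 80 %MVC and back over 5 s, peak at the
#' midpoint), `step_climbing` (a staircase of 20/40/60/80 %MVC steps
#' joined by 0.5 s ramps, 8.5 s total), `random` (a seeded piecewise
#' linear path bounded by 80 %MVC over 5 s), or `ramp_hold` (rise to a
#' plateau level in 1.5 s then hold 4 s -- the classification-trial
#' profile).
#'
#' @param kind Profile kind (see above).
#' @param level Plateau level in %MVC for `ramp_hold` (20, 50 or 80 in
#'   the standard design; other values are accepted with a warning).
#' @param seed Integer seed; required for `random`.
#' @param ramp_s Ramp duration for the rectangular profile transitions
#'   (default 0.25 s).
#' @param n_knots Number of interior knots for the random profile
#'   (default 5).
#' @return Object of class `target_profile` with fields `kind`,
#'   `breakpoints` (data.frame `time`, `force`), `duration`.
#' @export
make_target_profile <- function(kind = c("rectangular", "triangle",
                                         "step_climbing", "random",
                                         "ramp_hold"),
                                level = 20, seed = NULL, ramp_s = 0.25,
                                n_knots = 5) {
  kind <- match.arg(kind)
  bp <- switch(kind,
    rectangular = {
      lv <- c(20, 50, 80)
      t <- 0; f <- 0; tt <- c(0); ff <- c(0)
      for (l in lv) {
        t <- t + ramp_s; tt <- c(tt, t); ff <- c(ff, l)
        t <- t + 2;      tt <- c(tt, t); ff <- c(ff, l)
      }
      t <- t + ramp_s; tt <- c(tt, t); ff <- c(ff, 0)
      data.frame(time = tt, force = ff)
    },
    triangle = data.frame(time = c(0, 2.5, 5), force = c(0, 80, 0)),
    step_climbing = {
      # 4 ramps of 0.5 s + 4 plateaus of equal width filling 8.5 s
      steps <- c(20, 40, 60, 80)
      plateau <- (8.5 - 4 * 0.5) / 4
      t <- 0; tt <- 0; ff <- 0
      for (s in steps) {
        t <- t + 0.5;     tt <- c(tt, t); ff <- c(ff, s)
        t <- t + plateau; tt <- c(tt, t); ff <- c(ff, s)
      }
      data.frame(time = tt, force = ff)
    },
    random = {
      if (is.null(seed)) stop("random profile requires a seed")
      set.seed(seed)
      tt <- seq(0, 5, length.out = n_knots + 2)
      ff <- c(0, stats::runif(n_knots, 5, 80), stats::runif(1, 0, 40))
      data.frame(time = tt, force = ff)
    },
    ramp_hold = {
      if (!level %in% c(20, 50, 80)) {
        warning("ramp_hold level ", level,
                " is outside the standard {20, 50, 80} %MVC design")
      }
      stopifnot(level >= 0, level <= 100)
      data.frame(time = c(0, 1.5, 5.5), force = c(0, level, level))
    }
  )
  stopifnot(all(diff(bp$time) > 0), all(bp$force >= 0),
            all(bp$force <= 100))
  structure(list(kind = kind, level = if (kind == "ramp_hold") level else NA,
                 breakpoints = bp, duration = max(bp$time)),
            class = "target_profile")
}

#' Evaluate a target profile
#'
#' Linear interpolation of the profile's breakpoints; 0 outside its
#' support.
#'
#' @param profile A `target_profile`.
#' @param t Numeric vector of times (s).
#' @return Force in %MVC at each time.
#' @export
eval_profile <- function(profile, t) {
  stopifnot(inherits(profile, "target_profile"))
  stats::approx(profile$breakpoints$time, profile$breakpoints$force,
                xout = t, rule = 2, yleft = 0, yright = 0)$y *
    as.numeric(t >= 0 & t <= profile$duration) +
    0  # outside support the profile is rest
}

# internal: unit-variance Gaussian noise band-limited to [20, 450] Hz
bandlimited_noise <- function(n, fs) {
  if (fs <= 2 * 450) stop("sampling rate too low for the 450 Hz band limit")
  x <- stats::rnorm(n + 2000)  # pad to absorb filter edge effects
  bf <- signal::butter(4, c(20, 450) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, x)[1001:(n + 1000)]
  y / stats::sd(y)
}

#' Simulate one 13 s grasp trial
#'
#' Generates the 8-channel EMG and the measured force for a single trial:
#' a rest period, a 0.5 s reach, then execution of the target profile.
#' The rest period is sized so the whole trial lasts exactly 13 s
#' (7 s rest for the standard 5.5 s ramp-and-hold and 5 s profiles;
#' shorter rest for the 8.5 s staircase, which otherwise would not fit).
#'
#' @param movement One of [movement_names()].
#' @param profile A `target_profile`.
#' @param gains Gain matrix from [make_gain_matrix()].
#' @param noise A [noise_config()].
#' @param fs Sampling rate in Hz (default 2000).
#' @param seed Integer seed; the trial is deterministic given the seed.
#' @param mvc MVC values (newtons) per movement; default [default_mvc()].
#' @param trial_s Total trial duration, s (default 13).
#' @return List with `emg` (8 x N matrix), `force` (newtons, length N),
#'   `fs`, `movement`, `profile`, `rest_s`, `reach_s`, and
#'   `active_window` (start/end of profile execution, s from trial start).
#' @export
simulate_trial <- function(movement, profile, gains,
                           noise = noise_config(), fs = 2000, seed = 1,
                           mvc = default_mvc(), trial_s = 13) {
  stopifnot(movement %in% movement_names(),
            inherits(profile, "target_profile"))
  validate_gain_matrix(gains)
  reach_s <- 0.5
  rest_s <- trial_s - reach_s - profile$duration
  if (rest_s < 0) stop("profile of ", profile$duration,
                       " s does not fit in a ", trial_s, " s trial")
  set.seed(seed)
  n <- round(trial_s * fs)
  t <- (seq_len(n) - 1) / fs
  f_pct <- eval_profile(profile, t - rest_s - reach_s)
  # muscle activation leads measured force by the electromechanical delay
  f_emg <- eval_profile(profile, t - rest_s - reach_s + noise$emd_s)
  if (noise$overshoot > 0) {
    # executed force overshoots and rings after commanded jumps; the
    # ringing lives in the force response only, not in the EMG
    bp <- profile$breakpoints
    slopes <- diff(bp$force) / diff(bp$time)
    signs <- sample(c(-1, 1), length(slopes), replace = TRUE)
    for (s in seq_along(slopes)) {
      if (abs(slopes[s]) <= noise$fast_slope) next
      t_k <- rest_s + reach_s + bp$time[s + 1]
      amp <- signs[s] * noise$overshoot * abs(diff(bp$force)[s])
      dt <- t - t_k
      ring <- ifelse(dt >= 0,
                     amp * exp(-dt / 0.6) * sin(2 * pi * 1.5 * dt), 0)
      f_pct <- pmax(f_pct + ring, 0)
    }
  }
  mod <- (f_emg / 100)^noise$alpha
  emg <- matrix(0, 8, n, dimnames = list(channel_names(), NULL))
  for (c in 1:8) {
    drive <- gains[c, movement] * mod * bandlimited_noise(n, fs)
    base <- if (noise$baseline_amp > 0) {
      noise$baseline_amp * bandlimited_noise(n, fs)
    } else 0
    emg[c, ] <- drive + base
  }
  force <- mvc[[movement]] * f_pct / 100 +
    stats::rnorm(n, sd = noise$force_noise_pct / 100 * mvc[[movement]])
  list(emg = emg, force = force, fs = fs, movement = movement,
       profile = profile, rest_s = rest_s, reach_s = reach_s,
       active_window = c(rest_s + reach_s, rest_s + reach_s +
                           profile$duration))
}

#' Experiment design for a simulated session
#'
#' Experiment 1 is the classification study: ramp-and-hold trials at
#' force levels (in %MVC) for each movement. Experiment 2 is the force
#' estimation study: trials tracking the named target profiles.
#'
#' @param experiment 1 (classification) or 2 (force estimation).
#' @param movements Movements included (default all four).
#' @param levels Force levels in %MVC, experiment 1 (default 20/50/80).
#' @param profiles Profile kinds, experiment 2.
#' @param trials_per_condition Trials per movement x condition cell
#'   (the full study uses 50 for experiment 1 and 20 for experiment 2).
#' @param fs Sampling rate, Hz.
#' @param shuffle Shuffle trial order within the session (seeded).
#' @return List of class `experiment_design`.
#' @export
experiment_design <- function(experiment = 1,
                              movements = movement_names(),
                              levels = c(20, 50, 80),
                              profiles = c("rectangular", "triangle",
                                           "step_climbing", "random"),
                              trials_per_condition = if (experiment == 1) 50 else 20,
                              fs = 2000, shuffle = TRUE) {
  stopifnot(experiment %in% c(1, 2), all(movements %in% movement_names()))
  structure(list(experiment = experiment, movements = movements,
                 levels = levels, profiles = profiles,
                 trials_per_condition = trials_per_condition,
                 fs = fs, shuffle = shuffle),
            class = "experiment_design")
}

#' Simulate a full recording session
#'
#' Concatenates seeded trials into continuous EMG/force/trigger streams.
#' A 50 ms rectangular trigger pulse of amplitude 1 marks each trial
#' onset; annotations record the ground-truth onset sample, movement and
#' condition of every trial.
#'
#' @param design An [experiment_design()].
#' @param gains Gain matrix.
#' @param seed Master seed; trial order and every trial's noise are
#'   reproducible from it.
#' @param noise A [noise_config()].
#' @param mvc MVC values (newtons) per movement.
#' @param trigger_width_s Trigger pulse width, s (default 0.05).
#' @return List of class `session_recording`: `emg` (8 x N), `force`,
#'   `trigger`, `fs`, `annotations` (data.frame trial / movement /
#'   condition / onset_sample), `mvc`.
#' @export
simulate_session <- function(design, gains, seed = 1,
                             noise = noise_config(), mvc = default_mvc(),
                             trigger_width_s = 0.05) {
  stopifnot(inherits(design, "experiment_design"))
  conds <- if (design$experiment == 1) design$levels else design$profiles
  plan <- expand.grid(movement = design$movements, condition = conds,
                      rep = seq_len(design$trials_per_condition),
                      stringsAsFactors = FALSE)
  set.seed(seed)
  if (design$shuffle) plan <- plan[sample(nrow(plan)), ]
  fs <- design$fs
  n_trial <- round(13 * fs)
  n_total <- n_trial * nrow(plan)
  emg <- matrix(0, 8, n_total, dimnames = list(channel_names(), NULL))
  force <- numeric(n_total)
  trigger <- numeric(n_total)
  ann <- data.frame(trial = seq_len(nrow(plan)),
                    movement = plan$movement,
                    condition = as.character(plan$condition),
                    onset_sample = NA_integer_)
  pw <- round(trigger_width_s * fs)
  for (i in seq_len(nrow(plan))) {
    tseed <- derive_seed(seed, i)
    prof <- if (design$experiment == 1) {
      make_target_profile("ramp_hold", level = as.numeric(plan$condition[i]))
    } else {
      make_target_profile(plan$condition[i], seed = tseed)
    }
    tr <- simulate_trial(plan$movement[i], prof, gains, noise = noise,
                         fs = fs, seed = tseed, mvc = mvc)
    at <- (i - 1) * n_trial
    idx <- (at + 1):(at + n_trial)
    emg[, idx] <- tr$emg
    force[idx] <- tr$force
    trigger[(at + 1):(at + pw)] <- 1
    ann$onset_sample[i] <- at + 1L
  }
  structure(list(emg = emg, force = force, trigger = trigger, fs = fs,
                 annotations = ann, mvc = mvc, design = design,
                 seed = seed),
            class = "session_recording")
}

#' Write / read a session directory
#'
#' Plain-text container: per-stream CSV files plus a JSON sidecar with
#' the sampling rate, channel labels and trial annotations.
#'
#' @param session A `session_recording`.
#' @param dir Output directory (created if absent).
#' @return `write_session` returns `dir` invisibly; `read_session`
#'   returns a `session_recording`.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(t(session$emg)),
                   file.path(dir, "emg.csv"), row.names = FALSE)
  utils::write.csv(data.frame(force = session$force,
                              trigger = session$trigger),
                   file.path(dir, "force_trigger.csv"), row.names = FALSE)
  meta <- list(fs = session$fs, channels = channel_names(),
               mvc = as.list(session$mvc),
               annotations = session$annotations)
  jsonlite::write_json(meta, file.path(dir, "session.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  emg <- t(as.matrix(utils::read.csv(file.path(dir, "emg.csv"))))
  rownames(emg) <- channel_names()
  ft <- utils::read.csv(file.path(dir, "force_trigger.csv"))
  meta <- jsonlite::read_json(file.path(dir, "session.json"),
                              simplifyVector = TRUE)
  structure(list(emg = emg, force = ft$force, trigger = ft$trigger,
                 fs = meta$fs, annotations = meta$annotations,
                 mvc = unlist(meta$mvc)),
            class = "session_recording")
}
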