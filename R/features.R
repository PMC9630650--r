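# Sliding-window segmentation and the five classical time-domain EMG
# features: MAV, RMS, VAR, WAMP, WL.

#' Sliding-window specification
#'
#' @param width_ms Window width, ms.
#' @param step_ms Step between consecutive window starts, ms.
#' @param fs Sampling rate, Hz. `width_ms * fs / 1000` must be integral.
#' @return List of class `window_spec`.
#' @export
window_spec <- function(width_ms, step_ms, fs = 2000) {
  w <- width_ms * fs / 1000
  s <- step_ms * fs / 1000
  stopifnot(width_ms >= step_ms, step_ms > 0,
            abs(w - round(w)) < 1e-9, abs(s - round(s)) < 1e-9)
  structure(list(width_ms = width_ms, step_ms = step_ms, fs = fs,
                 width = as.integer(round(w)), step = as.integer(round(s))),
            class = "window_spec")
}

#' Sliding-window index layout
#'
#' Start/end (inclusive, 1-based) sample indices of every full window in
#' a signal of `length` samples: floor((length - W) / S) + 1 windows,
#' trailing partial windows discarded.
#'
#' @param length Signal length, samples.
#' @param spec A [window_spec()].
#' @return Data frame with columns `start`, `end`; zero rows (with a
#'   warning) when the signal is shorter than one window.
#' @export
window_indices <- function(length, spec) {
  stopifnot(inherits(spec, "window_spec"))
  w <- spec$width; s <- spec$step
  if (length < w) {
    warning("signal shorter than one window")
    return(data.frame(start = integer(0), end = integer(0)))
  }
  starts <- seq.int(1L, length - w + 1L, by = s)
  data.frame(start = starts, end = starts + w - 1L)
}

#' Time-domain EMG window features
#'
#' The five classical features of a window x of N samples:
#' * `mav(x)` -- mean absolute value, (1/N) * sum |x_i|;
#' * `rms(x)` -- root mean square, sqrt((1/N) * sum x_i^2);
#' * `emg_var(x)` -- unbiased sample variance about the window mean,
#'   (1/(N-1)) * sum (x_i - mean)^2;
#' * `wamp(x, threshold)` -- Willison amplitude, the count of
#'   consecutive-sample differences with |x_(i+1) - x_i| >= threshold;
#' * `wl(x)` -- waveform length (total variation), sum |x_(i+1) - x_i|.
#'
#' @param x Numeric vector, one window of samples.
#' @param threshold Nonnegative amplitude threshold for `wamp`.
#' @return A single numeric value (integer count for `wamp`).
#' @export
mav <- function(x) {
  if (length(x) == 0) stop("empty window")
  mean(abs(x))
}

#' @rdname mav
#' @export
rms <- function(x) {
  if (length(x) == 0) stop("empty window")
  sqrt(mean(x^2))
}

#' @rdname mav
#' @export
emg_var <- function(x) {
  if (length(x) < 2) stop("variance requires at least 2 samples")
  stats::var(x)
}

#' @rdname mav
#' @export
wamp <- function(x, threshold) {
  if (length(x) < 2) stop("wamp requires at least 2 samples")
  if (threshold < 0) stop("wamp threshold must be nonnegative")
  sum(abs(diff(x)) >= threshold)
}

#' @rdname mav
#' @export
wl <- function(x) {
  if (length(x) < 2) stop("waveform length requires at least 2 samples")
  sum(abs(diff(x)))
}

#' Feature names in canonical order
#' @return `c("mav", "rms", "var", "wamp", "wl")`
#' @export
feature_names <- function() c("mav", "rms", "var", "wamp", "wl")

#' Active-phase window of a trial condition
#'
#' Seconds from trial onset during which the grasp is executed. For
#' classification (ramp-and-hold) trials this is the force-hold analysis
#' window, 10--13 s; for the force-tracking profiles it is the profile's
#' execution span (rest and reach excluded).
#'
#' @param condition A force level (numeric or numeric string) or a
#'   profile kind.
#' @param analysis_window Window used for ramp-and-hold trials
#'   (default `c(10, 13)`).
#' @return Numeric `(start, end)` in seconds.
#' @export
active_window <- function(condition, analysis_window = c(10, 13)) {
  if (!is.na(suppressWarnings(as.numeric(condition)))) {
    return(analysis_window)
  }
  switch(as.character(condition),
    rectangular   = c(6.0, 13.0),
    triangle      = c(7.5, 12.5),
    step_climbing = c(4.5, 13.0),
    random        = c(7.5, 12.5),
    ramp_hold     = analysis_window,
    stop("unknown condition: ", condition)
  )
}

# internal: per-channel WAMP threshold from the rest phase
wamp_thresholds <- function(trial, rest_window = c(0, 3.5)) {
  rest <- extract_phase(trial, rest_window)
  apply(rest$emg, 1, function(x) 2 * stats::mad(x))
}

#' Build the windows-by-features matrix for a set of trials
#'
#' Segments the requested phase of each trial with a sliding window and
#' computes the selected time-domain features per channel per window.
#' Columns are ordered channel-major ("C1_mav", "C1_rms", ...,
#' "C2_mav", ...). Each window carries the trial's class annotations and
#' the window-mean normalized force as the regression target.
#'
#' @param trials List of `emg_trial`.
#' @param spec A [window_spec()].
#' @param channels Channel subset, e.g. `c("C2", "C4")` or indices.
#' @param features Feature subset from [feature_names()].
#' @param phase `(start, end)` analysis window in seconds, or `NULL` to
#'   use each trial's [active_window()].
#' @param wamp_threshold `"adaptive"` (2 x MAD of the trial's rest-phase
#'   signal, per channel) or a fixed numeric value.
#' @return List of class `feature_matrix`: `X` (windows x columns),
#'   `y_force` (window-mean %MVC), `movement`, `condition`, `trial_id`
#'   (per window), `channels`, `features`, `spec`.
#' @export
featurize <- function(trials, spec, channels = channel_names(),
                      features = feature_names(), phase = NULL,
                      wamp_threshold = "adaptive") {
  stopifnot(length(trials) > 0, length(channels) > 0,
            length(features) > 0, all(features %in% feature_names()))
  if (is.numeric(channels)) channels <- channel_names()[channels]
  stopifnot(all(channels %in% channel_names()))
  rows <- list(); yf <- list(); mv <- list(); cond <- list(); tid <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    ph <- if (is.null(phase)) active_window(tr$condition) else phase
    seg <- extract_phase(tr, ph)
    win <- suppressWarnings(window_indices(length(seg$force), spec))
    if (nrow(win) == 0) stop("phase shorter than one window")
    thr <- if (identical(wamp_threshold, "adaptive")) {
      wamp_thresholds(tr)[channels]
    } else {
      stats::setNames(rep(wamp_threshold, length(channels)), channels)
    }
    Xt <- matrix(0, nrow(win), length(channels) * length(features))
    col <- 1
    for (ch in channels) {
      x <- seg$emg[ch, ]
      for (f in features) {
        Xt[, col] <- vapply(seq_len(nrow(win)), function(k) {
          xv <- x[win$start[k]:win$end[k]]
          switch(f,
                 mav = mav(xv), rms = rms(xv), var = emg_var(xv),
                 wamp = wamp(xv, thr[[ch]]), wl = wl(xv))
        }, numeric(1))
        col <- col + 1
      }
    }
    rows[[i]] <- Xt
    yf[[i]] <- vapply(seq_len(nrow(win)), function(k) {
      mean(seg$force[win$start[k]:win$end[k]])
    }, numeric(1))
    mv[[i]] <- rep(tr$movement, nrow(win))
    cond[[i]] <- rep(as.character(tr$condition), nrow(win))
    tid[[i]] <- rep(i, nrow(win))
  }
  X <- do.call(rbind, rows)
  colnames(X) <- as.vector(t(outer(channels, features, paste, sep = "_")))
  structure(list(X = X, y_force = unlist(yf), movement = unlist(mv),
                 condition = unlist(cond), trial_id = unlist(tid),
                 channels = channels, features = features, spec = spec),
            class = "feature_matrix")
}

#' Subset the channels of a feature matrix
#'
#' Selects the column blocks of the given channels without recomputing
#' features; used by the channel-subset scans.
#'
#' @param fm A `feature_matrix` built over a superset of `channels`.
#' @param channels Channel subset to keep.
#' @return A `feature_matrix` restricted to those channels.
#' @export
subset_channels <- function(fm, channels) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (is.numeric(channels)) channels <- channel_names()[channels]
  stopifnot(all(channels %in% fm$channels))
  keep <- as.vector(t(outer(channels, fm$features, paste, sep = "_")))
  fm$X <- fm$X[, keep, drop = FALSE]
  fm$channels <- channels
  fm
}

#' Write / read a feature matrix as CSV
#'
#' One row per window: feature columns named "C3_rms" etc., then
#' `movement`, `condition`, `trial_id`, `y_force`.
#'
#' @param fm A `feature_matrix`.
#' @param path CSV file path.
#' @return `write_feature_matrix` returns `path` invisibly;
#'   `read_feature_matrix` the data frame.
#' @export
write_feature_matrix <- function(fm, path) {
  df <- as.data.frame(fm$X)
  df$movement <- fm$movement
  df$condition <- fm$condition
  df$trial_id <- fm$trial_id
  df$y_force <- fm$y_force
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) utils::read.csv(path)
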