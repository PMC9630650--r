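# Raw-stream conditioning: band-pass + notch filtering, trigger
# detection, MVC normalization, and trial segmentation.

#' EMG filter specification
#'
#' Sixth-order Butterworth band-pass 10--500 Hz plus a 50 Hz notch,
#' applied zero-phase (forward-backward). The band-pass is realized as a
#' cascaded high-pass and low-pass so the 10 Hz edge keeps full
#' Butterworth roll-off independent of the 500 Hz edge.
#'
#' @param low,high Band edges, Hz.
#' @param order Butterworth order (even, >= 2). Default 6.
#' @param notch_freq Power-line notch frequency, Hz. Default 50.
#' @param notch_q Notch quality factor (centre frequency / -3 dB
#'   bandwidth). Default 30.
#' @return List of class `filter_spec`.
#' @export
filter_spec <- function(low = 10, high = 500, order = 6,
                        notch_freq = 50, notch_q = 30) {
  stopifnot(low > 0, high > low, order >= 2, order %% 2 == 0,
            notch_q > 0)
  structure(list(low = low, high = high, order = order,
                 notch_freq = notch_freq, notch_q = notch_q),
            class = "filter_spec")
}

# internal: RBJ biquad notch coefficients
notch_coefs <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

#' Band-pass and notch filter an EMG stream
#'
#' Zero-phase (filtfilt) application of the [filter_spec()] design to a
#' vector or a channels-by-samples matrix. Output length equals input
#' length.
#'
#' @param emg Numeric vector or matrix (channels x samples).
#' @param fs Sampling rate, Hz.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same shape as the input.
#' @export
bandpass_notch <- function(emg, fs, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  if (spec$high > fs / 2) stop("upper band edge at or above Nyquist")
  hp <- signal::butter(spec$order, spec$low / (fs / 2), type = "high")
  lp <- signal::butter(spec$order, min(spec$high / (fs / 2), 0.999),
                       type = "low")
  nc <- notch_coefs(spec$notch_freq, fs, spec$notch_q)
  filt1 <- function(x) {
    y <- signal::filtfilt(hp, x)
    y <- signal::filtfilt(lp, y)
    signal::filtfilt(signal::Arma(b = nc$b, a = nc$a), y)
  }
  if (is.matrix(emg)) {
    out <- t(apply(emg, 1, filt1))
    dimnames(out) <- dimnames(emg)
    out
  } else {
    filt1(emg)
  }
}

#' Detect trigger pulse onsets
#'
#' Returns the leading-edge sample (first supra-threshold sample) of
#' each trigger pulse. Edges closer together than `merge_ms` are treated
#' as one pulse (bounce/noise suppression).
#'
#' @param trigger Numeric vector, the trigger stream.
#' @param threshold Detection threshold, between baseline and pulse
#'   amplitude. Default 0.5 for unit pulses.
#' @param fs Sampling rate, Hz.
#' @param merge_ms Minimum pulse separation, ms (default 100).
#' @return Integer vector of onset samples (1-based); empty with a
#'   warning when no pulse crosses the threshold.
#' @export
detect_triggers <- function(trigger, threshold = 0.5, fs = 2000,
                            merge_ms = 100) {
  above <- trigger > threshold
  edges <- which(diff(c(FALSE, above)) == 1)
  if (length(edges) == 0) {
    warning("no trigger pulses found above threshold ", threshold)
    return(integer(0))
  }
  min_sep <- round(merge_ms / 1000 * fs)
  keep <- c(TRUE, diff(edges) >= min_sep)
  as.integer(edges[keep])
}

#' Maximum voluntary contraction reference
#'
#' The MVC reference for a movement is the arithmetic mean of the force
#' maxima of three maximal-effort attempts.
#'
#' @param maxima Numeric vector of exactly three positive force maxima
#'   (newtons).
#' @param movement Movement the reference belongs to.
#' @return List of class `mvc_reference` with fields `movement`, `value`
#'   (newtons) and `source_maxima`.
#' @export
compute_mvc <- function(maxima, movement = NA_character_) {
  if (length(maxima) != 3) stop("exactly three MVC attempt maxima required")
  if (any(maxima <= 0)) stop("MVC maxima must be positive")
  structure(list(movement = movement, value = mean(maxima),
                 source_maxima = maxima),
            class = "mvc_reference")
}

#' Cut a session into annotated, normalized trials
#'
#' Segments the continuous streams at trigger onsets, filters each
#' trial's EMG with [bandpass_notch()], and normalizes force to %MVC by
#' the per-movement MVC reference. Trials whose 13 s extent runs past
#' the end of the stream are dropped with a warning. Onsets are matched
#' to the session annotations in order; a mismatch beyond
#' `onset_tol` samples is an error.
#'
#' @param session A `session_recording`.
#' @param onsets Trigger onset samples, e.g. from [detect_triggers()].
#' @param mvc Named numeric vector of MVC values (newtons) per movement;
#'   defaults to the session's own.
#' @param spec A [filter_spec()].
#' @param trial_s Trial duration, s.
#' @param onset_tol Allowed |detected - annotated| onset gap, samples.
#' @return List of `trial` objects: `emg` (filtered, 8 x M), `force`
#'   (%MVC), `movement`, `condition`, `fs`, `phase_bounds`.
#' @export
cut_trials <- function(session, onsets, mvc = session$mvc,
                       spec = filter_spec(), trial_s = 13,
                       onset_tol = 10) {
  ann <- session$annotations
  if (length(onsets) != nrow(ann)) {
    stop("detected ", length(onsets), " onsets but session annotates ",
         nrow(ann), " trials")
  }
  gap <- abs(onsets - ann$onset_sample)
  if (any(gap > onset_tol)) {
    stop("trigger onsets deviate from annotations by up to ",
         max(gap), " samples (tolerance ", onset_tol, ")")
  }
  fs <- session$fs
  n_trial <- round(trial_s * fs)
  trials <- list()
  for (i in seq_along(onsets)) {
    a <- onsets[i]
    b <- a + n_trial - 1
    if (b > length(session$force)) {
      warning("trial ", i, " extends past stream end; dropped")
      next
    }
    mv <- ann$movement[i]
    emg <- bandpass_notch(session$emg[, a:b, drop = FALSE], fs, spec)
    force_pct <- session$force[a:b] / mvc[[mv]] * 100
    cond <- ann$condition[i]
    level <- suppressWarnings(as.numeric(cond))
    trials[[length(trials) + 1]] <- structure(
      list(emg = emg, force = force_pct, movement = mv,
           condition = cond,
           level = if (is.na(level)) NA_real_ else level,
           fs = fs,
           phase_bounds = c(rest = 0, reach = 7, ramp = 7.5,
                            hold = 9, end = 13)),
      class = "emg_trial")
  }
  trials
}

#' Extract a time window from a trial
#'
#' @param trial An `emg_trial`.
#' @param window `(start, end)` in seconds from trial onset; must lie
#'   within the trial and satisfy start < end.
#' @return List with `emg` (8 x M) and `force` (length M), where
#'   M = (end - start) * fs exactly.
#' @export
extract_phase <- function(trial, window = c(10, 13)) {
  stopifnot(length(window) == 2)
  if (window[2] <= window[1]) stop("inverted phase window")
  n <- ncol(trial$emg)
  fs <- trial$fs
  i0 <- round(window[1] * fs) + 1
  i1 <- round(window[2] * fs)
  if (i0 < 1 || i1 > n) stop("phase window outside trial extent")
  list(emg = trial$emg[, i0:i1, drop = FALSE], force = trial$force[i0:i1])
}

#' Simulate, detect, cut: session to trial list
#'
#' Convenience wrapper running trigger detection and trial cutting on a
#' (typically simulated) session with its own MVC reference.
#'
#' @param session A `session_recording`.
#' @param spec A [filter_spec()].
#' @param ... Passed to [cut_trials()].
#' @return List of `emg_trial`.
#' @export
preprocess_session <- function(session, spec = filter_spec(), ...) {
  onsets <- detect_triggers(session$trigger, fs = session$fs)
  cut_trials(session, onsets, spec = spec, ...)
}
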