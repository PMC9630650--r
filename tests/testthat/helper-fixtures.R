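# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

# small classification session: 4 movements x 3 levels x 3 trials
fixture_exp1_session <- function() {
  if (is.null(.fx$exp1_session)) {
    design <- experiment_design(1, trials_per_condition = 3)
    .fx$exp1_session <- simulate_session(design,
                                         make_gain_matrix("paperlike"),
                                         seed = 101)
  }
  .fx$exp1_session
}

fixture_exp1_trials <- function() {
  if (is.null(.fx$exp1_trials)) {
    .fx$exp1_trials <- preprocess_session(fixture_exp1_session())
  }
  .fx$exp1_trials
}

# one filtered trial per movement at level 50
fixture_single_trials <- function() {
  if (is.null(.fx$single)) {
    design <- experiment_design(1, levels = 50, trials_per_condition = 1,
                                shuffle = FALSE)
    sess <- simulate_session(design, make_gain_matrix("paperlike"),
                             seed = 55)
    .fx$single <- preprocess_session(sess)
  }
  .fx$single
}

# independent naive-loop oracles for the five time-domain features
oracle_mav <- function(x) {
  s <- 0
  for (v in x) s <- s + abs(v)
  s / length(x)
}
oracle_rms <- function(x) {
  s <- 0
  for (v in x) s <- s + v * v
  sqrt(s / length(x))
}
oracle_var <- function(x) {
  m <- 0
  for (v in x) m <- m + v
  m <- m / length(x)
  s <- 0
  for (v in x) s <- s + (v - m)^2
  s / (length(x) - 1)
}
oracle_wamp <- function(x, thr) {
  n <- 0L
  for (i in seq_len(length(x) - 1)) {
    if (abs(x[i + 1] - x[i]) >= thr) n <- n + 1L
  }
  n
}
oracle_wl <- function(x) {
  s <- 0
  for (i in seq_len(length(x) - 1)) s <- s + abs(x[i + 1] - x[i])
  s
}

# brute-force window start enumeration
oracle_window_starts <- function(len, w, s) {
  starts <- integer(0)
  st <- 1L
  while (st + w - 1L <= len) {
    starts <- c(starts, st)
    st <- st + as.integer(s)
  }
  starts
}
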