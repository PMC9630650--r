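test_that("target profiles satisfy their defining geometry", {
  tri <- make_target_profile("triangle")
  expect_equal(eval_profile(tri, 2.5), 80)
  expect_equal(eval_profile(tri, 0), 0)
  expect_equal(tri$duration, 5)

  rh <- make_target_profile("ramp_hold", level = 50)
  expect_equal(eval_profile(rh, 0), 0)
  expect_equal(eval_profile(rh, 1.5), 50)
  expect_equal(eval_profile(rh, 5), 50)

  # numerically integrate the generated polyline over its three plateau
  # segments: 2 s each at 20/50/80 %MVC -> 300 %MVC s in total
  rect <- make_target_profile("rectangular")
  bp <- rect$breakpoints
  flat <- which(diff(bp$force) == 0 & bp$force[-nrow(bp)] > 0)
  plateau_area <- sum(sapply(flat, function(i) {
    t <- seq(bp$time[i], bp$time[i + 1], by = 1e-4)
    mean(eval_profile(rect, t)) * (bp$time[i + 1] - bp$time[i])
  }))
  expect_equal(plateau_area, 300, tolerance = 1e-6)

  step <- make_target_profile("step_climbing")
  expect_equal(step$duration, 8.5)
  expect_true(all(diff(step$breakpoints$force) >= 0))  # monotone climb
  expect_equal(max(step$breakpoints$force), 80)

  rnd <- make_target_profile("random", seed = 9)
  expect_lte(max(rnd$breakpoints$force), 80)
  expect_equal(rnd$duration, 5)
  rnd2 <- make_target_profile("random", seed = 9)
  expect_identical(rnd$breakpoints, rnd2$breakpoints)

  expect_error(make_target_profile("sawtooth"))
  expect_warning(make_target_profile("ramp_hold", level = 37),
                 "outside the standard")
})

test_that("gain matrix presets satisfy invariants and determinism", {
  g <- make_gain_matrix("paperlike")
  expect_equal(dim(g), c(8, 4))
  expect_true(all(g >= 0))
  expect_true(all(apply(g, 2, max) > 0))
  # ordinal structure: C7 nearly silent for pinch, strong for plug
  expect_lt(g["C7", "pinch"], g["C7", "plug"])
  expect_lt(g["C8", "pinch"], 0.2)

  r1 <- make_gain_matrix("random", seed = 42)
  r2 <- make_gain_matrix("random", seed = 42)
  expect_identical(r1, r2)
  expect_error(make_gain_matrix("random"), "seed")
  # every movement has at least one informative, one near-zero channel
  expect_true(all(apply(r1, 2, max) > 0.2))
  expect_true(all(apply(r1, 2, min) < 0.05))
})

test_that("simulated trials are deterministic and force-coupled", {
  g <- make_gain_matrix("paperlike")
  p <- make_target_profile("ramp_hold", level = 50)
  t1 <- simulate_trial("palmar", p, g, seed = 7)
  t2 <- simulate_trial("palmar", p, g, seed = 7)
  expect_identical(t1$emg, t2$emg)
  expect_identical(t1$force, t2$force)

  # rest period: EMG variance equals baseline variance
  nc <- noise_config(baseline_amp = 0.05)
  tr <- simulate_trial("palmar", p, g, noise = nc, seed = 11)
  fs <- tr$fs
  rest_sd <- sd(tr$emg[4, 1:(6 * fs)])
  expect_equal(rest_sd, 0.05, tolerance = 0.1)

  # zero-gain channel carries no force information: its RMS envelope is
  # uncorrelated with a strongly varying (triangular) force trajectory
  g0 <- g; g0["C3", "palmar"] <- 0
  tr0 <- simulate_trial("palmar", make_target_profile("triangle"), g0,
                        seed = 11)
  starts <- seq(7.5 * fs, 12.3 * fs, by = 200)
  env <- sapply(starts, function(i) sqrt(mean(tr0$emg[3, i:(i + 399)]^2)))
  fwin <- sapply(starts, function(i) mean(tr0$force[i:(i + 399)]))
  expect_gt(sd(fwin), 5)               # the force really varies
  expect_lt(abs(cor(env, fwin)), 0.3)  # ~2.5 sigma for 49 windows

  # profile that does not fit the trial is rejected
  expect_error(simulate_trial("palmar", make_target_profile("step_climbing"),
                              g, trial_s = 8), "does not fit")
})

test_that("doubling a gain doubles the expected windowed RMS", {
  g <- make_gain_matrix("paperlike")
  g2 <- g; g2["C4", "palmar"] <- 2 * g["C4", "palmar"]
  p <- make_target_profile("ramp_hold", level = 50)
  nc <- noise_config(baseline_amp = 0)
  r1 <- r2 <- numeric(100)
  for (i in 1:100) {
    a <- simulate_trial("palmar", p, g, noise = nc, seed = 1000 + i)
    b <- simulate_trial("palmar", p, g2, noise = nc, seed = 1000 + i)
    hold <- (10 * 2000):(13 * 2000 - 1)
    r1[i] <- sqrt(mean(a$emg[4, hold]^2))
    r2[i] <- sqrt(mean(b$emg[4, hold]^2))
  }
  expect_equal(mean(r2) / mean(r1), 2, tolerance = 0.02)
})

test_that("sessions annotate every trial and reproduce bit-for-bit", {
  g <- make_gain_matrix("paperlike")
  d1 <- experiment_design(1, movements = "pinch", trials_per_condition = 2)
  s1 <- simulate_session(d1, g, seed = 5)
  expect_equal(nrow(s1$annotations), 3 * 2)  # 3 levels x 2 trials

  d2 <- experiment_design(2, movements = "pinch", trials_per_condition = 2)
  s2 <- simulate_session(d2, g, seed = 5)
  expect_equal(nrow(s2$annotations), 4 * 2)  # 4 profiles x 2 trials

  s1b <- simulate_session(d1, g, seed = 5)
  expect_identical(s1$emg, s1b$emg)
  expect_identical(s1$force, s1b$force)
  expect_identical(s1$trigger, s1b$trigger)

  # trigger pulse leading edges coincide with annotated onsets
  onsets <- detect_triggers(s1$trigger, fs = s1$fs)
  expect_identical(onsets, as.integer(s1$annotations$onset_sample))
})

test_that("simulated EMG keeps its power inside the analysis band", {
  g <- make_gain_matrix("paperlike")
  p <- make_target_profile("ramp_hold", level = 80)
  tr <- simulate_trial("twist", p, g, seed = 3)
  fs <- tr$fs
  x <- tr$emg[4, (10 * fs):(13 * fs - 1)]
  sp <- stats::spec.pgram(ts(x, frequency = fs), plot = FALSE, taper = 0)
  inband <- sp$freq >= 10 & sp$freq <= 500
  expect_gt(sum(sp$spec[inband]) / sum(sp$spec), 0.95)
})

test_that("hold-phase RMS increases strictly with force level", {
  g <- make_gain_matrix("paperlike")
  nc <- noise_config()
  med <- sapply(c(20, 50, 80), function(lv) {
    p <- make_target_profile("ramp_hold", level = lv)
    mean(sapply(1:50, function(i) {
      tr <- simulate_trial("palmar", p, g, noise = nc, seed = 2000 + i)
      sqrt(mean(tr$emg[4, (10 * 2000):(13 * 2000 - 1)]^2))
    }))
  })
  expect_true(all(diff(med) > 0))
})

test_that("session directories round-trip through write/read", {
  g <- make_gain_matrix("paperlike")
  d <- experiment_design(1, movements = "twist", levels = 20,
                         trials_per_condition = 1)
  s <- simulate_session(d, g, seed = 2)
  dir <- file.path(tempdir(), "sess_rt")
  write_session(s, dir)
  s2 <- read_session(dir)
  expect_equal(s2$fs, s$fs)
  expect_equal(s2$force, s$force, tolerance = 1e-10)
  expect_equal(dim(s2$emg), dim(s$emg))
  expect_equal(s2$annotations$onset_sample, s$annotations$onset_sample)
  unlink(dir, recursive = TRUE)
})
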