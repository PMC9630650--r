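test_that("r_squared matches hand computation and a two-pass oracle", {
  expect_equal(r_squared(c(0, 1, 2), c(0, 1, 2)), 1)
  expect_equal(r_squared(c(0, 1, 2), rep(1, 3)), 0)
  expect_equal(r_squared(c(0, 1, 2), c(0, 0, 2)), 0.5)
  expect_warning(out <- r_squared(rep(3, 5), 1:5), "constant")
  expect_true(is.nan(out))

  set.seed(21)
  for (i in 1:20) {
    ref <- rnorm(50); pred <- ref + rnorm(50, sd = 0.3)
    # brute-force two-pass formula
    m <- sum(ref) / 50
    sst <- 0; ssr <- 0
    for (j in 1:50) {
      sst <- sst + (ref[j] - m)^2
      ssr <- ssr + (ref[j] - pred[j])^2
    }
    expect_equal(r_squared(ref, pred), 1 - ssr / sst,
                 tolerance = 1e-12)
  }
})

test_that("regressor recovers a noiseless linear target", {
  set.seed(8)
  X <- matrix(runif(600, 0, 1), ncol = 3)
  colnames(X) <- paste0("C1_", c("mav", "rms", "wl"))
  y <- 60 * X[, 2] + 10
  mod <- train_regressor(X, y, regressor_config(seed = 2, maxit = 500))
  Xte <- matrix(runif(150, 0, 1), ncol = 3)
  expect_gt(r_squared(60 * Xte[, 2] + 10, predict(mod, Xte)), 0.99)
})

test_that("regressor training is deterministic and validates input", {
  set.seed(9)
  X <- matrix(rnorm(200), ncol = 2)
  y <- 20 + 10 * X[, 1]
  m1 <- train_regressor(X, y, regressor_config(seed = 5))
  m2 <- train_regressor(X, y, regressor_config(seed = 5))
  expect_identical(m1$net$wts, m2$net$wts)
  expect_identical(predict(m1, X), predict(m2, X))

  expect_error(train_regressor(cbind(X, NA), rep(1, 100)), "non-finite")
  expect_warning(train_regressor(X, rep(50, 100),
                                 regressor_config(maxit = 5)),
                 "constant")
})

test_that("predictions are clipped for reporting but raw on request", {
  set.seed(10)
  X <- matrix(rnorm(100), ncol = 1)
  y <- 100 * X[, 1]  # forces outside [0, 120] easily
  mod <- train_regressor(X, y, regressor_config(maxit = 200, seed = 3))
  p_clip <- predict(mod, X)
  expect_true(all(p_clip >= 0 & p_clip <= 120))
  p_raw <- predict(mod, X, clip = NULL)
  expect_true(any(p_raw < 0))
})

test_that("channel presets and top-k selection follow the tie rules", {
  expect_identical(select_channels(movement = "plug", mode = "preset"),
                   c("C2", "C4", "C5", "C7"))
  expect_identical(select_channels(movement = "pinch", mode = "preset"),
                   c("C1", "C2", "C3", "C5"))
  expect_identical(select_channels(movement = "palmar", mode = "preset"),
                   c("C2", "C4", "C5", "C6"))
  expect_identical(select_channels(movement = "twist", mode = "preset"),
                   c("C1", "C2", "C3", "C4"))
  expect_error(select_channels(movement = "plug", k = 9), "at most 8")

  m <- matrix(0, 4, 8, dimnames = list(movement_names(), channel_names()))
  m["twist", c("C2", "C3", "C6", "C8")] <- c(40, 90, 55, 70)
  tab <- structure(list(mean = m, sd = m * 0, n_trials = m * 0 + 3),
                   class = "correlation_table")
  # exactly four nonzero entries -> those four
  expect_identical(select_channels(tab, "twist", mode = "top_k"),
                   c("C2", "C3", "C6", "C8"))
  # all-equal entries -> lowest channel indices by tie-break
  m2 <- m; m2["twist", ] <- 50
  tab2 <- structure(list(mean = m2, sd = m2 * 0, n_trials = m2 * 0 + 3),
                    class = "correlation_table")
  expect_identical(select_channels(tab2, "twist", mode = "top_k"),
                   c("C1", "C2", "C3", "C4"))
})

test_that("channel-force correlation is bounded and exact on identity", {
  # envelope := force gives |r| = 1 -> 100%
  expect_equal(abs(cor(c(1, 3, 7, 9), c(1, 3, 7, 9))) * 100, 100)

  trials <- fixture_single_trials()  # one trial per movement, level 50
  # duplicate with a second seed so sd is defined
  design <- experiment_design(1, levels = 50, trials_per_condition = 1,
                              shuffle = FALSE)
  sess2 <- simulate_session(design, make_gain_matrix("paperlike"),
                            seed = 56)
  both <- c(trials, preprocess_session(sess2))
  ct <- channel_correlation(both, window_spec(200, 80, 2000))
  vals <- ct$mean[!is.na(ct$mean)]
  expect_true(all(vals >= 0 & vals <= 100))
  expect_equal(dim(ct$mean), c(4, 8))
  expect_true(all(ct$n_trials[unique(vapply(both, `[[`, "", "movement")), ] == 2))
})

test_that("profile R2 table carries AVE rows equal to profile means", {
  g <- make_gain_matrix("paperlike")
  tbp <- list()
  for (pf in c("triangle", "random")) {
    d <- experiment_design(2, movements = "plug", profiles = pf,
                           trials_per_condition = 5)
    tbp[[pf]] <- preprocess_session(simulate_session(d, g, seed = 77))
  }
  tab <- profile_r2_table(tbp, list(plug = c("C2", "C4", "C5", "C7")),
                          n_repeats = 2, seed = 3)
  ave <- tab$r2_mean_pct[tab$profile == "AVE"]
  expect_equal(ave, mean(tab$r2_mean_pct[tab$profile != "AVE"]))
  expect_equal(nrow(tab), 3)
})

test_that("regression scan respects budgets and aggregates correctly", {
  g <- make_gain_matrix("paperlike")
  d <- experiment_design(2, movements = "palmar", profiles = "triangle",
                         trials_per_condition = 5)
  trials <- preprocess_session(simulate_session(d, g, seed = 31))
  scan <- regression_scan(trials, sizes = c(2, 4), budget = 3,
                          n_repeats = 1, seed = 6)
  expect_lte(sum(scan$per_subset$size == 2), 3)
  for (n in c(2, 4)) {
    sub <- scan$per_subset$r2[scan$per_subset$size == n]
    agg <- scan$per_size[scan$per_size$size == n, ]
    expect_equal(agg$r2_mean, mean(sub))
    expect_equal(agg$r2_min, min(sub))
    expect_equal(agg$r2_max, max(sub))
  }
})

test_that("window sweep reports per-movement and mean rows", {
  g <- make_gain_matrix("paperlike")
  d <- experiment_design(2, movements = c("palmar", "plug"),
                         profiles = "step_climbing",
                         trials_per_condition = 4)
  trials <- preprocess_session(simulate_session(d, g, seed = 13))
  sw <- sweep_windows(trials, steps_ms = c(80, 160),
                      widths_ms = c(200, 300), fixed_width_ms = 300,
                      n_repeats = 1, seed = 2)
  t1 <- sw$table[sw$table$stage == 1, ]
  expect_setequal(unique(t1$movement), c("palmar", "plug", "mean"))
  # mean rows average the movement rows at each grid point
  for (s in c(80, 160)) {
    cell <- t1[t1$step_ms == s, ]
    expect_equal(cell$r2[cell$movement == "mean"],
                 mean(cell$r2[cell$movement != "mean"]))
  }
  expect_true(sw$best_step_ms %in% c(80, 160))
  t2 <- sw$table[sw$table$stage == 2, ]
  expect_true(all(t2$step_ms == sw$best_step_ms))
  expect_setequal(unique(t2$width_ms), c(200, 300))
  # wider window at fixed step -> fewer windows
  expect_gt(nrow(window_indices(6000, window_spec(200, 80))),
            nrow(window_indices(6000, window_spec(300, 80))))
})
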