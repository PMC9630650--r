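# shared feature matrix over the small classification fixture
fixture_fm <- local({
  fm <- NULL
  function() {
    if (is.null(fm)) {
      fm <<- featurize(fixture_exp1_trials(), window_spec(175, 60))
    }
    fm
  }
})

test_that("schemes define the documented class structures", {
  expect_equal(scheme_spec("SCH1")$n_classes, 4)
  expect_equal(scheme_spec("SCH2")$n_classes, 8)
  expect_equal(scheme_spec("SCH3")$levels_used, c(50, 80))
  expect_equal(scheme_spec("SCH4")$levels_used, c(20, 80))
  expect_equal(scheme_spec("SCH5")$n_classes, 12)

  fm <- fixture_fm()
  bl1 <- build_labels(fm, "SCH1")
  expect_equal(nlevels(bl1$labels), 4)
  expect_equal(nrow(bl1$fm$X), nrow(fm$X))  # SCH1 keeps every window

  bl5 <- build_labels(fm, "SCH5")
  expect_equal(nlevels(bl5$labels), 12)

  bl3 <- build_labels(fm, "SCH3")
  expect_equal(nlevels(bl3$labels), 8)
  # SCH3 drops level-20 trials: 2/3 of a balanced session remains
  expect_equal(nrow(bl3$fm$X) / nrow(fm$X), 2 / 3, tolerance = 0.01)

  fm_nolevel <- fm
  fm_nolevel$condition <- rep("triangle", length(fm$condition))
  expect_error(build_labels(fm_nolevel, "SCH2"), "level")
})

test_that("trial-wise folds never split a trial across train and test", {
  fm <- fixture_fm()
  bl <- build_labels(fm, "SCH1")
  fold <- graspemg:::trial_folds(bl$fm$trial_id, bl$labels, k = 3,
                                 seed = 4)
  # every trial has exactly one fold; windows inherit it wholesale
  per_window_fold <- fold[as.character(bl$fm$trial_id)]
  expect_true(all(tapply(per_window_fold, bl$fm$trial_id,
                         function(x) length(unique(x))) == 1))
  # stratification: every class appears in every fold
  per_trial_class <- tapply(as.character(bl$labels), bl$fm$trial_id,
                            function(x) x[1])
  tab <- table(per_trial_class, fold)
  expect_true(all(tab > 0))
})

test_that("cross-validated accuracy handles degenerate inputs", {
  fm <- fixture_fm()
  one_class <- factor(rep("pinch", nrow(fm$X)))
  expect_warning(out <- crossval_accuracy(fm, one_class, k = 3),
                 "single-class")
  expect_equal(out$mean_accuracy, 100)

  # one-hot encoding of the label is perfectly separable
  bl <- build_labels(fm, "SCH1")
  hot <- fm
  hot$X <- model.matrix(~ 0 + bl$labels)
  colnames(hot$X) <- paste0("C1_", seq_len(ncol(hot$X)))
  expect_equal(crossval_accuracy(hot, bl$labels, k = 3,
                                 seed = 2)$mean_accuracy, 100)

  # too few trials per class for the fold count
  expect_error(crossval_accuracy(fm, bl$labels, k = 10), "at least")
})

test_that("cross-validation is deterministic given the seed", {
  fm <- subset_channels(fixture_fm(), c("C2", "C4", "C5", "C7"))
  bl <- build_labels(fm, "SCH1")
  a <- crossval_accuracy(bl$fm, bl$labels, k = 3, seed = 9)
  b <- crossval_accuracy(bl$fm, bl$labels, k = 3, seed = 9)
  expect_identical(a, b)
})

test_that("channel scan aggregates satisfy their defining identities", {
  fm <- fixture_fm()
  bl <- build_labels(fm, "SCH1")
  scan <- channel_scan(bl$fm, bl$labels, sizes = c(1, 2), k = 3,
                       seed = 3, budget = 4)
  # per_size is the arithmetic mean of per_subset within each size
  for (n in c(1, 2)) {
    expect_equal(scan$per_size$mean_accuracy[scan$per_size$size == n],
                 mean(scan$per_subset$mean_accuracy[scan$per_subset$size == n]))
  }
  # budget caps each size at min(budget, choose(8, n)) subsets
  expect_equal(sum(scan$per_subset$size == 1), 4)
  expect_equal(sum(scan$per_subset$size == 2), 4)
  # IR is the first difference of per-size accuracy
  expect_equal(scan$ir$ir,
               diff(scan$per_size$mean_accuracy))

  # scan reproducibility
  scan2 <- channel_scan(bl$fm, bl$labels, sizes = c(1, 2), k = 3,
                        seed = 3, budget = 4)
  expect_identical(scan$per_subset, scan2$per_subset)
})

test_that("IR table telescopes and the scheme report lays out correctly", {
  # constructed per-size accuracies: IR2 = 30, IR3 = 5
  fake <- structure(list(
    per_subset = data.frame(size = 1:3, channels = c("C1", "C1+C2", "a"),
                            mean_accuracy = c(60, 90, 95),
                            sd_accuracy = 0),
    per_size = data.frame(size = 1:3, mean_accuracy = c(60, 90, 95)),
    ir = data.frame(size = 2:3, ir = c(30, 5)),
    budgeted = FALSE), class = "channel_scan_result")
  rep <- scheme_report(list(SCH1 = fake, SCH2 = fake))
  expect_equal(rep$ir_table$IR2, c(30, 30, 30))
  expect_equal(rep$ir_table$scheme, c("SCH1", "SCH2", "AVE"))
  # telescoping: sum of IRs spans first to last per-size accuracy
  expect_equal(sum(fake$ir$ir),
               fake$per_size$mean_accuracy[3] -
                 fake$per_size$mean_accuracy[1])
  expect_equal(nrow(rep$curves), 6)
})
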