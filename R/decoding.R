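# Movement/force classification: the five labeling schemes, trial-wise
# k-fold cross-validated SVM accuracy, exhaustive channel-subset
# scanning and the increase-of-rate (IR) analysis.

#' Classification scheme specification
#'
#' The five labeling schemes over 4 movements x 3 force levels
#' (level 1 = 20, level 2 = 50, level 3 = 80 %MVC):
#' SCH1 pools levels (4 classes); SCH2/SCH3/SCH4 pair two levels
#' (8 classes each: levels 1+2, 2+3, 1+3); SCH5 keeps all three
#' (12 classes).
#'
#' @param id `"SCH1"` .. `"SCH5"`.
#' @return List of class `scheme_spec` with `id`, `levels_used`
#'   (%MVC values; for SCH1 all levels are kept but pooled),
#'   `pool_levels`, `n_classes`.
#' @export
scheme_spec <- function(id = c("SCH1", "SCH2", "SCH3", "SCH4", "SCH5")) {
  id <- match.arg(id)
  levels_used <- switch(id,
    SCH1 = c(20, 50, 80), SCH2 = c(20, 50), SCH3 = c(50, 80),
    SCH4 = c(20, 80), SCH5 = c(20, 50, 80))
  pool <- id == "SCH1"
  n_classes <- if (pool) 4L else 4L * length(levels_used)
  structure(list(id = id, levels_used = levels_used,
                 pool_levels = pool, n_classes = n_classes),
            class = "scheme_spec")
}

#' Build per-window class labels under a scheme
#'
#' Maps each window's (movement, level) annotation to the scheme's class
#' label. Windows from levels outside the scheme are dropped. SCH1 labels
#' are the movement alone; the others use "movement_L<level>".
#'
#' @param fm A `feature_matrix` whose trials carry level annotations
#'   (experiment-1 data).
#' @param scheme A [scheme_spec()] or scheme id string.
#' @return List with `fm` (rows restricted to the scheme's levels) and
#'   `labels` (factor, one per remaining window).
#' @export
build_labels <- function(fm, scheme = "SCH1") {
  if (is.character(scheme)) scheme <- scheme_spec(scheme)
  lev <- suppressWarnings(as.numeric(fm$condition))
  if (anyNA(lev)) stop("trials lack force-level annotations")
  keep <- lev %in% scheme$levels_used
  fm$X <- fm$X[keep, , drop = FALSE]
  fm$y_force <- fm$y_force[keep]
  fm$movement <- fm$movement[keep]
  fm$condition <- fm$condition[keep]
  fm$trial_id <- fm$trial_id[keep]
  labels <- if (scheme$pool_levels) {
    factor(fm$movement, levels = movement_names())
  } else {
    factor(paste0(fm$movement, "_L", lev[keep]))
  }
  labels <- droplevels(labels)
  if (nlevels(labels) != scheme$n_classes) {
    warning("expected ", scheme$n_classes, " classes, found ",
            nlevels(labels))
  }
  list(fm = fm, labels = labels)
}

#' SVM classifier configuration
#'
#' RBF-kernel support vector machine; `gamma = NULL` scales as
#' 1 / n_features (the e1071 default).
#'
#' @param kernel,cost,gamma SVM hyperparameters.
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(kernel = "radial", cost = 1, gamma = NULL) {
  structure(list(kernel = kernel, cost = cost, gamma = gamma),
            class = "classifier_config")
}

# internal: stratified trial-level fold assignment.
# Returns fold id per trial; every class contributes trials to every fold.
trial_folds <- function(trial_id, labels, k, seed) {
  per_trial <- tapply(as.character(labels), trial_id, function(x) x[1])
  trials <- as.integer(names(per_trial))
  set.seed(seed)
  fold <- stats::setNames(integer(length(trials)), trials)
  for (cl in unique(per_trial)) {
    tr <- trials[per_trial == cl]
    if (length(tr) < k) {
      stop("class '", cl, "' has ", length(tr),
           " trials; need at least k = ", k, " for trial-wise folds")
    }
    fold[as.character(tr)] <- sample(rep_len(seq_len(k), length(tr)))
  }
  fold
}

# internal: z-scoring fit on training rows only
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd)
}
apply_scaler <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

#' Trial-wise k-fold cross-validated classification accuracy
#'
#' Folds are assigned at the trial level, stratified by class, so that
#' overlapping windows of one trial never straddle the train/test
#' boundary. Features are z-scored with statistics fitted on the
#' training folds only. Accuracy is the percentage of correctly
#' classified test windows, averaged over folds.
#'
#' @param fm A `feature_matrix`.
#' @param labels Factor of per-window class labels.
#' @param k Number of folds (default 5).
#' @param clf A [classifier_config()].
#' @param seed Integer seed (fold assignment).
#' @return List with `mean_accuracy` (%) and `fold_accuracy` (%, length
#'   k).
#' @export
crossval_accuracy <- function(fm, labels, k = 5,
                              clf = classifier_config(), seed = 1) {
  stopifnot(inherits(fm, "feature_matrix"),
            length(labels) == nrow(fm$X))
  if (nlevels(droplevels(factor(labels))) == 1) {
    warning("single-class labels: accuracy is trivially 100%")
    return(list(mean_accuracy = 100, fold_accuracy = rep(100, k)))
  }
  fold <- trial_folds(fm$trial_id, labels, k, seed)
  wfold <- fold[as.character(fm$trial_id)]
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- wfold != f
    sc <- fit_scaler(fm$X[tr, , drop = FALSE])
    Xtr <- apply_scaler(fm$X[tr, , drop = FALSE], sc)
    Xte <- apply_scaler(fm$X[!tr, , drop = FALSE], sc)
    ytr <- droplevels(factor(labels[tr]))
    if (nlevels(ytr) < nlevels(droplevels(factor(labels)))) {
      stop("a class is absent from the training folds; use more trials ",
           "or fewer folds")
    }
    fit <- e1071::svm(Xtr, ytr, kernel = clf$kernel, cost = clf$cost,
                      gamma = if (is.null(clf$gamma)) 1 / ncol(Xtr)
                              else clf$gamma, scale = FALSE)
    pred <- stats::predict(fit, Xte)
    acc[f] <- 100 * mean(as.character(pred) ==
                           as.character(labels[!tr]))
  }
  list(mean_accuracy = mean(acc), fold_accuracy = acc)
}

#' Channel-subset scan of classification accuracy
#'
#' Evaluates the cross-validated accuracy of every channel subset of
#' each requested size (or a seeded random sample of subsets when
#' `budget` is smaller than the number of combinations), then aggregates
#' per subset size and computes the increase of rate
#' IR_n = mean_acc(n) - mean_acc(n - 1).
#'
#' @param fm A `feature_matrix` over all 8 channels.
#' @param labels Per-window class labels (see [build_labels()]).
#' @param sizes Subset sizes to scan (default 1:8).
#' @param k Cross-validation folds.
#' @param clf A [classifier_config()].
#' @param seed Integer seed.
#' @param budget Max subsets per size; `NULL` = exhaustive.
#' @return List of class `channel_scan_result`: `per_subset` (data frame
#'   size / channels / mean_accuracy / sd_accuracy), `per_size` (size /
#'   mean_accuracy), `ir` (size / ir), `budgeted`.
#' @export
channel_scan <- function(fm, labels, sizes = 1:8, k = 5,
                         clf = classifier_config(), seed = 1,
                         budget = NULL) {
  stopifnot(length(fm$channels) == 8)
  rows <- list()
  for (n in sizes) {
    combs <- utils::combn(fm$channels, n, simplify = FALSE)
    budgeted <- !is.null(budget) && length(combs) > budget
    if (budgeted) {
      set.seed(derive_seed(seed, n))
      combs <- combs[sample(length(combs), budget)]
    }
    for (ch in combs) {
      sub <- subset_channels(fm, ch)
      cv <- crossval_accuracy(sub, labels, k = k, clf = clf, seed = seed)
      rows[[length(rows) + 1]] <- data.frame(
        size = n, channels = paste(ch, collapse = "+"),
        mean_accuracy = cv$mean_accuracy,
        sd_accuracy = stats::sd(cv$fold_accuracy))
    }
  }
  per_subset <- do.call(rbind, rows)
  per_size <- stats::aggregate(mean_accuracy ~ size, per_subset, mean)
  ir <- data.frame(size = per_size$size[-1],
                   ir = diff(per_size$mean_accuracy))
  structure(list(per_subset = per_subset, per_size = per_size, ir = ir,
                 budgeted = !is.null(budget)),
            class = "channel_scan_result")
}

#' Label-permutation chance control
#'
#' Shuffles trial labels (keeping windows of a trial together) and
#' recomputes the cross-validated accuracy; for balanced 4-class data
#' the mean over permutations should sit at the 25% chance level.
#'
#' @param fm A `feature_matrix`.
#' @param labels Per-window labels.
#' @param n_perm Number of permutations.
#' @param k,clf,seed As in [crossval_accuracy()].
#' @return Numeric vector of permuted accuracies (%), length `n_perm`.
#' @export
permutation_control <- function(fm, labels, n_perm = 20, k = 5,
                                clf = classifier_config(), seed = 1) {
  per_trial <- tapply(as.character(labels), fm$trial_id, function(x) x[1])
  trials <- as.integer(names(per_trial))
  out <- numeric(n_perm)
  for (p in seq_len(n_perm)) {
    set.seed(derive_seed(seed, p))
    shuffled <- stats::setNames(sample(per_trial), trials)
    lab_p <- factor(shuffled[as.character(fm$trial_id)])
    out[p] <- crossval_accuracy(fm, lab_p, k = k, clf = clf,
                                seed = derive_seed(seed, p))$mean_accuracy
  }
  out
}

#' Scheme report: accuracy curves and the IR table
#'
#' Assembles per-scheme accuracy-vs-channel-count curves and the
#' increase-of-rate table (one row per scheme, columns IR2..IR8 in %,
#' plus an AVE row of column-wise means).
#'
#' @param scans Named list of `channel_scan_result`, one per scheme
#'   (names "SCH1"..).
#' @return List with `curves` (data frame scheme / size /
#'   mean_accuracy) and `ir_table` (data frame, schemes + AVE row).
#' @export
scheme_report <- function(scans) {
  stopifnot(length(scans) >= 1, !is.null(names(scans)))
  curves <- do.call(rbind, lapply(names(scans), function(s) {
    cbind(scheme = s, scans[[s]]$per_size)
  }))
  ir_rows <- lapply(names(scans), function(s) {
    ir <- scans[[s]]$ir
    stats::setNames(as.list(ir$ir), paste0("IR", ir$size))
  })
  ir_table <- do.call(rbind, lapply(ir_rows, as.data.frame))
  ir_table <- cbind(scheme = names(scans), ir_table)
  ave <- c(scheme = "AVE",
           as.list(colMeans(ir_table[, -1, drop = FALSE])))
  ir_table <- rbind(ir_table, as.data.frame(ave))
  rownames(ir_table) <- NULL
  list(curves = curves, ir_table = ir_table)
}
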