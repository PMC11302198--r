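#' Configuration of one decision-pipeline evaluation
#'
#' Bundles the classifier, its hyperparameters, the variance-filter
#' thresholds, the PCA dimensionality rule and the Monte-Carlo
#' cross-validation settings. CV is repeated random stratified splitting:
#' `n_folds` independent 70%/30% train-test splits by default, metrics
#' averaged over repetitions.
#'
#' @param classifier One of `"LR"`, `"KNN"`, `"RF"`, `"SVM"`.
#' @param params Named list of classifier hyperparameters: LR `C` (inverse
#'   ridge regularization), KNN `k`, RF `ntree` and `maxnodes` (`NA` for
#'   unbounded), SVM `cost` and `gamma` (`"scale"` for `1/ncol`).
#' @param pca Either a fraction in (0, 1) — keep the fewest components
#'   reaching that cumulative variance — or an integer component count
#'   (capped at the training rank, with a warning).
#' @param theta_rmad,theta_riqr Variance-filter lower bounds, fitted on
#'   training rows each fold.
#' @param n_folds Number of Monte-Carlo repetitions (default 100).
#' @param test_fraction Test proportion per split (default 0.3).
#' @param stratified Stratify splits by class (default `TRUE`).
#' @param seed Base seed; fold `f` uses `seed + f`.
#' @param variant `"full"` or `"reduced"` (bookkeeping label for reports).
#' @param signal_set Bookkeeping label for reports (e.g. `"fusion"`).
#' @param split_unit `"point"` (default): each (participant, test) row is an
#'   independent data point, so a participant with several rows can appear
#'   in both partitions. `"participant"`: splits are drawn over
#'   participants, keeping all of a participant's rows on one side (requires
#'   a dataset carrying `participant_id`, see [as_pipeline_dataset()]).
#' @param filter_train Optional [iknn_config()]: apply the informative-KNN
#'   point filter to the *training* partition of every fold, instead of the
#'   default protocol of filtering the whole dataset once before
#'   cross-validation.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(classifier = c("SVM", "LR", "KNN", "RF"),
                            params = list(),
                            pca = 0.95,
                            theta_rmad = 0, theta_riqr = 0,
                            n_folds = 100L, test_fraction = 0.3,
                            stratified = TRUE, seed = 1L,
                            variant = "full", signal_set = "fusion",
                            split_unit = c("point", "participant"),
                            filter_train = NULL) {
  classifier <- match.arg(classifier)
  split_unit <- match.arg(split_unit)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop_physioscreen("invalid_parameter", "test_fraction must lie in (0, 1)")
  }
  if (n_folds < 1) stop_physioscreen("invalid_parameter", "n_folds must be >= 1")
  structure(list(classifier = classifier, params = params, pca = pca,
                 theta_rmad = theta_rmad, theta_riqr = theta_riqr,
                 n_folds = as.integer(n_folds), test_fraction = test_fraction,
                 stratified = stratified, seed = as.integer(seed),
                 variant = variant, signal_set = signal_set,
                 split_unit = split_unit, filter_train = filter_train),
            class = "pipeline_config")
}

#' Stratified random train/test split
#'
#' Allocates `round(test_fraction * n_class)` points of each class
#' (round-half-up) to the test set, uniformly at random; deterministic for
#' a given seed.
#'
#' @param labels Class labels.
#' @param test_fraction Test proportion.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return List with integer vectors `train` and `test`.
#' @export
split_stratified <- function(labels, test_fraction = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labels <- as.character(labels)
  classes <- unique(labels)
  test <- integer(0)
  for (cl in classes) {
    idx <- which(labels == cl)
    n_test <- round_half_up(test_fraction * length(idx))
    if (n_test < 1 || n_test >= length(idx)) {
      stop_physioscreen("stratification_error", sprintf(
        "class %s too small to appear in both partitions", cl))
    }
    test <- c(test, sort(sample(idx, n_test)))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(labels), test), test = test)
}

fit_classifier <- function(classifier, params, x, y) {
  y <- factor(y, levels = c("CG", "EG"))
  switch(classifier,
    LR = {
      C <- params$C %||% 1
      xx <- if (ncol(x) < 2) cbind(x, `.pad` = 0) else x
      fit <- glmnet::glmnet(xx, y, family = "binomial", alpha = 0,
                            lambda = 1 / (C * nrow(xx)))
      list(kind = "LR", fit = fit, pad = ncol(x) < 2)
    },
    KNN = list(kind = "KNN", x = x, y = y, k = params$k %||% 5),
    RF = {
      maxnodes <- params$maxnodes
      if (!is.null(maxnodes) && is.na(maxnodes)) maxnodes <- NULL
      fit <- randomForest::randomForest(x, y, ntree = params$ntree %||% 300,
                                        maxnodes = maxnodes)
      list(kind = "RF", fit = fit)
    },
    SVM = {
      gamma <- params$gamma %||% "scale"
      if (identical(gamma, "scale")) gamma <- 1 / ncol(x)
      fit <- e1071::svm(x, y, kernel = "radial",
                        cost = params$cost %||% 1, gamma = gamma,
                        scale = FALSE)
      list(kind = "SVM", fit = fit)
    }
  )
}

predict_classifier <- function(model, x) {
  out <- switch(model$kind,
    LR = {
      xx <- if (model$pad) cbind(x, `.pad` = 0) else x
      p <- stats::predict(model$fit, newx = xx, type = "response")
      ifelse(as.vector(p) > 0.5, "EG", "CG")
    },
    KNN = as.character(class::knn(model$x, x, model$y, k = model$k)),
    RF = as.character(stats::predict(model$fit, x)),
    SVM = as.character(stats::predict(model$fit, x))
  )
  factor(out, levels = c("CG", "EG"))
}

confusion_metrics <- function(truth, pred) {
  tp <- sum(truth == "EG" & pred == "EG")
  tn <- sum(truth == "CG" & pred == "CG")
  fp <- sum(truth == "CG" & pred == "EG")
  fn <- sum(truth == "EG" & pred == "CG")
  c(tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' Monte-Carlo cross-validated evaluation of one configuration
#'
#' Per repetition: draw a stratified train/test split; on the training rows
#' only, compute the rMAD/rIQR feature mask, fit per-feature
#' standardization and PCA; project both partitions; fit the classifier;
#' score the held-out partition with EG as the positive class. Fold metrics
#' are averaged into the report.
#'
#' @param dataset A `pipeline_dataset` (see [as_pipeline_dataset()]) or a
#'   list with `x` (matrix) and `y` (labels `CG`/`EG`).
#' @param config A [pipeline_config()].
#' @return Object of class `metrics_report`: `summary` (one-row
#'   `data.frame` with mean accuracy/sensitivity/specificity), `folds`
#'   (per-fold detail), `config`.
#' @export
evaluate_config <- function(dataset, config) {
  x <- as.matrix(dataset$x)
  y <- factor(as.character(dataset$y), levels = c("CG", "EG"))
  if (config$split_unit == "participant") {
    pid <- dataset$participant_id
    if (is.null(pid)) {
      stop_physioscreen("invalid_parameter",
                        "participant-level splits need participant_id")
    }
    u_pid <- unique(pid)
    u_lab <- y[match(u_pid, pid)]
  }
  folds <- vector("list", config$n_folds)
  for (f in seq_len(config$n_folds)) {
    set.seed(config$seed + f)
    sp <- if (config$split_unit == "participant") {
      psp <- if (config$stratified) {
        split_stratified(u_lab, config$test_fraction)
      } else {
        te <- sort(sample(seq_along(u_pid),
                          max(1L, round_half_up(config$test_fraction * length(u_pid)))))
        list(train = setdiff(seq_along(u_pid), te), test = te)
      }
      list(train = which(pid %in% u_pid[psp$train]),
           test = which(pid %in% u_pid[psp$test]))
    } else if (config$stratified) {
      split_stratified(y, config$test_fraction)
    } else {
      n_test <- max(1L, round_half_up(config$test_fraction * length(y)))
      te <- sort(sample(seq_along(y), n_test))
      list(train = setdiff(seq_along(y), te), test = te)
    }
    if (!is.null(config$filter_train)) {
      filt <- filter_points(x[sp$train, , drop = FALSE],
                            as.character(y[sp$train]), config$filter_train)
      sp$train <- sp$train[filt$retained]
    }
    if (length(unique(y[sp$train])) < 2) {
      message(sprintf("fold %d skipped: single-class training partition", f))
      next
    }
    xtr_raw <- x[sp$train, , drop = FALSE]
    mask <- apply_variance_thresholds(xtr_raw, config$theta_rmad,
                                      config$theta_riqr)
    xtr <- xtr_raw[, mask, drop = FALSE]
    xte <- x[sp$test, mask, drop = FALSE]
    mu <- colMeans(xtr)
    sd <- apply(xtr, 2, stats::sd)
    sd[sd == 0] <- 1
    xtr <- sweep(sweep(xtr, 2, mu), 2, sd, "/")
    xte <- sweep(sweep(xte, 2, mu), 2, sd, "/")
    pc <- stats::prcomp(xtr, center = FALSE, scale. = FALSE)
    ncomp <- n_components(pc, config$pca)
    xtr_p <- pc$x[, seq_len(ncomp), drop = FALSE]
    xte_p <- xte %*% pc$rotation[, seq_len(ncomp), drop = FALSE]
    model <- fit_classifier(config$classifier, config$params, xtr_p, y[sp$train])
    pred <- predict_classifier(model, xte_p)
    folds[[f]] <- c(fold = f, confusion_metrics(y[sp$test], pred),
                    n_components = ncomp, n_features = sum(mask))
  }
  folds <- as.data.frame(do.call(rbind, folds[!vapply(folds, is.null, logical(1))]))
  if (!nrow(folds)) stop_physioscreen("degenerate_folds", "no usable folds")
  summary <- data.frame(
    signal_set = config$signal_set, variant = config$variant,
    classifier = config$classifier,
    accuracy = mean(folds$accuracy, na.rm = TRUE),
    sensitivity = mean(folds$sensitivity, na.rm = TRUE),
    specificity = mean(folds$specificity, na.rm = TRUE),
    stringsAsFactors = FALSE
  )
  structure(list(summary = summary, folds = folds, config = config),
            class = "metrics_report")
}

n_components <- function(pc, pca) {
  rank <- sum(pc$sdev > 1e-10)
  if (pca < 1) {
    cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    max(1L, min(which(cum >= pca)))
  } else {
    ncomp <- as.integer(pca)
    if (ncomp > rank) {
      warning(sprintf("PCA components reduced from %d to train rank %d",
                      ncomp, rank))
      ncomp <- rank
    }
    max(1L, ncomp)
  }
}

#' Expert-default hyperparameter grids
#'
#' @return Named list (by classifier) of `data.frame` parameter grids.
#' @export
default_grids <- function() {
  list(
    LR = data.frame(C = c(0.01, 0.1, 1, 10)),
    KNN = data.frame(k = c(3, 5, 7, 9)),
    RF = expand.grid(ntree = c(100, 300), maxnodes = c(NA, 32)),
    SVM = expand.grid(cost = c(0.1, 1, 10), gamma = c("scale", "0.01", "0.1"),
                      stringsAsFactors = FALSE)
  )
}

#' Tune thresholds and hyperparameters by Monte-Carlo CV accuracy
#'
#' Evaluates every combination of classifier hyperparameters and
#' rMAD/rIQR thresholds (and optionally PCA rules) under identical fold
#' seeds, and returns the configuration maximizing mean test accuracy (tie:
#' first in grid order). Whether the full or the i-KNN-reduced dataset is
#' used is *not* a tuned hyperparameter; tune on each variant separately.
#' Grid points whose thresholds discard every feature are skipped.
#'
#' @param dataset A `pipeline_dataset` or `list(x =, y =)`.
#' @param classifier Classifier name.
#' @param param_grid `data.frame` of hyperparameter combinations (one row
#'   each); default from [default_grids()].
#' @param theta_grid `data.frame` with columns `theta_rmad`, `theta_riqr`.
#' @param pca_grid Numeric vector of PCA rules (fractions or counts).
#' @param ... Passed to [pipeline_config()] (e.g. `n_folds`, `seed`,
#'   `variant`, `signal_set`).
#' @return List with `best_config`, `report` (its [evaluate_config()]
#'   output) and `grid` (per-candidate mean accuracy).
#' @export
tune_and_evaluate <- function(dataset, classifier,
                              param_grid = default_grids()[[classifier]],
                              theta_grid = data.frame(theta_rmad = 0,
                                                      theta_riqr = 0),
                              pca_grid = 0.95, ...) {
  if (!nrow(param_grid) || !nrow(theta_grid) || !length(pca_grid)) {
    stop_physioscreen("invalid_grid", "empty tuning grid")
  }
  candidates <- list()
  for (p in seq_len(nrow(param_grid))) {
    for (t in seq_len(nrow(theta_grid))) {
      for (pc in pca_grid) {
        params <- as.list(param_grid[p, , drop = FALSE])
        if (!is.null(params$gamma) && params$gamma != "scale") {
          params$gamma <- as.numeric(params$gamma)
        }
        candidates[[length(candidates) + 1]] <- pipeline_config(
          classifier = classifier, params = params, pca = pc,
          theta_rmad = theta_grid$theta_rmad[t],
          theta_riqr = theta_grid$theta_riqr[t], ...)
      }
    }
  }
  acc <- rep(NA_real_, length(candidates))
  reports <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    reports[[i]] <- tryCatch(
      suppressWarnings(evaluate_config(dataset, candidates[[i]])),
      all_discarded = function(e) NULL)
    if (!is.null(reports[[i]])) acc[i] <- reports[[i]]$summary$accuracy
  }
  if (all(is.na(acc))) {
    stop_physioscreen("invalid_grid", "no tunable grid point survived")
  }
  best <- which.max(acc)
  list(best_config = candidates[[best]], report = reports[[best]],
       grid = data.frame(candidate = seq_along(acc), accuracy = acc))
}

#' Full-versus-reduced balanced-accuracy comparison
#'
#' Balanced accuracy is the mean of sensitivity and specificity. For each
#' classifier and dataset the relative change
#' `(reduced - original) / original` of balanced accuracy is computed, and
#' per classifier the mean relative change over the datasets is reported as
#' a percentage.
#'
#' @param original,reduced `data.frame`s with columns `signal_set`,
#'   `classifier`, `sensitivity`, `specificity` (percent or fractions —
#'   relative change is scale-free), covering the same
#'   (signal_set, classifier) pairs. [metrics_report] summaries, possibly
#'   row-bound over datasets, fit directly.
#' @return Object of class `comparison_report`: `detail` (per
#'   classifier/dataset balanced accuracies and relative change in
#'   percent), `mean_relative_change` (named numeric per classifier, in
#'   percent).
#' @export
balanced_accuracy_change <- function(original, reduced) {
  original <- as.data.frame(original)
  reduced <- as.data.frame(reduced)
  key <- function(d) paste(d$signal_set, d$classifier)
  if (!setequal(key(original), key(reduced)) ||
      nrow(original) != nrow(reduced)) {
    stop_physioscreen("alignment_error",
                      "reports must cover the same (dataset, classifier) pairs")
  }
  reduced <- reduced[match(key(original), key(reduced)), , drop = FALSE]
  ba <- function(d) (d$sensitivity + d$specificity) / 2
  detail <- data.frame(
    signal_set = original$signal_set, classifier = original$classifier,
    ba_original = ba(original), ba_reduced = ba(reduced),
    stringsAsFactors = FALSE
  )
  detail$relative_change_pct <-
    100 * (detail$ba_reduced - detail$ba_original) / detail$ba_original
  cls <- unique(detail$classifier)
  mrc <- vapply(cls, function(cl) {
    mean(detail$relative_change_pct[detail$classifier == cl])
  }, numeric(1))
  structure(list(detail = detail, mean_relative_change = mrc),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Mean relative change in balanced accuracy (reduced vs original):\n")
  for (cl in names(x$mean_relative_change)) {
    cat(sprintf("  %s: %+.2f%%\n", cl, x$mean_relative_change[[cl]]))
  }
  invisible(x)
}

#' @export
print.metrics_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("%s / %s / %s over %d folds: accuracy %.1f%%, sensitivity %.1f%%, specificity %.1f%%\n",
              s$signal_set, s$variant, s$classifier, nrow(x$folds),
              100 * s$accuracy, 100 * s$sensitivity, 100 * s$specificity))
  invisible(x)
}
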