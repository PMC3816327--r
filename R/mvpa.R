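#' Trial-pattern container for decoding
#'
#' Bundles single-trial beta patterns with their class labels and run
#' membership, the unit of input to the cross-validated classifier.
#'
#' @param betas Numeric matrix, trials x features (voxels).
#' @param labels Class label per trial.
#' @param run_ids Run label per trial.
#' @param task Optional task label carried through to results.
#' @return An object of class `fd_patterns`.
#' @export
trial_patterns <- function(betas, labels, run_ids, task = NA_character_) {
  betas <- as.matrix(betas)
  stopifnot(nrow(betas) == length(labels),
            nrow(betas) == length(run_ids),
            all(is.finite(betas)))
  structure(list(betas = betas, labels = as.character(labels),
                 run_ids = run_ids, task = task), class = "fd_patterns")
}

#' Fit per-feature [-1, 1] normalization parameters on training data
#'
#' Records the per-feature minimum, maximum and range of the training
#' patterns.  The implied affine map `x -> 2 (x - min) / range - 1` sends
#' the training data of every non-constant feature exactly onto [-1, 1];
#' constant features (range 0) map to 0.
#'
#' @param x Training patterns: an `fd_patterns` or a trials x features
#'   matrix.
#' @return An object of class `fd_norm`: `min`, `max`, `range` per feature.
#' @export
fit_normalizer <- function(x) {
  m <- if (inherits(x, "fd_patterns")) x$betas else as.matrix(x)
  stopifnot(nrow(m) >= 1)
  mins <- apply(m, 2, min)
  maxs <- apply(m, 2, max)
  structure(list(min = mins, max = maxs, range = maxs - mins),
            class = "fd_norm")
}

#' Apply training-derived normalization parameters
#'
#' Applies the identical affine map to new data (the test set is normalized
#' with the training parameters, never its own), so test values may fall
#' outside [-1, 1].
#'
#' @param params An `fd_norm` from [fit_normalizer()].
#' @param x An `fd_patterns` or matrix with matching feature count.
#' @return Same type as `x`, normalized.
#' @export
apply_normalizer <- function(params, x) {
  is_pat <- inherits(x, "fd_patterns")
  m <- if (is_pat) x$betas else as.matrix(x)
  if (ncol(m) != length(params$min))
    stop("feature count does not match the normalization parameters")
  scale <- ifelse(params$range > 0, 2 / params$range, 0)
  offset <- ifelse(params$range > 0, -1 - 2 * params$min / params$range, 0)
  out <- sweep(sweep(m, 2, scale, "*"), 2, offset, "+")
  if (is_pat) trial_patterns(out, x$labels, x$run_ids, x$task) else out
}

#' Sub-sampling schedule of feature-set sizes
#'
#' Default schedule: 15 strictly increasing set sizes evenly spaced from 1
#' to `min(max_features, max_size)` inclusive (rounded to integers).  With
#' 160 available features this starts at 1 and ends at 160.  When fewer
#' distinct sizes than requested are possible a shorter schedule is
#' returned with a warning.  `mode = "arithmetic"` gives the raw
#' arithmetic sequence 1, 11, 21, ... instead.
#'
#' @param max_features Number of available features (>= 1).
#' @param n_sizes Number of set sizes in the schedule.
#' @param max_size Largest set size considered.
#' @param mode `"even"` (default) or `"arithmetic"`.
#' @return Strictly increasing integer vector of set sizes.
#' @export
subsample_schedule <- function(max_features, n_sizes = 15, max_size = 160,
                               mode = c("even", "arithmetic")) {
  stopifnot(max_features >= 1, n_sizes >= 1)
  mode <- match.arg(mode)
  M <- min(max_features, max_size)
  sizes <- if (mode == "even") {
    unique(round(seq(1, M, length.out = min(n_sizes, M))))
  } else {
    unique(pmin(seq(1, max_size, by = 10), M))
  }
  if (mode == "even" && length(sizes) < n_sizes)
    warning("only ", length(sizes), " distinct set sizes available")
  sizes
}

#' Random feature subsets for sub-sampled decoding
#'
#' Draws `n_draws` independent feature subsets of the given size, each
#' without replacement, reproducibly for a fixed seed.
#'
#' @param n_features Number of available features.
#' @param size Subset size (<= `n_features`).
#' @param n_draws Number of draws, default 30.
#' @param seed Integer seed.
#' @return List of integer index vectors.
#' @export
draw_subsets <- function(n_features, size, n_draws = 30, seed = 1) {
  if (size > n_features)
    stop("'size' exceeds the number of available features")
  with_seed(seed, lapply(seq_len(n_draws), function(i)
    sample.int(n_features, size)))
}

#' Train a linear maximum-margin classifier
#'
#' Linear soft-margin SVM (libsvm via e1071) with cost C = 1 by default and
#' no internal rescaling (the decoding pipeline applies its own [-1, 1]
#' normalization).  Multi-class problems use one-vs-one voting.  Training
#' is deterministic given (x, y, cost).
#'
#' @param x Training matrix, examples x features.
#' @param y Class labels (>= 2 classes present).
#' @param cost Soft-margin cost parameter C.
#' @return An object of class `fd_svm` wrapping the fitted model.
#' @export
train_linear_classifier <- function(x, y, cost = 1) {
  y <- factor(y)
  if (nlevels(y) < 2) stop("training data contain a single class")
  x <- as.matrix(x)
  stopifnot(all(is.finite(x)))
  model <- e1071::svm(x, y, type = "C-classification", kernel = "linear",
                      cost = cost, scale = FALSE)
  structure(list(model = model, levels = levels(y), cost = cost),
            class = "fd_svm")
}

#' Predict class labels with a trained linear classifier
#' @param object An `fd_svm`.
#' @param newdata Matrix of examples x features.
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.fd_svm <- function(object, newdata, ...) {
  as.character(stats::predict(object$model, as.matrix(newdata)))
}

# one fold of LORO: returns accuracy (%) for one feature subset
.fold_accuracy <- function(train_x, train_y, test_x, test_y, test_mode,
                           cost) {
  norm <- fit_normalizer(train_x)
  model <- train_linear_classifier(apply_normalizer(norm, train_x),
                                   train_y, cost = cost)
  if (test_mode == "single_trial") {
    pred <- predict(model, apply_normalizer(norm, test_x))
    100 * mean(pred == test_y)
  } else {
    classes <- sort(unique(test_y))
    avg <- t(vapply(classes, function(cl)
      colMeans(test_x[test_y == cl, , drop = FALSE]),
      numeric(ncol(test_x))))
    pred <- predict(model, apply_normalizer(norm, avg))
    100 * mean(pred == classes)
  }
}

#' Leave-one-run-out cross-validated decoding
#'
#' One fold per run: the classifier is trained on the trials of the n - 1
#' remaining runs and tested on the held-out run, for each of the n
#' possible partitions.  Normalization parameters are fitted on the
#' training folds only and applied unchanged to the test fold.  Test
#' patterns are scored either trial by trial (`test_mode = "single_trial"`)
#' or as the per-class mean test pattern, averaged on raw betas before
#' normalization (`test_mode = "averaged"`).  With sub-sampling, accuracy
#' is averaged over the feature draws within each fold and then over folds.
#'
#' @param patterns An `fd_patterns` with at least two runs and two classes.
#' @param test_mode `"single_trial"` or `"averaged"`.
#' @param cost SVM cost parameter.
#' @param set_sizes `NULL` for the full feature set, or an integer vector
#'   of subset sizes (see [subsample_schedule()]).
#' @param n_draws Feature draws per set size, default 30.
#' @param seed Integer seed; per-fold draw seeds are derived
#'   deterministically from (seed, fold, size, draw).
#' @return An object of class `fd_decoding`: `accuracy` (% at the largest
#'   set size), `by_size` (size, accuracy), `detail` (fold x size x draw),
#'   `folds` (structural record: train/test indices and the fold's
#'   normalization parameters), `chance` (%), `n_folds`, `classes`,
#'   `test_mode`, `task`.
#' @export
loro_cv <- function(patterns, test_mode = c("single_trial", "averaged"),
                    cost = 1, set_sizes = NULL, n_draws = 30, seed = 1) {
  test_mode <- match.arg(test_mode)
  stopifnot(inherits(patterns, "fd_patterns"))
  runs <- unique(patterns$run_ids)
  if (length(runs) < 2) stop("leave-one-run-out requires at least 2 runs")
  classes <- sort(unique(patterns$labels))
  if (length(classes) < 2) stop("decoding requires at least 2 classes")
  for (r in runs) {
    present <- unique(patterns$labels[patterns$run_ids == r])
    if (!setequal(present, classes))
      warning("run ", r, " does not contain every class")
  }
  n_feat <- ncol(patterns$betas)
  sizes <- set_sizes %||% n_feat
  if (any(sizes > n_feat)) stop("set size exceeds available features")

  detail <- list()
  folds <- list()
  for (fi in seq_along(runs)) {
    r <- runs[fi]
    test_idx <- which(patterns$run_ids == r)
    train_idx <- which(patterns$run_ids != r)
    train_y <- patterns$labels[train_idx]
    if (length(unique(train_y)) < length(classes)) {
      warning("fold ", r, " skipped: a class is absent from training runs")
      next
    }
    test_y <- patterns$labels[test_idx]
    folds[[length(folds) + 1L]] <- list(
      run = r, train_index = train_idx, test_index = test_idx,
      norm = fit_normalizer(patterns$betas[train_idx, , drop = FALSE]))
    for (sz in sizes) {
      subsets <- if (is.null(set_sizes) && sz == n_feat) {
        list(seq_len(n_feat))
      } else {
        draw_subsets(n_feat, sz, n_draws,
                     seed = derive_seed(seed, fi, sz))
      }
      for (di in seq_along(subsets)) {
        cols <- subsets[[di]]
        acc <- .fold_accuracy(
          patterns$betas[train_idx, cols, drop = FALSE], train_y,
          patterns$betas[test_idx, cols, drop = FALSE], test_y,
          test_mode, cost)
        detail[[length(detail) + 1L]] <-
          data.frame(run = r, size = sz, draw = di, accuracy = acc)
      }
    }
  }
  if (!length(folds)) stop("no usable folds")
  detail <- do.call(rbind, detail)
  # average draws within fold, then folds
  per_fold <- stats::aggregate(accuracy ~ run + size, detail, mean)
  by_size <- stats::aggregate(accuracy ~ size, per_fold, mean)
  structure(list(accuracy = by_size$accuracy[which.max(by_size$size)],
                 by_size = by_size, detail = detail, folds = folds,
                 chance = 100 / length(classes),
                 n_folds = length(folds), classes = classes,
                 test_mode = test_mode, task = patterns$task),
            class = "fd_decoding")
}

#' @export
print.fd_decoding <- function(x, ...) {
  cat(sprintf(
    "LORO decoding (%s): %.2f%% over %d folds (%d classes, chance %.1f%%)\n",
    x$test_mode, x$accuracy, x$n_folds, length(x$classes), x$chance))
  invisible(x)
}

#' One-tailed group test of decoding performance against chance
#'
#' One-sample t-test (upper-tailed) of per-subject accuracies against the
#' chance level; dof = n - 1 (nine subjects give t with 8 dof).  A
#' zero-variance sample exactly at chance returns t = 0, p = 0.5.
#'
#' @param accuracies Per-subject (or per-dataset) accuracies in %.
#' @param chance Chance level in % (50 for two classes, 100/3 for three).
#' @return A list: `t`, `p` (one-tailed), `dof`, `mean`.
#' @export
group_performance_test <- function(accuracies, chance = 50) {
  accuracies <- accuracies[is.finite(accuracies)]
  n <- length(accuracies)
  if (n < 2) stop("group test requires at least 2 accuracies")
  d <- accuracies - chance
  s <- stats::sd(d)
  t <- if (s == 0) {
    if (mean(d) == 0) 0 else Inf * sign(mean(d))
  } else mean(d) / (s / sqrt(n))
  list(t = t, p = stats::pt(t, n - 1, lower.tail = FALSE), dof = n - 1,
       mean = mean(accuracies))
}

#' Null decoding accuracy from the full forward model
#'
#' Simulates one complete null dataset — six runs, two face classes with
#' identical ground-truth amplitudes (no class signal), Gaussian noise —
#' estimates single-trial betas by OLS, and runs the full leave-one-run-out
#' decoding stage (train-set normalization, linear SVM with C = 1).  Used
#' for chance calibration: averaged over many seeds the accuracy estimates
#' the empirical chance level of the whole pipeline.
#'
#' @param seed Integer seed for this dataset.
#' @param n_runs Number of runs.
#' @param trials_per_class_run Trials per class per run.
#' @param n_voxels Feature count.
#' @param sigma Noise SD (signal base amplitude is 1).
#' @param classes Two class labels.
#' @param test_mode Passed to [loro_cv()].
#' @return Decoding accuracy in % for this dataset.
#' @export
null_decoding_accuracy <- function(seed, n_runs = 6,
                                   trials_per_class_run = 20,
                                   n_voxels = 40, sigma = 1,
                                   classes = c("happy", "fear"),
                                   test_mode = "single_trial") {
  conditions <- c(classes, "baseline")
  design <- make_design(
    n_runs = n_runs,
    trials_per_condition = trials_per_class_run * n_runs,
    conditions = conditions, face_conditions = classes,
    lead_in_volumes = 5, lead_out_volumes = 5,
    seed = derive_seed(seed, 1))
  region <- region_truth(n_eye = 0, n_mouth = 0, n_rest = n_voxels,
                         n_outside = 0, seed = derive_seed(seed, 2))
  pattern <- make_pattern_truth(region, conditions = conditions,
                                tasks = unique(design$task_per_run),
                                face_conditions = classes,
                                mapping = character(0), signal = NULL,
                                seed = derive_seed(seed, 3))
  noise <- noise_model(sigma = sigma, seed = derive_seed(seed, 4))
  hrf <- double_gamma_hrf(tr = design$tr)

  betas <- list(); labels <- list(); run_ids <- list()
  for (r in seq_len(n_runs)) {
    run <- simulate_run(design, r, region, pattern, noise, hrf)
    events <- design$trials[design$trials$run == r, , drop = FALSE]
    dm <- build_single_trial_design(events, design$n_volumes[r],
                                    design$tr, hrf)
    fit <- fit_ols(dm, run)
    keep <- dm$columns$kind == "trial"
    betas[[r]] <- fit$betas[keep, , drop = FALSE]
    labels[[r]] <- dm$columns$condition[keep]
    run_ids[[r]] <- rep(r, sum(keep))
  }
  pats <- trial_patterns(do.call(rbind, betas), unlist(labels),
                         unlist(run_ids))
  loro_cv(pats, test_mode = test_mode, seed = derive_seed(seed, 5))$accuracy
}
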