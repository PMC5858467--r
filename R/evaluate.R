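#' Assemble an analysis-ready dataset from a cohort
#'
#' Runs the full preprocessing chain: quality-based trial rejection, FFT
#' band-feature extraction per trial, per-category length trimming, feature
#' selection and flattening, then aligns the questionnaire rows with the
#' surviving trials.
#'
#' @param cohort an `eeg_cohort` from [generate_cohort()], or any list with
#'   `recordings` and `labels` in the same layout (e.g. read from CSV).
#' @param bands a [band_definitions()] preset.
#' @param window_seconds FFT window length in seconds.
#' @param flatten `"mean"` (default, pools categories) or `"concat"`.
#' @param features feature columns to keep (default the eleven
#'   [default_features()]).
#' @param quality_cut,max_bad_fraction rejection filter settings
#'   (see [reject_abnormal()]).
#' @param trim_overrides optional named category -> length overrides for
#'   [trim_to_category_minimum()].
#' @return An `ad_dataset`: list with `x` (trials x features matrix), `meta`
#'   (trial metadata data frame) and `labels` (aligned label table).
#' @examples
#' cfg <- synthetic_config(n_subjects = 3, trials_per_subject = 4,
#'                         trial_duration_range = c(3, 5), seed = 2)
#' ds <- build_dataset(generate_cohort(cfg))
#' dim(ds$x)
#' @export
build_dataset <- function(cohort, bands = band_definitions(),
                          window_seconds = 1, flatten = "mean",
                          features = default_features(),
                          quality_cut = 50, max_bad_fraction = 0.1,
                          trim_overrides = NULL) {
  kept <- reject_abnormal(cohort$recordings, quality_cut = quality_cut,
                          max_bad_fraction = max_bad_fraction)
  series <- lapply(kept, extract_band_series, bands = bands,
                   window_seconds = window_seconds)
  series <- trim_to_category_minimum(series, overrides = trim_overrides)
  x <- flatten_trials(series, mode = flatten, feature_names = features)
  meta <- attr(x, "meta")
  labels <- cohort$labels[match(meta$trial_id, cohort$labels$trial_id), ,
                          drop = FALSE]
  if (anyNA(labels$trial_id)) {
    stop("label table is missing rows for surviving trials")
  }
  rownames(labels) <- NULL
  structure(list(x = x, meta = meta, labels = labels,
                 rejected_ids = attr(kept, "rejected_ids")),
            class = "ad_dataset")
}

#' @export
print.ad_dataset <- function(x, ...) {
  cat("Advertisement EEG dataset:", nrow(x$x), "trials x", ncol(x$x),
      "features,", length(unique(x$meta$subject_id)), "subjects\n")
  cat("  categories:", paste(names(table(x$meta$category)),
                             table(x$meta$category),
                             sep = "=", collapse = " "), "\n")
  invisible(x)
}

# row-subset of a dataset, keeping x/meta/labels aligned
dataset_subset <- function(dataset, idx) {
  structure(list(x = dataset$x[idx, , drop = FALSE],
                 meta = dataset$meta[idx, , drop = FALSE],
                 labels = dataset$labels[idx, , drop = FALSE],
                 rejected_ids = dataset$rejected_ids),
            class = "ad_dataset")
}

#' Confusion-matrix metrics
#'
#' Accuracy, recall, precision and F1 on the positive class:
#' recall = TP/(TP+FN), precision = TP/(TP+FP), F = 2PR/(P+R) (0 when
#' P + R = 0), accuracy = (TP+TN)/n.
#'
#' @param predicted,truth equal-length binary 0/1 vectors.
#' @return Named list with `accuracy`, `recall`, `precision`, `f_score`,
#'   `n`, and the confusion counts.
#' @examples
#' compute_metrics(c(1, 1, 1, 1, 0, 0, 0, 0, 0, 1),
#'                 c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0))
#' @export
compute_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length")
  }
  if (length(truth) < 1) stop("need at least one observation")
  predicted <- as.integer(predicted)
  truth <- as.integer(truth)
  tp <- sum(predicted == 1L & truth == 1L)
  fp <- sum(predicted == 1L & truth == 0L)
  fn <- sum(predicted == 0L & truth == 1L)
  tn <- sum(predicted == 0L & truth == 0L)
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(accuracy = (tp + tn) / length(truth),
       recall = recall, precision = precision, f_score = f,
       n = length(truth), tp = tp, fp = fp, fn = fn, tn = tn)
}

# Verify that no augmented row can reach a test set: every augmented row's
# provenance must trace to a training-fold original, and no augmented
# origin may sit in the test fold. Returns TRUE or aborts.
assert_no_leakage <- function(expanded, train_ids, test_ids) {
  origin <- attr(expanded, "origin")
  prov <- attr(expanded, "provenance")
  if (is.null(origin) || is.null(prov)) {
    stop("expanded design carries no provenance; refusing to evaluate")
  }
  aug_origin_ids <- unique(train_ids[origin[prov != "original"]])
  if (!all(aug_origin_ids %in% train_ids) ||
      any(aug_origin_ids %in% test_ids)) {
    stop("internal leakage check failed: augmented rows trace into the ",
         "test fold")
  }
  TRUE
}

# shared trainer: augment the training rows per the protocol and fit
fit_augmented <- function(x_train, y_train, spec, C) {
  boot <- gaussian_bootstrap_columns(x_train, spec)
  expanded <- combinatorial_expand(x_train, boot, spec)
  y_exp <- duplicate_labels(y_train, attr(expanded, "n_copies"), expanded)
  fit <- hinge2_svm(expanded, y_exp, C = C)
  list(fit = fit, expanded = expanded)
}

#' One in-sample evaluation run
#'
#' The canonical protocol for a single run: hold one subject out entirely
#' (untouched by this run), build the binary targets for the remaining
#' in-sample trials, split them into ratio-preserving ten folds, train on
#' folds 1--9 after Gaussian-bootstrap + combinatorial augmentation, and
#' score on fold 10. Augmented rows never enter the test fold; an internal
#' provenance assertion proves it on every run.
#'
#' @param dataset an `ad_dataset`.
#' @param scheme a [binarization_scheme()].
#' @param spec a [bootstrap_spec()]; its seed is re-derived from `seed`.
#' @param seed RNG seed for the fold shuffle and bootstrap draws.
#' @param C SVM regularization strength.
#' @param holdout_subject subject id to exclude (default: the last subject).
#' @return An `eval_report`: accuracy/recall/precision/F on the test fold,
#'   per-category test accuracies, `n_train`/`n_test` (pre-augmentation
#'   counts), the scheme, the seed, and `no_leakage = TRUE`.
#' @export
in_sample_run <- function(dataset, scheme = binarization_scheme(),
                          spec = bootstrap_spec(), seed = 1, C = 1,
                          holdout_subject = NULL) {
  stopifnot(inherits(dataset, "ad_dataset"))
  subjects <- unique(dataset$meta$subject_id)
  if (length(subjects) < 2) stop("need at least 2 subjects in-sample")
  holdout_subject <- holdout_subject %||% subjects[length(subjects)]
  in_idx <- which(dataset$meta$subject_id != holdout_subject)
  ds <- dataset_subset(dataset, in_idx)
  y <- build_targets(ds$labels, scheme)
  if (length(unique(y)) < 2L) {
    stop("binarization scheme yields a single target class in-sample")
  }
  spec$seed <- stage_seed(seed, "bootstrap")
  folds <- stratified_tenfold(y, seed = stage_seed(seed, "folds"))
  test <- folds$fold == 10L
  train_ids <- ds$meta$trial_id[!test]
  test_ids <- ds$meta$trial_id[test]

  trained <- fit_augmented(ds$x[!test, , drop = FALSE], y[!test], spec, C)
  leak_ok <- assert_no_leakage(trained$expanded, train_ids, test_ids)

  pred <- predict(trained$fit, ds$x[test, , drop = FALSE])
  metrics <- compute_metrics(pred, y[test])
  cat_test <- ds$meta$category[test]
  per_category <- vapply(sort(unique(cat_test)), function(cc) {
    mean(pred[cat_test == cc] == y[test][cat_test == cc])
  }, numeric(1))

  structure(c(metrics, list(
    per_category = per_category,
    n_train = sum(!test), n_test = sum(test),
    holdout_subject = holdout_subject,
    scheme = scheme, seed = seed, no_leakage = leak_ok
  )), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("In-sample evaluation (test fold of the stratified ten-fold)\n")
  cat(sprintf("  accuracy %.3f  recall %.3f  precision %.3f  F %.3f  (n_test = %d)\n",
              x$accuracy, x$recall, x$precision, x$f_score, x$n_test))
  if (length(x$per_category) > 0) {
    cat("  per category:",
        paste(names(x$per_category), sprintf("%.3f", x$per_category),
              sep = "=", collapse = "  "), "\n")
  }
  cat("  train/test split:", x$n_train, "/", x$n_test,
      " held-out subject:", x$holdout_subject, "\n")
  invisible(x)
}

#' Leave-one-subject-out evaluation
#'
#' For each subject in turn: train on all other subjects' trials (folds
#' 1--9 of the ratio-preserving ten-fold, augmented), then score on every
#' trial of the held-out subject. Reports the macro-average (per-subject
#' mean) of accuracy, recall and F with their dispersion, and per-category
#' mean accuracies; micro-averaging (pooling all held-out trials) is
#' available by flag.
#'
#' @inheritParams in_sample_run
#' @param micro also report micro-averaged (pooled) metrics.
#' @param permute_targets permute the targets before evaluating (label-
#'   permutation null; chance-level accuracy is the expected outcome).
#' @return A `loso_report`: `accuracy`, `recall`, `f_score` (macro means),
#'   `accuracy_sd`, `per_subject` data frame, `per_category` means, and the
#'   number of subjects evaluated.
#' @export
leave_one_subject_out <- function(dataset, scheme = binarization_scheme(),
                                  spec = bootstrap_spec(), seed = 1, C = 1,
                                  micro = FALSE, permute_targets = FALSE) {
  stopifnot(inherits(dataset, "ad_dataset"))
  subjects <- unique(dataset$meta$subject_id)
  if (length(subjects) < 3) stop("leave-one-subject-out needs >= 3 subjects")
  y_all <- build_targets(dataset$labels, scheme)
  if (permute_targets) {
    y_all <- with_seed(stage_seed(seed, "perm"), sample(y_all))
  }
  rows <- list()
  cat_rows <- list()
  pooled_pred <- integer(0)
  pooled_truth <- integer(0)
  skipped <- character(0)
  for (s in subjects) {
    out_idx <- which(dataset$meta$subject_id == s)
    if (length(out_idx) == 0L) {
      warning("subject ", s, " has zero trials; skipped")
      skipped <- c(skipped, s)
      next
    }
    in_idx <- setdiff(seq_len(nrow(dataset$x)), out_idx)
    y_in <- y_all[in_idx]
    if (length(unique(y_in)) < 2L) {
      warning("single-class training targets with subject ", s,
              " held out; skipped")
      skipped <- c(skipped, s)
      next
    }
    folds <- stratified_tenfold(y_in, seed = stage_seed(seed, "folds"))
    train <- folds$fold != 10L
    spec_s <- spec
    spec_s$seed <- stage_seed(seed, "bootstrap")
    trained <- fit_augmented(dataset$x[in_idx[train], , drop = FALSE],
                             y_in[train], spec_s, C)
    assert_no_leakage(trained$expanded,
                      dataset$meta$trial_id[in_idx[train]],
                      dataset$meta$trial_id[out_idx])
    pred <- predict(trained$fit, dataset$x[out_idx, , drop = FALSE])
    m <- compute_metrics(pred, y_all[out_idx])
    rows[[s]] <- data.frame(subject_id = s, accuracy = m$accuracy,
                            recall = m$recall, f_score = m$f_score,
                            n = m$n, stringsAsFactors = FALSE)
    pooled_pred <- c(pooled_pred, pred)
    pooled_truth <- c(pooled_truth, y_all[out_idx])
    cats <- dataset$meta$category[out_idx]
    cat_rows[[s]] <- data.frame(
      subject_id = s, category = unique(cats),
      accuracy = vapply(unique(cats), function(cc) {
        mean(pred[cats == cc] == y_all[out_idx][cats == cc])
      }, numeric(1)), stringsAsFactors = FALSE)
  }
  per_subject <- do.call(rbind, rows)
  rownames(per_subject) <- NULL
  cat_long <- do.call(rbind, cat_rows)
  per_category <- if (is.null(cat_long)) numeric(0) else {
    tapply(cat_long$accuracy, cat_long$category, mean)
  }
  out <- list(
    accuracy = mean(per_subject$accuracy),
    accuracy_sd = stats::sd(per_subject$accuracy),
    recall = mean(per_subject$recall),
    f_score = mean(per_subject$f_score),
    per_category = per_category,
    per_subject = per_subject,
    n_subjects = nrow(per_subject),
    skipped = skipped,
    scheme = scheme, seed = seed, no_leakage = TRUE
  )
  if (micro) out$micro <- compute_metrics(pooled_pred, pooled_truth)
  structure(out, class = "loso_report")
}

#' @export
print.loso_report <- function(x, ...) {
  cat("Leave-one-subject-out evaluation over", x$n_subjects, "subjects\n")
  cat(sprintf("  mean accuracy %.3f (sd %.3f)  mean recall %.3f  mean F %.3f\n",
              x$accuracy, x$accuracy_sd, x$recall, x$f_score))
  if (length(x$per_category) > 0) {
    cat("  per category:",
        paste(names(x$per_category), sprintf("%.3f", x$per_category),
              sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}

#' Accuracy over a grid of binarization thresholds
#'
#' Runs one in-sample evaluation per cell of the Cartesian threshold grid,
#' for each product category separately and for the pooled dataset. The
#' axes are named explicitly (`ranked_threshold`, `binary_threshold`,
#' `dataset_threshold`) to avoid any ambiguity about which threshold is
#' which. Degenerate cells — thresholds yielding single-class targets, or
#' category subsets too small to split — are reported as `NA`.
#'
#' @inheritParams in_sample_run
#' @param ranked_set,binary_set,dataset_set threshold grids; `binary_set`
#'   is ignored (reported as `NA`) unless `label_group` uses binary answers.
#' @param label_group `"ranked"`, `"binary"` or `"combined"`.
#' @param alpha,beta combined-group weights.
#' @return A `threshold_grid` data frame: `category` (including `"all"`),
#'   the three threshold columns, `accuracy`, `positive_rate`, `n`.
#' @export
threshold_grid_scan <- function(dataset,
                                ranked_set = c(3.5, 4, 4.5),
                                binary_set = 0.5,
                                dataset_set = c(0.4, 0.5, 0.6),
                                label_group = "ranked",
                                alpha = 0.5, beta = 0.5,
                                spec = bootstrap_spec(), seed = 1, C = 1) {
  stopifnot(inherits(dataset, "ad_dataset"))
  if (length(ranked_set) == 0 || length(dataset_set) == 0 ||
      length(binary_set) == 0) {
    stop("threshold sets must be nonempty")
  }
  use_binary <- label_group %in% c("binary", "combined")
  if (!use_binary) binary_set <- NA_real_
  cats <- c("all", sort(unique(dataset$meta$category)))
  grid <- expand.grid(category = cats, ranked_threshold = ranked_set,
                      binary_threshold = binary_set,
                      dataset_threshold = dataset_set,
                      stringsAsFactors = FALSE)
  grid$accuracy <- NA_real_
  grid$positive_rate <- NA_real_
  grid$n <- NA_integer_
  for (i in seq_len(nrow(grid))) {
    scheme <- binarization_scheme(
      label_group = label_group,
      ranked_threshold = grid$ranked_threshold[i],
      binary_threshold = if (use_binary) grid$binary_threshold[i] else 0.5,
      alpha = alpha, beta = beta,
      dataset_threshold = grid$dataset_threshold[i])
    ds <- if (grid$category[i] == "all") dataset else {
      dataset_subset(dataset,
                     which(dataset$meta$category == grid$category[i]))
    }
    grid$n[i] <- nrow(ds$x)
    grid$positive_rate[i] <- tryCatch(
      attr(build_targets(ds$labels, scheme), "positive_rate"),
      error = function(e) NA_real_)
    rep <- tryCatch(
      in_sample_run(ds, scheme, spec = spec, seed = seed, C = C),
      error = function(e) NULL)
    if (!is.null(rep)) grid$accuracy[i] <- rep$accuracy
  }
  structure(grid, class = c("threshold_grid", "data.frame"))
}

#' Cross-validated learning curve
#'
#' Diagnoses over/under-fitting: for increasing training-set sizes, fits on
#' a stratified subsample of each cross-validation training split and
#' scores both that subsample (training score) and the held-out fold (test
#' score). Sizes count pre-augmentation rows; when a `spec` is supplied the
#' training subsample is augmented before fitting, exactly as in
#' [in_sample_run()]. Bands for plotting are mean +- one standard deviation
#' across folds.
#'
#' @inheritParams in_sample_run
#' @param sizes increasing training fractions in (0, 1] of each training
#'   split; sizes leaving fewer than one trial per class are skipped with a
#'   warning.
#' @param n_folds number of stratified folds.
#' @param spec optional [bootstrap_spec()]; `NULL` (default) trains on the
#'   raw subsample.
#' @return A `learning_curve` data frame: `train_size`, `train_mean`,
#'   `train_std`, `test_mean`, `test_std`.
#' @export
learning_curve <- function(dataset, scheme = binarization_scheme(),
                           sizes = seq(0.2, 1, by = 0.2), n_folds = 10,
                           spec = NULL, seed = 1, C = 1) {
  stopifnot(inherits(dataset, "ad_dataset"))
  if (is.unsorted(sizes, strictly = TRUE)) {
    stop("sizes must be strictly increasing")
  }
  if (any(sizes <= 0 | sizes > 1)) stop("sizes must lie in (0, 1]")
  y <- build_targets(dataset$labels, scheme)
  if (length(unique(y)) < 2L) {
    stop("binarization scheme yields a single target class")
  }
  folds <- stratified_kfold(y, k = n_folds,
                            seed = stage_seed(seed, "folds"))
  scores <- array(NA_real_, dim = c(length(sizes), n_folds, 2))
  n_at_size <- integer(length(sizes))
  for (f in seq_len(n_folds)) {
    test <- folds$fold == f
    pool <- which(!test)
    # stratified-shuffled pool so every prefix keeps the class ratio
    ord <- with_seed(stage_seed(seed, "curve") + f, {
      p1 <- sample(pool[y[pool] == 1L])
      p0 <- sample(pool[y[pool] == 0L])
      n1 <- length(p1)
      n0 <- length(p0)
      # interleave the two classes proportionally so every prefix is mixed
      take <- order(c((seq_len(n1) - 0.5) / n1, (seq_len(n0) - 0.5) / n0))
      c(p1, p0)[take]
    })
    for (si in seq_along(sizes)) {
      m <- floor(sizes[si] * length(ord))
      sub <- ord[seq_len(m)]
      n_at_size[si] <- m
      if (length(unique(y[sub])) < 2L) next  # skipped: one class only
      x_sub <- dataset$x[sub, , drop = FALSE]
      y_sub <- y[sub]
      fit <- if (is.null(spec)) {
        hinge2_svm(x_sub, y_sub, C = C)
      } else {
        spec_f <- spec
        spec_f$seed <- stage_seed(seed, "bootstrap") + f
        fit_augmented(x_sub, y_sub, spec_f, C)$fit
      }
      scores[si, f, 1] <- mean(predict(fit, x_sub) == y_sub)
      scores[si, f, 2] <-
        mean(predict(fit, dataset$x[test, , drop = FALSE]) == y[test])
    }
  }
  tr <- matrix(scores[, , 1], nrow = length(sizes))
  te <- matrix(scores[, , 2], nrow = length(sizes))
  ok <- rowSums(!is.na(tr)) > 0
  if (!all(ok)) {
    warning("skipped ", sum(!ok),
            " size(s) with single-class training subsamples")
  }
  row_sd <- function(m) apply(m, 1, function(v) stats::sd(v, na.rm = TRUE))
  out <- data.frame(
    train_size = n_at_size[ok],
    train_mean = rowMeans(tr, na.rm = TRUE)[ok],
    train_std = row_sd(tr)[ok],
    test_mean = rowMeans(te, na.rm = TRUE)[ok],
    test_std = row_sd(te)[ok])
  structure(out, class = c("learning_curve", "data.frame"))
}

#' @export
print.learning_curve <- function(x, ...) {
  cat("Cross-validated learning curve (", nrow(x), " sizes)\n", sep = "")
  print.data.frame(cbind(x[1], round(x[-1], 4)), row.names = FALSE)
  invisible(x)
}

#' @describeIn learning_curve Plot train (red) and test (green) score
#'   trajectories with mean +- sd bands.
#' @param x a `learning_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.learning_curve <- function(x, ...) {
  rng <- range(c(x$train_mean - x$train_std, x$test_mean + x$test_std,
                 x$test_mean - x$test_std), na.rm = TRUE)
  graphics::plot(x$train_size, x$train_mean, type = "n", ylim = rng,
                 xlab = "training examples", ylab = "accuracy", ...)
  band <- function(m, s, col) {
    graphics::polygon(c(x$train_size, rev(x$train_size)),
                      c(m - s, rev(m + s)), border = NA, col = col)
  }
  band(x$train_mean, x$train_std, grDevices::adjustcolor("red", 0.2))
  band(x$test_mean, x$test_std, grDevices::adjustcolor("darkgreen", 0.2))
  graphics::lines(x$train_size, x$train_mean, col = "red", lwd = 2)
  graphics::lines(x$train_size, x$test_mean, col = "darkgreen", lwd = 2)
  graphics::legend("bottomright", legend = c("training", "testing"),
                   col = c("red", "darkgreen"), lwd = 2, bty = "n")
  invisible(x)
}
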