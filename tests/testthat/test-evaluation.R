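test_that("confusion metrics match hand-computed counts", {
  # TP=3, FP=1, FN=2, TN=4
  pred <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  truth <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  m <- compute_metrics(pred, truth)
  expect_equal(m$accuracy, 0.7)
  expect_equal(m$recall, 0.6)
  expect_equal(m$precision, 0.75)
  expect_equal(m$f_score, 2 * 0.75 * 0.6 / (0.75 + 0.6))
  expect_equal(c(m$tp, m$fp, m$fn, m$tn), c(3, 1, 2, 4))

  perfect <- compute_metrics(truth, truth)
  expect_equal(c(perfect$accuracy, perfect$recall, perfect$f_score),
               c(1, 1, 1))

  allneg <- compute_metrics(rep(0, 10), truth)
  expect_equal(allneg$recall, 0)
  expect_equal(allneg$f_score, 0)
  expect_error(compute_metrics(1, c(1, 0)), "equal length")
})

test_that("in-sample run keeps partition bookkeeping and proves no leakage", {
  ds <- medium_dataset()
  rep <- in_sample_run(ds, seed = 3)
  n_insample <- sum(ds$meta$subject_id != rep$holdout_subject)
  expect_equal(rep$n_train + rep$n_test, n_insample)
  expect_true(rep$no_leakage)
  expect_true(rep$accuracy >= 0 && rep$accuracy <= 1)
  expect_true(all(rep$per_category >= 0 & rep$per_category <= 1))

  # deterministic under the same seed
  rep2 <- in_sample_run(ds, seed = 3)
  expect_equal(rep2$accuracy, rep$accuracy)
})

test_that("the leakage assertion detects augmented rows in a test fold", {
  expanded <- matrix(0, 6, 2)
  attr(expanded, "origin") <- c(1:3, 1:3)
  attr(expanded, "provenance") <- rep(c("original", "boot:r=1:cols=1"),
                                      each = 3)
  expect_true(adimpact:::assert_no_leakage(expanded,
                                           train_ids = c("a", "b", "c"),
                                           test_ids = c("d", "e")))
  # an augmented origin sitting in the test set must abort
  expect_error(adimpact:::assert_no_leakage(expanded,
                                            train_ids = c("a", "b", "d"),
                                            test_ids = c("d", "e")),
               "leakage")
  # missing provenance is never silently accepted
  expect_error(adimpact:::assert_no_leakage(matrix(0, 2, 2), "a", "b"),
               "provenance")
})

test_that("leave-one-subject-out macro-averages per-subject reports", {
  ds <- medium_dataset()
  lo <- leave_one_subject_out(ds, seed = 2)
  expect_equal(lo$n_subjects, 8)
  expect_equal(nrow(lo$per_subject), 8)
  expect_lte(lo$accuracy, max(lo$per_subject$accuracy))
  expect_gte(lo$accuracy, min(lo$per_subject$accuracy))
  expect_true(all(names(lo$per_category) %in%
                    unique(ds$meta$category)))

  lo_micro <- leave_one_subject_out(ds, seed = 2, micro = TRUE)
  expect_equal(lo_micro$micro$n, nrow(ds$x))
})

test_that("cloned subjects score identically under LOSO", {
  ds <- medium_dataset()
  # clone a subject whose own trials carry both classes comfortably
  y <- build_targets(ds$labels, binarization_scheme())
  balance <- tapply(y, ds$meta$subject_id, function(v) min(sum(v), sum(!v)))
  donor <- names(balance)[which.max(balance)]
  one <- which(ds$meta$subject_id == donor)
  idx <- rep(one, 4)
  cloned <- adimpact:::dataset_subset(ds, idx)
  cloned$meta$subject_id <- rep(paste0("C", 1:4), each = length(one))
  cloned$meta$trial_id <- sprintf("T%03d", seq_along(idx))
  cloned$labels$trial_id <- cloned$meta$trial_id
  lo <- leave_one_subject_out(cloned, seed = 1)
  expect_equal(stats::sd(lo$per_subject$accuracy), 0)
})

test_that("label permutation collapses accuracy to chance", {
  ds <- medium_dataset()
  accs <- vapply(1:5, function(s) {
    leave_one_subject_out(ds, seed = s, permute_targets = TRUE)$accuracy
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("LOSO accuracy increases with the planted coupling strength", {
  accs <- vapply(c(0, 0.4, 1.5), function(eff) {
    cfg <- synthetic_config(n_subjects = 8, trials_per_subject = 10,
                            trial_duration_range = c(3, 5),
                            effect_size = eff, label_noise = 0.02,
                            seed = 23)
    ds <- suppressMessages(build_dataset(generate_cohort(cfg)))
    leave_one_subject_out(ds, seed = 1)$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) > -0.05))  # non-decreasing up to noise
  expect_lt(accs[1], 0.65)
  expect_gt(accs[3], 0.85)
})

test_that("threshold grid scan covers categories and marks degenerate cells", {
  ds <- medium_dataset()
  grid <- threshold_grid_scan(ds, ranked_set = c(4, 7.5),
                              dataset_set = c(0, 0.5),
                              label_group = "ranked", seed = 1)
  cats <- c("all", sort(unique(ds$meta$category)))
  expect_equal(nrow(grid), length(cats) * 2 * 2)
  # dataset threshold 0 makes every target positive: single class -> NA
  expect_true(all(is.na(grid$accuracy[grid$dataset_threshold == 0])))
  expect_true(all(grid$positive_rate[grid$dataset_threshold == 0] == 1,
                  na.rm = TRUE))
  # the pooled rows at a workable threshold are computed
  pooled <- grid$category == "all" & grid$dataset_threshold == 0.5 &
    grid$ranked_threshold == 4
  expect_false(any(is.na(grid$accuracy[pooled])))
  # a ranked threshold above the scale: nobody positive -> NA
  expect_true(all(is.na(grid$accuracy[grid$ranked_threshold == 7.5 &
                                        grid$dataset_threshold == 0.5])))
})

test_that("learning curve is well-formed and learns on a strong cohort", {
  ds <- medium_dataset()
  lc <- learning_curve(ds, sizes = c(0.3, 0.6, 1), n_folds = 5, seed = 4)
  expect_s3_class(lc, "learning_curve")
  expect_true(all(diff(lc$train_size) > 0))
  expect_true(all(lc$train_std >= 0 & lc$test_std >= 0))
  expect_gt(lc$test_mean[nrow(lc)], 0.6)
  expect_error(learning_curve(ds, sizes = c(0.5, 0.4)), "increasing")
})
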