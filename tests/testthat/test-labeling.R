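test_that("per-answer binarization follows the >= boundary convention", {
  expect_equal(binarize_ranked(5, 4), 1L)
  expect_equal(binarize_ranked(3, 3.5), 0L)
  expect_equal(binarize_ranked(4, 4), 1L)  # midpoint stays positive
  expect_equal(binarize_ranked(c(1, 4, 7), 4.5), c(0L, 0L, 1L))
  expect_error(binarize_ranked(8, 4), "1..7")
  expect_error(binarize_ranked(0, 4), "1..7")

  expect_equal(binarize_binary(1, 0.5), 1L)
  expect_equal(binarize_binary(0, 0.5), 0L)
  expect_equal(binarize_binary(0, 0), 1L)  # threshold 0 admits everything
  expect_error(binarize_binary(2, 0.5), "0 or 1")

  # idempotence on already-binary data at the canonical threshold
  v <- c(0, 1, 1, 0)
  expect_equal(binarize_binary(binarize_binary(v, 0.5), 0.5),
               binarize_binary(v, 0.5))
})

test_that("combined scheme threshold is the weighted scalar", {
  sch <- binarization_scheme("combined", ranked_threshold = 4,
                             binary_threshold = 0.4)
  expect_equal(combined_threshold(sch), 2.2)
  sch2 <- binarization_scheme("combined", ranked_threshold = 4,
                              binary_threshold = 1)
  expect_equal(combined_threshold(sch2), 2.5)
  sch3 <- binarization_scheme("combined", ranked_threshold = 4,
                              binary_threshold = 0.4, alpha = 1, beta = 0)
  expect_equal(combined_threshold(sch3), 4)
  expect_error(binarization_scheme("combined", alpha = 0.7, beta = 0.5),
               "alpha \\+ beta")
})

test_that("row aggregation thresholds the mean of binarized answers", {
  sch <- binarization_scheme(dataset_threshold = 0.4)
  expect_equal(aggregate_target(label_row(rep(7, 11), rep(0, 11)), sch), 1L)
  expect_equal(aggregate_target(label_row(rep(1, 11), rep(0, 11)), sch), 0L)
  # 4 of 11 ranked answers over threshold: 4/11 < 0.4
  row <- label_row(c(7, 7, 7, 7, 1, 1, 1, 1, 1, 1, 1), rep(0, 11))
  expect_equal(aggregate_target(row, sch), 0L)
  # 5 of 11 = 0.4545 >= 0.4
  row5 <- label_row(c(7, 7, 7, 7, 7, 1, 1, 1, 1, 1, 1), rep(0, 11))
  expect_equal(aggregate_target(row5, sch), 1L)

  # single-label group reads one item
  s9 <- binarization_scheme("single:Y9", dataset_threshold = 0.5)
  expect_equal(aggregate_target(label_row(c(rep(1, 8), 6, 1, 1),
                                          rep(0, 11)), s9), 1L)
  expect_error(binarization_scheme("single:Y23"), "Y1..Y22")
})

test_that("aggregation is permutation-invariant within answer groups", {
  sch <- binarization_scheme("combined", ranked_threshold = 4,
                             binary_threshold = 0.5,
                             dataset_threshold = 0.4)
  tbl <- random_label_table(50, seed = 7)
  y <- build_targets(tbl, sch)
  perm <- with_seed_local(8, {
    tbl2 <- tbl
    tbl2[, paste0("Y", 1:11)] <- tbl[, paste0("Y", sample(1:11))]
    tbl2[, paste0("Y", 12:22)] <- tbl[, paste0("Y", sample(12:22))]
    tbl2
  })
  expect_equal(build_targets(perm, sch), y, ignore_attr = TRUE)
})

test_that("positive counts are monotone non-increasing in every threshold", {
  for (s in 1:5) {
    tbl <- random_label_table(80, seed = s)
    # ranked threshold axis
    pos_r <- vapply(c(1, 3.5, 4, 4.5, 7.5), function(th) {
      sum(build_targets(tbl, binarization_scheme(
        "combined", ranked_threshold = th, binary_threshold = 0.5,
        dataset_threshold = 0.4)))
    }, numeric(1))
    expect_true(all(diff(pos_r) <= 0))
    # binary threshold axis
    pos_b <- vapply(c(0, 0.4, 0.5, 1, 1.5), function(th) {
      sum(build_targets(tbl, binarization_scheme(
        "combined", ranked_threshold = 4, binary_threshold = th,
        dataset_threshold = 0.4)))
    }, numeric(1))
    expect_true(all(diff(pos_b) <= 0))
    # dataset threshold axis
    pos_d <- vapply(c(0, 0.4, 0.5, 0.6, 1.01), function(th) {
      sum(build_targets(tbl, binarization_scheme(
        "combined", ranked_threshold = 4, binary_threshold = 0.5,
        dataset_threshold = th)))
    }, numeric(1))
    expect_true(all(diff(pos_d) <= 0))
    # degenerate ends
    expect_equal(pos_d[1], 80)  # dataset threshold 0: everything positive
  }
})

test_that("label tables are validated with row/column locations", {
  tbl <- random_label_table(10, seed = 2)
  tbl$Y3[4] <- 9
  expect_error(build_targets(tbl, binarization_scheme()), "Y3.*row 4")
  tbl2 <- random_label_table(10, seed = 2)
  tbl2$Y15[2] <- 0.5
  expect_error(build_targets(tbl2, binarization_scheme()), "Y15.*row 2")
})
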