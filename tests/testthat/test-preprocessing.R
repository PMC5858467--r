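test_that("a pure tone concentrates its band power in the right band", {
  rec <- generate_sinusoid_recording(10, 1, 4, 512)
  bs <- extract_band_series(rec)
  bands <- c("Delta", "Theta", "LowAlpha", "HighAlpha",
             "LowBeta", "HighBeta", "LowGamma", "HighGamma")
  total <- rowSums(bs$data[, bands])
  expect_true(all(bs$data$HighAlpha / total >= 0.9))
  # Raw is the window-mean voltage: ~0 for a whole number of cycles
  expect_true(all(abs(bs$data$Raw) < 1e-10))
  expect_equal(bs$data$TimeStamp, 1:4)
})

test_that("band powers are non-negative, additive and Parseval-consistent", {
  set.seed(3)
  x <- rnorm(512)
  sp <- adimpact:::window_power_spectrum(x, 512)
  expect_equal(sum(sp$power), sum(x^2), tolerance = 1e-6)
  expect_true(all(sp$power >= 0))

  rec <- adimpact:::new_raw_recording("t", "s", "a", "car", 512,
                                      x, rep(0L, 512))
  bs <- extract_band_series(rec)
  # additivity over the disjoint adjacent Beta bands
  expect_equal(bs$data$LowBeta + bs$data$HighBeta,
               sum(sp$power[sp$freq >= 12 & sp$freq < 18]))
})

test_that("zero voltage yields exactly zero band powers", {
  rec <- generate_sinusoid_recording(10, 0, 2, 512)
  bs <- extract_band_series(rec)
  bands <- c("Delta", "Theta", "LowAlpha", "HighAlpha",
             "LowBeta", "HighBeta", "LowGamma", "HighGamma")
  expect_true(all(as.matrix(bs$data[, bands]) == 0))
})

test_that("band extraction is translation-covariant over whole windows", {
  set.seed(11)
  x <- rnorm(2 * 512)
  pad <- rnorm(512)
  r1 <- adimpact:::new_raw_recording("t1", "s", "a", "car", 512,
                                     x, rep(0L, length(x)))
  r2 <- adimpact:::new_raw_recording("t2", "s", "a", "car", 512,
                                     c(pad, x), rep(0L, length(x) + 512))
  bands <- c("Delta", "Theta", "LowAlpha", "HighAlpha",
             "LowBeta", "HighBeta", "LowGamma", "HighGamma")
  b1 <- as.matrix(extract_band_series(r1)$data[, bands])
  b2 <- as.matrix(extract_band_series(r2)$data[, bands])
  expect_equal(b1, b2[2:3, , drop = FALSE], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("too-short recordings and tiny windows are rejected", {
  rec <- generate_sinusoid_recording(10, 1, 0.5, 512)
  expect_error(extract_band_series(rec, window_seconds = 1), "shorter")
  expect_error(extract_band_series(rec, window_seconds = 1 / 512), "2 samples")
})

test_that("quality rejection drops exactly the over-threshold trials", {
  good <- generate_sinusoid_recording(10, 1, 2, 512)
  bad <- adimpact:::new_raw_recording("bad", "s", "a", "car", 512,
                                      rnorm(1024),
                                      rep(c(200L, 0L), c(200, 824)))
  kept <- suppressMessages(reject_abnormal(list(good, bad)))
  expect_length(kept, 1)
  expect_equal(attr(kept, "rejected_ids"), "bad")
  # max_bad_fraction = 1 disables rejection
  expect_length(reject_abnormal(list(good, bad), max_bad_fraction = 1), 2)
  expect_error(suppressMessages(reject_abnormal(list(bad))), "all 1 trials")
})

make_series <- function(id, category, len, value = 1) {
  rec <- generate_sinusoid_recording(10, 1, len, 512)
  s <- extract_band_series(rec)
  s$trial_id <- id
  s$category <- category
  s$subject_id <- "S1"
  s$ad_id <- paste0(category, "_ad")
  s$data <- s$data[seq_len(len), , drop = FALSE]
  s
}

test_that("category trimming cuts to the minimum and is idempotent", {
  series <- list(make_series("a", "car", 24), make_series("b", "car", 30),
                 make_series("c", "car", 27), make_series("d", "food", 16))
  trimmed <- trim_to_category_minimum(series)
  lens <- vapply(trimmed, function(s) nrow(s$data), integer(1))
  expect_equal(lens, c(24L, 24L, 24L, 16L))
  expect_equal(trim_to_category_minimum(trimmed), trimmed)

  # explicit overrides are applied verbatim
  ov <- trim_to_category_minimum(series, c(car = 20, food = 13))
  expect_equal(vapply(ov, function(s) nrow(s$data), integer(1)),
               c(20L, 20L, 20L, 13L))
  expect_error(trim_to_category_minimum(series, c(car = 28)),
               "exceeds the length of trial a")
})

test_that("feature selection enforces the modeling column set", {
  s <- make_series("a", "car", 4)
  expect_equal(ncol(select_features(s)$data), 11)
  expect_named(select_features(s, "Theta")$data, "Theta")
  expect_error(select_features(s, c("Theta", "TimeStamp")), "TimeStamp")
  expect_error(select_features(s, "NotAColumn"), "valid features")
})

test_that("flattening produces the expected shapes in both modes", {
  series <- list(make_series("a", "car", 6), make_series("b", "car", 8),
                 make_series("c", "food", 5))
  trimmed <- trim_to_category_minimum(series)
  x <- flatten_trials(trimmed, mode = "mean")
  expect_equal(dim(x), c(3L, 11L))
  expect_equal(attr(x, "meta")$trial_id, c("a", "b", "c"))
  # a constant column means to itself
  expect_equal(unname(x["a", "Theta"]), mean(trimmed[[1]]$data$Theta))

  car_only <- trimmed[1:2]
  xc <- flatten_trials(car_only, mode = "concat")
  expect_equal(dim(xc), c(2L, 6L * 11L))
  expect_error(flatten_trials(trimmed, mode = "concat"), "pool")
  expect_error(flatten_trials(series, mode = "mean"), "trimmed")
})
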