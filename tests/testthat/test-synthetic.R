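test_that("cohort generation is deterministic and structurally complete", {
  cfg <- small_config()
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  n <- sum(cfg$trials_per_subject)
  expect_length(a$recordings, n)
  expect_equal(nrow(a$labels), n)
  expect_equal(nrow(a$emotion), n)
  expect_setequal(a$labels$trial_id, a$emotion$trial_id)

  # answers respect the questionnaire ranges
  for (j in 1:11) expect_true(all(a$labels[[paste0("Y", j)]] %in% 1:7))
  for (j in 12:22) expect_true(all(a$labels[[paste0("Y", j)]] %in% 0:1))

  # a different seed changes the draw
  expect_false(identical(a$emotion$e,
                         generate_cohort(small_config(seed = 43))$emotion$e))
})

test_that("sinusoid fixture is an exact sampled sine with perfect quality", {
  rec <- generate_sinusoid_recording(10, amplitude = 1, duration = 4,
                                     sample_rate = 512)
  expect_length(rec$voltage, 2048)
  t <- (0:2047) / 512
  expect_equal(rec$voltage, sin(2 * pi * 10 * t))
  expect_true(all(rec$quality == 0))

  expect_silent(generate_sinusoid_recording(0.5, 1, 2, 512))
  expect_error(generate_sinusoid_recording(300, 1, 2, 512), "Nyquist")
  expect_error(generate_sinusoid_recording(256, 1, 2, 512), "Nyquist")
})

test_that("planted abnormal trials are exactly those the filter rejects", {
  cfg <- synthetic_config(n_subjects = 4, trials_per_subject = 6,
                          trial_duration_range = c(3, 4),
                          rejection_rate = 4 / 24, seed = 5)
  co <- generate_cohort(cfg)
  expect_length(co$planted_abnormal, 4)
  kept <- suppressMessages(reject_abnormal(co$recordings))
  expect_setequal(attr(kept, "rejected_ids"), co$planted_abnormal)
  expect_length(kept, 20)
})

test_that("zero surviving trials is an explicit failure naming the rate", {
  # rejection_rate close to 1 is rejected at construction
  expect_error(synthetic_config(rejection_rate = 1), "rejection_rate")
})

test_that("emotion-linked band power rises monotonically with latent e", {
  cfg <- synthetic_config(n_subjects = 4, trials_per_subject = 100,
                          trial_duration_range = c(2, 3),
                          effect_size = 1, seed = 17)
  co <- generate_cohort(cfg)
  ds <- suppressMessages(build_dataset(co))
  e <- co$emotion$e[match(ds$meta$trial_id, co$emotion$trial_id)]
  quint <- cut(e, stats::quantile(e, probs = seq(0, 1, 0.2)),
               include.lowest = TRUE, labels = FALSE)
  for (band in c("Theta", "LowBeta", "HighBeta")) {
    m <- tapply(ds$x[, band], quint, mean)
    expect_true(all(diff(m) > 0),
                info = paste("quintile means of", band))
  }
  # an unlinked band carries no trend of comparable size
  delta_m <- tapply(ds$x[, "Delta"], quint, mean)
  theta_m <- tapply(ds$x[, "Theta"], quint, mean)
  expect_lt(abs(delta_m[[5]] - delta_m[[1]]),
            (theta_m[[5]] - theta_m[[1]]) / 4)
})

test_that("aggregated target balance tracks the requested proportion", {
  for (bal in c(0.3, 0.5, 0.7)) {
    cfg <- synthetic_config(n_subjects = 10, trials_per_subject = 300,
                            target_balance = bal, seed = 8)
    co <- generate_cohort(cfg, signals = FALSE)
    y <- build_targets(co$labels, binarization_scheme())
    expect_lt(abs(attr(y, "positive_rate") - bal), 0.05)
  }
})

test_that("Bayes oracle hits its limiting values and is reproducible", {
  # noiseless limit: the target is deterministic in e
  expect_gt(planted_bayes_accuracy(synthetic_config(label_noise = 0),
                                   n_mc = 2e4), 0.99)
  # pure-noise limit: binary answers flipped with probability 1/2
  sch <- binarization_scheme("binary", dataset_threshold = 0.5)
  expect_lt(abs(planted_bayes_accuracy(synthetic_config(label_noise = 0.5),
                                       sch, n_mc = 2e4) - 0.5), 0.02)
  # intermediate: strictly between chance and certainty, stable across seeds
  cfg <- synthetic_config(label_noise = 0.2)
  a <- planted_bayes_accuracy(cfg, n_mc = 1e5, seed = 1)
  b <- planted_bayes_accuracy(cfg, n_mc = 1e5, seed = 2)
  expect_gt(a, 0.5)
  expect_lt(a, 1)
  expect_lt(abs(a - b), 0.01)
  expect_error(planted_bayes_accuracy(cfg, n_mc = 10), "n_mc")
})

test_that("oracle agrees with brute-force label simulation on a tiny config", {
  # independent route: simulate full label tables and classify by the
  # majority target at each latent value bin
  cfg <- synthetic_config(n_subjects = 10, trials_per_subject = 2000,
                          label_noise = 0.2, seed = 31)
  sch <- binarization_scheme()
  co <- generate_cohort(cfg, signals = FALSE)
  y <- build_targets(co$labels, sch)
  e <- co$emotion$e
  # empirical best rule: predict the majority class within narrow e bins
  bins <- cut(e, breaks = stats::quantile(e, seq(0, 1, 0.02)),
              include.lowest = TRUE, labels = FALSE)
  emp <- mean(unlist(lapply(split(y, bins), function(v) {
    pmax(mean(v), 1 - mean(v))
  })[as.character(bins)] ))
  expect_lt(abs(emp - planted_bayes_accuracy(cfg, sch, n_mc = 1e5)), 0.03)
})
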