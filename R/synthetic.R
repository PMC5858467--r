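#' Configuration for the synthetic advertisement-viewing cohort
#'
#' Collects every knob of the generator in one validated object. The defaults
#' emulate the study design the pipeline targets: 30 subjects, 15 trials each
#' (450 trials), four product categories, single-channel EEG at 512 Hz,
#' ad durations such that per-category minimum lengths land at the canonical
#' 24/13/28/16 one-second timestamps.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param trials_per_subject trials per subject; a single count or a vector of
#'   length `n_subjects` (>= 1 each).
#' @param categories named integer vector: ads available per category.
#' @param sample_rate sampling rate in Hz.
#' @param trial_duration_range ad duration ranges in whole seconds: either a
#'   length-2 vector applied to every category or a named list of length-2
#'   vectors, one per category. Each ad gets a fixed duration; trials of the
#'   same ad share it.
#' @param effect_size dimensionless coupling strength between the latent
#'   per-trial emotion and the emotion-linked band amplitudes (Theta and the
#'   two Beta bands). 0 decouples EEG from the questionnaire entirely.
#' @param label_noise probability in \[0, 1\] that an individual questionnaire
#'   answer is perturbed (ranked answers redrawn uniformly from 1..7, binary
#'   answers flipped).
#' @param rejection_rate probability in \[0, 1) that a trial is planted as
#'   voltage-abnormal (amplitude clipping plus bad quality flags); the
#'   planted count is `round(rejection_rate * n_trials)` exactly.
#' @param target_balance requested positive-class proportion of the
#'   aggregated questionnaire target under the default binarization scheme.
#' @param noise_sd standard deviation of the additive white measurement noise
#'   on the voltage trace, in the same arbitrary microvolt-like units as the
#'   band amplitudes.
#' @param seed RNG seed; identical config + seed gives identical cohorts.
#' @return A `synthetic_config` object (a validated list).
#' @seealso [generate_cohort()], [planted_bayes_accuracy()]
#' @examples
#' cfg <- synthetic_config(n_subjects = 4, trials_per_subject = 3,
#'                         trial_duration_range = c(3, 5), seed = 1)
#' cfg
#' @export
synthetic_config <- function(n_subjects = 30,
                             trials_per_subject = 15,
                             categories = c(car = 55, clothing = 55,
                                            digital = 55, food = 55),
                             sample_rate = 512,
                             trial_duration_range = list(
                               car = c(24, 30), clothing = c(13, 20),
                               digital = c(28, 34), food = c(16, 22)),
                             effect_size = 1,
                             label_noise = 0.05,
                             rejection_rate = 0,
                             target_balance = 0.5,
                             noise_sd = 2,
                             seed = 1) {
  if (n_subjects < 2) stop("n_subjects must be >= 2")
  if (length(trials_per_subject) == 1L) {
    trials_per_subject <- rep(as.integer(trials_per_subject), n_subjects)
  }
  if (length(trials_per_subject) != n_subjects ||
      any(trials_per_subject < 1)) {
    stop("trials_per_subject must be a count >= 1, or one count per subject")
  }
  if (is.null(names(categories)) || any(!nzchar(names(categories)))) {
    stop("categories must be a named vector (ads per category)")
  }
  if (label_noise < 0 || label_noise > 1) {
    stop("label_noise must lie in [0, 1]")
  }
  if (rejection_rate < 0 || rejection_rate >= 1) {
    stop("rejection_rate must lie in [0, 1)")
  }
  if (target_balance <= 0 || target_balance >= 1) {
    stop("target_balance must lie in (0, 1)")
  }
  if (!is.list(trial_duration_range)) {
    trial_duration_range <- stats::setNames(
      rep(list(as.numeric(trial_duration_range)), length(categories)),
      names(categories))
  }
  missing_cat <- setdiff(names(categories), names(trial_duration_range))
  if (length(missing_cat) > 0) {
    stop("trial_duration_range missing categories: ",
         paste(missing_cat, collapse = ", "))
  }
  for (rng in trial_duration_range) {
    if (length(rng) != 2L || rng[1] > rng[2] || rng[1] < 1) {
      stop("each duration range must be c(min, max) seconds with min >= 1")
    }
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    trials_per_subject = as.integer(trials_per_subject),
    categories = categories,
    sample_rate = sample_rate,
    trial_duration_range = trial_duration_range,
    effect_size = effect_size,
    label_noise = label_noise,
    rejection_rate = rejection_rate,
    target_balance = target_balance,
    noise_sd = noise_sd,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  subjects:", x$n_subjects,
      " trials:", sum(x$trials_per_subject),
      " categories:", paste(names(x$categories), collapse = "/"), "\n")
  cat("  sample rate:", x$sample_rate, "Hz",
      " effect size:", x$effect_size,
      " label noise:", x$label_noise,
      " rejection rate:", signif(x$rejection_rate, 4), "\n")
  cat("  target balance:", x$target_balance, " seed:", x$seed, "\n")
  invisible(x)
}

# ---- raw recordings ---------------------------------------------------------

new_raw_recording <- function(trial_id, subject_id, ad_id, category,
                              sample_rate, voltage, quality) {
  stopifnot(length(voltage) == length(quality), sample_rate > 0)
  if (any(quality < 0 | quality > 255)) {
    stop("quality values must lie in [0, 255]")
  }
  structure(list(trial_id = trial_id, subject_id = subject_id, ad_id = ad_id,
                 category = category, sample_rate = sample_rate,
                 voltage = as.numeric(voltage),
                 quality = as.integer(quality)),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat("Raw single-channel EEG recording\n")
  cat("  trial:", x$trial_id, " subject:", x$subject_id,
      " ad:", x$ad_id, " category:", x$category, "\n")
  cat("  ", length(x$voltage), " samples at ", x$sample_rate, " Hz (",
      round(length(x$voltage) / x$sample_rate, 2), " s)\n", sep = "")
  invisible(x)
}

#' Pure-sinusoid test recording
#'
#' Deterministic fixture for validating the FFT band-power path: a single
#' sinusoid of known frequency with perfect signal quality.
#'
#' @param freq frequency in Hz; must satisfy `0 < freq < sample_rate / 2`.
#' @param amplitude peak amplitude.
#' @param duration duration in seconds.
#' @param sample_rate sampling rate in Hz.
#' @return A `raw_recording`.
#' @examples
#' rec <- generate_sinusoid_recording(10, 1, 4, 512)
#' length(rec$voltage)  # 2048
#' @export
generate_sinusoid_recording <- function(freq, amplitude = 1, duration = 4,
                                        sample_rate = 512) {
  stop_if_not_scalar_number(freq, "freq")
  if (freq <= 0 || freq >= sample_rate / 2) {
    stop("freq must lie strictly between 0 and the Nyquist frequency (",
         sample_rate / 2, " Hz)")
  }
  n <- round(duration * sample_rate)
  t <- (seq_len(n) - 1) / sample_rate
  new_raw_recording(trial_id = sprintf("sine_%gHz", freq),
                    subject_id = "fixture", ad_id = "fixture",
                    category = "fixture", sample_rate = sample_rate,
                    voltage = amplitude * sin(2 * pi * freq * t),
                    quality = rep(0L, n))
}

# ---- generative model internals --------------------------------------------

# Band carrier frequencies and baseline amplitudes of the synthetic voltage.
# Theta and the two Beta bands are the emotion-linked carriers.
synthetic_band_params <- function() {
  list(
    bands = c("Delta", "Theta", "LowAlpha", "HighAlpha",
              "LowBeta", "HighBeta", "LowGamma", "HighGamma"),
    freqs = c(2, 5, 8, 11, 13, 16, 40, 100),
    baseline = c(8, 6, 5, 5, 4, 4, 2, 1),
    linked = c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE)
  )
}

# Questionnaire answer model shared between the generator and the Bayes
# oracle. e0 centers the aggregate target at the requested class balance;
# d_offsets spread the 11 items of each group around that center; the gain is
# fixed (not tied to effect_size) so that the questionnaire keeps a balanced
# random target even when the EEG coupling is switched off.
label_model_params <- function(config) {
  list(
    gain = 1.5,
    e0 = stats::qnorm(1 - config$target_balance),
    ranked_offsets = seq(-0.5, 0.5, length.out = 11),
    binary_offsets = seq(-0.5, 0.5, length.out = 11)
  )
}

# Noiseless ranked answers (1..7) for latent values e: a monotone map of e
# discretized so that the default threshold 4 splits at the latent center.
ranked_answer_base <- function(e, j, params) {
  pmin(pmax(round_half_up(3.5 + params$ranked_offsets[j] +
                            params$gain * (e - params$e0)), 1), 7)
}

binary_answer_base <- function(e, j, params) {
  as.integer(e > params$e0 + params$binary_offsets[j])
}

generate_answers <- function(e, config) {
  params <- label_model_params(config)
  n <- length(e)
  out <- matrix(0L, nrow = n, ncol = 22,
                dimnames = list(NULL, paste0("Y", 1:22)))
  for (j in 1:11) {
    a <- ranked_answer_base(e, j, params)
    noisy <- stats::runif(n) < config$label_noise
    a[noisy] <- sample.int(7, sum(noisy), replace = TRUE)
    out[, j] <- as.integer(a)
  }
  for (j in 1:11) {
    b <- binary_answer_base(e, j, params)
    flip <- stats::runif(n) < config$label_noise
    b[flip] <- 1L - b[flip]
    out[, 11 + j] <- b
  }
  out
}

synthesize_voltage <- function(e, duration_s, config) {
  bp <- synthetic_band_params()
  n <- round(duration_s * config$sample_rate)
  t <- (seq_len(n) - 1) / config$sample_rate
  amps <- bp$baseline *
    ifelse(bp$linked, pmax(0, 1 + config$effect_size * e), 1)
  phases <- stats::runif(length(bp$freqs), 0, 2 * pi)
  s <- sin(outer(2 * pi * t, bp$freqs) +
             matrix(phases, n, length(bp$freqs), byrow = TRUE))
  as.numeric(s %*% amps) + stats::rnorm(n, sd = config$noise_sd)
}

# Emulate voltage abnormality: the trace is overdriven and clipped at a
# ceiling, and the clipped samples get a bad quality flag (200), so that the
# default quality filter (cut 50, max bad fraction 0.1) catches exactly the
# planted trials.
make_abnormal <- function(voltage) {
  ceiling_v <- stats::quantile(abs(voltage), 0.6)
  over <- abs(voltage * 4) > ceiling_v
  voltage <- pmin(pmax(voltage * 4, -ceiling_v), ceiling_v)
  quality <- ifelse(over, 200L, sample.int(26L, length(voltage),
                                           replace = TRUE) - 1L)
  list(voltage = voltage, quality = as.integer(quality))
}

# ---- cohort generation ------------------------------------------------------

#' Generate a synthetic advertisement-viewing cohort
#'
#' Draws a latent per-trial emotion `e ~ N(0, 1)` and composes (a) a raw
#' voltage trace as a sum of eight band-centered sinusoids with random phases
#' plus white noise, where the amplitudes of the emotion-linked bands (Theta,
#' LowBeta, HighBeta) scale as `baseline * max(0, 1 + effect_size * e)`, and
#' (b) a 22-item questionnaire row: eleven ranked answers as a monotone noisy
#' map of `e` onto 1..7 and eleven binary answers as noisy threshold
#' indicators of `e`. A `round(rejection_rate * n)` subset of trials is
#' planted as voltage-abnormal (overdriven, clipped, bad quality flags); the
#' preprocessing quality filter is expected to remove exactly those.
#'
#' All recordings — including the planted-abnormal ones — are returned, so
#' that [reject_abnormal()] can be exercised downstream; the planted ids are
#' recorded in the `planted_abnormal` field.
#'
#' @param config a [synthetic_config()].
#' @param signals if `FALSE`, skip voltage synthesis and return only labels
#'   and latent emotions (fast path for studying the label model at large n).
#' @return An `eeg_cohort` object: list with `recordings` (list of
#'   `raw_recording`), `labels` (data frame: `trial_id`, `subject_id`,
#'   `ad_id`, `category`, `Y1`..`Y22`), `emotion` (data frame: `trial_id`,
#'   `e`), `planted_abnormal` (character ids), and the `config`.
#' @examples
#' cfg <- synthetic_config(n_subjects = 3, trials_per_subject = 4,
#'                         trial_duration_range = c(3, 5), seed = 7)
#' cohort <- generate_cohort(cfg)
#' length(cohort$recordings)
#' head(cohort$labels[, 1:6])
#' @export
generate_cohort <- function(config, signals = TRUE) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(stage_seed(config$seed, "cohort"), {
    n_trials <- sum(config$trials_per_subject)
    cats <- names(config$categories)

    # fixed per-ad durations: ads within a category share the category range
    ad_durations <- lapply(cats, function(cat) {
      rng <- config$trial_duration_range[[cat]]
      sample(seq(rng[1], rng[2]), config$categories[[cat]], replace = TRUE)
    })
    names(ad_durations) <- cats

    subject_id <- rep(sprintf("S%02d", seq_len(config$n_subjects)),
                      times = config$trials_per_subject)
    # categories cycle within each subject so every subject sees all genres;
    # the cycle start rotates by subject so categories stay balanced overall
    category <- unlist(lapply(seq_along(config$trials_per_subject),
                              function(i) {
      k <- config$trials_per_subject[i]
      cats[((seq_len(k) - 1) + (i - 1)) %% length(cats) + 1]
    }), use.names = FALSE)
    ad_index <- vapply(category, function(cat) {
      sample.int(config$categories[[cat]], 1L)
    }, integer(1))
    ad_id <- sprintf("%s_ad%02d", category, ad_index)
    trial_id <- sprintf("T%03d", seq_len(n_trials))

    e <- stats::rnorm(n_trials)
    answers <- generate_answers(e, config)

    n_abnormal <- round_half_up(config$rejection_rate * n_trials)
    abnormal_idx <- if (n_abnormal > 0) {
      sort(sample.int(n_trials, n_abnormal))
    } else integer(0)
    if (n_trials - length(abnormal_idx) == 0L) {
      stop("rejection_rate ", config$rejection_rate,
           " leaves zero surviving trials")
    }

    recordings <- vector("list", n_trials)
    if (signals) {
      for (i in seq_len(n_trials)) {
        dur <- ad_durations[[category[i]]][ad_index[i]]
        v <- synthesize_voltage(e[i], dur, config)
        if (i %in% abnormal_idx) {
          ab <- make_abnormal(v)
          v <- ab$voltage
          q <- ab$quality
        } else {
          q <- sample.int(26L, length(v), replace = TRUE) - 1L
        }
        recordings[[i]] <- new_raw_recording(
          trial_id = trial_id[i], subject_id = subject_id[i],
          ad_id = ad_id[i], category = category[i],
          sample_rate = config$sample_rate, voltage = v, quality = q)
      }
    }

    labels <- data.frame(trial_id = trial_id, subject_id = subject_id,
                         ad_id = ad_id, category = category,
                         stringsAsFactors = FALSE)
    labels <- cbind(labels, as.data.frame(answers))

    structure(list(
      recordings = if (signals) recordings else NULL,
      labels = labels,
      emotion = data.frame(trial_id = trial_id, e = e,
                           stringsAsFactors = FALSE),
      planted_abnormal = trial_id[abnormal_idx],
      config = config
    ), class = "eeg_cohort")
  })
}

#' @export
print.eeg_cohort <- function(x, ...) {
  cat("Synthetic EEG cohort:", nrow(x$labels), "trials,",
      x$config$n_subjects, "subjects\n")
  cat("  planted abnormal trials:", length(x$planted_abnormal), "\n")
  cat("  categories:", paste(names(table(x$labels$category)),
                             table(x$labels$category),
                             sep = "=", collapse = " "), "\n")
  invisible(x)
}

# ---- Bayes oracle -----------------------------------------------------------

# Per-answer probability that the *binarized* answer equals 1 given latent e,
# under the generator's noise model and a binarization scheme. Closed-form in
# e; only the latent variable itself is Monte-Carlo sampled.
answer_success_probs <- function(e, config, scheme) {
  params <- label_model_params(config)
  nu <- config$label_noise
  p7 <- matrix(0, length(e), 11)
  u7 <- mean(seq_len(7) >= scheme$ranked_threshold)  # redraw is uniform 1..7
  for (j in 1:11) {
    z <- as.numeric(ranked_answer_base(e, j, params) >=
                      scheme$ranked_threshold)
    p7[, j] <- (1 - nu) * z + nu * u7
  }
  p2 <- matrix(0, length(e), 11)
  for (j in 1:11) {
    b <- binary_answer_base(e, j, params)
    pb1 <- (1 - nu) * b + nu * (1 - b)  # P(observed binary answer = 1)
    p2[, j] <- if (scheme$binary_threshold <= 0) {
      1
    } else if (scheme$binary_threshold > 1) {
      0
    } else {
      pb1
    }
  }
  list(p7 = p7, p2 = p2)
}

# Poisson-binomial count distribution: column k+1 = P(count == k | e_i).
poisson_binomial <- function(p) {
  n <- nrow(p)
  k <- ncol(p)
  dist <- matrix(0, n, k + 1)
  dist[, 1] <- 1
  for (j in seq_len(k)) {
    pj <- p[, j]
    dist <- cbind(dist * (1 - pj), 0)[, 1:(k + 1)] +
      cbind(0, dist * pj)[, 1:(k + 1)]
  }
  dist
}

#' Best achievable accuracy on the planted synthetic target
#'
#' Monte-Carlo estimate of the Bayes accuracy for predicting the aggregated
#' binary questionnaire target from the latent emotion itself, under a
#' generator configuration and binarization scheme. Given each sampled latent
#' value the conditional positive probability is computed exactly (the
#' answers are conditionally independent Bernoullis, so the aggregate count
#' is Poisson-binomial); only the latent variable is sampled. This is the
#' ceiling no feature-based classifier can beat, used by the recovery tests.
#'
#' @param config a [synthetic_config()].
#' @param scheme a [binarization_scheme()]; defaults to the ranked-answer
#'   scheme at threshold 4.
#' @param n_mc number of Monte-Carlo draws of the latent variable (>= 1000).
#' @param seed RNG seed for the latent draws (default: from the config seed).
#' @return The estimated Bayes accuracy, a proportion in \[0, 1\].
#' @examples
#' cfg <- synthetic_config(label_noise = 0)
#' planted_bayes_accuracy(cfg, n_mc = 5000)  # ~1: noiseless limit
#' @export
planted_bayes_accuracy <- function(config, scheme = binarization_scheme(),
                                   n_mc = 1e5, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (n_mc < 1000) stop("n_mc must be >= 1000")
  seed <- seed %||% stage_seed(config$seed, "mc")
  with_seed(seed, {
    e <- stats::rnorm(n_mc)
    p <- answer_success_probs(e, config, scheme)
    group <- scheme$label_group
    frac <- (0:11) / 11
    p_pos <- if (group == "ranked") {
      d7 <- poisson_binomial(p$p7)
      rowSums(d7[, frac >= scheme$dataset_threshold - 1e-12, drop = FALSE])
    } else if (group == "binary") {
      d2 <- poisson_binomial(p$p2)
      rowSums(d2[, frac >= scheme$dataset_threshold - 1e-12, drop = FALSE])
    } else if (group == "combined") {
      d7 <- poisson_binomial(p$p7)
      d2 <- poisson_binomial(p$p2)
      acc <- numeric(n_mc)
      for (k7 in 0:11) {
        w <- scheme$alpha * k7 / 11 + scheme$beta * frac
        cols <- which(w >= scheme$dataset_threshold - 1e-12)
        if (length(cols) > 0) {
          acc <- acc + d7[, k7 + 1] *
            rowSums(d2[, cols, drop = FALSE])
        }
      }
      acc
    } else {  # single:Yi
      j <- scheme$single_index
      agg <- if (j <= 11) p$p7[, j] else p$p2[, j - 11]
      # target = 1 iff the single binarized value >= dataset threshold
      if (scheme$dataset_threshold <= 0) rep(1, n_mc)
      else if (scheme$dataset_threshold > 1) rep(0, n_mc)
      else agg
    }
    mean(pmax(p_pos, 1 - p_pos))
  })
}
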