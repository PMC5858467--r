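#' The 13-column per-timestamp feature schema
#'
#' Column names of the device-style band feature table: a time index, signal
#' quality, mean raw voltage, the two proprietary-style mental-state scores,
#' and the eight band powers.
#'
#' @return Character vector of the 13 column names.
#' @export
band_series_columns <- function() {
  c("TimeStamp", "SignalQuality", "Raw", "Attention", "Meditation",
    "Delta", "Theta", "LowAlpha", "HighAlpha",
    "LowBeta", "HighBeta", "LowGamma", "HighGamma")
}

#' Default modeling features
#'
#' The eleven feature columns used for classification: the eight band powers
#' plus Raw, Meditation and Attention. TimeStamp and SignalQuality are
#' bookkeeping columns, never features.
#'
#' @return Character vector of 11 feature names.
#' @export
default_features <- function() {
  c("Delta", "Theta", "LowAlpha", "HighAlpha",
    "LowBeta", "HighBeta", "LowGamma", "HighGamma",
    "Raw", "Meditation", "Attention")
}

#' Reject voltage-abnormal trials by signal quality
#'
#' Drops every recording whose fraction of samples with quality worse than
#' `quality_cut` exceeds `max_bad_fraction` (quality is 0 = perfect to 255 =
#' unusable). Dropped trial ids are reported in a message and attached as the
#' `rejected_ids` attribute.
#'
#' @param recordings list of `raw_recording` objects.
#' @param quality_cut samples with quality strictly above this count as bad.
#' @param max_bad_fraction maximum tolerated bad-sample fraction in \[0, 1\];
#'   1 disables rejection.
#' @return The surviving recordings (same order), with attribute
#'   `rejected_ids`.
#' @examples
#' rec <- generate_sinusoid_recording(10, 1, 2, 512)
#' length(reject_abnormal(list(rec)))  # perfect quality is always kept
#' @export
reject_abnormal <- function(recordings, quality_cut = 50,
                            max_bad_fraction = 0.1) {
  if (max_bad_fraction < 0 || max_bad_fraction > 1) {
    stop("max_bad_fraction must lie in [0, 1]")
  }
  bad_frac <- vapply(recordings, function(r) {
    mean(r$quality > quality_cut)
  }, numeric(1))
  drop <- bad_frac > max_bad_fraction
  if (all(drop)) {
    stop("all ", length(recordings),
         " trials rejected by the quality filter (quality_cut = ",
         quality_cut, ", max_bad_fraction = ", max_bad_fraction, ")")
  }
  rejected <- vapply(recordings[drop], `[[`, character(1), "trial_id")
  if (length(rejected) > 0) {
    message("rejected ", length(rejected), " voltage-abnormal trial(s): ",
            paste(rejected, collapse = ", "))
  }
  structure(recordings[!drop], rejected_ids = rejected)
}

# one-sided power spectrum normalized so that sum(power) == sum(x^2)
window_power_spectrum <- function(x, sample_rate) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n
  half <- floor(n / 2)
  k <- 0:half
  power <- sp[k + 1]
  dbl <- k > 0 & (k < n / 2 | n %% 2 == 1)
  power[dbl] <- 2 * power[dbl]
  list(freq = k * sample_rate / n, power = power)
}

# bounded monotone proxies for the proprietary attention/meditation scores
esense_proxies <- function(bandpow) {
  alpha <- bandpow[["LowAlpha"]] + bandpow[["HighAlpha"]]
  beta <- bandpow[["LowBeta"]] + bandpow[["HighBeta"]]
  theta <- bandpow[["Theta"]]
  att <- 100 * beta / (alpha + theta + beta)
  med <- 100 * alpha / (alpha + beta)
  c(Attention = if (is.finite(att)) att else 50,
    Meditation = if (is.finite(med)) med else 50)
}

#' Extract the per-timestamp band feature series from a raw recording
#'
#' Slices the voltage trace into non-overlapping windows (default 1 s, so
#' one "timestamp" per second of advertisement), Fourier-transforms each
#' window, and accumulates the one-sided power spectrum over the bins whose
#' frequency lies in `[low, high)` for every band. The spectrum is
#' normalized so that the total power over all bins equals the window's
#' signal energy (Parseval). `Raw` is the window-mean voltage and
#' `SignalQuality` the window-mean quality. `Attention`/`Meditation` are
#' passed through when the recording carries device-reported values
#' (elements `attention`/`meditation`, one per window); otherwise they are
#' derived as bounded monotone band-ratio proxies
#' (`100 * Beta / (Alpha + Theta + Beta)` and `100 * Alpha / (Alpha + Beta)`)
#' since the proprietary formulas are unpublished.
#'
#' @param raw a `raw_recording`.
#' @param bands a [band_definitions()] object.
#' @param window_seconds window length in seconds; the window must hold at
#'   least 2 samples and the recording at least one window.
#' @return A `band_series` object: trial metadata plus a data frame with the
#'   13 [band_series_columns()], one row per window.
#' @examples
#' rec <- generate_sinusoid_recording(10, 1, 4, 512)
#' bs <- extract_band_series(rec)
#' bs$data[, c("TimeStamp", "HighAlpha", "Delta")]
#' @export
extract_band_series <- function(raw, bands = band_definitions(),
                                window_seconds = 1) {
  stopifnot(inherits(raw, "raw_recording"))
  validate_band_definitions(bands)
  win <- round(window_seconds * raw$sample_rate)
  if (win < 2) stop("window must contain at least 2 samples")
  n_win <- floor(length(raw$voltage) / win)
  if (n_win < 1) {
    stop("recording ", raw$trial_id, " is shorter than one window (",
         length(raw$voltage), " < ", win, " samples)")
  }
  rows <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * win + 1):(w * win)
    x <- raw$voltage[idx]
    sp <- window_power_spectrum(x, raw$sample_rate)
    bandpow <- vapply(seq_len(nrow(bands)), function(b) {
      sum(sp$power[sp$freq >= bands$low[b] & sp$freq < bands$high[b]])
    }, numeric(1))
    names(bandpow) <- bands$band
    es <- if (!is.null(raw$attention) && !is.null(raw$meditation)) {
      c(Attention = raw$attention[w], Meditation = raw$meditation[w])
    } else {
      esense_proxies(bandpow)
    }
    rows[[w]] <- c(TimeStamp = w,
                   SignalQuality = mean(raw$quality[idx]),
                   Raw = mean(x),
                   Attention = unname(es[["Attention"]]),
                   Meditation = unname(es[["Meditation"]]),
                   bandpow)
  }
  data <- as.data.frame(do.call(rbind, rows))[, band_series_columns()]
  structure(list(trial_id = raw$trial_id, subject_id = raw$subject_id,
                 ad_id = raw$ad_id, category = raw$category,
                 data = data),
            class = "band_series")
}

#' @export
print.band_series <- function(x, ...) {
  cat("Band feature series: trial", x$trial_id, "(subject", x$subject_id,
      ", category", paste0(x$category, ")"), "-", nrow(x$data),
      "timestamps\n")
  invisible(x)
}

#' Trim trials to their category's minimum length
#'
#' Truncates every trial to the minimum timestamp count observed in its
#' product category (or to an explicit override, e.g. the canonical
#' `c(car = 24, clothing = 13, digital = 28, food = 16)`), so that all
#' trials within a category have equal length. Idempotent.
#'
#' @param series_list list of `band_series`.
#' @param overrides optional named vector, category -> length; an override
#'   exceeding some trial's length is an error naming the trial.
#' @return The trimmed list.
#' @export
trim_to_category_minimum <- function(series_list, overrides = NULL) {
  cats <- vapply(series_list, `[[`, character(1), "category")
  lens <- vapply(series_list, function(s) nrow(s$data), integer(1))
  target <- tapply(lens, cats, min)
  if (!is.null(overrides)) {
    for (cat in names(overrides)) {
      if (!cat %in% names(target)) next
      short <- which(cats == cat & lens < overrides[[cat]])
      if (length(short) > 0) {
        stop("override ", overrides[[cat]], " for category '", cat,
             "' exceeds the length of trial ",
             series_list[[short[1]]]$trial_id, " (",
             lens[short[1]], " timestamps)")
      }
      target[[cat]] <- overrides[[cat]]
    }
  }
  lapply(series_list, function(s) {
    k <- target[[s$category]]
    s$data <- s$data[seq_len(k), , drop = FALSE]
    s
  })
}

#' Select feature columns from a band series
#'
#' Subsets the per-timestamp table to the requested feature columns, in the
#' requested order. TimeStamp and SignalQuality are excluded by construction
#' and requesting them is an error.
#'
#' @param series a `band_series`.
#' @param feature_names character vector of feature names; default the
#'   eleven [default_features()].
#' @return The series with its data restricted to the requested columns.
#' @export
select_features <- function(series, feature_names = default_features()) {
  stopifnot(inherits(series, "band_series"))
  valid <- setdiff(band_series_columns(), c("TimeStamp", "SignalQuality"))
  unknown <- setdiff(feature_names, valid)
  if (length(unknown) > 0) {
    stop("unknown or excluded feature(s): ",
         paste(unknown, collapse = ", "),
         "; valid features are: ", paste(valid, collapse = ", "))
  }
  series$data <- series$data[, feature_names, drop = FALSE]
  series
}

#' Flatten per-timestamp series into a trials-by-features matrix
#'
#' Two reductions are supported. `mode = "mean"` (default) averages each
#' feature over the trial's timestamps, giving a fixed-width matrix that can
#' pool trials across categories of different trimmed lengths — the
#' representation the cross-category classifier needs. `mode = "concat"`
#' concatenates feature-by-timestamp values (columns like `Theta_t03`),
#' which preserves temporal structure but only within one category: trials
#' of different categories have different lengths, so pooling is rejected.
#'
#' @param series_list list of `band_series`, trimmed so lengths are equal
#'   within each category.
#' @param mode `"mean"` or `"concat"`.
#' @param feature_names features to keep (see [select_features()]).
#' @return A numeric matrix with one row per trial and attribute `meta`, a
#'   data frame with `trial_id`, `subject_id`, `ad_id`, `category`.
#' @examples
#' recs <- list(generate_sinusoid_recording(10, 1, 3, 512),
#'              generate_sinusoid_recording(5, 1, 3, 512))
#' series <- lapply(recs, extract_band_series)
#' x <- flatten_trials(series)
#' dim(x)  # 2 trials x 11 features
#' @export
flatten_trials <- function(series_list, mode = c("mean", "concat"),
                           feature_names = default_features()) {
  mode <- match.arg(mode)
  series_list <- lapply(series_list, select_features, feature_names)
  cats <- vapply(series_list, `[[`, character(1), "category")
  lens <- vapply(series_list, function(s) nrow(s$data), integer(1))
  if (any(stats::ave(lens, cats, FUN = function(v) max(v) - min(v)) != 0)) {
    stop("trials must be trimmed to equal length within each category; ",
         "run trim_to_category_minimum() first")
  }
  if (mode == "concat" && length(unique(cats)) > 1L) {
    stop("concat mode cannot pool categories of different trimmed lengths (",
         paste(unique(cats), collapse = ", "),
         "); flatten one category at a time or use mode = 'mean'")
  }
  x <- if (mode == "mean") {
    m <- vapply(series_list, function(s) colMeans(as.matrix(s$data)),
                numeric(length(feature_names)))
    m <- if (is.matrix(m)) t(m) else matrix(m, ncol = 1)
    colnames(m) <- feature_names
    m
  } else {
    k <- lens[1]
    # row layout: all features at timestamp 1, then timestamp 2, ...
    cn <- as.vector(outer(feature_names, seq_len(k),
                          function(f, t) sprintf("%s_t%02d", f, t)))
    m <- vapply(series_list, function(s) {
      as.vector(t(as.matrix(s$data)))
    }, numeric(length(feature_names) * k))
    m <- if (is.matrix(m)) t(m) else matrix(m, ncol = 1)
    colnames(m) <- cn
    m
  }
  if (anyNA(x)) stop("flattened feature matrix contains missing values")
  meta <- data.frame(
    trial_id = vapply(series_list, `[[`, character(1), "trial_id"),
    subject_id = vapply(series_list, `[[`, character(1), "subject_id"),
    ad_id = vapply(series_list, `[[`, character(1), "ad_id"),
    category = cats, stringsAsFactors = FALSE)
  rownames(x) <- meta$trial_id
  structure(x, meta = meta)
}
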