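# fixtures are generated in code; heavier ones are cached per test run

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- force(expr)
  }
  .fixture_cache[[key]]
}

# tiny cohort: enough structure for shape/bookkeeping tests
small_config <- function(seed = 42, ...) {
  synthetic_config(n_subjects = 4, trials_per_subject = 5,
                   trial_duration_range = c(3, 5), seed = seed, ...)
}

small_dataset <- function() {
  cached_fixture("small_dataset", {
    suppressMessages(build_dataset(generate_cohort(small_config())))
  })
}

# medium cohort: large enough for stratified folds within category subsets
medium_config <- function(...) {
  synthetic_config(n_subjects = 8, trials_per_subject = 8,
                   trial_duration_range = c(3, 6), seed = 99, ...)
}

medium_dataset <- function() {
  cached_fixture("medium_dataset", {
    suppressMessages(build_dataset(generate_cohort(medium_config())))
  })
}

# full-scale strong-coupling cohort shared by the recovery and
# learning-curve acceptance checks
strong_dataset <- function() {
  cached_fixture("strong_dataset", {
    suppressMessages(build_dataset(generate_cohort(
      synthetic_config(seed = 2026))))
  })
}

# one-row label table with explicit ranked/binary answers
label_row <- function(ranked, binary) {
  stopifnot(length(ranked) == 11, length(binary) == 11)
  as.data.frame(as.list(stats::setNames(c(ranked, binary),
                                        paste0("Y", 1:22))))
}

# random valid label table for property tests
random_label_table <- function(n, seed) {
  with_seed_local(seed, {
    df <- as.data.frame(matrix(sample(1:7, n * 11, replace = TRUE),
                               nrow = n))
    names(df) <- paste0("Y", 1:11)
    for (j in 12:22) df[[paste0("Y", j)]] <- sample(0:1, n, replace = TRUE)
    df
  })
}

with_seed_local <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}
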