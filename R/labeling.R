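#' Threshold binarization scheme for questionnaire answers
#'
#' Describes how the 22 questionnaire answers (eleven ranked 1--7 items Y1..
#' Y11, eleven binary 0/1 items Y12..Y22) are reduced to a single 0/1
#' purchase-intent target per trial:
#'
#' 1. each answer is binarized against its group threshold
#'    (`value >= threshold` maps to 1);
#' 2. the binarized answers of the selected group are averaged (for
#'    `"combined"`, the two group means are weighted by `alpha` and `beta`);
#' 3. the trial is positive iff that aggregate reaches `dataset_threshold`.
#'
#' The conventional ranked thresholds are 3.5, 4 = (7+1)/2 and 4.5; binary
#' thresholds 0, 0.5 = (0+1)/2 and 1 (or 0.4/0.5/0.6 in grid scans); for the
#' combined group the nominal scalar threshold is
#' `alpha * ranked_threshold + beta * binary_threshold`
#' (see [combined_threshold()]).
#'
#' @param label_group `"ranked"`, `"binary"`, `"combined"`, or `"single:Yi"`
#'   (e.g. `"single:Y9"` for the willingness-to-buy item alone).
#' @param ranked_threshold threshold applied to ranked answers.
#' @param binary_threshold threshold applied to binary answers.
#' @param alpha,beta non-negative weights of the ranked and binary components
#'   for the combined group; must sum to 1.
#' @param dataset_threshold threshold applied to the aggregated proportion.
#' @return A `binarization_scheme` object.
#' @examples
#' binarization_scheme()  # ranked answers at threshold 4
#' binarization_scheme("combined", ranked_threshold = 4,
#'                     binary_threshold = 0.4, dataset_threshold = 0.4)
#' @export
binarization_scheme <- function(label_group = "ranked",
                                ranked_threshold = 4,
                                binary_threshold = 0.5,
                                alpha = 0.5, beta = 0.5,
                                dataset_threshold = 0.5) {
  single_index <- NULL
  if (grepl("^single:Y", label_group)) {
    single_index <- suppressWarnings(
      as.integer(sub("^single:Y", "", label_group)))
    if (is.na(single_index) || single_index < 1 || single_index > 22) {
      stop("single-label group must name one of Y1..Y22, got '",
           label_group, "'")
    }
    label_group <- "single"
  } else {
    label_group <- match.arg(label_group,
                             c("ranked", "binary", "combined"))
  }
  if (alpha < 0 || beta < 0) stop("alpha and beta must be non-negative")
  if (label_group == "combined" && abs(alpha + beta - 1) > 1e-8) {
    stop("alpha + beta must equal 1 for the combined group")
  }
  structure(list(label_group = label_group,
                 ranked_threshold = ranked_threshold,
                 binary_threshold = binary_threshold,
                 alpha = alpha, beta = beta,
                 dataset_threshold = dataset_threshold,
                 single_index = single_index),
            class = "binarization_scheme")
}

#' @export
print.binarization_scheme <- function(x, ...) {
  grp <- if (x$label_group == "single") {
    paste0("single:Y", x$single_index)
  } else x$label_group
  cat("Binarization scheme (", grp, ")\n", sep = "")
  cat("  ranked threshold:", x$ranked_threshold,
      " binary threshold:", x$binary_threshold, "\n")
  if (x$label_group == "combined") {
    cat("  weights alpha =", x$alpha, ", beta =", x$beta,
        " -> nominal threshold", combined_threshold(x), "\n")
  }
  cat("  dataset threshold:", x$dataset_threshold, "\n")
  invisible(x)
}

#' Binarize a ranked (1--7) questionnaire answer
#'
#' @param value integer answers in 1..7 (vectorized).
#' @param threshold real threshold; `value >= threshold` maps to 1. The `>=`
#'   convention keeps the scale midpoint (7+1)/2 = 4 in the positive class at
#'   the integer threshold 4.
#' @return 0/1 integer vector.
#' @examples
#' binarize_ranked(c(3, 4, 5), 4)  # 0 1 1
#' @export
binarize_ranked <- function(value, threshold) {
  if (any(value != round(value)) || any(value < 1 | value > 7)) {
    stop("ranked answers must be integers in 1..7")
  }
  as.integer(value >= threshold)
}

#' Binarize a binary (0/1) questionnaire answer
#'
#' @param value 0/1 answers (vectorized).
#' @param threshold real threshold; `value >= threshold` maps to 1, so a
#'   threshold of 0 admits every answer and a threshold above 1 none.
#' @return 0/1 integer vector.
#' @examples
#' binarize_binary(c(0, 1), 0.5)  # 0 1
#' binarize_binary(0, 0)          # 1
#' @export
binarize_binary <- function(value, threshold) {
  if (!all(value %in% c(0, 1))) {
    stop("binary answers must be 0 or 1")
  }
  as.integer(value >= threshold)
}

#' Nominal threshold of a combined scheme
#'
#' The weighted scalar `alpha * ranked_threshold + beta * binary_threshold`
#' summarizing a combined ranked/binary scheme.
#'
#' @param scheme a [binarization_scheme()] with `label_group = "combined"`.
#' @return A single number.
#' @examples
#' sch <- binarization_scheme("combined", ranked_threshold = 4,
#'                            binary_threshold = 0.4)
#' combined_threshold(sch)  # 2.2
#' @export
combined_threshold <- function(scheme) {
  stopifnot(inherits(scheme, "binarization_scheme"))
  if (scheme$label_group != "combined") {
    stop("combined_threshold() requires label_group = 'combined'")
  }
  if (abs(scheme$alpha + scheme$beta - 1) > 1e-8) {
    stop("weights alpha + beta must sum to 1")
  }
  scheme$alpha * scheme$ranked_threshold +
    scheme$beta * scheme$binary_threshold
}

label_columns <- function() paste0("Y", 1:22)
ranked_columns <- function() paste0("Y", 1:11)
binary_columns <- function() paste0("Y", 12:22)

validate_label_table <- function(table) {
  missing <- setdiff(label_columns(), names(table))
  if (length(missing) > 0) {
    stop("label table is missing columns: ",
         paste(missing, collapse = ", "))
  }
  for (cn in ranked_columns()) {
    v <- table[[cn]]
    if (anyNA(v) || any(v != round(v) | v < 1 | v > 7)) {
      bad <- which(is.na(v) | v != round(v) | v < 1 | v > 7)[1]
      stop("ranked column ", cn, " has an invalid value at row ", bad,
           " (must be an integer in 1..7)")
    }
  }
  for (cn in binary_columns()) {
    v <- table[[cn]]
    if (anyNA(v) || !all(v %in% c(0, 1))) {
      bad <- which(is.na(v) | !v %in% c(0, 1))[1]
      stop("binary column ", cn, " has an invalid value at row ", bad,
           " (must be 0 or 1)")
    }
  }
  invisible(table)
}

# aggregate proportion for each row of a label table under a scheme
aggregate_scores <- function(table, scheme) {
  validate_label_table(table)
  r7 <- sapply(ranked_columns(), function(cn) {
    binarize_ranked(table[[cn]], scheme$ranked_threshold)
  })
  r2 <- sapply(binary_columns(), function(cn) {
    binarize_binary(table[[cn]], scheme$binary_threshold)
  })
  if (nrow(table) == 1L) {
    r7 <- matrix(r7, nrow = 1)
    r2 <- matrix(r2, nrow = 1)
  }
  switch(scheme$label_group,
    ranked = rowMeans(r7),
    binary = rowMeans(r2),
    combined = scheme$alpha * rowMeans(r7) + scheme$beta * rowMeans(r2),
    single = {
      j <- scheme$single_index
      if (j <= 11) r7[, j] else r2[, j - 11]
    }
  )
}

#' Aggregate one questionnaire row to a 0/1 target
#'
#' Binarizes each answer of the scheme's label group, averages the binarized
#' answers (weighted for the combined group), and thresholds the aggregate at
#' the dataset threshold.
#'
#' @param row a single label-table row (a one-row data frame, or a named
#'   vector with entries `Y1`..`Y22`).
#' @param scheme a [binarization_scheme()].
#' @return 0 or 1.
#' @examples
#' row <- as.data.frame(as.list(stats::setNames(
#'   c(rep(7, 4), rep(1, 7), rep(0, 11)), paste0("Y", 1:22))))
#' aggregate_target(row, binarization_scheme(dataset_threshold = 0.4))
#' # 4/11 binarized positives < 0.4 -> 0
#' @export
aggregate_target <- function(row, scheme) {
  if (!is.data.frame(row)) {
    row <- as.data.frame(as.list(row))
  }
  if (nrow(row) != 1L) stop("aggregate_target() expects a single row")
  as.integer(aggregate_scores(row, scheme) >=
               scheme$dataset_threshold - 1e-12)
}

#' Build the binary target vector for a label table
#'
#' Vectorized [aggregate_target()] over all trials; the positive-class
#' proportion is attached as the `positive_rate` attribute.
#'
#' @param table a label table: data frame with columns `Y1`..`Y22` (ranked
#'   columns integer 1..7, binary columns 0/1), plus any metadata columns.
#' @param scheme a [binarization_scheme()].
#' @return Integer 0/1 vector of length `nrow(table)`.
#' @examples
#' cohort <- generate_cohort(synthetic_config(
#'   n_subjects = 3, trials_per_subject = 4,
#'   trial_duration_range = c(3, 4)), signals = FALSE)
#' y <- build_targets(cohort$labels, binarization_scheme())
#' attr(y, "positive_rate")
#' @export
build_targets <- function(table, scheme) {
  stopifnot(inherits(scheme, "binarization_scheme"))
  y <- as.integer(aggregate_scores(table, scheme) >=
                    scheme$dataset_threshold - 1e-12)
  attr(y, "positive_rate") <- mean(y)
  y
}
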