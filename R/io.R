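# Plain headered CSV throughout (UTF-8, "." decimal): the device emits
# tabular per-second feature rows, not clinical EEG containers, so CSV is
# the native interchange dialect.

#' Write band feature series to CSV
#'
#' One file for a whole set of trials: metadata columns (`trial_id`,
#' `subject_id`, `ad_id`, `category`) followed by the 13
#' [band_series_columns()], one row per timestamp.
#'
#' @param series_list list of `band_series`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_band_series_csv <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    cbind(data.frame(trial_id = s$trial_id, subject_id = s$subject_id,
                     ad_id = s$ad_id, category = s$category,
                     stringsAsFactors = FALSE),
          s$data)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read band feature series from CSV
#'
#' Validates that the header carries the metadata columns plus all 13
#' [band_series_columns()] (order-insensitive) and that feature cells are
#' numeric; errors name the missing column or the offending row.
#'
#' @param path CSV file written by [write_band_series_csv()] or in the same
#'   dialect.
#' @return List of `band_series`, one per `trial_id`, in file order.
#' @export
read_band_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta_cols <- c("trial_id", "subject_id", "ad_id", "category")
  missing <- setdiff(c(meta_cols, band_series_columns()), names(df))
  if (length(missing) > 0) {
    stop("band series file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  for (cn in band_series_columns()) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))))[1]
      stop("non-numeric value in column ", cn, " at data row ",
           bad %||% 1, " of ", path)
    }
  }
  ids <- unique(df$trial_id)
  lapply(ids, function(id) {
    sub <- df[df$trial_id == id, , drop = FALSE]
    if (is.unsorted(sub$TimeStamp, strictly = TRUE)) {
      stop("timestamps of trial ", id, " are not strictly increasing")
    }
    structure(list(trial_id = id,
                   subject_id = sub$subject_id[1],
                   ad_id = sub$ad_id[1],
                   category = sub$category[1],
                   data = {
                     d <- sub[, band_series_columns(), drop = FALSE]
                     rownames(d) <- NULL
                     d
                   }),
              class = "band_series")
  })
}

#' Write a questionnaire label table to CSV
#'
#' @param table label table data frame (metadata columns plus `Y1`..`Y22`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_label_csv <- function(table, path) {
  validate_label_table(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a questionnaire label table from CSV
#'
#' Range-validates the 22 answer columns: `Y1`..`Y11` must be integers in
#' 1..7 (ranked answers), `Y12`..`Y22` must be 0/1 (binary answers). Errors
#' name the row and column of the first violation.
#'
#' @param path CSV file with columns `Y1`..`Y22` (plus any metadata).
#' @return The validated data frame.
#' @export
read_label_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_label_table(df)
  df
}

#' Write / read a feature matrix as CSV
#'
#' Metadata columns (`trial_id`, `subject_id`, `ad_id`, `category`) first,
#' then one column per feature.
#'
#' @param x feature matrix with a `meta` attribute (from
#'   [flatten_trials()]), or an `ad_dataset`'s `x`.
#' @param meta metadata data frame; defaults to `attr(x, "meta")`.
#' @param path file path.
#' @return `path` (write) or a list `x`/`meta` (read).
#' @export
write_feature_matrix_csv <- function(x, path, meta = attr(x, "meta")) {
  if (is.null(meta)) stop("feature matrix has no metadata")
  utils::write.csv(cbind(meta, as.data.frame(unclass(x))), path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix_csv
#' @export
read_feature_matrix_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta_cols <- c("trial_id", "subject_id", "ad_id", "category")
  missing <- setdiff(meta_cols, names(df))
  if (length(missing) > 0) {
    stop("feature matrix file is missing metadata column(s): ",
         paste(missing, collapse = ", "))
  }
  x <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  if (!is.numeric(x)) stop("feature columns must be numeric")
  rownames(x) <- df$trial_id
  structure(x, meta = df[, meta_cols])
}

#' Write / read a fold assignment as CSV
#'
#' Two columns: `trial_index`, `fold`.
#'
#' @param folds a `fold_assignment` from [stratified_tenfold()].
#' @param path file path.
#' @return `path` (write) or a data frame (read).
#' @export
write_folds_csv <- function(folds, path) {
  utils::write.csv(data.frame(trial_index = seq_along(folds$fold),
                              fold = folds$fold), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_folds_csv
#' @export
read_folds_csv <- function(path) {
  utils::read.csv(path)
}

#' Serialize / restore a fitted classifier as JSON
#'
#' Stores feature names, weights, intercept, `C` and the standardization
#' parameters, so a fit can be archived next to its report.
#'
#' @param object a fitted [hinge2_svm()].
#' @param path JSON file path.
#' @return `path` (write) or the restored `hinge2_svm` (read).
#' @export
write_model_json <- function(object, path) {
  stopifnot(inherits(object, "hinge2_svm"))
  payload <- object[c("w", "b", "C", "feature_names", "standardize",
                      "center", "scale", "objective", "n", "n_pos")]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  payload$w <- stats::setNames(as.numeric(payload$w),
                               payload$feature_names)
  if (!is.null(payload$center)) {
    payload$center <- stats::setNames(as.numeric(payload$center),
                                      payload$feature_names)
    payload$scale <- stats::setNames(as.numeric(payload$scale),
                                     payload$feature_names)
  }
  payload$converged <- TRUE
  structure(payload, class = "hinge2_svm")
}
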