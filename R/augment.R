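#' Bootstrap and combinatorial-expansion settings
#'
#' Parameters of the two augmentation algorithms: the per-column scaled
#' Gaussian bootstrap (perturbations drawn from a standard normal truncated
#' to the open interval (-1, 1), scaled by `0.5 * (col_min + col_max)`), and
#' the combinatorial column-replacement expansion (for each subset size `r`,
#' copies of the original matrix with an `r`-subset of columns replaced by
#' their bootstrapped versions).
#'
#' Full enumeration over 11 feature columns would emit 2^11 - 1 = 2047
#' copies; the defaults cap the enumeration at `max_copies_per_r = 20`
#' subsets per size and `expansion_cap = 50` total copies per original row,
#' keeping augmented designs desk-scale. Subset choice under a cap is
#' deterministic given the seed.
#'
#' @param seed RNG seed driving both the truncated-normal draws and the
#'   capped subset sampling.
#' @param r_range subset sizes to enumerate; sizes beyond the actual column
#'   count are ignored. Default 1..12.
#' @param max_copies_per_r maximum enumerated subsets per size (>= 1).
#' @param expansion_cap ceiling on total augmented rows, expressed as a
#'   multiple of the input row count (`expansion_cap * n` rows of copies);
#'   `Inf` disables the ceiling.
#' @return A `bootstrap_spec` object.
#' @examples
#' bootstrap_spec(seed = 3, r_range = 1:2, max_copies_per_r = 5)
#' @export
bootstrap_spec <- function(seed = 1, r_range = 1:12,
                           max_copies_per_r = 20, expansion_cap = 50) {
  if (max_copies_per_r < 1) stop("max_copies_per_r must be >= 1")
  if (expansion_cap < 1) stop("expansion_cap must be >= 1")
  if (any(r_range < 1)) stop("r_range must contain positive subset sizes")
  structure(list(seed = as.integer(seed),
                 r_range = sort(unique(as.integer(r_range))),
                 max_copies_per_r = max_copies_per_r,
                 expansion_cap = expansion_cap),
            class = "bootstrap_spec")
}

#' @export
print.bootstrap_spec <- function(x, ...) {
  cat("Bootstrap/expansion spec: seed", x$seed,
      " r in {", paste(range(x$r_range), collapse = ".."), "}",
      " cap/r =", x$max_copies_per_r,
      " total cap =", x$expansion_cap, "x n\n")
  invisible(x)
}

#' Ratio-preserving ten-fold assignment
#'
#' Splits trial indices into ten folds preserving the positive/negative
#' ratio: with `ratio` the positive proportion, folds 1--9 each receive
#' `round(ratio * n / 10)` positives and `round((1 - ratio) * n / 10)`
#' negatives dealt from the shuffled per-class index lists (short when a
#' class runs out), and fold 10 receives all leftovers. Rounding is half-up.
#'
#' @param targets binary 0/1 vector; both classes must be present and
#'   `n >= 10`.
#' @param seed RNG seed for the within-class shuffles; the per-fold class
#'   counts are determined by the data alone.
#' @return A `fold_assignment`: list with `fold` (integer 1..10 per trial),
#'   `ratio`, and `counts` (10 x 2 matrix of per-fold ones/zeros).
#' @examples
#' y <- rep(c(1, 0), c(30, 70))
#' fa <- stratified_tenfold(y, seed = 1)
#' fa$counts  # folds 1..9: 3 ones + 7 zeros; fold 10: the leftovers
#' @export
stratified_tenfold <- function(targets, seed = 1) {
  stratified_kfold(targets, k = 10, seed = seed)
}

# the general k-fold version of the dealing rule (k = 10 is the canonical
# protocol; learning curves reuse the same splitter at other k)
stratified_kfold <- function(targets, k = 10, seed = 1) {
  y <- as.integer(targets)
  n <- length(y)
  if (!all(y %in% c(0L, 1L))) stop("targets must be 0/1")
  if (length(unique(y)) < 2L) {
    stop("targets contain a single class; stratified folds need both")
  }
  if (n < k) stop("need at least ", k, " trials for ", k, " folds")
  idx1 <- which(y == 1L)
  idx0 <- which(y == 0L)
  ratio <- length(idx1) / n
  # ratio * n and (1 - ratio) * n are exactly the class counts; using the
  # integer counts avoids float error at the .5 rounding boundary
  ones <- round_half_up(length(idx1) / k)
  zeros <- round_half_up(length(idx0) / k)
  with_seed(seed, {
    idx1 <- sample(idx1)
    idx0 <- sample(idx0)
  })
  fold <- integer(n)
  p1 <- 0L
  p0 <- 0L
  for (i in seq_len(k - 1)) {
    take1 <- idx1[seq_len(min(ones, length(idx1) - p1)) + p1]
    take0 <- idx0[seq_len(min(zeros, length(idx0) - p0)) + p0]
    fold[c(take1, take0)] <- i
    p1 <- p1 + length(take1)
    p0 <- p0 + length(take0)
  }
  fold[fold == 0L] <- k  # fold k = appended leftover ones and zeros
  counts <- t(vapply(seq_len(k), function(f) {
    c(ones = sum(y == 1L & fold == f), zeros = sum(y == 0L & fold == f))
  }, c(ones = 0, zeros = 0)))
  structure(list(fold = fold, ratio = ratio, counts = counts, k = k,
                 seed = seed),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat("Stratified ", x$k, "-fold assignment (positive ratio ",
      signif(x$ratio, 4), ")\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Per-column scaled Gaussian bootstrap
#'
#' Perturbs every entry by `scale * g` where `scale = 0.5 * (col_min +
#' col_max)` for the entry's column and `g` is drawn from a standard normal
#' truncated to the open interval (-1, 1). Every perturbation is therefore
#' strictly bounded by the column scale, so the spread of the data is
#' preserved. Columns whose `min + max` is zero pass through unchanged.
#'
#' @param x numeric matrix (rows = trials).
#' @param spec a [bootstrap_spec()]; its seed drives the draws.
#' @return A matrix of the same shape; unchanged (zero-scale) columns are
#'   listed in the `passthrough_columns` attribute.
#' @examples
#' x <- cbind(a = c(2, 10), b = c(0, 0))
#' xb <- gaussian_bootstrap_columns(x, bootstrap_spec(seed = 1))
#' all(abs(xb[, "a"] - x[, "a"]) < 6)  # scale = 0.5 * (2 + 10)
#' identical(xb[, "b"], x[, "b"])      # zero-scale pass-through
#' @export
gaussian_bootstrap_columns <- function(x, spec = bootstrap_spec()) {
  stopifnot(is.matrix(x), nrow(x) >= 1, is.numeric(x))
  scales <- 0.5 * (apply(x, 2, min) + apply(x, 2, max))
  g <- with_seed(stage_seed(spec$seed, "bootstrap"), {
    matrix(rtruncnorm_open(length(x)), nrow(x), ncol(x))
  })
  out <- x + sweep(g, 2, scales, `*`)
  structure(out,
            passthrough_columns = colnames(x)[scales == 0] %||% character(0))
}

# number of r-subsets actually emitted per size, given column count and cap
expansion_copy_counts <- function(n_cols, r_range, max_copies_per_r) {
  r_range <- r_range[r_range >= 1 & r_range <= n_cols]
  vapply(r_range, function(r) {
    min(choose(n_cols, r), max_copies_per_r)
  }, numeric(1))
}

# lexicographic unranking of the rank-th r-subset of 1..k (rank 1-based)
unrank_subset <- function(rank, k, r) {
  res <- integer(r)
  x <- 1L
  rank <- rank - 1
  for (i in seq_len(r)) {
    repeat {
      cnt <- choose(k - x, r - i)
      if (rank < cnt) break
      rank <- rank - cnt
      x <- x + 1L
    }
    res[i] <- x
    x <- x + 1L
  }
  res
}

# deterministic capped choice of column subsets of size r
choose_subsets <- function(k, r, cap) {
  total <- choose(k, r)
  if (total <= cap) {
    lapply(seq_len(total), function(i) unrank_subset(i, k, r))
  } else {
    ranks <- sort(sample(total, cap))
    lapply(ranks, function(i) unrank_subset(i, k, r))
  }
}

#' Combinatorial column-replacement expansion
#'
#' For each subset size `r` in the spec's range and each selected `r`-subset
#' of feature columns, emits a copy of the original matrix with those
#' columns replaced by the corresponding bootstrapped columns. The output is
#' the original rows followed by all copies; with `k` columns and no caps
#' the copy count is `sum_r C(k, r)` (all 2^k - 1 nonempty subsets when
#' `r_range` covers every size). Caps truncate the enumeration per size
#' (`max_copies_per_r`, deterministic subset choice under the spec seed) and
#' in total (`expansion_cap * n` augmented rows, truncated at whole copies
#' so the label duplication stays row-aligned).
#'
#' @param x_orig original feature matrix.
#' @param x_boot its bootstrapped counterpart (same shape, e.g. from
#'   [gaussian_bootstrap_columns()]).
#' @param spec a [bootstrap_spec()].
#' @return The expanded matrix with attributes `n_copies` (copies emitted),
#'   `origin` (original row index of every output row) and `provenance`
#'   (`"original"` or `"boot:r=<r>:cols=<subset>"` per row).
#' @examples
#' x <- matrix(rnorm(20), 4, 5, dimnames = list(NULL, letters[1:5]))
#' spec <- bootstrap_spec(seed = 1, r_range = 1, max_copies_per_r = Inf,
#'                        expansion_cap = Inf)
#' xb <- gaussian_bootstrap_columns(abs(x), spec)
#' dim(combinatorial_expand(abs(x), xb, spec))  # (1 + 5) * 4 rows
#' @export
combinatorial_expand <- function(x_orig, x_boot, spec = bootstrap_spec()) {
  stopifnot(is.matrix(x_orig), is.matrix(x_boot))
  if (!all(dim(x_orig) == dim(x_boot))) {
    stop("x_orig and x_boot must have the same shape (",
         paste(dim(x_orig), collapse = "x"), " vs ",
         paste(dim(x_boot), collapse = "x"), ")")
  }
  n <- nrow(x_orig)
  k <- ncol(x_orig)
  r_range <- spec$r_range[spec$r_range >= 1 & spec$r_range <= k]
  subsets <- with_seed(stage_seed(spec$seed, "expand"), {
    out <- list()
    for (r in r_range) {
      for (s in choose_subsets(k, r, spec$max_copies_per_r)) {
        out[[length(out) + 1L]] <- s
      }
    }
    out
  })
  # each copy is n rows, so the expansion_cap * n row ceiling truncates at
  # whole copies: at most floor(expansion_cap) of them
  max_copies <- min(length(subsets), floor(spec$expansion_cap))
  subsets <- subsets[seq_len(max_copies)]
  blocks <- vector("list", length(subsets) + 1L)
  prov <- vector("list", length(subsets) + 1L)
  blocks[[1]] <- x_orig
  prov[[1]] <- rep("original", n)
  for (i in seq_along(subsets)) {
    s <- subsets[[i]]
    copy <- x_orig
    copy[, s] <- x_boot[, s, drop = FALSE]
    blocks[[i + 1L]] <- copy
    prov[[i + 1L]] <- rep(sprintf("boot:r=%d:cols=%s", length(s),
                                  paste(s, collapse = ".")), n)
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  structure(out,
            n_copies = length(subsets),
            origin = rep(seq_len(n), times = length(subsets) + 1L),
            provenance = unlist(prov))
}

#' Duplicate the target vector to match an expanded design
#'
#' The augmentation copies whole blocks of training rows, so the labels are
#' repeated block-for-block: with `copies` appended blocks the result has
#' `(copies + 1) * length(y)` entries and the class ratio is preserved
#' exactly.
#'
#' @param y binary target vector.
#' @param copies number of appended augmentation blocks (>= 0); typically
#'   the `n_copies` attribute of [combinatorial_expand()] output.
#' @param expanded optional expanded matrix to validate row alignment
#'   against; a length mismatch is an error.
#' @return The repeated target vector.
#' @examples
#' duplicate_labels(c(0, 1, 1), copies = 2)
#' @export
duplicate_labels <- function(y, copies, expanded = NULL) {
  if (copies < 0) stop("copies must be >= 0")
  out <- rep(as.integer(y), times = copies + 1)
  if (!is.null(expanded) && nrow(expanded) != length(out)) {
    stop("duplicated labels (", length(out),
         ") do not align with the expanded design (", nrow(expanded),
         " rows)")
  }
  out
}
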