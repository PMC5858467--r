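# internal helpers shared across the pipeline

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Classic round-half-up, used wherever a counting rule depends on rounding
#' (fold sizes, planted rejection counts, ranked-answer discretization).
#' Base R `round()` rounds half to even, which would shift fold counts.
#'
#' @param x numeric vector.
#' @return `floor(x + 0.5)` for non-negative `x`; symmetric for negative.
#' @keywords internal
#' @noRd
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Evaluate `code` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# One documented splitting scheme: every stage draws from a seed derived from
# the user's single seed, so any stage is reproducible in isolation.
stage_seed <- function(seed, stage) {
  offsets <- c(cohort = 101L, bootstrap = 211L, folds = 307L, expand = 401L,
               curve = 503L, mc = 601L, perm = 701L, holdout = 809L)
  if (!stage %in% names(offsets)) {
    stop("unknown RNG stage: ", stage)
  }
  as.integer((abs(as.numeric(seed)) * 1009 + offsets[[stage]]) %% 2147483629)
}

# Standard normal truncated to the open interval (-1, 1), by rejection.
rtruncnorm_open <- function(n) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0L) {
    draw <- stats::rnorm(length(need))
    ok <- draw > -1 & draw < 1
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

# CDF of the standard normal truncated to (-1, 1); the distributional oracle
# for the bootstrap perturbations.
ptruncnorm_open <- function(q) {
  lo <- stats::pnorm(-1)
  hi <- stats::pnorm(1)
  p <- (stats::pnorm(q) - lo) / (hi - lo)
  pmin(pmax(p, 0), 1)
}

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a single finite number", call. = FALSE)
  }
  invisible(x)
}
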