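#' Linear maximum-margin classifier with squared hinge loss
#'
#' Fits the linear classifier at the core of the pipeline by minimizing the
#' L2-regularized squared-hinge primal objective
#' \deqn{\tfrac12 \lVert w \rVert^2 +
#'       C \sum_i \max(0,\, 1 - y_i (\langle w, x_i\rangle - b))^2}
#' over the weight vector `w` and intercept `b`, with the 0/1 targets
#' handled internally as -1/+1. The objective is convex and continuously
#' differentiable, so it is minimized by BFGS with the analytic gradient;
#' the fit is deterministic given the data up to solver tolerance. The
#' decision function is `f(x) = <w, x> - b`, and a point is classified
#' positive iff `f(x) >= 0` (ties go to the positive class, matching the
#' `>=` convention used throughout the package).
#'
#' Band powers span orders of magnitude, so by default each feature column
#' is centered and scaled (parameters learned on the training rows only and
#' stored in the fit; disable with `standardize = FALSE`). Constant columns
#' get unit scale.
#'
#' @param x numeric feature matrix (rows = trials), or a formula.
#' @param y binary 0/1 targets (numeric, logical, or a two-level factor);
#'   both classes must be present.
#' @param C positive regularization strength: the weight of the loss term
#'   relative to the L2 penalty.
#' @param standardize center/scale feature columns before fitting.
#' @param tol relative convergence tolerance of the solver.
#' @param maxit maximum BFGS iterations.
#' @param ... unused.
#' @return An object of class `hinge2_svm` with components `w` (named
#'   weights on the standardized scale), `b`, `C`, `feature_names`,
#'   `center`/`scale` (when standardizing), `objective`, `converged`, and
#'   the training dimensions.
#' @examples
#' x <- cbind(f1 = c(-1, 1), f2 = c(0, 0))
#' fit <- hinge2_svm(x, c(0, 1), standardize = FALSE)
#' predict(fit, x)
#' coef(fit)
#' @export
hinge2_svm <- function(x, ...) UseMethod("hinge2_svm")

#' @rdname hinge2_svm
#' @export
hinge2_svm.default <- function(x, y, C = 1, standardize = TRUE,
                               tol = 1e-6, maxit = 1000, ...) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("feature matrix must be numeric and finite with no missing values")
  }
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (!all(y %in% c(0L, 1L))) stop("targets must be binary 0/1")
  if (length(unique(y)) < 2L) {
    stop("both classes must be present in the training targets")
  }
  if (C <= 0) stop("C must be positive")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))

  center <- scale_ <- NULL
  if (standardize) {
    center <- colMeans(x)
    scale_ <- apply(x, 2, stats::sd)
    scale_[scale_ == 0 | !is.finite(scale_)] <- 1
    x <- sweep(sweep(x, 2, center), 2, scale_, `/`)
  }

  ypm <- ifelse(y == 1L, 1, -1)
  p <- ncol(x)
  objective <- function(par) {
    w <- par[seq_len(p)]
    b <- par[p + 1]
    m <- 1 - ypm * (drop(x %*% w) - b)
    0.5 * sum(w^2) + C * sum(pmax(m, 0)^2)
  }
  gradient <- function(par) {
    w <- par[seq_len(p)]
    b <- par[p + 1]
    m <- 1 - ypm * (drop(x %*% w) - b)
    act <- m > 0
    gm <- ypm[act] * m[act]
    c(w - 2 * C * drop(crossprod(x[act, , drop = FALSE], gm)),
      2 * C * sum(gm))
  }
  opt <- stats::optim(rep(0, p + 1), objective, gradient, method = "BFGS",
                      control = list(maxit = maxit, reltol = tol))

  structure(list(
    w = stats::setNames(opt$par[seq_len(p)], colnames(x)),
    b = opt$par[p + 1],
    C = C,
    feature_names = colnames(x),
    standardize = standardize,
    center = center,
    scale = scale_,
    objective = opt$value,
    converged = opt$convergence == 0L,
    n = nrow(x),
    n_pos = sum(y == 1L)
  ), class = "hinge2_svm")
}

#' @rdname hinge2_svm
#' @param data data frame holding the variables of the formula.
#' @export
hinge2_svm.formula <- function(x, data, C = 1, standardize = TRUE, ...) {
  mf <- stats::model.frame(x, data)
  y <- stats::model.response(mf)
  mm <- stats::model.matrix(attr(mf, "terms"), mf)
  mm <- mm[, colnames(mm) != "(Intercept)", drop = FALSE]
  hinge2_svm.default(mm, y, C = C, standardize = standardize, ...)
}

check_feature_columns <- function(object, x) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) {
    if (ncol(x) != length(object$feature_names)) {
      stop("expected ", length(object$feature_names),
           " feature columns, got ", ncol(x))
    }
    colnames(x) <- object$feature_names
  }
  missing <- setdiff(object$feature_names, colnames(x))
  extra <- setdiff(colnames(x), object$feature_names)
  if (length(missing) > 0 || length(extra) > 0) {
    stop("feature columns do not match the training columns",
         if (length(missing)) paste0("; missing: ",
                                     paste(missing, collapse = ", ")),
         if (length(extra)) paste0("; extra: ",
                                   paste(extra, collapse = ", ")))
  }
  x[, object$feature_names, drop = FALSE]
}

#' Signed distances to the decision boundary
#'
#' The pre-sign decision quantity `<w, x> - b` per row, on the model's
#' (standardized) feature scale.
#'
#' @param object a fitted [hinge2_svm()].
#' @param x feature matrix with the training columns.
#' @return Numeric vector of decision values.
#' @export
decision_values <- function(object, x) {
  stopifnot(inherits(object, "hinge2_svm"))
  x <- check_feature_columns(object, x)
  if (object$standardize) {
    x <- sweep(sweep(x, 2, object$center), 2, object$scale, `/`)
  }
  drop(x %*% object$w) - object$b
}

#' @describeIn hinge2_svm Predicted classes (`type = "class"`, 0/1) or raw
#'   decision values (`type = "decision"`).
#' @param object a fitted `hinge2_svm`.
#' @param newdata feature matrix to predict for.
#' @param type `"class"` or `"decision"`.
#' @export
predict.hinge2_svm <- function(object, newdata,
                               type = c("class", "decision"), ...) {
  type <- match.arg(type)
  d <- decision_values(object, newdata)
  if (type == "decision") d else as.integer(d >= 0)
}

#' @export
print.hinge2_svm <- function(x, ...) {
  cat("Linear squared-hinge SVM (C =", x$C, ")\n")
  cat("  ", length(x$w), " features, trained on ", x$n, " rows (",
      x$n_pos, " positive)\n", sep = "")
  cat("  objective:", format(x$objective, digits = 6),
      if (!x$converged) " [solver did not converge]", "\n")
  invisible(x)
}

#' @export
summary.hinge2_svm <- function(object, ...) {
  structure(list(fit = object,
                 weights = sort(abs(object$w), decreasing = TRUE)),
            class = "summary.hinge2_svm")
}

#' @export
print.summary.hinge2_svm <- function(x, ...) {
  print(x$fit)
  cat("  intercept b:", format(x$fit$b, digits = 4), "\n")
  cat("  |weights|, largest first:\n")
  print(round(x$weights, 4))
  invisible(x)
}

#' @export
coef.hinge2_svm <- function(object, ...) {
  c(object$w, b = object$b)
}

#' @describeIn hinge2_svm Margin slacks `max(0, 1 - y f(x))` of the training
#'   convention for supplied data: zero for points beyond the margin.
#' @export
residuals.hinge2_svm <- function(object, newdata, y, ...) {
  ypm <- ifelse(as.integer(y) == 1L, 1, -1)
  pmax(0, 1 - ypm * decision_values(object, newdata))
}

#' @export
fitted.hinge2_svm <- function(object, ...) {
  stop("hinge2_svm does not store its training data; ",
       "use predict(object, newdata)")
}
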