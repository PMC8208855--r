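#' Maximum-uncertainty regularization of a scatter matrix
#'
#' Eigendecomposes a symmetric pooled within-class scatter `Sw = V L V'`,
#' raises every eigenvalue below the eigenvalue mean up to that mean, and
#' reconstructs. The result is symmetric positive definite whenever the mean
#' eigenvalue is positive, which is what lets the discriminant be fitted when
#' features outnumber samples.
#'
#' @param sw Symmetric p x p matrix.
#' @param tol Symmetry tolerance (relative).
#' @return The regularized p x p matrix.
#' @export
regularize_scatter <- function(sw, tol = 1e-8) {
  sw <- as.matrix(sw)
  if (nrow(sw) != ncol(sw) || any(!is.finite(sw)))
    stop("regularize_scatter: need a finite square matrix")
  asym <- max(abs(sw - t(sw)))
  if (asym > tol * max(1, max(abs(sw))))
    stop("regularize_scatter: matrix is not symmetric")
  sw <- (sw + t(sw)) / 2
  e <- eigen(sw, symmetric = TRUE)
  lbar <- mean(e$values)
  lstar <- pmax(e$values, lbar)
  out <- e$vectors %*% (lstar * t(e$vectors))
  (out + t(out)) / 2
}

#' Maximum-uncertainty linear discriminant analysis
#'
#' Fits a two-class linear discriminant in which the pooled within-class
#' scatter (sum of class-centered outer products) is regularized by
#' [regularize_scatter()] before inversion. The weight vector is
#' `w = S*^{-1} (mu1 - mu0)` and the bias places the decision boundary at the
#' midpoint of the projected class means, so the rule is
#' `sign(w'x + b)` with 1 (SZ) for positive scores and 0 (HC) otherwise,
#' ties going to class 0.
#'
#' @param x n x p numeric matrix.
#' @param y Binary labels (0/1), both classes present.
#' @return An object of class `mlda` with components `weights`, `bias`,
#'   `class_means`, `regularized_scatter`, `eigenvalues` (original and
#'   floored) and `class_labels`.
#' @export
mlda <- function(x, y) {
  x <- as.matrix(x)
  if (ncol(x) < 1) stop("mlda: no features")
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("mlda: label length mismatch")
  if (length(unique(y)) < 2) stop("mlda: both classes must be present")
  if (!all(y %in% c(0L, 1L))) stop("mlda: labels must be 0/1")
  mu0 <- colMeans(x[y == 0L, , drop = FALSE])
  mu1 <- colMeans(x[y == 1L, , drop = FALSE])
  x0 <- sweep(x[y == 0L, , drop = FALSE], 2, mu0)
  x1 <- sweep(x[y == 1L, , drop = FALSE], 2, mu1)
  sw <- crossprod(x0) + crossprod(x1)
  e <- eigen((sw + t(sw)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sstar <- regularize_scatter(sw)
  w <- as.numeric(solve(sstar, mu1 - mu0))
  b <- -sum(w * (mu0 + mu1)) / 2
  structure(list(weights = w, bias = b,
                 class_means = rbind(HC = mu0, SZ = mu1),
                 regularized_scatter = sstar,
                 eigenvalues = list(original = e, floored = pmax(e, mean(e))),
                 class_labels = c(0L, 1L), p = ncol(x),
                 feature_names = colnames(x)),
            class = "mlda")
}

#' @export
print.mlda <- function(x, ...) {
  cat(sprintf("mlda discriminant: %d features; eigenvalue floor %.4g (%d of %d raised)\n",
              x$p, mean(x$eigenvalues$original),
              sum(x$eigenvalues$original < mean(x$eigenvalues$original)),
              x$p))
  invisible(x)
}

#' @export
coef.mlda <- function(object, ...) {
  w <- object$weights
  names(w) <- object$feature_names
  w
}

#' Predict from a fitted MLDA discriminant
#'
#' @param object An [mlda()] fit.
#' @param newdata m x p matrix (or a vector of length p).
#' @param ... Unused.
#' @return Data frame with `score` (`w'x + b`) and `label` (1 = SZ when
#'   score > 0, else 0 = HC; an exact tie is class 0).
#' @export
predict.mlda <- function(object, newdata, ...) {
  x <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(x) != object$p)
    stop("predict.mlda: newdata has ", ncol(x), " features, model has ", object$p)
  score <- as.numeric(x %*% object$weights + object$bias)
  data.frame(score = score, label = as.integer(score > 0))
}

#' Serialize an MLDA model to JSON
#'
#' Audit-oriented dump: weights, bias, class labels and the eigenvalue
#' summary of the scatter regularization.
#'
#' @param object An [mlda()] fit.
#' @param path Optional path; when `NULL` the JSON string is returned.
#' @return The path (invisibly) or a JSON string.
#' @export
mlda_to_json <- function(object, path = NULL) {
  stopifnot(inherits(object, "mlda"))
  payload <- list(weights = object$weights, bias = object$bias,
                  class_labels = object$class_labels,
                  eigenvalues_original = object$eigenvalues$original,
                  eigenvalues_floored = object$eigenvalues$floored)
  if (is.null(path))
    return(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
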