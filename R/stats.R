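#' ROC area under the curve (Mann-Whitney form)
#'
#' Mean over all (positive, negative) score pairs of the indicator that the
#' positive scores higher, with ties counting one half.
#'
#' @param scores Continuous classifier scores, higher = more SZ-like.
#' @param labels Binary truth (1 = positive/SZ).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stop("roc_auc: length mismatch")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("roc_auc: both classes must be present")
  r <- rank(scores)       # midranks handle ties as 1/2
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# placement values of one score vector: V10 per positive, V01 per negative
.placements <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  v10 <- vapply(x, function(xi) mean((xi > y) + 0.5 * (xi == y)), 0)
  v01 <- vapply(y, function(yj) mean((x > yj) + 0.5 * (x == yj)), 0)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong test for two correlated ROC curves
#'
#' Compares the AUCs of two score vectors computed on the same subjects,
#' using the placement-value covariance: with m positives and n negatives,
#' `S = S10/m + S01/n` where `S10`/`S01` are the 2x2 covariance matrices of
#' the per-positive / per-negative placement values of the two scores;
#' `z = (AUC1 - AUC2) / sqrt(S11 + S22 - 2 S12)` with a two-sided normal P.
#' Identical (or rank-identical) scores give zero variance of the
#' difference; by convention `z = 0`, `p = 1`.
#'
#' @param scores1,scores2 Two score vectors on the same subjects.
#' @param labels Binary truth (1 = positive).
#' @return An object of class `roc_comparison`: `auc1`, `auc2`, `z`,
#'   `p_value`, `n`.
#' @export
delong_test <- function(scores1, scores2, labels) {
  labels <- as.integer(labels)
  if (length(scores1) != length(labels) || length(scores2) != length(labels))
    stop("delong_test: score vectors must match the subjects")
  m <- sum(labels == 1); n <- sum(labels == 0)
  if (m == 0 || n == 0) stop("delong_test: both classes must be present")
  p1 <- .placements(scores1, labels)
  p2 <- .placements(scores2, labels)
  s10 <- stats::cov(cbind(p1$v10, p2$v10))
  s01 <- stats::cov(cbind(p1$v01, p2$v01))
  s <- s10 / m + s01 / n
  vd <- s[1, 1] + s[2, 2] - 2 * s[1, 2]
  if (vd <= .Machine$double.eps) {
    message("delong_test: zero variance of the AUC difference; z = 0, p = 1")
    z <- 0; p <- 1
  } else {
    z <- (p1$auc - p2$auc) / sqrt(vd)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc1 = p1$auc, auc2 = p2$auc, z = z, p_value = p,
                 n = length(labels)),
            class = "roc_comparison")
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf("DeLong test: AUC %.4f vs %.4f, z = %.3f, P = %.3g (n = %d)\n",
              x$auc1, x$auc2, x$z, x$p_value, x$n))
  invisible(x)
}

# lean LOOCV accuracy at a fixed threshold: same procedure as m3_loocv
# (within-fold scaling, selection, MLDA, weighted vote) without the
# bookkeeping objects; used inside permutation loops
.loocv_accuracy <- function(x, y, feature_index, p_threshold,
                            weight_rule = "train_accuracy") {
  n <- nrow(x)
  mods <- unique(feature_index$modality)
  correct <- 0L
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]; ytr <- y[-i]
    mu <- colMeans(xtr)
    sg <- sqrt((colSums(xtr^2) - (n - 1) * mu^2) / (n - 2))
    keep <- which(sg > 0)
    xs <- sweep(sweep(xtr[, keep, drop = FALSE], 2, mu[keep]), 2, sg[keep], "/")
    xte <- (x[i, keep] - mu[keep]) / sg[keep]
    fi <- feature_index$modality[keep]
    tt <- .col_ttest(xs, ytr)
    s <- 0; wsum <- 0; votes <- numeric(0); accs <- numeric(0)
    for (m in mods) {
      sel <- which(fi == m & tt$p <= p_threshold)
      if (!length(sel)) next
      fit <- mlda(xs[, sel, drop = FALSE], ytr)
      tr_lab <- as.integer(xs[, sel, drop = FALSE] %*% fit$weights + fit$bias > 0)
      a <- mean(tr_lab == ytr)
      v <- if (sum(xte[sel] * fit$weights) + fit$bias > 0) 1 else -1
      votes <- c(votes, v); accs <- c(accs, a)
    }
    if (length(votes)) {
      w <- if (weight_rule == "uniform" || sum(accs) == 0) rep(1, length(accs)) else accs
      s <- sum(w / sum(w) * votes)
    }
    correct <- correct + as.integer(as.integer(s > 0) == y[i])
  }
  correct / n
}

.perm_p <- function(observed, permuted, inclusive) {
  if (inclusive) mean(permuted >= observed) else mean(permuted > observed)
}

#' Permutation test of classification accuracy
#'
#' Shuffles the group labels (a permutation of the label multiset, i.e.
#' without replacement) `n_perm` times, reapplies the entire procedure —
#' within-fold standardization, selection, fitting, voting — to each
#' permuted cohort, and reports the fraction of permutations whose accuracy
#' reaches the observed one. The default estimator is `count / n_perm` and
#' can legitimately return 0; `add_one = TRUE` switches to
#' `(count + 1) / (n_perm + 1)`.
#'
#' @param table A [feature_table()].
#' @param p_threshold Fixed selection threshold, or `NULL` to grid-search
#'   (`grid`) inside every permutation — faithful but far slower.
#' @param grid Threshold grid used when `p_threshold` is `NULL`.
#' @param n_perm Number of permutations.
#' @param seed Integer seed governing the label shuffles.
#' @param inclusive Count permutations with accuracy `>=` the observed
#'   (conservative); `FALSE` uses strict `>`.
#' @param add_one Use the (count + 1)/(n_perm + 1) estimator.
#' @inheritParams m3
#' @return An object of class `perm_test`.
#' @export
permutation_test_accuracy <- function(table, p_threshold = NULL,
                                      grid = default_p_grid(), n_perm = 1000,
                                      seed = 1L, inclusive = TRUE,
                                      add_one = FALSE,
                                      weight_rule = c("train_accuracy", "uniform")) {
  weight_rule <- match.arg(weight_rule)
  stopifnot(inherits(table, "feature_table"), n_perm >= 1)
  run <- function(yb) {
    if (is.null(p_threshold))
      m3_grid_search(feature_table(table$x, yb, table$feature_index,
                                   table$subject_ids),
                     grid, weight_rule = weight_rule)$performance$accuracy
    else
      .loocv_accuracy(table$x, yb, table$feature_index, p_threshold,
                      weight_rule)
  }
  if (is.null(p_threshold) && n_perm > 100)
    warning("permutation_test_accuracy: full grid search inside ", n_perm,
            " permutations is slow; consider a fixed p_threshold")
  observed <- run(table$y)
  set.seed(seed)
  permuted <- vapply(seq_len(n_perm), function(b) run(sample(table$y)), 0)
  structure(list(statistic = "accuracy", observed = observed,
                 permuted = permuted,
                 p_value = if (add_one)
                   (sum(if (inclusive) permuted >= observed else permuted > observed) + 1) /
                     (n_perm + 1)
                 else .perm_p(observed, permuted, inclusive),
                 n_perm = n_perm, seed = seed),
            class = "perm_test")
}

#' Permutation test of the AUC
#'
#' Permutes the continuous vote scores against the fixed labels and
#' recomputes the AUC each time.
#'
#' @param scores Observed continuous scores.
#' @param labels Binary truth.
#' @inheritParams permutation_test_accuracy
#' @return An object of class `perm_test`.
#' @export
permutation_test_auc <- function(scores, labels, n_perm = 1000, seed = 1L,
                                 inclusive = TRUE, add_one = FALSE) {
  if (length(scores) != length(labels))
    stop("permutation_test_auc: scores and labels must be aligned")
  observed <- roc_auc(scores, labels)
  set.seed(seed)
  permuted <- vapply(seq_len(n_perm), function(b)
    roc_auc(sample(scores), labels), 0)
  structure(list(statistic = "auc", observed = observed, permuted = permuted,
                 p_value = if (add_one)
                   (sum(if (inclusive) permuted >= observed else permuted > observed) + 1) /
                     (n_perm + 1)
                 else .perm_p(observed, permuted, inclusive),
                 n_perm = n_perm, seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("permutation test (%s): observed %.4f, p = %.4g (%d permutations, seed %d)\n",
              x$statistic, x$observed, x$p_value, x$n_perm, x$seed))
  invisible(x)
}

#' @export
plot.perm_test <- function(x, ...) {
  graphics::hist(x$permuted, breaks = 30, col = "grey85", border = "white",
                 main = sprintf("permuted %s", x$statistic),
                 xlab = x$statistic, ...)
  graphics::abline(v = x$observed, col = "red", lwd = 2)
  invisible(x)
}

#' Pearson chi-square for a 2x2 table
#'
#' Without continuity correction, 1 degree of freedom — the convention used
#' for demographics sex-ratio comparisons.
#'
#' @param a,b First row counts (e.g. male/female in group 1).
#' @param c,d Second row counts.
#' @return List with `statistic`, `p_value`, `df = 1`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  cnt <- c(a, b, c, d)
  if (any(cnt < 0)) stop("chi_square_2x2: counts must be nonnegative")
  n <- sum(cnt)
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("chi_square_2x2: zero margin")
  stat <- n * (a * d - b * c)^2 / prod(margins)
  list(statistic = stat, p_value = stats::pchisq(stat, 1, lower.tail = FALSE),
       df = 1L)
}

#' Two-sample pooled t from summary statistics
#'
#' Equal-variance two-sample t with `df = n1 + n2 - 2`, computed from group
#' means, SDs and sizes — as used to compare group ages reported as
#' mean ± SD.
#'
#' @param m1,sd1,n1 Mean, SD, size of group 1.
#' @param m2,sd2,n2 Mean, SD, size of group 2.
#' @return List with `t`, `df`, `p_value` (two-sided).
#' @export
t_from_summary <- function(m1, sd1, n1, m2, sd2, n2) {
  if (sd1 <= 0 || sd2 <= 0) stop("t_from_summary: SDs must be positive")
  if (n1 < 2 || n2 < 2) stop("t_from_summary: group sizes must be >= 2")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}
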