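#' Z-score scaler fitted on training rows
#'
#' Records per-feature training mean and sample SD. Features with zero
#' training SD are dropped (with a warning) because they carry no
#' discriminative information and cannot be scaled.
#'
#' @param x Training matrix.
#' @return An object of class `zscaler` with `mean`, `sd` and `keep`
#'   (original column indices retained).
#' @export
zscore_fit <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  sg <- apply(x, 2, stats::sd)
  keep <- unname(which(sg > 0))
  if (length(keep) < ncol(x))
    warning("zscore_fit: dropped ", ncol(x) - length(keep),
            " zero-variance feature(s)")
  structure(list(mean = mu[keep], sd = sg[keep], keep = keep,
                 p_original = ncol(x)),
            class = "zscaler")
}

#' @rdname zscore_fit
#' @param scaler A fitted `zscaler`.
#' @param rows Matrix (or single row) to transform with the training
#'   parameters.
#' @export
zscore_apply <- function(scaler, rows) {
  stopifnot(inherits(scaler, "zscaler"))
  x <- if (is.null(dim(rows))) matrix(rows, nrow = 1) else as.matrix(rows)
  if (ncol(x) != scaler$p_original)
    stop("zscore_apply: expected ", scaler$p_original, " columns")
  x <- x[, scaler$keep, drop = FALSE]
  sweep(sweep(x, 2, scaler$mean), 2, scaler$sd, "/")
}

# vectorized equal-variance two-sample t over columns; SZ (1) minus HC (0)
.col_ttest <- function(x, y) {
  i1 <- y == 1L; i0 <- !i1
  n1 <- sum(i1); n0 <- sum(i0)
  m1 <- colMeans(x[i1, , drop = FALSE]); m0 <- colMeans(x[i0, , drop = FALSE])
  v1 <- (colSums(x[i1, , drop = FALSE]^2) - n1 * m1^2) / (n1 - 1)
  v0 <- (colSums(x[i0, , drop = FALSE]^2) - n0 * m0^2) / (n0 - 1)
  sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  t <- ifelse(se > 0, (m1 - m0) / se, ifelse(m1 == m0, 0, Inf * sign(m1 - m0)))
  p <- 2 * stats::pt(-abs(t), df = n1 + n0 - 2)
  list(t = t, p = p, df = n1 + n0 - 2)
}

#' Per-modality t-test feature selection
#'
#' Equal-variance two-sided two-sample t-tests per feature on training rows
#' only; within each modality block, features with `P <= p_threshold` are
#' selected independently of the other blocks.
#'
#' @param x Training matrix (typically already z-scored; the t statistic is
#'   scale-invariant either way).
#' @param y Binary training labels.
#' @param p_threshold Selection threshold in (0, 1); inclusive.
#' @param feature_index Data frame with a `modality` column aligned to the
#'   columns of `x`.
#' @return An object of class `m3_selection`: per-modality selected column
#'   indices plus the full `t` and `p` vectors.
#' @export
select_features_ttest <- function(x, y, p_threshold, feature_index) {
  if (!(p_threshold > 0 && p_threshold < 1))
    stop("select_features_ttest: p_threshold must lie in (0, 1)")
  tt <- .col_ttest(as.matrix(x), as.integer(y))
  mods <- unique(feature_index$modality)
  sel <- lapply(mods, function(m) {
    cols <- which(feature_index$modality == m)
    cols[tt$p[cols] <= p_threshold]
  })
  names(sel) <- mods
  structure(list(p_threshold = p_threshold, selected = sel,
                 t = tt$t, p = tt$p),
            class = "m3_selection")
}

# fit the five base classifiers on already-scaled training data
.fit_bases <- function(xs, y, selected, weight_rule) {
  mods <- names(selected)
  models <- vector("list", length(mods)); names(models) <- mods
  train_acc <- rep(NA_real_, length(mods)); names(train_acc) <- mods
  for (m in mods) {
    sel <- selected[[m]]
    if (!length(sel)) next
    fit <- mlda(xs[, sel, drop = FALSE], y)
    models[[m]] <- fit
    train_acc[m] <- mean(predict(fit, xs[, sel, drop = FALSE])$label == y)
  }
  active <- !vapply(models, is.null, TRUE)
  if (!any(active))
    stop("m3: all five modality selections are empty; untrainable at this threshold")
  w <- rep(0, length(mods)); names(w) <- mods
  if (weight_rule == "uniform") w[active] <- 1 else w[active] <- train_acc[active]
  if (sum(w) == 0) w[active] <- 1   # degenerate all-zero training accuracy
  w <- w / sum(w)
  list(models = models, voting_weights = w, train_accuracy = train_acc)
}

.vote_score <- function(models, weights, selected, xrow_scaled) {
  s <- 0
  for (m in names(models)) {
    if (is.null(models[[m]])) next
    pr <- predict(models[[m]], xrow_scaled[, selected[[m]], drop = FALSE])
    s <- s + weights[m] * ifelse(pr$label == 1L, 1, -1)
  }
  s
}

#' Fit the M3 multimodal multiclassifier
#'
#' The full training procedure on one training set: z-score standardization,
#' per-modality two-sample-t feature selection at `p_threshold`, one
#' maximum-uncertainty LDA base classifier per modality, and fusion weights
#' for weighted voting. A modality whose selection is empty abstains (voting
#' weight 0); the remaining weights are renormalized to sum to 1. Fitting
#' fails only if every modality abstains.
#'
#' @param table A [feature_table()] (or a numeric matrix, in which case `y`
#'   and `feature_index` must be given).
#' @param p_threshold Selection threshold.
#' @param y,feature_index Labels and feature index when `table` is a matrix.
#' @param weight_rule `"train_accuracy"` (each base classifier's training
#'   accuracy, normalized to sum 1 — the convention adopted here) or
#'   `"uniform"`.
#' @return An object of class `m3`: `scaler`, `selection`, `base_models`,
#'   `voting_weights`, `feature_index`.
#' @export
m3 <- function(table, p_threshold = 0.05, y = NULL, feature_index = NULL,
               weight_rule = c("train_accuracy", "uniform")) {
  weight_rule <- match.arg(weight_rule)
  if (inherits(table, "feature_table")) {
    x <- table$x; y <- table$y; feature_index <- table$feature_index
  } else {
    x <- as.matrix(table)
    if (is.null(y) || is.null(feature_index))
      stop("m3: matrix input needs 'y' and 'feature_index'")
  }
  if (length(unique(y)) < 2) stop("m3: both classes must be present")
  scaler <- zscore_fit(x)
  xs <- zscore_apply(scaler, x)
  fi <- feature_index[scaler$keep, , drop = FALSE]
  sel <- select_features_ttest(xs, y, p_threshold, fi)
  bases <- .fit_bases(xs, y, sel$selected, weight_rule)
  structure(list(scaler = scaler, selection = sel,
                 base_models = bases$models,
                 voting_weights = bases$voting_weights,
                 train_accuracy = bases$train_accuracy,
                 feature_index = fi, feature_index_full = feature_index,
                 p_threshold = p_threshold, weight_rule = weight_rule),
            class = "m3")
}

#' @export
print.m3 <- function(x, ...) {
  cat(sprintf("m3 multiclassifier (P threshold %.3f)\n", x$p_threshold))
  for (m in names(x$base_models)) {
    k <- length(x$selection$selected[[m]])
    cat(sprintf("  %-5s: %3d features, voting weight %.3f%s\n", m, k,
                x$voting_weights[m], if (k == 0) " (abstains)" else ""))
  }
  invisible(x)
}

#' @export
summary.m3 <- function(object, ...) {
  out <- data.frame(
    modality = names(object$base_models),
    n_selected = vapply(object$selection$selected, length, 0L),
    train_accuracy = unname(object$train_accuracy),
    voting_weight = unname(object$voting_weights))
  structure(list(p_threshold = object$p_threshold,
                 weight_rule = object$weight_rule, bases = out),
            class = "summary.m3")
}

#' @export
print.summary.m3 <- function(x, ...) {
  cat(sprintf("m3 fit at P threshold %.3f (voting: %s)\n",
              x$p_threshold, x$weight_rule))
  print(x$bases, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
coef.m3 <- function(object, ...) {
  out <- lapply(names(object$base_models), function(m) {
    fit <- object$base_models[[m]]
    if (is.null(fit)) return(NULL)
    data.frame(modality = m,
               column = object$selection$selected[[m]],
               feature = object$feature_index$region_name[object$selection$selected[[m]]],
               coefficient = fit$weights, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Predict group membership with a fitted M3 model
#'
#' Each base classifier votes +1 (SZ) or -1 (HC); the continuous vote score
#' is the voting-weight-weighted sum, in `[-1, 1]`. The predicted label is
#' SZ (1) when the score is strictly positive, HC (0) otherwise — an exact
#' tie goes to HC.
#'
#' @param object An [m3()] fit.
#' @param newdata Matrix of rows in the model's original feature layout, or a
#'   [feature_table()].
#' @param ... Unused.
#' @return Data frame with `score` and `label`.
#' @export
predict.m3 <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "feature_table")) newdata$x else newdata
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(x) != object$scaler$p_original)
    stop("predict.m3: feature layout mismatch (expected ",
         object$scaler$p_original, " columns)")
  xs <- zscore_apply(object$scaler, x)
  score <- vapply(seq_len(nrow(xs)), function(i)
    .vote_score(object$base_models, object$voting_weights,
                object$selection$selected, xs[i, , drop = FALSE]), 0)
  data.frame(score = score, label = as.integer(score > 0))
}

#' Classification performance summary
#'
#' With SZ (1) the positive class: accuracy, sensitivity `TP/(TP+FN)`,
#' specificity `TN/(TN+FP)`, and the ROC AUC of the continuous score.
#'
#' @param truth,label Binary vectors.
#' @param score Continuous scores for the AUC (optional).
#' @return An object of class `m3_performance`.
#' @export
performance_summary <- function(truth, label, score = NULL) {
  truth <- as.integer(truth); label <- as.integer(label)
  tp <- sum(truth == 1 & label == 1); fn <- sum(truth == 1 & label == 0)
  tn <- sum(truth == 0 & label == 0); fp <- sum(truth == 0 & label == 1)
  structure(list(accuracy = (tp + tn) / length(truth),
                 sensitivity = tp / (tp + fn),
                 specificity = tn / (tn + fp),
                 auc = if (is.null(score)) NA_real_ else roc_auc(score, truth),
                 n = length(truth), n_sz = tp + fn, n_hc = tn + fp,
                 confusion = c(TP = tp, FN = fn, TN = tn, FP = fp)),
            class = "m3_performance")
}

#' @export
print.m3_performance <- function(x, ...) {
  cat(sprintf("accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%  AUC %s  (n = %d: %d SZ / %d HC)\n",
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity,
              ifelse(is.na(x$auc), "NA", sprintf("%.4f", x$auc)),
              x$n, x$n_sz, x$n_hc))
  invisible(x)
}

#' Leave-one-out cross-validation of the M3 procedure
#'
#' Each subject in turn is held out; standardization, feature selection,
#' base-classifier fitting and voting weights are recomputed from the
#' remaining subjects only, and the held-out subject is scored. A fold in
#' which every modality abstains (possible under permuted labels at strict
#' thresholds) is scored 0 — the tie rule, hence predicted HC — and counted
#' in `n_untrainable_folds`.
#'
#' @param table A [feature_table()].
#' @param p_threshold Selection threshold used in every fold.
#' @inheritParams m3
#' @return An object of class `m3_cv`: `predictions` (subject, truth, label,
#'   score), `folds` (per-fold selections, coefficients, voting weights),
#'   `performance` (an [performance_summary()]), `p_threshold`.
#' @export
m3_loocv <- function(table, p_threshold,
                     weight_rule = c("train_accuracy", "uniform")) {
  weight_rule <- match.arg(weight_rule)
  stopifnot(inherits(table, "feature_table"))
  n <- nrow(table$x)
  if (n < 4 || sum(table$y == 1) < 2 || sum(table$y == 0) < 2)
    stop("m3_loocv: need n >= 4 with at least 2 subjects per class")
  score <- numeric(n); label <- integer(n)
  folds <- vector("list", n)
  untrainable <- 0L
  for (i in seq_len(n)) {
    fit <- tryCatch(
      suppressWarnings(m3(table$x[-i, , drop = FALSE], p_threshold,
                          y = table$y[-i], feature_index = table$feature_index,
                          weight_rule = weight_rule)),
      error = function(e) NULL)
    if (is.null(fit)) {
      untrainable <- untrainable + 1L
      score[i] <- 0; label[i] <- 0L
      folds[[i]] <- list(selected = NULL, coefficients = NULL,
                         voting_weights = NULL)
      next
    }
    pr <- predict(fit, table$x[i, , drop = FALSE])
    score[i] <- pr$score; label[i] <- pr$label
    # map selected kept-column indices back to the original layout
    sel_orig <- lapply(fit$selection$selected,
                       function(s) fit$scaler$keep[s])
    coefs <- lapply(names(fit$base_models), function(m) {
      if (is.null(fit$base_models[[m]])) return(numeric(0))
      stats::setNames(fit$base_models[[m]]$weights,
                      as.character(sel_orig[[m]]))
    })
    names(coefs) <- names(fit$base_models)
    folds[[i]] <- list(selected = sel_orig, coefficients = coefs,
                       voting_weights = fit$voting_weights)
  }
  perf <- performance_summary(table$y, label, score)
  perf$optimal_p_threshold <- p_threshold
  structure(list(predictions = data.frame(subject_id = table$subject_ids,
                                          truth = table$y, label = label,
                                          score = score,
                                          stringsAsFactors = FALSE),
                 folds = folds, performance = perf,
                 p_threshold = p_threshold, weight_rule = weight_rule,
                 n_untrainable_folds = untrainable,
                 feature_index = table$feature_index),
            class = "m3_cv")
}

#' @export
print.m3_cv <- function(x, ...) {
  cat(sprintf("m3 LOOCV (%d folds, P threshold %.3f)\n",
              nrow(x$predictions), x$p_threshold))
  print(x$performance)
  if (x$n_untrainable_folds > 0)
    cat(sprintf("  %d untrainable fold(s) scored as HC\n", x$n_untrainable_folds))
  invisible(x)
}

#' Grid search of the selection P threshold under LOOCV
#'
#' Runs the full leave-one-out procedure at every threshold in `grid`
#' (default 0.001 to 0.050 in steps of 0.001 — 50 candidates) and returns
#' the threshold with the highest LOOCV accuracy, ties broken toward the
#' smallest threshold. Within each fold, standardization and the per-feature
#' t-tests are computed once and shared across thresholds, and base-
#' classifier fits are cached on the selected-feature set, which changes only
#' when the threshold crosses an observed P value.
#'
#' @param table A [feature_table()].
#' @param grid Ascending vector of thresholds in (0, 1).
#' @inheritParams m3
#' @return An object of class `m3_grid`: `curve` (threshold vs LOOCV
#'   accuracy), `optimal_p_threshold`, `cv` (the full [m3_loocv()] result at
#'   the optimum) and `performance`.
#' @export
m3_grid_search <- function(table, grid = default_p_grid(),
                           weight_rule = c("train_accuracy", "uniform")) {
  weight_rule <- match.arg(weight_rule)
  stopifnot(inherits(table, "feature_table"))
  if (!length(grid) || any(grid <= 0 | grid >= 1) || is.unsorted(grid))
    stop("m3_grid_search: grid must be ascending values in (0, 1)")
  n <- nrow(table$x); ng <- length(grid)
  labels <- matrix(NA_integer_, n, ng)
  scores <- matrix(NA_real_, n, ng)
  mods <- unique(table$feature_index$modality)
  for (i in seq_len(n)) {
    ytr <- table$y[-i]
    scaler <- suppressWarnings(zscore_fit(table$x[-i, , drop = FALSE]))
    xs <- zscore_apply(scaler, table$x[-i, , drop = FALSE])
    xte <- zscore_apply(scaler, table$x[i, , drop = FALSE])
    fi <- table$feature_index[scaler$keep, , drop = FALSE]
    tt <- .col_ttest(xs, ytr)
    modcols <- lapply(mods, function(m) which(fi$modality == m))
    names(modcols) <- mods
    cache <- new.env(parent = emptyenv())
    for (g in seq_len(ng)) {
      votes <- rep(NA_real_, length(mods)); names(votes) <- mods
      acc <- rep(NA_real_, length(mods)); names(acc) <- mods
      for (m in mods) {
        sel <- modcols[[m]][tt$p[modcols[[m]]] <= grid[g]]
        if (!length(sel)) next
        key <- paste(m, paste(sel, collapse = ","))
        ent <- cache[[key]]
        if (is.null(ent)) {
          fit <- mlda(xs[, sel, drop = FALSE], ytr)
          ent <- list(
            acc = mean(predict(fit, xs[, sel, drop = FALSE])$label == ytr),
            vote = ifelse(predict(fit, xte[, sel, drop = FALSE])$label == 1L,
                          1, -1))
          cache[[key]] <- ent
        }
        votes[m] <- ent$vote; acc[m] <- ent$acc
      }
      active <- !is.na(votes)
      if (!any(active)) { scores[i, g] <- 0; labels[i, g] <- 0L; next }
      w <- rep(0, length(mods))
      if (weight_rule == "uniform") w[active] <- 1 else w[active] <- acc[active]
      if (sum(w) == 0) w[active] <- 1
      w <- w / sum(w)
      s <- sum(w[active] * votes[active])
      scores[i, g] <- s; labels[i, g] <- as.integer(s > 0)
    }
  }
  accuracy <- colMeans(labels == table$y)
  best <- which.max(accuracy)          # first max = smallest threshold
  cv <- m3_loocv(table, grid[best], weight_rule = weight_rule)
  structure(list(curve = data.frame(p_threshold = grid, accuracy = accuracy),
                 optimal_p_threshold = grid[best],
                 cv = cv, performance = cv$performance,
                 labels = labels, scores = scores, grid = grid),
            class = "m3_grid")
}

#' Default selection-threshold grid
#'
#' Fifty candidate P thresholds, 0.001 to 0.050 in steps of 0.001.
#' @return Numeric vector of length 50.
#' @export
default_p_grid <- function() seq(0.001, 0.05, by = 0.001)

#' @export
print.m3_grid <- function(x, ...) {
  cat(sprintf("m3 threshold grid search (%d candidates)\n", length(x$grid)))
  cat(sprintf("optimal P threshold: %.3f\n", x$optimal_p_threshold))
  print(x$performance)
  invisible(x)
}

#' @export
plot.m3_grid <- function(x, ...) {
  graphics::plot(x$curve$p_threshold, 100 * x$curve$accuracy, type = "b",
                 pch = 16, cex = 0.6, xlab = "P threshold",
                 ylab = "LOOCV accuracy (%)", ...)
  graphics::abline(v = x$optimal_p_threshold, lty = 2)
  invisible(x)
}

#' Fold-aggregated feature weights
#'
#' For every base classifier and fold, the absolute discriminant coefficients
#' are normalized by their fold maximum and multiplied by that fold's voting
#' weight; features not selected in a fold contribute 0. These per-fold
#' weights are averaged over folds per modality and summed across the five
#' modalities per region. The "most discriminative" report is restricted to
#' regions whose feature was selected in every fold of at least one modality.
#'
#' @param cv An [m3_cv()] result.
#' @param table The [feature_table()] the CV was run on; used to attach the
#'   per-(region, modality) full-sample t statistic and P value.
#' @return An object of class `feature_weight_report`: `report` (qualifying
#'   regions, descending weight), `all_regions` (every region's weight) and
#'   `stats` (per region x modality t and P).
#' @export
compute_feature_weights <- function(cv, table = NULL) {
  stopifnot(inherits(cv, "m3_cv"))
  ok <- !vapply(cv$folds, function(f) is.null(f$selected), TRUE)
  if (!any(ok)) stop("compute_feature_weights: no trainable folds")
  folds <- cv$folds[ok]
  fi <- cv$feature_index
  mods <- unique(fi$modality)
  p <- nrow(fi)
  nf <- length(folds)
  wsum <- numeric(p)
  nsel <- matrix(0L, p, 1)
  for (f in folds) {
    for (m in mods) {
      sel <- f$selected[[m]]
      if (is.null(sel) || !length(sel)) next
      co <- f$coefficients[[m]]
      wnorm <- abs(co) / max(abs(co)) * f$voting_weights[[m]]
      wsum[sel] <- wsum[sel] + wnorm
      nsel[sel] <- nsel[sel] + 1L
    }
  }
  per_feature <- wsum / nf
  every_fold <- nsel == nf
  regions <- sort(unique(fi$region_label))
  agg <- function(v, fun) vapply(regions, function(r)
    fun(v[fi$region_label == r]), 0)
  region_weight <- agg(per_feature, sum)
  region_every <- vapply(regions, function(r)
    any(every_fold[fi$region_label == r]), TRUE)
  rn <- fi$region_name[match(regions, fi$region_label)]
  all_regions <- data.frame(region_label = regions, region_name = rn,
                            weight = region_weight,
                            appears_in_every_fold = region_every,
                            stringsAsFactors = FALSE)
  stats_df <- NULL
  if (!is.null(table)) {
    tt <- .col_ttest(table$x, table$y)
    stats_df <- cbind(table$feature_index,
                      data.frame(t = tt$t, p = tt$p))
  }
  rep_df <- all_regions[all_regions$appears_in_every_fold, , drop = FALSE]
  rep_df <- rep_df[order(-rep_df$weight), , drop = FALSE]
  rownames(rep_df) <- NULL
  structure(list(report = rep_df, all_regions = all_regions,
                 stats = stats_df, n_folds = nf,
                 p_threshold = cv$p_threshold),
            class = "feature_weight_report")
}

#' @export
print.feature_weight_report <- function(x, n = 10, ...) {
  cat(sprintf("feature weights over %d LOOCV folds (P threshold %.3f)\n",
              x$n_folds, x$p_threshold))
  print(utils::head(x$report, n))
  invisible(x)
}
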