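#' Experiment arm descriptor
#'
#' One preprocessing arm of a model-comparison experiment: an atlas and a
#' global-signal-regression setting, labelled `<atlas>_<GSR|noGSR>`.
#'
#' @param atlas_id Atlas name, e.g. `"BN-246"`.
#' @param gsr Whether the arm's features were computed with global signal
#'   regression.
#' @return An object of class `experiment_arm`.
#' @export
experiment_arm <- function(atlas_id, gsr = FALSE) {
  structure(list(atlas_id = atlas_id, gsr = isTRUE(gsr),
                 label = paste0(atlas_id, "_", if (isTRUE(gsr)) "GSR" else "noGSR")),
            class = "experiment_arm")
}

#' Run a multi-arm classification experiment
#'
#' For each arm: grid search of the selection threshold under LOOCV and,
#' optionally, a label-permutation test of the resulting accuracy. For each
#' requested pair of arms the vote scores at each arm's optimal threshold
#' are compared with the DeLong test (the arms must hold the same subjects
#' in the same order). All randomness derives from `seed`, split
#' deterministically per arm.
#'
#' @param arms List of [experiment_arm()] descriptors.
#' @param tables List of [feature_table()] objects, one per arm, same order.
#' @param grid Threshold grid.
#' @param n_perm Permutations for the accuracy test; 0 skips it.
#' @param seed Root seed.
#' @param pairs `"all"` for every pair of arms, a 2-column matrix of arm
#'   indices, or `NULL` for none.
#' @param perm_p_threshold Fixed threshold used inside permutations (the
#'   observed statistic still comes from the full grid search); `NULL`
#'   grid-searches inside each permutation.
#' @inheritParams m3
#' @return An object of class `m3_experiment`: `summary` (one row per arm:
#'   optimal threshold, AUC, accuracy/sensitivity/specificity in percent,
#'   permutation p), `comparisons` (pairwise DeLong results), `fits` (per-arm
#'   [m3_grid_search()] results) and `manifest`.
#' @export
run_experiment <- function(arms, tables, grid = default_p_grid(), n_perm = 0,
                           seed = 1L, pairs = "all", perm_p_threshold = NULL,
                           weight_rule = c("train_accuracy", "uniform")) {
  weight_rule <- match.arg(weight_rule)
  if (!length(arms)) stop("run_experiment: need at least one arm")
  if (length(arms) != length(tables))
    stop("run_experiment: one feature table per arm required")
  labels <- vapply(arms, function(a) a$label, "")
  fits <- vector("list", length(arms)); names(fits) <- labels
  perm_p <- rep(NA_real_, length(arms))
  for (k in seq_along(arms)) {
    fits[[k]] <- m3_grid_search(tables[[k]], grid, weight_rule = weight_rule)
    if (n_perm > 0) {
      thr <- if (is.null(perm_p_threshold)) fits[[k]]$optimal_p_threshold
             else perm_p_threshold
      pt <- permutation_test_accuracy(tables[[k]], p_threshold = thr,
                                      n_perm = n_perm,
                                      seed = seed + 1000L * k,
                                      weight_rule = weight_rule)
      # compare permuted accuracies against the grid-search observed accuracy
      perm_p[k] <- mean(pt$permuted >= fits[[k]]$performance$accuracy)
    }
  }
  summary_df <- data.frame(
    arm = labels,
    optimal_p_threshold = vapply(fits, function(f) f$optimal_p_threshold, 0),
    auc = vapply(fits, function(f) f$performance$auc, 0),
    accuracy_pct = 100 * vapply(fits, function(f) f$performance$accuracy, 0),
    sensitivity_pct = 100 * vapply(fits, function(f) f$performance$sensitivity, 0),
    specificity_pct = 100 * vapply(fits, function(f) f$performance$specificity, 0),
    perm_p = perm_p, stringsAsFactors = FALSE)
  comparisons <- NULL
  if (!is.null(pairs) && length(arms) > 1) {
    if (identical(pairs, "all")) pairs <- t(utils::combn(length(arms), 2))
    rows <- vector("list", nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      ti <- tables[[i]]; tj <- tables[[j]]
      if (!identical(ti$subject_ids, tj$subject_ids) ||
          !identical(ti$y, tj$y))
        stop("run_experiment: arms ", labels[i], " and ", labels[j],
             " do not share subjects; DeLong comparison undefined")
      dl <- delong_test(fits[[i]]$cv$predictions$score,
                        fits[[j]]$cv$predictions$score, ti$y)
      rows[[r]] <- data.frame(arm1 = labels[i], arm2 = labels[j],
                              auc1 = dl$auc1, auc2 = dl$auc2, z = dl$z,
                              p_value = dl$p_value, stringsAsFactors = FALSE)
    }
    comparisons <- do.call(rbind, rows)
  }
  structure(list(summary = summary_df, comparisons = comparisons, fits = fits,
                 manifest = list(seed = seed, n_perm = n_perm, grid = grid,
                                 weight_rule = weight_rule,
                                 arms = labels,
                                 timestamp = format(Sys.time(), tz = "UTC"),
                                 version = as.character(utils::packageVersion("m3class")))),
            class = "m3_experiment")
}

#' @export
print.m3_experiment <- function(x, ...) {
  cat("M3 experiment\n")
  print(x$summary, digits = 4, row.names = FALSE)
  if (!is.null(x$comparisons)) {
    cat("pairwise DeLong comparisons:\n")
    print(x$comparisons, digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Table of the most discriminative regions
#'
#' Formats the top `top_k` regions of a [compute_feature_weights()] report:
#' one row per region, per-modality cells `t (P)` — or `"NS"` when the
#' full-sample P exceeds the optimal selection threshold — plus the final
#' weight, in descending weight order.
#'
#' @param report A `feature_weight_report`.
#' @param top_k Number of regions to report (default 15).
#' @param p_threshold Significance cut for the `NS` marker; defaults to the
#'   threshold the CV was run at.
#' @return Data frame, one row per region.
#' @export
report_discriminative_regions <- function(report, top_k = 15,
                                          p_threshold = NULL) {
  stopifnot(inherits(report, "feature_weight_report"))
  if (!nrow(report$report)) stop("report_discriminative_regions: empty report")
  if (is.null(p_threshold)) p_threshold <- report$p_threshold
  k <- min(top_k, nrow(report$report))
  if (top_k > nrow(report$report))
    warning("report_discriminative_regions: only ", nrow(report$report),
            " qualifying regions available")
  top <- report$report[seq_len(k), , drop = FALSE]
  out <- data.frame(region = top$region_name, stringsAsFactors = FALSE)
  if (!is.null(report$stats)) {
    for (m in unique(report$stats$modality)) {
      sm <- report$stats[report$stats$modality == m, , drop = FALSE]
      row <- match(top$region_label, sm$region_label)
      cell <- ifelse(sm$p[row] <= p_threshold,
                     sprintf("%.2f (%.3g)", sm$t[row], sm$p[row]), "NS")
      out[[m]] <- cell
    }
  }
  out$weight <- top$weight
  out
}
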