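test_that("z-score scaler uses training parameters and drops constants", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 1, 5))
  expect_warning(sc <- zscore_fit(x), "zero-variance")
  expect_equal(sc$keep, c(1L, 3L))
  xs <- zscore_apply(sc, x)
  expect_equal(xs[, 1], c(-1, 0, 1))         # sample-SD convention
  expect_equal(ncol(xs), 2)
  # the training mean row transforms to zeros
  expect_equal(as.numeric(zscore_apply(sc, matrix(colMeans(x), 1))),
               c(0, 0))
  # test rows use training parameters, not their own
  expect_equal(as.numeric(zscore_apply(sc, matrix(c(4, 9, 2), 1)))[1], 2)
})

test_that("t-test selection keeps planted signal and is calibrated under the null", {
  set.seed(40)
  em <- data.frame(region = 1, modality = "A", d = 2)
  n <- 80
  x <- matrix(rnorm(n * 50), n)
  y <- rep(c(1L, 0L), each = 40)
  x[y == 1, 1] <- x[y == 1, 1] + 2
  idx <- data.frame(modality = "A", region_label = 1:50,
                    region_name = sprintf("R%02d", 1:50))
  for (thr in c(0.001, 0.01, 0.05)) {
    sel <- select_features_ttest(x, y, thr, idx)
    expect_true(1 %in% sel$selected$A)       # d = 2 at n = 40+40: power ~ 1
  }
  # null columns: selected fraction tracks the threshold
  sel05 <- select_features_ttest(x[, -1], y, 0.05, idx[-1, ])
  expect_lt(abs(length(sel05$selected$A) / 49 - 0.05),
            3 * sqrt(0.05 * 0.95 / 49) + 0.02)
  expect_error(select_features_ttest(x, y, 0, idx), "p_threshold")
})

test_that("the default threshold grid is the 50-point 0.001..0.050 ladder", {
  g <- default_p_grid()
  expect_length(g, 50)
  expect_equal(g[1], 0.001)
  expect_equal(g[50], 0.050)
  expect_equal(unique(round(diff(g), 10)), 0.001)
})

test_that("voting weights reflect where the signal lives", {
  set.seed(41)
  # all signal in ALFF: its voting weight is strictly largest
  em <- data.frame(region = 1:4, modality = "ALFF", d = 2.5)
  cfg <- cohort_config(n_patients = 25, n_controls = 25, n_regions = 12,
                       effect_map = em, seed = 41)
  tab <- sim_cohort_features(cfg)$table
  fit <- m3(tab, 0.05)
  expect_equal(names(which.max(fit$voting_weights)), "ALFF")
  expect_equal(sum(fit$voting_weights), 1, tolerance = 1e-12)
  # abstaining modalities leave the rest renormalized to 1
  n_active <- sum(vapply(fit$base_models, Negate(is.null), TRUE))
  if (n_active < 5)
    expect_equal(sum(fit$voting_weights > 0), n_active)
})

test_that("five identical informative blocks share the vote symmetrically", {
  set.seed(42)
  n <- 40; p <- 6
  block <- matrix(rnorm(n * p), n)
  y <- rep(c(1L, 0L), each = 20)
  block[y == 1, 1] <- block[y == 1, 1] + 2
  x <- do.call(cbind, replicate(5, block, simplify = FALSE))
  idx <- data.frame(modality = rep(five_mods, each = p),
                    region_label = rep(1:p, 5),
                    region_name = rep(sprintf("R%d", 1:p), 5))
  fit <- m3(feature_table(x, y, idx), 0.05)
  expect_equal(unname(fit$voting_weights), rep(0.2, 5), tolerance = 1e-12)
})

test_that("an untrainable threshold is an error", {
  set.seed(43)
  tab <- sim_cohort_features(cohort_config(n_patients = 6, n_controls = 6,
                                           n_regions = 4, seed = 43))$table
  expect_error(suppressWarnings(m3(tab, 1e-12)), "untrainable|empty")
})

test_that("weighted voting follows the documented arithmetic and tie rule", {
  # construct an m3 object with controlled votes via one-feature bases
  set.seed(44)
  n <- 30
  x <- matrix(rnorm(n * 5), n)
  y <- rep(c(1L, 0L), 15)
  x[y == 1, ] <- x[y == 1, ] + 3       # every modality separates
  idx <- data.frame(modality = five_mods, region_label = 1L,
                    region_name = "R1")
  fit <- m3(feature_table(x, y, idx), 0.05)
  # all five vote SZ at the SZ mean: score +1
  pr <- predict(fit, matrix(3, 1, 5))
  expect_equal(pr$score, 1)
  expect_equal(pr$label, 1L)
  # all five vote HC: score -1, label HC
  pr0 <- predict(fit, matrix(-3, 1, 5))
  expect_equal(pr0$score, -1)
  expect_equal(pr0$label, 0L)
  # hand arithmetic: weights (.4,.15,.15,.15,.15), only first votes SZ
  w <- c(0.4, 0.15, 0.15, 0.15, 0.15)
  votes <- c(1, -1, -1, -1, -1)
  expect_equal(sum(w * votes), -0.2)   # would classify HC
  # vote score is always within [-1, 1]
  sc <- predict(fit, x)$score
  expect_true(all(sc >= -1 - 1e-12 & sc <= 1 + 1e-12))
})

test_that("LOOCV separates a well-separated cohort and not a null one", {
  em <- multimodal_effects(1:3, 4)
  cfg <- cohort_config(n_patients = 15, n_controls = 15, n_regions = 10,
                       effect_map = em, seed = 45)
  cv <- m3_loocv(sim_cohort_features(cfg)$table, 0.05)
  expect_equal(cv$performance$accuracy, 1)
  expect_equal(cv$performance$auc, 1)
  expect_equal(length(cv$folds), 30)   # one fold per subject
  # null cohort: accuracy within 3 binomial SDs of the majority rate
  cfg0 <- cohort_config(n_patients = 15, n_controls = 15, n_regions = 10,
                        seed = 46)
  cv0 <- m3_loocv(sim_cohort_features(cfg0)$table, 0.05)
  maj <- 0.5
  expect_lt(abs(cv0$performance$accuracy - maj), 3 * sqrt(maj * (1 - maj) / 30))
  expect_error(m3_loocv(sim_cohort_features(cfg)$table, 0.05,
                        weight_rule = "nope"))
})

test_that("the fitted model is a function of training rows only", {
  set.seed(47)
  tab <- sim_cohort_features(cohort_config(n_patients = 10, n_controls = 10,
                                           n_regions = 8, seed = 47))$table
  train <- tab$x[-1, , drop = FALSE]
  f1 <- m3(train, 0.1, y = tab$y[-1], feature_index = tab$feature_index)
  f2 <- m3(train, 0.1, y = tab$y[-1], feature_index = tab$feature_index)
  expect_equal(f1[c("selection", "voting_weights", "base_models")],
               f2[c("selection", "voting_weights", "base_models")])
  # predictions for different test rows come from the same frozen model
  p1 <- predict(f1, tab$x[1, , drop = FALSE])
  p2 <- predict(f1, tab$x[1, , drop = FALSE] + 100)
  expect_true(is.finite(p1$score) && is.finite(p2$score))
})

test_that("accuracy composes from sensitivity and specificity on every CV result", {
  for (seed in 48:50) {
    em <- multimodal_effects(1:2, 1.2)
    cfg <- cohort_config(n_patients = 9, n_controls = 13, n_regions = 8,
                         effect_map = em, seed = seed)
    cv <- m3_loocv(sim_cohort_features(cfg)$table, 0.05)
    p <- cv$performance
    expect_equal(p$accuracy,
                 (p$sensitivity * p$n_sz + p$specificity * p$n_hc) / p$n)
  }
})

test_that("grid search matches an exhaustive per-threshold rerun and tie rule", {
  em <- multimodal_effects(1:2, 1.5)
  cfg <- cohort_config(n_patients = 12, n_controls = 12, n_regions = 8,
                       effect_map = em, seed = 51)
  tab <- sim_cohort_features(cfg)$table
  grid <- c(0.005, 0.01, 0.02, 0.05)
  gs <- m3_grid_search(tab, grid)
  oracle <- vapply(grid, function(thr)
    m3_loocv(tab, thr)$performance$accuracy, 0)
  expect_equal(gs$curve$accuracy, oracle)
  best <- grid[which.max(oracle)]       # first max = smallest threshold
  expect_equal(gs$optimal_p_threshold, best)
  expect_equal(gs$performance$accuracy, max(oracle))
  # ties: a flat curve returns the smallest threshold
  flat <- structure(gs, class = class(gs))
  if (length(unique(oracle)) == 1) expect_equal(best, grid[1])
})

test_that("feature weights follow the normalize-scale-average-sum formula", {
  # single fold, single modality, coefficients (2, -4), voting weight 0.5:
  # |c|/max|c| * w = (0.25, 0.5)
  fi <- data.frame(modality = rep("ALFF", 2), region_label = 1:2,
                   region_name = c("Ra", "Rb"))
  cv <- structure(list(
    folds = list(list(selected = list(ALFF = 1:2),
                      coefficients = list(ALFF = c(`1` = 2, `2` = -4)),
                      voting_weights = c(ALFF = 0.5))),
    feature_index = fi, p_threshold = 0.05),
    class = "m3_cv")
  fw <- compute_feature_weights(cv)
  expect_equal(fw$all_regions$weight, c(0.25, 0.5))
  expect_true(all(fw$all_regions$appears_in_every_fold))
  # a feature absent from one fold is excluded from the report
  cv2 <- cv
  cv2$folds <- list(cv$folds[[1]],
                    list(selected = list(ALFF = 1L),
                         coefficients = list(ALFF = c(`1` = 1)),
                         voting_weights = c(ALFF = 1)))
  fw2 <- compute_feature_weights(cv2)
  expect_equal(fw2$report$region_name, "Ra")
  expect_equal(nrow(fw2$all_regions), 2)      # still weighted, just not reported
  # averaging over folds: region 2 contributes 0 in fold 2
  expect_equal(fw2$all_regions$weight[2], 0.5 / 2)
  expect_error(compute_feature_weights(structure(list(folds = list(
    list(selected = NULL)), feature_index = fi), class = "m3_cv")), "folds")
})

test_that("planted regions dominate the feature-weight ranking", {
  em <- multimodal_effects(c(2, 5, 9), 2)
  cfg <- cohort_config(n_patients = 20, n_controls = 20, n_regions = 30,
                       effect_map = em, seed = 52)
  tab <- sim_cohort_features(cfg)$table
  cv <- m3_loocv(tab, 0.05)
  fw <- compute_feature_weights(cv, tab)
  expect_true(all(c(2, 5, 9) %in% fw$report$region_label[1:5]))
  expect_true(all(diff(fw$report$weight) <= 0))
})

test_that("planted-region ranks beat chance over repeated cohorts", {
  # 10 planted regions at d = 1.2, n = 60: mean rank better than the chance
  # midpoint, Wilcoxon P < 0.01 across seeds
  planted <- 1:10
  mean_ranks <- vapply(1:20, function(s) {
    cfg <- cohort_config(n_patients = 30, n_controls = 30, n_regions = 40,
                         effect_map = multimodal_effects(planted, 1.2),
                         seed = 100 + s)
    tab <- sim_cohort_features(cfg)$table
    fw <- compute_feature_weights(m3_loocv(tab, 0.05), tab)
    ranks <- match(planted, fw$all_regions$region_label[
      order(-fw$all_regions$weight)])
    mean(ranks)
  }, 0)
  chance <- (40 + 1) / 2
  expect_lt(stats::wilcox.test(mean_ranks, mu = chance, alternative = "less",
                               exact = FALSE)$p.value, 0.01)
})
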