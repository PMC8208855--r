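#' Cohort simulation configuration
#'
#' Describes a two-group cohort (patients vs controls) with per-modality
#' feature blocks over a common set of regions, planted group effects, and
#' an exchangeable within-modality correlation structure.
#'
#' @param n_patients,n_controls Group sizes (each >= 2).
#' @param n_regions Number of regions per modality block.
#' @param modalities Character vector of modality names. The default is the
#'   five-block layout used throughout the package: ALFF, ReHo, DC, VMHC, GMD.
#' @param effect_map Data frame with columns `region` (integer label),
#'   `modality` (name) and `d` (Cohen's d of the planted mean shift), or
#'   `NULL` for a null cohort.
#' @param within_modality_corr Exchangeable correlation among columns of one
#'   modality block, in `[0, 1)`.
#' @param noise_sd Marginal standard deviation of every feature column.
#' @param seed Integer seed; identical seed and config give bit-identical
#'   tables.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 45L, n_controls = 64L, n_regions = 246L,
                          modalities = c("ALFF", "ReHo", "DC", "VMHC", "GMD"),
                          effect_map = NULL, within_modality_corr = 0.3,
                          noise_sd = 1, seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 2)
    stop("cohort_config: 'n_patients' must be >= 2")
  if (!is.numeric(n_controls) || n_controls < 2)
    stop("cohort_config: 'n_controls' must be >= 2")
  if (!is.numeric(n_regions) || n_regions < 1)
    stop("cohort_config: 'n_regions' must be >= 1")
  if (!is.character(modalities) || length(modalities) < 1 || anyDuplicated(modalities))
    stop("cohort_config: 'modalities' must be distinct names")
  if (!is.numeric(within_modality_corr) || within_modality_corr < 0 ||
      within_modality_corr >= 1)
    stop("cohort_config: 'within_modality_corr' must lie in [0, 1)")
  if (!is.numeric(noise_sd) || noise_sd <= 0)
    stop("cohort_config: 'noise_sd' must be positive")
  if (!is.null(effect_map)) {
    effect_map <- as.data.frame(effect_map)
    need <- c("region", "modality", "d")
    if (!all(need %in% names(effect_map)))
      stop("cohort_config: 'effect_map' needs columns region, modality, d")
    if (any(!is.finite(effect_map$d)))
      stop("cohort_config: 'effect_map' d values must be finite")
    if (any(!effect_map$modality %in% modalities))
      stop("cohort_config: 'effect_map' names a modality not in 'modalities'")
    if (any(effect_map$region < 1 | effect_map$region > n_regions))
      stop("cohort_config: 'effect_map' region out of 1..n_regions")
  }
  structure(list(n_patients = as.integer(n_patients),
                 n_controls = as.integer(n_controls),
                 n_regions = as.integer(n_regions),
                 modalities = modalities, effect_map = effect_map,
                 within_modality_corr = within_modality_corr,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Read a cohort configuration from YAML
#'
#' Field names in the YAML file mirror the arguments of [cohort_config()];
#' `effect_map` is a list of `{region, modality, d}` mappings.
#'
#' @param path Path to a YAML file.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$effect_map))
    raw$effect_map <- do.call(rbind, lapply(raw$effect_map, as.data.frame))
  do.call(cohort_config, raw)
}

#' Simulate a subject-by-feature table with planted group effects
#'
#' Features are multivariate normal within each modality block with an
#' exchangeable correlation, standardized to unit marginal variance and then
#' scaled by `noise_sd`. A planted effect `(region, modality, d)` shifts the
#' patient group by `d` marginal (hence pooled) standard deviations, so
#' Cohen's d is the single effect parameter.
#'
#' @param config A [cohort_config()].
#' @return A list with elements `table` (a [feature_table()]) and `truth`
#'   (the effect map actually planted, possibly `NULL`).
#' @export
sim_cohort_features <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n1 <- config$n_patients; n0 <- config$n_controls; n <- n1 + n0
  p <- config$n_regions; rho <- config$within_modality_corr
  # patients first, then controls; SZ = 1, HC = 0
  y <- c(rep(1L, n1), rep(0L, n0))
  ids <- sprintf("sub-%03d", seq_len(n))
  blocks <- vector("list", length(config$modalities))
  names(blocks) <- config$modalities
  for (m in config$modalities) {
    shared <- rnorm(n)
    eps <- matrix(rnorm(n * p), n, p)
    x <- sqrt(rho) * shared + sqrt(1 - rho) * eps   # unit variance, corr rho
    if (!is.null(config$effect_map)) {
      em <- config$effect_map[config$effect_map$modality == m, , drop = FALSE]
      if (nrow(em)) {
        for (k in seq_len(nrow(em)))
          x[y == 1L, em$region[k]] <- x[y == 1L, em$region[k]] + em$d[k]
      }
    }
    blocks[[m]] <- x * config$noise_sd
  }
  x <- do.call(cbind, blocks)
  idx <- data.frame(
    modality = rep(config$modalities, each = p),
    region_label = rep.int(seq_len(p), length(config$modalities)),
    region_name = rep.int(sprintf("R%03d", seq_len(p)), length(config$modalities)),
    stringsAsFactors = FALSE)
  tab <- feature_table(x, y, idx, subject_ids = ids)
  list(table = tab, truth = config$effect_map)
}

#' Image simulation configuration
#'
#' @param grid_shape Three spatial extents in voxels.
#' @param n_volumes Number of time points (> 10).
#' @param tr_seconds Repetition time in seconds.
#' @param n_atlas_labels Number of atlas regions tiling the mask.
#' @param signal_bands List of `c(freq_hz, amplitude)` pairs; region `k`
#'   receives the band `((k - 1) %% length(signal_bands)) + 1`.
#' @param motion_amplitude Peak absolute excursion of the simulated motion
#'   parameters, in mm (translations) / degrees (rotations).
#' @param noise_sd Standard deviation of i.i.d. voxel noise added on top of
#'   the deterministic band signal.
#' @param symmetric When `TRUE` the noise-free signal is mirror-symmetric in
#'   the first spatial axis (requires an even x extent).
#' @param seed Integer seed.
#' @return An object of class `image_sim_config`.
#' @export
image_sim_config <- function(grid_shape = c(12L, 12L, 6L), n_volumes = 60L,
                             tr_seconds = 2, n_atlas_labels = 4L,
                             signal_bands = list(c(0.05, 1)),
                             motion_amplitude = 0.2, noise_sd = 0.1,
                             symmetric = TRUE, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 2))
    stop("image_sim_config: 'grid_shape' must be 3 extents >= 2")
  if (symmetric && grid_shape[1] %% 2 != 0)
    stop("image_sim_config: symmetric images need an even x extent")
  if (n_volumes <= 10) stop("image_sim_config: 'n_volumes' must exceed 10")
  if (tr_seconds <= 0) stop("image_sim_config: 'tr_seconds' must be positive")
  if (n_atlas_labels < 1 || n_atlas_labels > prod(grid_shape))
    stop("image_sim_config: 'n_atlas_labels' out of range")
  structure(list(grid_shape = grid_shape, n_volumes = as.integer(n_volumes),
                 tr_seconds = tr_seconds,
                 n_atlas_labels = as.integer(n_atlas_labels),
                 signal_bands = signal_bands,
                 motion_amplitude = motion_amplitude, noise_sd = noise_sd,
                 symmetric = isTRUE(symmetric), seed = as.integer(seed)),
            class = "image_sim_config")
}

#' Simulate a 4D time-series image with a toy atlas and motion parameters
#'
#' Every atlas region carries a sinusoid from `signal_bands` (random phase
#' per region) plus i.i.d. Gaussian noise. Under `symmetric = TRUE` the atlas
#' and the noise-free signal are mirror images across the first axis, so
#' homotopic correlations are exactly 1 at zero noise. Motion parameters are
#' smooth random walks rescaled to `motion_amplitude`.
#'
#' @param config An [image_sim_config()].
#' @return A list with `img` (a [ts_image()]), `atlas` (an [atlas()]) and
#'   `motion` (an `n_volumes` x 6 matrix).
#' @export
sim_timeseries_image <- function(config) {
  stopifnot(inherits(config, "image_sim_config"))
  set.seed(config$seed)
  g <- config$grid_shape; tt <- config$n_volumes; tr <- config$tr_seconds
  nx <- g[1]
  time <- (seq_len(tt) - 1) * tr
  # atlas: tile labels over voxels; under symmetry, label by canonical
  # (left-half) x so each voxel and its mirror share a label
  xi <- slice.index(array(0, g), 1)
  xc <- if (config$symmetric) pmin(xi, nx + 1L - xi) else xi
  lin <- (xc - 1) +
    (slice.index(array(0, g), 2) - 1) * nx +
    (slice.index(array(0, g), 3) - 1) * nx * g[2]
  labels <- array(as.integer(lin %% config$n_atlas_labels) + 1L, g)
  nb <- length(config$signal_bands)
  phases <- runif(config$n_atlas_labels, 0, 2 * pi)
  region_ts <- sapply(seq_len(config$n_atlas_labels), function(k) {
    band <- config$signal_bands[[((k - 1) %% nb) + 1]]
    band[2] * sin(2 * pi * band[1] * time + phases[k])
  })                                               # tt x n_labels
  data <- array(0, c(g, tt))
  flat <- matrix(region_ts[, as.vector(labels)], nrow = tt)  # tt x nvox
  if (config$noise_sd > 0)
    flat <- flat + matrix(rnorm(length(flat), sd = config$noise_sd), nrow = tt)
  data[] <- t(flat)
  img <- ts_image(data, tr_seconds = tr, mask = array(TRUE, g))
  lut <- data.frame(label = seq_len(config$n_atlas_labels),
                    name = sprintf("region_%02d", seq_len(config$n_atlas_labels)),
                    stringsAsFactors = FALSE)
  atl <- atlas(labels, lut)
  walk <- apply(matrix(rnorm(tt * 6), tt, 6), 2, cumsum)
  motion <- walk / max(abs(walk)) * config$motion_amplitude
  colnames(motion) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  list(img = img, atlas = atl, motion = motion)
}

#' Simulate a demographics table with exact group age moments
#'
#' Ages are drawn normal and then affinely rescaled within each group so the
#' sample mean and SD match the request exactly; two-sample statistics on the
#' result are therefore deterministic.
#'
#' @param n1,n2 Group sizes (group 1 = patients, group 2 = controls).
#' @param sex_split List of two `c(male, female)` count pairs.
#' @param age_params List of two `c(mean, sd)` pairs.
#' @param seed Integer seed.
#' @return Data frame with columns `subject_id`, `group` (SZ/HC), `sex`, `age`.
#' @export
sim_demographics <- function(n1, n2, sex_split, age_params, seed = 1L) {
  if (sum(sex_split[[1]]) != n1 || sum(sex_split[[2]]) != n2)
    stop("sim_demographics: sex_split counts inconsistent with n1/n2")
  set.seed(seed)
  mk_age <- function(n, mu, sd) {
    a <- rnorm(n)
    (a - mean(a)) / stats::sd(a) * sd + mu
  }
  data.frame(
    subject_id = sprintf("sub-%03d", seq_len(n1 + n2)),
    group = rep(c("SZ", "HC"), c(n1, n2)),
    sex = c(rep(c("M", "F"), sex_split[[1]]), rep(c("M", "F"), sex_split[[2]])),
    age = c(mk_age(n1, age_params[[1]][1], age_params[[1]][2]),
            mk_age(n2, age_params[[2]][1], age_params[[2]][2])),
    stringsAsFactors = FALSE)
}
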