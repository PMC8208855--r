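#' Integer-label parcellation atlas
#'
#' @param labels 3D integer array; 0 is background.
#' @param lut Data frame with columns `label` and `name` covering every
#'   nonzero label.
#' @return An object of class `atlas`.
#' @export
atlas <- function(labels, lut) {
  if (length(dim(labels)) != 3L) stop("atlas: 'labels' must be 3D")
  if (any(labels < 0)) stop("atlas: labels must be nonnegative")
  lut <- as.data.frame(lut)
  if (!all(c("label", "name") %in% names(lut)))
    stop("atlas: lut needs columns 'label' and 'name'")
  present <- sort(unique(labels[labels > 0]))
  missing <- setdiff(present, lut$label)
  if (length(missing))
    stop("atlas: labels without a name in lut: ", paste(missing, collapse = ", "))
  structure(list(labels = array(as.integer(labels), dim(labels)),
                 lut = lut[lut$label %in% present, , drop = FALSE],
                 n_regions = length(present)),
            class = "atlas")
}

#' @export
print.atlas <- function(x, ...) {
  cat(sprintf("atlas: %s grid, %d regions\n",
              paste(dim(x$labels), collapse = " x "), x$n_regions))
  invisible(x)
}

#' ROI-mean feature extraction
#'
#' Reduces a set of voxelwise maps (one per modality) to one value per
#' (modality, region): the mean over voxels carrying that atlas label and,
#' when a mask is supplied, lying inside it. Ordering is modality-major with
#' regions in ascending label order, so the feature layout is identical for
#' every subject.
#'
#' @param maps Named list of [metric_map()] objects or 3D arrays; names are
#'   the modalities, in the order the feature vector should use.
#' @param atl An [atlas()] on the same grid.
#' @param mask Optional 3D logical analysis mask; defaults to each map's own
#'   mask when the map is a `metric_map`.
#' @return List with `features` (numeric vector, named
#'   `<modality>__<region_name>`) and `feature_index` (data frame with
#'   modality, region_label, region_name).
#' @export
extract_roi_features <- function(maps, atl, mask = NULL) {
  stopifnot(inherits(atl, "atlas"))
  if (is.null(names(maps)) || any(!nzchar(names(maps))))
    stop("extract_roi_features: 'maps' must be a named list (modalities)")
  labs <- sort(atl$lut$label)
  nm <- atl$lut$name[match(labs, atl$lut$label)]
  out <- vector("list", length(maps))
  for (i in seq_along(maps)) {
    m <- maps[[i]]
    vals <- if (inherits(m, "metric_map")) m$values else m
    if (!identical(dim(vals), dim(atl$labels)))
      stop("extract_roi_features: map and atlas grids differ for modality ",
           names(maps)[i])
    use <- atl$labels > 0
    if (!is.null(mask)) use <- use & mask
    else if (inherits(m, "metric_map")) use <- use & m$mask
    lv <- atl$labels[use]
    mv <- vals[use]
    sums <- tapply(mv, factor(lv, levels = labs), mean)
    empty <- labs[is.na(sums)]
    if (length(empty))
      stop("extract_roi_features: region(s) with no in-mask voxels for ",
           names(maps)[i], ": ", paste(empty, collapse = ", "))
    out[[i]] <- as.numeric(sums)
  }
  idx <- data.frame(modality = rep(names(maps), each = length(labs)),
                    region_label = rep.int(labs, length(maps)),
                    region_name = rep.int(nm, length(maps)),
                    stringsAsFactors = FALSE)
  feats <- unlist(out)
  names(feats) <- paste0(idx$modality, "__", idx$region_name)
  list(features = feats, feature_index = idx)
}

#' Subjects-by-features table
#'
#' The unit object of the classification pipeline: a numeric matrix of
#' subjects by (modality, region) features, binary group labels (SZ = 1,
#' HC = 0), and the feature index that gives each column its identity.
#'
#' @param x Numeric matrix, subjects in rows.
#' @param y Binary labels, 1 = patient (SZ), 0 = control (HC).
#' @param feature_index Data frame with columns modality, region_label,
#'   region_name, one row per column of `x`.
#' @param subject_ids Optional character ids; defaults to `sub-001`, ...
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(x, y, feature_index, subject_ids = NULL) {
  x <- as.matrix(x)
  if (anyNA(x) || any(!is.finite(x))) stop("feature_table: missing values")
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop("feature_table: label length mismatch")
  if (!all(y %in% c(0L, 1L))) stop("feature_table: labels must be 0/1")
  feature_index <- as.data.frame(feature_index)
  if (nrow(feature_index) != ncol(x))
    stop("feature_table: feature_index rows must match columns of x")
  if (is.null(subject_ids)) subject_ids <- sprintf("sub-%03d", seq_len(nrow(x)))
  colnames(x) <- paste0(feature_index$modality, "__", feature_index$region_name)
  rownames(x) <- subject_ids
  structure(list(x = x, y = y, feature_index = feature_index,
                 subject_ids = subject_ids),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d subjects (%d SZ / %d HC) x %d features (%s)\n",
              nrow(x$x), sum(x$y == 1), sum(x$y == 0), ncol(x$x),
              paste(unique(x$feature_index$modality), collapse = ", ")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$x)

#' Assemble per-subject feature vectors into a table
#'
#' @param vectors List of outputs of [extract_roi_features()] (or numeric
#'   vectors sharing one layout), one per subject, in row order.
#' @param y Binary group labels (SZ = 1, HC = 0).
#' @param subject_ids Optional ids.
#' @return A [feature_table()].
#' @export
assemble_feature_table <- function(vectors, y, subject_ids = NULL) {
  if (!length(vectors)) stop("assemble_feature_table: no subjects")
  first <- vectors[[1]]
  idx <- if (is.list(first)) first$feature_index else NULL
  getv <- function(v) if (is.list(v)) v$features else v
  ref <- getv(first)
  for (i in seq_along(vectors)) {
    v <- vectors[[i]]
    if (is.list(v) && !is.null(idx) && !identical(v$feature_index, idx)) {
      div <- which(!(v$feature_index$modality == idx$modality &
                     v$feature_index$region_label == idx$region_label))[1]
      stop("assemble_feature_table: subject ", i,
           " feature index diverges first at feature ", div)
    }
    if (length(getv(v)) != length(ref))
      stop("assemble_feature_table: subject ", i, " has a different length")
  }
  x <- do.call(rbind, lapply(vectors, getv))
  if (is.null(idx)) {
    nm <- names(ref)
    if (is.null(nm)) nm <- sprintf("f%04d", seq_along(ref))
    parts <- strsplit(nm, "__", fixed = TRUE)
    idx <- data.frame(modality = vapply(parts, `[`, "", 1),
                      region_label = seq_along(ref),
                      region_name = vapply(parts, function(p) p[length(p)], ""),
                      stringsAsFactors = FALSE)
  }
  feature_table(x, y, idx, subject_ids)
}

#' Write / read a feature table as TSV
#'
#' Layout: header `subject_id`, `group` (SZ = 1 / HC = 0), then one column
#' per feature named `<modality>__<region_name>`. Values are written with
#' full double precision, so a write/read round trip is numerically lossless
#' far beyond 12 significant digits.
#'
#' @param tab A [feature_table()].
#' @param path Output path.
#' @return `write_feature_table` returns `path` invisibly;
#'   `read_feature_table` returns a [feature_table()].
#' @export
write_feature_table <- function(tab, path) {
  stopifnot(inherits(tab, "feature_table"))
  df <- data.frame(subject_id = tab$subject_ids, group = tab$y,
                   check.names = FALSE, stringsAsFactors = FALSE)
  xv <- as.data.frame(tab$x, check.names = FALSE)
  xv[] <- lapply(xv, function(col) sprintf("%.17g", col))
  utils::write.table(cbind(df, xv), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @param feature_index Optional explicit index; reconstructed from the
#'   column names otherwise.
#' @export
read_feature_table <- function(path, feature_index = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("subject_id", "group")
  if (!all(need %in% names(df)))
    stop("read_feature_table: missing subject_id/group columns")
  featcols <- setdiff(names(df), need)
  x <- as.matrix(df[, featcols, drop = FALSE])
  if (is.null(feature_index)) {
    parts <- strsplit(featcols, "__", fixed = TRUE)
    feature_index <- data.frame(
      modality = vapply(parts, `[`, "", 1),
      region_label = as.integer(stats::ave(seq_along(featcols),
        vapply(parts, `[`, "", 1), FUN = seq_along)),
      region_name = vapply(parts, function(p) paste(p[-1], collapse = "__"), ""),
      stringsAsFactors = FALSE)
  }
  feature_table(x, df$group, feature_index, df$subject_id)
}

#' NIfTI I/O for maps and atlases
#'
#' Thin wrappers over RNifti. `write_metric_nifti` also writes a JSON
#' sidecar recording the metric name and processing flags.
#'
#' @param map A [metric_map()]; NA outside-mask values are written as 0.
#' @param path Output `.nii.gz` path.
#' @return The path, invisibly.
#' @export
write_metric_nifti <- function(map, path) {
  stopifnot(inherits(map, "metric_map"))
  v <- map$values
  v[is.na(v)] <- 0
  RNifti::writeNifti(RNifti::asNifti(v), path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(list(metric = map$metric_name,
                            standardized = map$standardized,
                            smoothing_fwhm_mm = map$smoothing_fwhm_mm),
                       sidecar, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_metric_nifti
#' @param metric_name Metric to tag the loaded map with.
#' @export
read_metric_nifti <- function(path, metric_name = "GMD") {
  v <- as.array(RNifti::readNifti(path))
  metric_map(array(as.numeric(v), dim(v)[1:3]), metric_name)
}

#' @rdname write_metric_nifti
#' @param atl An [atlas()]; written as an integer NIfTI plus a `label, name`
#'   TSV lookup next to it.
#' @export
write_atlas_nifti <- function(atl, path) {
  stopifnot(inherits(atl, "atlas"))
  RNifti::writeNifti(RNifti::asNifti(atl$labels), path)
  utils::write.table(atl$lut, sub("\\.nii(\\.gz)?$", ".tsv", path),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metric_nifti
#' @param lut_path Path to the TSV lookup; defaults to `path` with a `.tsv`
#'   extension.
#' @export
read_atlas_nifti <- function(path, lut_path = NULL) {
  if (is.null(lut_path)) lut_path <- sub("\\.nii(\\.gz)?$", ".tsv", path)
  v <- as.array(RNifti::readNifti(path))
  lut <- utils::read.delim(lut_path, stringsAsFactors = FALSE)
  atlas(array(as.integer(round(v)), dim(v)[1:3]), lut)
}
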