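# shared fixture builders; everything is generated in code at test time

five_mods <- c("ALFF", "ReHo", "DC", "VMHC", "GMD")

# effect map planting the same d for each region in every modality
multimodal_effects <- function(regions, d) {
  do.call(rbind, lapply(five_mods, function(m)
    data.frame(region = regions, modality = m, d = d)))
}

# tiny feature table with explicit values, one modality per block
toy_table <- function(x, y, modalities = "A") {
  p <- ncol(x)
  per <- p / length(modalities)
  idx <- data.frame(modality = rep(modalities, each = per),
                    region_label = rep.int(seq_len(per), length(modalities)),
                    region_name = rep.int(sprintf("R%02d", seq_len(per)),
                                          length(modalities)))
  feature_table(x, y, idx)
}

# small 4D image from an explicit t x V matrix of voxel series
img_from_series <- function(series, dims, tr = 2, mask = NULL) {
  stopifnot(prod(dims) == ncol(series))
  data <- array(t(series), c(dims, nrow(series)))
  ts_image(data, tr_seconds = tr, mask = mask)
}
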