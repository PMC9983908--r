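#!/usr/bin/env Rscript
# Peak-based augmentation of the MSC spectra.
#
# The two operators: a random per-peak shift (Gaussian, std dev in
# seconds, applied in linear time coordinates) and a random
# intensity-preserving stretch about the peak centroid (Gaussian, std
# dev as a fraction of peak width).  The selected study parameters are
# 1 % stretch with 5 ms shift for MSCs (factor 5) and 1 % / 1 ms for
# cell lines.  Unmodified parents are kept and flagged, mirroring the
# "_Original" file convention of the source datasets.

library(relaxcell)

seed <- 1L
out_dir <- "results"
files <- list.files(file.path(out_dir, "spectra"), pattern = "^MSC",
                    full.names = TRUE)
spectra <- lapply(files, function(f) {
  s <- read_spectrum_csv(f)
  s$metadata$sample_id <- sub("\\.csv$", "", basename(f))
  s$metadata$class_label <- sub("_[0-9]+$", "", s$metadata$sample_id)
  s
})

aug <- augment_dataset(spectra,
                       augmentation_preset("msc", factor = 5L, seed = seed))
message(sprintf("%d MSC spectra -> %d after factor-5 augmentation",
                length(spectra), length(aug$spectra)))
utils::write.csv(aug$manifest, file.path(out_dir, "augmentation_manifest.csv"),
                 row.names = FALSE)

dir.create(file.path(out_dir, "augmented"), showWarnings = FALSE)
for (s in aug$spectra) {
  suffix <- if (isTRUE(s$metadata$augmented)) "" else "_Original"
  write_spectrum_png(crop_to_cell_window(s),
                     file.path(out_dir, "augmented",
                               paste0(s$metadata$sample_id, suffix, ".png")))
}

# how augmentation spreads the centroid clouds
cen_aug <- centroid_table(aug$spectra)
spread <- do.call(rbind, lapply(split(cen_aug, cen_aug$class_label), function(d) {
  data.frame(class_label = d$class_label[1], n = nrow(d),
             t2_sd = stats::sd(d$t2))
}))
print(spread, digits = 3)
message("augmented maps and lineage manifest written")
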