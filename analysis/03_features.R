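#!/usr/bin/env Rscript
# Weighted-centroid features and cell-window maps.
#
# Every spectrum is reduced to the intensity-weighted centroid of its
# strongest cell-tagged peak (the SVM feature pair), and cropped to the
# cell window T1 <= 3.0079 s / T2 <= 0.4062 s (the network input, which
# excludes the media peak).  Cropped maps are exported as 8-bit
# grayscale PNGs mirroring the exports the original networks consumed.

library(relaxcell)

out_dir <- "results"
files <- list.files(file.path(out_dir, "spectra"), full.names = TRUE)
spectra <- lapply(files, function(f) {
  s <- read_spectrum_csv(f)
  s$metadata$sample_id <- sub("\\.csv$", "", basename(f))
  s$metadata$class_label <- sub("_[0-9]+$", "", s$metadata$sample_id)
  s
})
message(sprintf("loaded %d spectra", length(spectra)))

cen <- centroid_table(spectra)
write_centroids_csv(cen, file.path(out_dir, "centroids.csv"))
excl <- attr(cen, "exclusions")
message(sprintf("centroid records: %d (excluded: %d)", nrow(cen), nrow(excl)))
if (nrow(excl)) utils::write.csv(excl, file.path(out_dir, "exclusions.csv"),
                                 row.names = FALSE)

# per-class centroid summary: the cluster layout that motivates the SVM
summ <- do.call(rbind, lapply(split(cen, cen$class_label), function(d) {
  data.frame(class_label = d$class_label[1], n = nrow(d),
             t1_mean = mean(d$t1), t1_sd = stats::sd(d$t1),
             t2_mean = mean(d$t2), t2_sd = stats::sd(d$t2))
}))
utils::write.csv(summ, file.path(out_dir, "centroid_summary.csv"),
                 row.names = FALSE)
print(summ, digits = 3)

dir.create(file.path(out_dir, "maps"), showWarnings = FALSE)
for (s in spectra) {
  cr <- crop_to_cell_window(s)
  write_spectrum_png(cr, file.path(out_dir, "maps",
                                   paste0(s$metadata$sample_id, ".png")))
}
message("cropped cell-window PNG maps written to results/maps/")
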